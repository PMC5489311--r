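#!/usr/bin/env Rscript
# Stage 5: per-pixel seasonal MARS models and variable importance.
#
# For every retained pixel and season, fits a MARS model of the pixel's
# seasonal Chl-a on the season's VIF-retained (spatially constant)
# covariates, then maps training R^2 and the variable of greatest importance
# and tabulates the top-variable percentage shares per season.

suppressPackageStartupMessages(library(bloomdyn))

grid <- read_chl_csv("results/chl_filled.csv")
covariates <- read.csv("results/covariates.csv")
covariates$bin_start <- as.Date(covariates$bin_start)
covariates$season <- season_of(covariates$bin_start)

vifs <- vif_screen_by_season(covariates)
t0 <- Sys.time()
fits <- fit_all_pixels(grid, covariates, vifs)
message(sprintf("%d pixel-season fits (%d skipped) in %.1f min",
                nrow(fits$results),
                if (is.null(fits$skipped)) 0L else nrow(fits$skipped),
                as.numeric(difftime(Sys.time(), t0, units = "mins"))))

r2 <- r2_map(fits)
message("seasonal mean training R^2:")
print(round(r2$means, 3))

imp <- summarize_importance(fits)
message("top-variable shares per season (% of fitted pixels):")
print(cbind(variable = imp$variable, round(imp[, -1], 1)))

write.csv(fits$results, "results/pixel_fits.csv", row.names = FALSE)
write.csv(imp, "results/importance_shares.csv", row.names = FALSE)
for (s in names(r2$maps)) {
  write.csv(r2$maps[[s]], sprintf("results/r2_map_%s.csv", s), row.names = FALSE)
}
jsonlite::write_json(as.list(round(r2$means, 4)), "results/r2_means.json",
                     auto_unbox = TRUE)
message("wrote results/pixel_fits.csv, results/importance_shares.csv, results/r2_map_<season>.csv")
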