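#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# A 20 x 30 pixel biweekly Chl-a grid spanning 5 Jan 2002 - 21 Mar 2012
# (267 bins): annual + semiannual cycles, two nearshore bloom hotspots,
# AR(1) red-noise background, ~20% cloud-like contiguous gaps, plus the
# nine-variable environmental covariate table. Everything downstream reads
# the plain-text files this stage writes.

suppressPackageStartupMessages(library(bloomdyn))
dir.create("results", showWarnings = FALSE)

# water temperature and solar radiation are strongly collinear in reality;
# the injected dependence gives the VIF screening stage real work
cfg <- synthetic_config(
  seed = 1L,
  collinearity = list(list(target = "WTMP", source = "Rs", r2 = 0.95)))
study <- synth_study(cfg)

write_chl_csv(study$truth, "results/chl_truth.csv")
write_chl_csv(study$observed, "results/chl_observed.csv")
write.csv(study$covariates, "results/covariates.csv", row.names = FALSE)

frac <- mean(is.na(study$observed$values))
message(sprintf("grid: %d bins x %d x %d pixels; %.1f%% of cells cloud-masked",
                dim(study$truth)[1], dim(study$truth)[2], dim(study$truth)[3],
                100 * frac))
message(sprintf("pixels above 50%% missing (will be dropped downstream): %d",
                sum(missing_fraction(study$observed) > 0.5)))
message("wrote results/chl_truth.csv, results/chl_observed.csv, results/covariates.csv")
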