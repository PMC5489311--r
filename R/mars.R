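#' Generalized cross-validation score
#'
#' `GCV = RSS / (N * (1 - M/N)^2)` where `M` is the effective number of
#' parameters: it charges the model both for its basis functions and for the
#' knots chosen adaptively during the forward pass.
#'
#' @param rss residual sum of squares.
#' @param n number of training observations.
#' @param m_eff effective number of parameters, `0 < m_eff < n`.
#' @return the GCV score.
#' @export
gcv <- function(rss, n, m_eff) {
  if (m_eff >= n) stop("model saturated: effective parameters >= observations", call. = FALSE)
  if (m_eff <= 0) stop("effective parameters must be positive", call. = FALSE)
  rss / (n * (1 - m_eff / n)^2)
}

# Effective parameters for a subset: number of basis functions plus
# `penalty` (3 when interactions are allowed, 2 for additive models) per
# distinct knot site among the retained terms. A reflected hinge pair shares
# one site; pruning that keeps a lone hinge still pays for its knot.
mars_m_eff <- function(terms, penalty) {
  sites <- unique(unlist(lapply(terms, function(term) {
    vapply(term, function(f) paste(f$var, f$knot), character(1))
  })))
  length(terms) + penalty * length(sites)
}

gcv_safe <- function(rss, n, m_eff) {
  if (m_eff >= n) Inf else gcv(rss, n, m_eff)
}

# A term is a list of hinge factors list(var =, knot =, dir = +1/-1);
# the intercept is the empty list.
term_col <- function(term, X) {
  col <- rep(1, nrow(X))
  for (f in term) col <- col * pmax(f$dir * (X[, f$var] - f$knot), 0)
  col
}

term_vars <- function(term) vapply(term, `[[`, integer(1), "var")

term_label <- function(term, xnames) {
  if (!length(term)) return("(Intercept)")
  paste(vapply(term, function(f) {
    if (f$dir > 0) sprintf("h(%s-%g)", xnames[f$var], f$knot)
    else sprintf("h(%g-%s)", f$knot, xnames[f$var])
  }, character(1)), collapse = "*")
}

basis_matrix <- function(terms, Xmat) {
  vapply(terms, function(term) term_col(term, Xmat), numeric(nrow(Xmat)))
}

#' MARS forward pass
#'
#' Greedy basis construction: starting from the intercept-only model, each
#' step considers the product of every existing basis function with a
#' reflected pair of hinge functions `(x - t)+ / (t - x)+` of every variable
#' not already in that basis function, with candidate knots at all distinct
#' observed values, and adds the pair giving the maximal reduction in the
#' residual sum of squares. Stops at `max_terms` basis functions or when the
#' relative RSS reduction falls below `thresh`. Ties are broken toward the
#' lowest variable index, then the smallest knot.
#'
#' @param X numeric predictor matrix (no missing values).
#' @param y numeric response.
#' @param max_terms maximum number of basis functions including the
#'   intercept; default `min(2 * ncol(X) + 1, 21)`.
#' @param max_degree maximum number of hinge factors per basis function.
#' @param thresh relative RSS-reduction stopping threshold.
#' @param minspan minimum number of observations between candidate knots:
#'   a positive integer, or `"auto"` for Friedman's local-adaptivity formula.
#'   `1` admits every distinct observed value.
#' @param endspan number of observations at each end of the (parent-support)
#'   data excluded from knot candidacy; integer or `"auto"` for Friedman's
#'   formula. `0` disables the guard.
#' @return an unpruned object of class `mars_model`.
#' @export
forward_pass <- function(X, y, max_terms = NULL, max_degree = 2, thresh = 1e-4,
                         minspan = "auto", endspan = "auto") {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (is.null(max_terms)) max_terms <- min(2L * p + 1L, 21L)
  if (n <= max_terms) stop("need more observations than max_terms", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values not supported", call. = FALSE)
  penalty <- if (max_degree > 1) 3 else 2

  terms <- list(list())
  Bcols <- matrix(1, n, 1)
  Q <- matrix(1 / sqrt(n), n, 1)
  r <- y - Q %*% crossprod(Q, y)
  rss <- sum(r^2)
  tss <- rss

  if (tss > 0) {
    repeat {
      if (length(terms) + 2L > max_terms) break
      best <- list(red = 0, parent = NA, var = NA, knot = NA)
      for (pi in seq_along(terms)) {
        term <- terms[[pi]]
        if (length(term) >= max_degree) next
        parent <- Bcols[, pi]
        for (v in setdiff(seq_len(p), term_vars(term))) {
          knots <- candidate_knots(X[, v], parent, p, minspan, endspan)
          if (!length(knots)) next
          D <- outer(X[, v], knots, "-")
          H1 <- pmax(D, 0) * parent
          H2 <- pmax(-D, 0) * parent
          A1 <- H1 - Q %*% crossprod(Q, H1)
          A2 <- H2 - Q %*% crossprod(Q, H2)
          g11 <- colSums(A1^2); g22 <- colSums(A2^2); g12 <- colSums(A1 * A2)
          c1 <- drop(crossprod(A1, r)); c2 <- drop(crossprod(A2, r))
          scale1 <- pmax(colSums(H1^2), 1e-300)
          scale2 <- pmax(colSums(H2^2), 1e-300)
          ok1 <- g11 > 1e-9 * scale1
          ok2 <- g22 > 1e-9 * scale2
          det <- g11 * g22 - g12^2
          joint_ok <- ok1 & ok2 & det > 1e-9 * g11 * g22
          red <- numeric(length(knots))
          red[joint_ok] <- (c1^2 * g22 - 2 * c1 * c2 * g12 + c2^2 * g11)[joint_ok] /
            det[joint_ok]
          single <- !joint_ok
          r1 <- ifelse(ok1, c1^2 / pmax(g11, 1e-300), 0)
          r2 <- ifelse(ok2, c2^2 / pmax(g22, 1e-300), 0)
          red[single] <- pmax(r1, r2)[single]
          jbest <- which.max(red)
          if (length(jbest) && red[jbest] > best$red) {
            best <- list(red = red[jbest], parent = pi, var = v, knot = knots[jbest])
          }
        }
      }
      if (!is.finite(best$red) || is.na(best$parent) || best$red <= 0) break
      if (best$red / rss < thresh || rss < 1e-10 * tss) break

      parent_term <- terms[[best$parent]]
      parent_col <- Bcols[, best$parent]
      for (dir in c(1, -1)) {
        h <- parent_col * pmax(dir * (X[, best$var] - best$knot), 0)
        a <- h - Q %*% crossprod(Q, h)
        if (sum(a^2) <= 1e-9 * max(sum(h^2), 1e-300)) next
        q <- a / sqrt(sum(a^2))
        terms[[length(terms) + 1L]] <- c(parent_term,
                                         list(list(var = best$var, knot = best$knot, dir = dir)))
        Bcols <- cbind(Bcols, h)
        Q <- cbind(Q, q)
        r <- r - q * drop(crossprod(q, r))
      }
      rss_new <- sum(r^2)
      if (rss - rss_new <= 0) break
      rss <- rss_new
    }
  }

  coef <- qr.coef(qr(Bcols), y)
  coef[is.na(coef)] <- 0
  fitted <- drop(Bcols %*% coef)
  rss <- sum((y - fitted)^2)
  structure(
    list(terms = terms, coefficients = coef, fitted = fitted,
         rss = rss, tss = tss, n = n, p = p, xnames = colnames(X),
         max_degree = max_degree, penalty = penalty,
         gcv = gcv_safe(rss, n, mars_m_eff(terms, penalty)),
         prune_trace = NULL, pruned = FALSE),
    class = "mars_model"
  )
}

# Candidate knots for splitting variable `xv` under a given parent basis
# function: order statistics of xv over the parent's support, thinned by
# `minspan` and kept `endspan` observations clear of the support ends
# (Friedman's knot-placement guards against fitting runs of correlated
# noise; "auto" uses his alpha = 0.05 formulas).
candidate_knots <- function(xv, parent, p, minspan = "auto", endspan = "auto") {
  v <- sort(xv[parent != 0])
  nn <- length(v)
  if (nn < 2) return(numeric(0))
  L <- if (identical(minspan, "auto")) {
    max(1L, floor(-log2(-log(0.95) / (nn * p)) / 2.5))
  } else max(1L, as.integer(minspan))
  Le <- if (identical(endspan, "auto")) {
    max(1L, floor(3 - log2(0.05 / p)))
  } else max(0L, as.integer(endspan))
  lo <- 1L + Le; hi <- nn - Le
  if (lo > hi) return(numeric(0))
  unique(v[seq(lo, hi, by = L)])
}

#' MARS backward pruning pass
#'
#' Starting from the unpruned model, repeatedly deletes the basis function
#' (never the intercept) whose removal least increases the residual sum of
#' squares, producing one best subset of each size; the returned model is the
#' subset with the smallest GCV. The full pruning trace -- term set, RSS and
#' GCV per subset -- is retained for variable-importance computation.
#'
#' @param model an unpruned `mars_model` from [forward_pass()].
#' @param X,y the training data the model was fitted on.
#' @return a pruned `mars_model` with `prune_trace`.
#' @export
backward_prune <- function(model, X, y) {
  stopifnot(inherits(model, "mars_model"))
  X <- as.matrix(X)
  B <- basis_matrix(model$terms, X)
  n <- model$n
  M <- length(model$terms)

  rss_of <- function(cols) {
    fit <- stats::lm.fit(B[, cols, drop = FALSE], y)
    sum(fit$residuals^2)
  }

  active <- seq_len(M)
  trace <- list(list(terms_idx = active, rss = model$rss,
                     gcv = gcv_safe(model$rss, n,
                                    mars_m_eff(model$terms, model$penalty))))
  while (length(active) > 1L) {
    drop_cand <- active[active != 1L]
    rss_d <- vapply(drop_cand, function(j) rss_of(setdiff(active, j)), numeric(1))
    j <- drop_cand[which.min(rss_d)]
    active <- setdiff(active, j)
    trace[[length(trace) + 1L]] <- list(
      terms_idx = active, rss = min(rss_d),
      gcv = gcv_safe(min(rss_d), n,
                     mars_m_eff(model$terms[active], model$penalty)))
  }

  gcvs <- vapply(trace, `[[`, numeric(1), "gcv")
  best <- trace[[which.min(gcvs)]]
  keep <- best$terms_idx
  coef <- qr.coef(qr(B[, keep, drop = FALSE]), y)
  coef[is.na(coef)] <- 0
  fitted <- drop(B[, keep, drop = FALSE] %*% coef)
  rss <- sum((y - fitted)^2)

  out <- model
  out$selected_idx <- keep
  out$terms <- model$terms[keep]
  out$coefficients <- coef
  out$fitted <- fitted
  out$rss <- rss
  out$gcv <- gcv_safe(rss, n, mars_m_eff(model$terms[keep], model$penalty))
  out$prune_trace <- list(subsets = trace, all_terms = model$terms)
  out$pruned <- TRUE
  out
}

#' Fit a MARS model
#'
#' Forward pass then GCV backward pruning.
#'
#' @inheritParams forward_pass
#' @return a pruned `mars_model`; `r2` is the training R-squared.
#' @export
mars <- function(X, y, max_terms = NULL, max_degree = 2, thresh = 1e-4,
                 minspan = "auto", endspan = "auto") {
  fwd <- forward_pass(X, y, max_terms = max_terms, max_degree = max_degree,
                      thresh = thresh, minspan = minspan, endspan = endspan)
  fit <- backward_prune(fwd, X, y)
  fit$r2 <- if (fit$tss > 0) min(1, max(0, 1 - fit$rss / fit$tss)) else 0
  fit
}

#' @export
print.mars_model <- function(x, ...) {
  cat(sprintf("<mars_model> %d basis functions (n = %d, p = %d)%s\n",
              length(x$terms), x$n, x$p, if (x$pruned) ", pruned" else ""))
  lbl <- vapply(x$terms, term_label, character(1), xnames = x$xnames)
  for (i in seq_along(lbl)) {
    cat(sprintf("  %+.4g * %s\n", x$coefficients[i], lbl[i]))
  }
  cat(sprintf("  RSS %.4g, GCV %.4g%s\n", x$rss, x$gcv,
              if (!is.null(x$r2)) sprintf(", R2 %.3f", x$r2) else ""))
  invisible(x)
}

#' @export
predict.mars_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  drop(basis_matrix(object$terms, X) %*% object$coefficients)
}

#' Variable importance on the three standard criteria
#'
#' From the pruning trace: (1) `nsubsets`, the number of pruning subsets that
#' include the variable; (2) `rss`, the decrease in RSS of each subset
#' relative to the previous (smaller) subset, accrued to every variable in
#' the subset, summed and scaled so the largest score is 100; (3) `gcv`, the
#' same with GCV decreases. The top variable is chosen by `nsubsets`, ties
#' broken by the RSS criterion, then by canonical column order.
#'
#' @param model a pruned `mars_model`.
#' @return data.frame (one row per predictor, in column order) with the three
#'   scores; attributes `top` (top variable name, `NA` for an intercept-only
#'   model) and `intercept_only`.
#' @export
importance <- function(model) {
  stopifnot(inherits(model, "mars_model"))
  if (is.null(model$prune_trace)) stop("model has no pruning trace; use mars()", call. = FALSE)
  p <- model$p
  nsub <- rss_crit <- gcv_crit <- numeric(p)
  subsets <- rev(model$prune_trace$subsets)   # ascending size: 1 .. M terms
  all_terms <- model$prune_trace$all_terms
  prev <- NULL
  for (s in subsets) {
    vars_in <- unique(unlist(lapply(all_terms[s$terms_idx], term_vars)))
    nsub[vars_in] <- nsub[vars_in] + 1L
    if (!is.null(prev) && length(vars_in)) {
      rss_crit[vars_in] <- rss_crit[vars_in] + (prev$rss - s$rss)
      if (is.finite(prev$gcv) && is.finite(s$gcv)) {
        gcv_crit[vars_in] <- gcv_crit[vars_in] + (prev$gcv - s$gcv)
      }
    }
    prev <- s
  }
  scale100 <- function(x) if (max(x) > 0) 100 * x / max(x) else x
  out <- data.frame(variable = model$xnames,
                    nsubsets = nsub,
                    rss = scale100(rss_crit),
                    gcv = scale100(gcv_crit))
  intercept_only <- all(nsub == 0)
  top <- if (intercept_only) NA_character_ else {
    ord <- order(-out$nsubsets, -out$rss, seq_len(p))
    model$xnames[ord[1L]]
  }
  attr(out, "top") <- top
  attr(out, "intercept_only") <- intercept_only
  out
}

#' Serialize a MARS model to JSON
#'
#' Basis functions, coefficients and the pruning trace in a plain format an
#' external MARS implementation can be compared against.
#'
#' @param model a `mars_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
mars_to_json <- function(model, path) {
  obj <- list(
    xnames = model$xnames,
    coefficients = unname(model$coefficients),
    terms = lapply(model$terms, function(term) {
      lapply(term, function(f) list(var = model$xnames[f$var],
                                    knot = f$knot, dir = f$dir))
    }),
    rss = model$rss, gcv = model$gcv, n = model$n
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a fitting problem as plain-text fixture files
#'
#' Writes `<prefix>_xy.csv` (predictors plus a `y` column) so the identical
#' data can be fed to an external reference implementation for cross-checks.
#'
#' @param X,y the fitting problem.
#' @param prefix file-path prefix.
#' @return the CSV path, invisibly.
#' @export
export_mars_fixture <- function(X, y, prefix) {
  df <- as.data.frame(X)
  df$y <- y
  path <- paste0(prefix, "_xy.csv")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
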