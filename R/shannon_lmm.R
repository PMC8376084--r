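#' Fit the log-Shannon linear mixed model
#'
#' REML fit of `log(H) ~ 1 + ig_class * cohort * stage + (1 | dog_id)`
#' (factors with a single observed level are dropped from the fixed part).
#' Samples with Shannon index <= 0 cannot enter the log-scale model; they
#' are excluded and reported.
#'
#' @param h named numeric vector of per-sample Shannon indices (see
#'   [sample_shannon()]).
#' @param metadata metadata whose `sample_id` covers `names(h)`.
#' @param formula optional model formula overriding the default; must use a
#'   `log_shannon` response and a `(1 | dog_id)` random term.
#' @return list of class `lmm_fit`: `fit` (the `lmerMod`), `beta`, `vcov`,
#'   `sigma_dog2`, `sigma_resid2`, `data`, `excluded` (sample ids with
#'   H <= 0), `factors` (fixed-effect factor levels used).
#' @export
fit_shannon_lmm <- function(h, metadata, formula = NULL) {
  validate_metadata(metadata)
  md <- metadata[match(names(h), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("all samples in h must appear in metadata")
  excluded <- names(h)[h <= 0 | !is.finite(h)]
  keep <- !(names(h) %in% excluded)
  dat <- data.frame(log_shannon = log(h[keep]), md[keep, , drop = FALSE])
  dat$ig_class <- factor(dat$ig_class, levels = c("IgA", "IgG"))
  dat$cohort <- factor(dat$cohort,
                       levels = intersect(c("healthy", "DRE", "ARE", "IRE"),
                                          unique(dat$cohort)))
  dat$stage <- factor(dat$stage, levels = intersect(c("before", "after"),
                                                    unique(dat$stage)))
  if (length(unique(dat$dog_id)) < 2) stop("need at least two dogs")
  if (is.null(formula)) {
    fixed <- c("ig_class", "cohort", "stage")
    fixed <- fixed[vapply(fixed, function(f) nlevels(droplevels(dat[[f]])) > 1,
                          logical(1))]
    for (f in fixed) dat[[f]] <- droplevels(dat[[f]])
    rhs <- if (length(fixed)) paste(fixed, collapse = " * ") else "1"
    formula <- as.formula(paste("log_shannon ~", rhs, "+ (1 | dog_id)"))
  }
  fit <- lme4::lmer(formula, data = dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_dog2 <- vc$vcov[vc$grp == "dog_id"]
  sigma_resid2 <- vc$vcov[vc$grp == "Residual"]
  structure(list(fit = fit, beta = lme4::fixef(fit),
                 vcov = as.matrix(vcov(fit)),
                 sigma_dog2 = sigma_dog2, sigma_resid2 = sigma_resid2,
                 data = dat, excluded = excluded),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("log-Shannon LMM: %d obs, %d dogs; sigma_dog^2 = %.4g, sigma_resid^2 = %.4g\n",
              nrow(x$data), length(unique(x$data$dog_id)),
              x$sigma_dog2, x$sigma_resid2))
  if (length(x$excluded))
    cat("excluded (Shannon <= 0):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Nakagawa coefficients of determination from variance components
#'
#' `marginal = var_fixed / (var_fixed + var_random + var_resid)`;
#' `conditional = (var_fixed + var_random) / (same denominator)`. For a
#' binomial-logit GLMM, pass `var_resid = pi^2 / 3` (the latent logistic
#' distribution variance).
#'
#' @param var_fixed variance of the fixed-effect linear predictor.
#' @param var_random summed random-effect variance on the link scale.
#' @param var_resid residual (or link-scale distribution-specific) variance.
#' @return named numeric: `marginal`, `conditional`.
#' @export
nakagawa_r2 <- function(var_fixed, var_random, var_resid) {
  stopifnot(var_fixed >= 0, var_random >= 0, var_resid >= 0)
  denom <- var_fixed + var_random + var_resid
  c(marginal = var_fixed / denom,
    conditional = (var_fixed + var_random) / denom)
}

#' Marginal and conditional R-squared of the log-Shannon LMM
#'
#' Plug-in of the fitted fixed-effect variance (population variance of the
#' fixed linear predictor over the data rows) and the REML variance
#' components into [nakagawa_r2()].
#'
#' @param fit an `lmm_fit` from [fit_shannon_lmm()].
#' @return named numeric: `marginal`, `conditional`.
#' @export
lmm_r2 <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  X <- model.matrix(fit$fit)
  eta <- drop(X %*% fit$beta)
  vf <- mean((eta - mean(eta))^2)
  nakagawa_r2(vf, fit$sigma_dog2, fit$sigma_resid2)
}

# equal-weight averaging matrix over non-grid factors of a fitted fixed part
reference_grid_lincomb <- function(fit, grid) {
  tt <- stats::delete.response(stats::terms(fit$fit))
  fac <- all.vars(tt)
  lev <- lapply(fac, function(f) levels(fit$data[[f]]))
  names(lev) <- fac
  full <- expand.grid(lev, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (f in fac) full[[f]] <- factor(full[[f]], levels = lev[[f]])
  Xfull <- model.matrix(tt, full)
  t(vapply(seq_len(nrow(grid)), function(i) {
    sel <- rep(TRUE, nrow(full))
    for (f in intersect(names(grid), fac))
      sel <- sel & full[[f]] == as.character(grid[[f]][i])
    if (!any(sel)) stop("grid cell outside fitted factor levels")
    colMeans(Xfull[sel, , drop = FALSE])
  }, numeric(ncol(Xfull))))
}

#' Estimated marginal means with confidence intervals
#'
#' For each grid cell, averages the fixed-effect predictions over the
#' levels of all non-grid factors with equal weights (the reference-grid
#' convention) and reports a normal-approximation confidence interval from
#' the fixed-effect covariance. Estimates are on the model (log) scale;
#' `exponentiate = TRUE` adds back-transformed columns.
#'
#' @param fit an `lmm_fit`.
#' @param grid data.frame of factor combinations (columns a subset of the
#'   fitted factors).
#' @param level confidence level (default 0.95).
#' @param exponentiate also report `exp(estimate)` and its interval.
#' @return data.frame: grid columns, `estimate`, `se`, `lower`, `upper`.
#' @export
marginal_means <- function(fit, grid, level = 0.95, exponentiate = FALSE) {
  stopifnot(inherits(fit, "lmm_fit"), level > 0, level < 1)
  L <- reference_grid_lincomb(fit, grid)
  est <- drop(L %*% fit$beta)
  se <- sqrt(rowSums((L %*% fit$vcov) * L))
  z <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(grid, estimate = est, se = se,
                    lower = est - z * se, upper = est + z * se,
                    row.names = NULL)
  if (exponentiate) {
    out$response <- exp(est)
    out$response_lower <- exp(out$lower)
    out$response_upper <- exp(out$upper)
  }
  out
}
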