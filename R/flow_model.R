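#' Fit the hierarchical binomial model for Ig-coating proportions
#'
#' Bayesian binomial-logit regression for flow-cytometry coating counts:
#' `positive_i ~ Binomial(total_i, plogis(x_i' beta + u_d + v_d * IgG_i))`
#' with correlated per-dog random intercept and IgG slope,
#' `(u_d, v_d) ~ N(0, Sigma)`. Priors: improper flat on `beta` by default
#' (`prior_sd = 0`; set e.g. `prior_sd = 10` for a weak normal prior),
#' half-Student-t(3, 0, 2.5) on the random-effect SDs, and a flat (LKJ(1))
#' prior on the correlation. Sampling is adaptive Metropolis-within-Gibbs;
#' see the package vignette for the proposal scheme.
#'
#' Convergence is checked against the split R-hat < 1.05 and ESS > 100
#' gate; an offending fit is returned with a warning and flagged in
#' `$meta$convergence`, never silently accepted.
#'
#' @param counts data.frame of flow counts with columns `dog_id`, `cohort`,
#'   `stage`, `ig_class`, `positive`, `total` (see
#'   [simulate_flow_counts()]).
#' @param design optional [build_design()] result; built from `counts` by
#'   default.
#' @param chains number of chains (>= 2, required by the diagnostics).
#' @param iter kept iterations per chain.
#' @param warmup warmup (adaptation) iterations per chain, discarded.
#' @param seed integer seed; chain c uses the sub-seed
#'   `spawn_seed(seed, "flow_chain_c")`.
#' @param prior_sd SD of a mean-zero normal prior on `beta`; 0 = flat.
#' @param hyper_scale scale of the half-t(3) hyperprior on the SDs.
#' @param check run the convergence gate (default TRUE).
#' @return a [posterior_draws()] with parameters `beta` (named by design
#'   columns), `u[dog]`, `v[dog]`, `sigma_u`, `sigma_v`, `rho`; the design
#'   is attached as attribute `design`.
#' @export
fit_flow_model <- function(counts, design = NULL, chains = 4, iter = 1000,
                           warmup = 1000, seed = 1L, prior_sd = 0,
                           hyper_scale = 2.5, check = TRUE) {
  if (chains < 2) stop("at least 2 chains are required for split-chain diagnostics")
  stopifnot(iter >= 4, warmup >= 20)
  if (any(counts$positive < 0) || any(counts$positive > counts$total) ||
      any(counts$total < 1))
    stop("need 0 <= positive <= total and total >= 1")
  if (is.null(design)) design <- build_design(counts)
  if (nrow(design$fixed) != nrow(counts))
    stop("design rows must align with counts rows")
  if (length(design$dog_ids) < 2) stop("need at least 2 dogs")

  D <- length(design$dog_ids)
  pn <- c(design$term_names,
          paste0("u[", design$dog_ids, "]"),
          paste0("v[", design$dog_ids, "]"),
          "sigma_u", "sigma_v", "rho")
  ch <- lapply(seq_len(chains), function(c) {
    with_seed(spawn_seed(seed, paste0("flow_chain_", c)),
      flow_mcmc_cpp(as.numeric(counts$positive), as.numeric(counts$total),
                    design$fixed, design$dog_index - 1L,
                    as.numeric(design$ig), D,
                    as.integer(warmup), as.integer(iter),
                    prior_sd, hyper_scale))
  })
  arr <- array(0, dim = c(chains, iter, length(pn)),
               dimnames = list(NULL, NULL, pn))
  for (c in seq_len(chains)) arr[c, , ] <- ch[[c]]
  fit <- posterior_draws(arr, meta = list(
    model = "flow_binomial", seed = seed, chains = chains, iter = iter,
    warmup = warmup, prior_sd = prior_sd, hyper_scale = hyper_scale))
  attr(fit, "design") <- design
  if (check) {
    gate <- check_convergence(
      fit, params = c(design$term_names, "sigma_u", "sigma_v"))
    fit$meta$convergence <- gate
    if (!gate$ok)
      warning("convergence gate failed for: ",
              paste(gate$flagged$parameter, collapse = ", "),
              " (split R-hat > 1.05 or ESS < 100)")
  }
  fit
}

flow_beta_draws <- function(fit) {
  design <- attr(fit, "design")
  pooled_draws(fit, design$term_names)
}

#' Posterior predicted coating proportions
#'
#' For each factor combination of `grid`, summarises the posterior of the
#' coating proportion. In `"population"` mode random effects are fixed at
#' zero: `p = plogis(x' beta)`. In `"marginal"` mode each posterior draw is
#' averaged over `n_mc` Monte-Carlo draws of `(u, v) ~ N(0, Sigma)` using
#' that draw's Sigma, giving the population-averaged proportion.
#'
#' @param fit a flow-model [posterior_draws()].
#' @param grid data.frame of factor combinations (levels within the fitted
#'   levels); default = all fitted combinations.
#' @param interval_mass credible-interval mass (default 0.90).
#' @param mode `"population"` or `"marginal"`.
#' @param n_mc Monte-Carlo draws per posterior draw in marginal mode.
#' @param seed seed for the marginalisation draws.
#' @return data.frame: grid columns, `median`, `lower`, `upper`.
#' @export
predict_proportions <- function(fit, grid = NULL, interval_mass = 0.90,
                                mode = c("population", "marginal"),
                                n_mc = 100, seed = 1L) {
  mode <- match.arg(mode)
  design <- attr(fit, "design")
  if (is.null(design)) stop("fit carries no design")
  if (is.null(grid))
    grid <- expand.grid(design$factor_levels, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  Xg <- design_grid_matrix(design, grid)
  beta <- flow_beta_draws(fit)
  eta <- beta %*% t(Xg)                    # draws x cells
  if (mode == "population") {
    p <- plogis(eta)
  } else {
    ig <- if ("ig_class" %in% names(grid))
      as.integer(grid$ig_class == "IgG") else integer(nrow(grid))
    su <- as.vector(t(param_draws(fit, "sigma_u")))
    sv <- as.vector(t(param_draws(fit, "sigma_v")))
    rho <- as.vector(t(param_draws(fit, "rho")))
    p <- with_seed(seed, {
      z1 <- matrix(rnorm(nrow(beta) * n_mc), nrow(beta))
      z2 <- matrix(rnorm(nrow(beta) * n_mc), nrow(beta))
      u <- z1 * su
      v <- (rho * z1 + sqrt(1 - rho^2) * z2) * sv
      out <- matrix(0, nrow(beta), nrow(Xg))
      for (cell in seq_len(nrow(Xg)))
        out[, cell] <- rowMeans(plogis(eta[, cell] + u + v * ig[cell]))
      out
    })
  }
  ci <- apply(p, 2, central_interval, mass = interval_mass)
  data.frame(grid, median = apply(p, 2, median),
             lower = ci[1, ], upper = ci[2, ], row.names = NULL)
}

#' Marginal and conditional R-squared of the binomial GLMM
#'
#' Nakagawa decomposition on the logit scale, computed per posterior draw
#' and summarised by the median: fixed-effect variance `var(X beta)` over
#' the fitted rows; random-effect variance
#' `sigma_u^2 + 2 rho sigma_u sigma_v mean(ig) + sigma_v^2 mean(ig^2)`
#' (the mean quadratic form of the per-dog effect over the design);
#' residual variance `pi^2 / 3` (latent logistic).
#'
#' @param fit a flow-model [posterior_draws()].
#' @param design optional design override (defaults to the fitted one).
#' @return named numeric: `marginal`, `conditional`.
#' @export
glmm_r2 <- function(fit, design = NULL) {
  design <- design %||% attr(fit, "design")
  if (is.null(design)) stop("fit carries no design")
  beta <- flow_beta_draws(fit)
  eta <- beta %*% t(design$fixed)
  vf <- apply(eta, 1, function(e) mean((e - mean(e))^2))
  su <- as.vector(t(param_draws(fit, "sigma_u")))
  sv <- as.vector(t(param_draws(fit, "sigma_v")))
  rho <- as.vector(t(param_draws(fit, "rho")))
  mi <- mean(design$ig); mi2 <- mean(design$ig^2)
  vr <- su^2 + 2 * rho * su * sv * mi + sv^2 * mi2
  vres <- pi^2 / 3
  marg <- vf / (vf + vr + vres)
  cond <- (vf + vr) / (vf + vr + vres)
  c(marginal = median(marg), conditional = median(cond))
}

#' Write posterior summaries as TSV
#' @param fit a [posterior_draws()].
#' @param path output path.
#' @param interval_mass credible-interval mass.
#' @export
write_posterior_summary <- function(fit, path, interval_mass = 0.9) {
  write.table(posterior_summary(fit, interval_mass), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
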