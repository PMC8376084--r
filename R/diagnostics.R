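#' Posterior draws container
#'
#' Wraps MCMC output as a chains x iterations x parameters array with
#' parameter names and sampler metadata (seed, warmup, acceptance rates).
#'
#' @param draws 3-d numeric array (chains x iterations x parameters) with
#'   parameter dimnames.
#' @param meta list of sampler metadata.
#' @return object of class `posterior_draws`.
#' @export
posterior_draws <- function(draws, meta = list()) {
  stopifnot(is.array(draws), length(dim(draws)) == 3)
  if (is.null(dimnames(draws)[[3]]))
    stop("parameter names required on the third dimension")
  if (any(!is.finite(draws))) stop("all draws must be finite")
  structure(list(draws = draws, param_names = dimnames(draws)[[3]],
                 meta = meta), class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("posterior_draws: %d chains x %d iterations x %d parameters\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Extract one parameter's draws as a chains x iterations matrix
#' @param x a `posterior_draws`.
#' @param name parameter name.
#' @return numeric matrix.
#' @export
param_draws <- function(x, name) {
  stopifnot(inherits(x, "posterior_draws"))
  x$draws[, , name, drop = TRUE]
}

#' Pool all chains of selected parameters into a draws matrix
#' @param x a `posterior_draws`.
#' @param names parameter names (default all).
#' @return matrix, total draws x parameters.
#' @export
pooled_draws <- function(x, names = x$param_names) {
  stopifnot(inherits(x, "posterior_draws"))
  do.call(cbind, lapply(names, function(nm) as.vector(t(param_draws(x, nm))))) |>
    (\(m) { colnames(m) <- names; m })()
}

split_chains <- function(m) {
  # m: chains x iterations -> 2*chains x floor(n/2)
  n <- ncol(m) %/% 2
  rbind(m[, seq_len(n), drop = FALSE],
        m[, ncol(m) - n + seq_len(n), drop = FALSE])
}

#' Split-chain Gelman-Rubin diagnostic (R-hat)
#'
#' Potential scale reduction factor computed on split chains: each chain is
#' halved so within-chain drift also inflates the statistic. Values near 1
#' indicate convergence. Parameters with zero within-chain variance return
#' `NA` (diagnostic undefined) rather than failing.
#'
#' @param x a `posterior_draws` (or a chains x iterations matrix).
#' @param params parameter names (default all).
#' @return named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(x, params = NULL) {
  mats <- draws_matrices(x, params)
  vapply(mats, function(m) {
    m <- split_chains(m)
    if (nrow(m) < 2 || ncol(m) < 2) return(NA_real_)
    n <- ncol(m)
    means <- rowMeans(m)
    vars <- apply(m, 1, var)
    W <- mean(vars)
    B <- n * var(means)
    if (!is.finite(W) || W <= 0) return(NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Effective sample size
#'
#' Autocorrelation-based ESS on split chains, using the mean within-chain
#' autocovariance, Geyer's initial-positive and initial-monotone sequence
#' truncation, and a cap at the total number of draws. Constant parameters
#' return `NA`.
#'
#' @inheritParams gelman_rubin
#' @return named numeric vector of effective sample sizes.
#' @export
effective_sample_size <- function(x, params = NULL) {
  mats <- draws_matrices(x, params)
  vapply(mats, function(m) {
    total <- length(m)
    m <- split_chains(m)
    n <- ncol(m); nc <- nrow(m)
    if (n < 4) return(NA_real_)
    vars <- apply(m, 1, var)
    W <- mean(vars)
    if (!is.finite(W) || W <= 0) return(NA_real_)
    B <- n * var(rowMeans(m))
    var_plus <- (n - 1) / n * W + B / n
    # mean autocovariance across chains
    acov <- rowMeans(vapply(seq_len(nc), function(c) {
      a <- acf(m[c, ], lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
      a * (n - 1) / n
    }, numeric(n)))
    rho <- 1 - (W - acov) / var_plus   # rho[1] is lag 0 ( = 1 up to FP)
    # Geyer initial positive sequence over pairs
    max_pairs <- (n - 1) %/% 2
    P <- numeric(0)
    for (t in seq_len(max_pairs)) {
      p <- rho[2 * t] + rho[2 * t + 1]
      if (p <= 0) break
      P <- c(P, p)
    }
    if (length(P) > 1) P <- cummin(P)  # initial monotone sequence
    tau <- max(-1 + 2 * sum(P), 1 / total)
    min(total, total / tau)
  }, numeric(1))
}

draws_matrices <- function(x, params) {
  if (inherits(x, "posterior_draws")) {
    params <- params %||% x$param_names
    setNames(lapply(params, function(nm) param_draws(x, nm)), params)
  } else if (is.matrix(x)) {
    list(par = x)
  } else stop("x must be posterior_draws or a chains x iterations matrix")
}

#' Posterior summary table with convergence diagnostics
#'
#' @param x a `posterior_draws`.
#' @param interval_mass credible-interval mass (default 0.9).
#' @param params parameter names (default all).
#' @return data.frame: parameter, median, interval bounds, R-hat, ESS.
#' @export
posterior_summary <- function(x, interval_mass = 0.9, params = NULL) {
  stopifnot(inherits(x, "posterior_draws"))
  params <- params %||% x$param_names
  rhat <- gelman_rubin(x, params)
  ess <- effective_sample_size(x, params)
  rows <- lapply(params, function(nm) {
    dr <- as.vector(param_draws(x, nm))
    ci <- central_interval(dr, interval_mass)
    data.frame(parameter = nm, median = median(dr),
               lower = ci[1], upper = ci[2],
               rhat = rhat[[nm]], ess = ess[[nm]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Check a fit against the convergence gate
#'
#' Flags parameters with split R-hat above `rhat_max` or ESS below
#' `ess_min`. The result is attached so downstream summaries can refuse to
#' silently use an unconverged fit.
#'
#' @param x a `posterior_draws`.
#' @param rhat_max maximum acceptable split R-hat (default 1.05).
#' @param ess_min minimum acceptable ESS (default 100).
#' @param params parameters to check (default all).
#' @return list: `ok` (logical), `flagged` (data.frame of offenders).
#' @export
check_convergence <- function(x, rhat_max = 1.05, ess_min = 100,
                              params = NULL) {
  s <- posterior_summary(x, params = params)
  bad <- !is.na(s$rhat) & (s$rhat > rhat_max | s$ess < ess_min)
  list(ok = !any(bad), flagged = s[bad, , drop = FALSE])
}
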