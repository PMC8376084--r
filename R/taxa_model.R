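#' Fit the hierarchical multinomial model for taxon counts
#'
#' Baseline-category multinomial logistic regression over M focal taxa plus
#' an `other` reference (the last row of `table`): for taxon m,
#' `log(p_m / p_other) = x' beta_m + u_{d,m}`, with per-sample counts
#' `Multinomial(depth, softmax)`, independent per-dog, per-taxon random
#' intercepts `u_{d,m} ~ N(0, sigma_m)`, `N(0, 5)` priors on all regression
#' coefficients and half-Student-t(3, 0, 2.5) hyperpriors on the
#' `sigma_m`. Following the study design this is fitted per Ig-class
#' dataset, with the sorting fraction, disease cohort and treatment stage
#' (and their interactions) as fixed effects.
#'
#' Taxa with all-zero counts are tolerated with a warning (their posterior
#' is prior-driven).
#'
#' @param table a [feature_table()] whose rows are the focal taxa with
#'   `other` last (see [aggregate_top_taxa()]) and whose columns are
#'   samples present in `metadata`.
#' @param metadata sample metadata.
#' @param factors,reference_levels fixed-effect factors, as in
#'   [build_design()]; defaults are fraction x cohort x stage with
#'   references presort / healthy / before.
#' @inheritParams fit_flow_model
#' @return a [posterior_draws()] with parameters `b[term|taxon]`,
#'   `u[dog|taxon]`, `sigma[taxon]`; design and taxon names attached as
#'   attributes.
#' @export
fit_taxa_model <- function(table, metadata,
                           factors = c("fraction", "cohort", "stage"),
                           reference_levels = c(fraction = "presort",
                                                cohort = "healthy",
                                                stage = "before"),
                           chains = 4, iter = 1000, warmup = 1000,
                           seed = 1L, prior_sd = 5, hyper_scale = 2.5,
                           check = TRUE) {
  stopifnot(is_feature_table(table))
  if (chains < 2) stop("at least 2 chains are required for split-chain diagnostics")
  if (nrow(table) < 2) stop("need at least one focal taxon plus 'other'")
  if (rownames(table)[nrow(table)] != "other")
    stop("the last row of table must be the 'other' reference category")
  md <- metadata[match(colnames(table), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("all table samples must appear in metadata")
  design <- build_design(md, factors, reference_levels)
  if (length(design$dog_ids) < 2) stop("need at least 2 dogs")
  taxa <- rownames(table)[-nrow(table)]
  zero <- taxa[rowSums(table)[-nrow(table)] == 0]
  if (length(zero))
    warning("taxa with all-zero counts (posterior driven by the prior): ",
            paste(zero, collapse = ", "))

  Y <- t(ft_unclass(table))                    # samples x (M + 1)
  M <- length(taxa); P <- ncol(design$fixed)
  D <- length(design$dog_ids)
  pn <- c(
    as.vector(outer(design$term_names, taxa,
                    function(tm, tx) paste0("b[", tm, "|", tx, "]"))),
    as.vector(outer(design$dog_ids, taxa,
                    function(d, tx) paste0("u[", d, "|", tx, "]"))),
    paste0("sigma[", taxa, "]"))
  ch <- lapply(seq_len(chains), function(c) {
    with_seed(spawn_seed(seed, paste0("taxa_chain_", c)),
      taxa_mcmc_cpp(Y, design$fixed, design$dog_index - 1L, D,
                    as.integer(warmup), as.integer(iter),
                    prior_sd, hyper_scale))
  })
  arr <- array(0, dim = c(chains, iter, length(pn)),
               dimnames = list(NULL, NULL, pn))
  for (c in seq_len(chains)) arr[c, , ] <- ch[[c]]
  fit <- posterior_draws(arr, meta = list(
    model = "taxa_multinomial", seed = seed, chains = chains, iter = iter,
    warmup = warmup, prior_sd = prior_sd, hyper_scale = hyper_scale))
  attr(fit, "design") <- design
  attr(fit, "taxa") <- taxa
  if (check) {
    gate <- check_convergence(fit, params = pn[seq_len(P * M)])
    fit$meta$convergence <- gate
    if (!gate$ok)
      warning("convergence gate failed for: ",
              paste(gate$flagged$parameter, collapse = ", "),
              " (split R-hat > 1.05 or ESS < 100)")
  }
  fit
}

taxa_beta_draws <- function(fit) {
  design <- attr(fit, "design")
  taxa <- attr(fit, "taxa")
  # list over taxa of draws x P matrices
  setNames(lapply(taxa, function(tx)
    pooled_draws(fit, paste0("b[", design$term_names, "|", tx, "]"))), taxa)
}

#' Posterior draws of per-taxon proportions under a condition
#'
#' Pushes each posterior draw through the baseline-category softmax at the
#' design row of `condition`. In `"population"` mode random effects are
#' zero; in `"subject"` mode the named dog's `u` draws are added, giving
#' that dog's predicted composition.
#'
#' @param fit a taxa-model [posterior_draws()].
#' @param condition named list / one-row data.frame of factor levels (e.g.
#'   `list(fraction = "ig_pos", cohort = "healthy", stage = "before")`).
#' @param mode `"population"` or `"subject"`.
#' @param dog dog id, required in subject mode.
#' @return matrix, draws x (taxa + other); rows sum to 1 exactly.
#' @export
predict_taxon_proportions <- function(fit, condition,
                                      mode = c("population", "subject"),
                                      dog = NULL) {
  mode <- match.arg(mode)
  design <- attr(fit, "design")
  taxa <- attr(fit, "taxa")
  if (is.null(design)) stop("fit carries no design")
  x <- drop(design_grid_matrix(design, as.data.frame(condition,
                                                     stringsAsFactors = FALSE)))
  betas <- taxa_beta_draws(fit)
  eta <- vapply(betas, function(b) drop(b %*% x), numeric(nrow(betas[[1]])))
  if (mode == "subject") {
    if (is.null(dog) || !dog %in% design$dog_ids)
      stop("subject mode requires a fitted dog id")
    u <- vapply(taxa, function(tx)
      as.vector(t(param_draws(fit, paste0("u[", dog, "|", tx, "]")))),
      numeric(nrow(eta)))
    eta <- eta + u
  }
  ex <- cbind(exp(eta), other = 1)
  p <- ex / rowSums(ex)
  colnames(p) <- c(taxa, "other")
  p
}

#' Posterior Ig enrichment ratio
#'
#' The model-based analogue of the Palm index: per taxon and posterior
#' draw, the ratio of the predicted proportional abundance in the
#' immunoglobulin-bound condition to the baseline condition; values above
#' 1 indicate enrichment by Ig binding. Summarised by the posterior median
#' with central 50% and 90% credible intervals.
#'
#' @param fit a taxa-model [posterior_draws()].
#' @param bound_condition,baseline_condition named lists of factor levels
#'   differing (typically) in `fraction`; the baseline defaults to the
#'   pre-sort input fraction, with the Ig-negative fraction as the
#'   alternative.
#' @param mode,dog as in [predict_taxon_proportions()]; both conditions
#'   use the same mode.
#' @return data.frame of class `enrichment_summary`: `taxon`,
#'   `ratio_median`, `lo50`, `hi50`, `lo90`, `hi90`, plus the condition
#'   levels as attributes.
#' @export
enrichment_ratio <- function(fit, bound_condition, baseline_condition,
                             mode = c("population", "subject"), dog = NULL) {
  mode <- match.arg(mode)
  pb <- predict_taxon_proportions(fit, bound_condition, mode, dog)
  p0 <- predict_taxon_proportions(fit, baseline_condition, mode, dog)
  ratio <- pb / p0
  out <- data.frame(
    taxon = colnames(ratio),
    ratio_median = apply(ratio, 2, median),
    lo50 = apply(ratio, 2, function(x) central_interval(x, 0.5)[1]),
    hi50 = apply(ratio, 2, function(x) central_interval(x, 0.5)[2]),
    lo90 = apply(ratio, 2, function(x) central_interval(x, 0.9)[1]),
    hi90 = apply(ratio, 2, function(x) central_interval(x, 0.9)[2]),
    row.names = NULL)
  attr(out, "bound_condition") <- bound_condition
  attr(out, "baseline_condition") <- baseline_condition
  attr(out, "draws") <- ratio
  class(out) <- c("enrichment_summary", "data.frame")
  out
}

#' Raw (data-level) Palm-style enrichment index
#'
#' The descriptive comparator of [enrichment_ratio()]: per taxon and group,
#' `(mean relative abundance in the bound fraction + psi) /
#'  (mean relative abundance in the baseline fraction + psi)` computed
#' directly from the counts, with pseudo-ratio `psi` guarding zeros (a
#' taxon absent from both fractions scores exactly 1).
#'
#' @param table a [feature_table()].
#' @param metadata sample metadata.
#' @param pseudocount the psi offset (default 1e-6).
#' @param bound,baseline fraction labels.
#' @param group_by metadata columns defining the comparison groups.
#' @return data.frame: group columns, `taxon`, `raw_ratio`.
#' @export
raw_palm_index <- function(table, metadata, pseudocount = 1e-6,
                           bound = "ig_pos", baseline = "presort",
                           group_by = c("ig_class", "cohort", "stage")) {
  stopifnot(is_feature_table(table), pseudocount > 0)
  md <- metadata[match(colnames(table), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("all table samples must appear in metadata")
  rel <- sweep(ft_unclass(table), 2, colSums(table), "/")
  groups <- unique(md[md$fraction %in% c(bound, baseline), group_by,
                      drop = FALSE])
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- rep(TRUE, nrow(md))
    for (f in group_by) sel <- sel & md[[f]] == groups[[f]][g]
    bs <- sel & md$fraction == bound
    ns <- sel & md$fraction == baseline
    if (!any(bs) || !any(ns))
      stop("group ", paste(groups[g, ], collapse = "/"),
           " lacks a ", if (!any(bs)) bound else baseline, " fraction")
    mb <- rowMeans(rel[, bs, drop = FALSE])
    m0 <- rowMeans(rel[, ns, drop = FALSE])
    data.frame(groups[g, , drop = FALSE], taxon = rownames(table),
               raw_ratio = (mb + pseudocount) / (m0 + pseudocount),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Write an enrichment summary as TSV
#' @param x an `enrichment_summary`.
#' @param path output path.
#' @export
write_enrichment <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
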