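# Shared fixtures, all built in code.

toy_table <- function(m, features = NULL, samples = NULL) {
  m <- as.matrix(m)
  rownames(m) <- features %||% paste0("f", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  feature_table(m)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal metadata for a set of sample ids
toy_metadata <- function(sample_ids, is_control = rep(FALSE, length(sample_ids)),
                         run = rep("run1", length(sample_ids)),
                         dog_id = paste0("dog_", seq_along(sample_ids)),
                         fraction = rep("presort", length(sample_ids)),
                         ig_class = rep("IgA", length(sample_ids)),
                         stage = rep("before", length(sample_ids)),
                         cohort = rep("healthy", length(sample_ids)),
                         replicate = rep(1L, length(sample_ids))) {
  data.frame(sample_id = sample_ids, dog_id = dog_id,
             cohort = ifelse(is_control, "control", cohort),
             stage = ifelse(is_control, NA, stage),
             ig_class = ifelse(is_control, NA, ig_class),
             fraction = ifelse(is_control, "control", fraction),
             run = run, replicate = replicate, is_control = is_control,
             stringsAsFactors = FALSE)
}

# exact one-sided hypergeometric tail by combinatorial enumeration,
# independent of phyper: P(X >= a) for X = number of "present" controls
# when k of N samples are present and n_ctrl are controls
oracle_prevalence_score <- function(a, n_ctrl, b, n_true) {
  k <- a + b; N <- n_ctrl + n_true
  xs <- max(0, k - n_true):min(k, n_ctrl)
  probs <- choose(n_ctrl, xs) * choose(n_true, k - xs) / choose(N, k)
  sum(probs[xs >= a])
}

# average-linkage clustering straight from the definition: inter-cluster
# distance recomputed every step as the mean of all original leaf pairs
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- lapply(seq_len(nrow(d)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in (i + 1):length(clusters)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < bd - 1e-12) { bd <- avg; best <- c(i, j) }
      }
    heights <- c(heights, bd / 2)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# degenerate posterior_draws for a one-taxon (plus other) model with fixed
# presort / ig_pos proportions; used by the exactness tests
degenerate_taxa_fit <- function(p_pre, p_pos, n_draws = 8) {
  md <- toy_metadata(paste0("s", 1:4),
                     dog_id = c("d1", "d1", "d2", "d2"),
                     fraction = c("presort", "ig_pos", "presort", "ig_pos"))
  design <- build_design(md, factors = c("fraction", "cohort", "stage"),
                         reference_levels = c(fraction = "presort",
                                              cohort = "healthy",
                                              stage = "before"))
  b0 <- log(p_pre / (1 - p_pre))
  b1 <- log(p_pos / (1 - p_pos)) - b0
  pn <- c("b[(Intercept)|A]", "b[fractionig_pos|A]",
          "u[d1|A]", "u[d2|A]", "sigma[A]")
  arr <- array(0, dim = c(2, n_draws, length(pn)),
               dimnames = list(NULL, NULL, pn))
  arr[, , 1] <- b0; arr[, , 2] <- b1; arr[, , 5] <- 0.1
  fit <- posterior_draws(arr)
  attr(fit, "design") <- design
  attr(fit, "taxa") <- "A"
  fit
}

# bare numeric matrix of a feature_table (drops class and attributes)
ft_mat <- function(x) {
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

# modify generator params, re-running the constructor's validation
within_params <- function(p, ...) {
  args <- list(...)
  fields <- unclass(p)
  for (nm in names(args)) fields[[nm]] <- args[[nm]]
  do.call(generator_params, fields)
}

# small simulated flow study shared by flow-model tests
flow_fixture <- function(n_dogs = 20, seed = 42, sigma_u = 0.5,
                         sigma_v = 0.3, trials = 1e4,
                         beta = c("(Intercept)" = qlogis(0.28),
                                  ig_classIgG = 0.3, stageafter = -0.2)) {
  design <- simulate_cohort(n_dogs, 0, 0, 0, seed = seed,
                            drop_one_after = FALSE,
                            n_negative_controls = 0)
  params <- generator_params(beta_flow = beta, sigma_dog_flow = sigma_u,
                             sigma_ig_dog = sigma_v, flow_trials = trials,
                             seed = seed)
  list(design = design, params = params,
       counts = simulate_flow_counts(design, params))
}
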