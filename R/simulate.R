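#' Simulate a longitudinal Ig-sorting cohort design
#'
#' Builds the sampling frame of a canine chronic-enteropathy Ig-coating
#' study: healthy dogs plus diseased dogs classified by treatment response
#' (diet-responsive DRE, antibiotic-responsive ARE, immunosuppressant IRE),
#' each sampled at two stages (`before` = active disease at diagnosis,
#' `after` = remission), with three sequenced fractions per Ig class
#' (pre-sort input, Ig-positive, Ig-negative), duplicate sequencing
#' replicates split across two runs, and negative-control samples
#' (sorting sheath fluid / water / buffer).
#'
#' To emulate realistic attrition, when any diseased dogs are present one of
#' them (chosen reproducibly from `seed`) contributes only the `before`
#' stage, giving an unbalanced design.
#'
#' @param n_healthy,n_dre,n_are,n_ire number of dogs per cohort.
#' @param seed integer seed; the design is deterministic given the seed.
#' @param replicates_per_sample sequencing replicates per biological sample;
#'   replicate r is assigned to run `run((r-1) %% n_runs + 1)`.
#' @param n_runs number of sequencing runs.
#' @param n_negative_controls total negative-control samples, alternated
#'   across runs.
#' @param drop_one_after if `TRUE` (default) one diseased dog lacks the
#'   `after` stage.
#' @return A list of class `cohort_design` with elements `dogs` (data.frame
#'   of dog_id, cohort), `metadata` (one row per physical sample plus
#'   controls, see [read_metadata()] for columns), and the design constants.
#' @export
simulate_cohort <- function(n_healthy, n_dre, n_are, n_ire, seed = 1L,
                            replicates_per_sample = 2L, n_runs = 2L,
                            n_negative_controls = 10L,
                            drop_one_after = TRUE) {
  counts <- c(healthy = n_healthy, DRE = n_dre, ARE = n_are, IRE = n_ire)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cohort sizes must be non-negative integers")
  if (sum(counts) == 0)
    stop("empty design: at least one dog is required")
  stopifnot(replicates_per_sample >= 1, n_runs >= 1,
            n_negative_controls >= 0)

  cohort <- rep(names(counts), counts)
  dogs <- data.frame(
    dog_id = sprintf("dog_%02d", seq_along(cohort)),
    cohort = cohort, stringsAsFactors = FALSE)

  stages_of <- setNames(rep(list(c("before", "after")), nrow(dogs)),
                        dogs$dog_id)
  diseased <- dogs$dog_id[dogs$cohort != "healthy"]
  if (drop_one_after && length(diseased) > 0) {
    dropped <- with_seed(seed, sample(diseased, 1L))
    stages_of[[dropped]] <- "before"
  }

  runs <- sprintf("run%d", seq_len(n_runs))
  grid <- do.call(rbind, lapply(seq_len(nrow(dogs)), function(i) {
    expand.grid(dog_id = dogs$dog_id[i], stage = stages_of[[dogs$dog_id[i]]],
                ig_class = c("IgA", "IgG"),
                fraction = c("presort", "ig_pos", "ig_neg"),
                replicate = seq_len(replicates_per_sample),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  grid$cohort <- dogs$cohort[match(grid$dog_id, dogs$dog_id)]
  grid$run <- runs[(grid$replicate - 1L) %% n_runs + 1L]
  grid$is_control <- FALSE
  grid$sample_id <- sprintf("%s_%s_%s_%s_r%d", grid$dog_id, grid$stage,
                            grid$ig_class, grid$fraction, grid$replicate)

  md <- grid[, metadata_columns]
  if (n_negative_controls > 0) {
    ctrl <- data.frame(
      sample_id = sprintf("ctrl_%02d", seq_len(n_negative_controls)),
      dog_id = NA_character_, cohort = "control", stage = NA_character_,
      ig_class = NA_character_, fraction = "control",
      run = runs[(seq_len(n_negative_controls) - 1L) %% n_runs + 1L],
      replicate = 1L, is_control = TRUE, stringsAsFactors = FALSE)
    md <- rbind(md, ctrl)
  }
  rownames(md) <- NULL

  structure(list(
    dogs = dogs, metadata = md, stages = c("before", "after"),
    ig_classes = c("IgA", "IgG"),
    fractions = c("presort", "ig_pos", "ig_neg"), runs = runs,
    replicates_per_sample = as.integer(replicates_per_sample),
    n_negative_controls = as.integer(n_negative_controls), seed = seed),
    class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "cohort_design: %d dogs (%s), %d samples + %d controls\n",
    nrow(x$dogs), paste(names(table(x$dogs$cohort)), table(x$dogs$cohort),
                        sep = "=", collapse = ", "),
    sum(!x$metadata$is_control), x$n_negative_controls))
  invisible(x)
}

#' Generator parameters for the synthetic Ig-sorting study
#'
#' Collects the data-generating parameters shared by
#' [simulate_flow_counts()], [simulate_fraction_counts()] and
#' [spike_contaminants()]. All regression coefficients are on the logit
#' scale; random effects are Normal on the logit scale, matching the
#' hierarchical models the fitting modules assume.
#'
#' Defaults encode the study's stated world: an average Ig-coating
#' proportion of 28% before treatment (`beta_flow` intercept
#' `qlogis(0.28)`), ~10,000 cells counted per flow sample, a target
#' sequencing depth of ~14,000 reads per sample, and a focal taxon whose
#' relative abundance is 0.30 in the Ig-bound fraction versus 0.10 in the
#' pre-sort input (a true enrichment ratio of 3).
#'
#' @param beta_flow named numeric: fixed-effect coefficients of the flow
#'   model, named by design-matrix columns of `~ ig_class*cohort*stage`
#'   (treatment coding, references IgA/healthy/before). Unnamed columns
#'   default to 0.
#' @param sigma_dog_flow SD of the per-dog random intercept (logit scale).
#' @param sigma_ig_dog SD of the per-dog IgG slope.
#' @param rho_dog correlation between dog intercept and IgG slope.
#' @param flow_trials cells counted per flow sample.
#' @param taxa character vector of M focal taxon names; an implicit `other`
#'   reference category absorbs the remainder.
#' @param beta_taxa numeric matrix, terms x taxa: baseline-category logit
#'   coefficients per focal taxon, rows named by design columns of
#'   `~ fraction*ig_class*cohort*stage` (references
#'   presort/IgA/healthy/before), columns named by `taxa`. Missing rows
#'   default to 0. See [taxa_betas_from_proportions()].
#' @param sigma_dog_taxa SD of the per-dog, per-taxon random intercept.
#' @param depth_mean target mean sequencing depth (reads/sample).
#' @param contaminant_taxa names of contaminant features spiked by
#'   [spike_contaminants()].
#' @param contaminant_load expected fraction of a true sample's reads that
#'   are contaminant (in `[0, 1)`); at the default depth this puts each
#'   contaminant at well under one expected read per true sample, i.e.
#'   stochastic presence/absence, while negative controls are pure
#'   contaminant.
#' @param contaminant_runs optional named character vector mapping a
#'   contaminant taxon to the single run it occurs in (`NULL` = all runs).
#' @param control_depth mean reads for negative-control samples (low
#'   biomass, hence shallower than true samples).
#' @param seed integer master seed; sub-streams for flow, fractions and
#'   contaminants are spawned deterministically from it.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(
    beta_flow = c("(Intercept)" = qlogis(0.28)),
    sigma_dog_flow = 0.5, sigma_ig_dog = 0.3, rho_dog = 0,
    flow_trials = 10000L,
    taxa = default_taxa(),
    beta_taxa = default_beta_taxa(taxa),
    sigma_dog_taxa = 0.5,
    depth_mean = 14000,
    contaminant_taxa = c("contam_sheath", "contam_buffer"),
    contaminant_load = 1e-4,
    contaminant_runs = NULL,
    control_depth = 2000,
    seed = 1L) {
  stopifnot(sigma_dog_flow >= 0, sigma_ig_dog >= 0, sigma_dog_taxa >= 0,
            abs(rho_dog) <= 1, flow_trials >= 1, depth_mean >= 1,
            control_depth >= 1, length(taxa) >= 1)
  if (contaminant_load < 0 || contaminant_load >= 1)
    stop("contaminant_load must be in [0, 1)")
  if (!is.matrix(beta_taxa) || ncol(beta_taxa) != length(taxa))
    stop("beta_taxa must be a terms x taxa matrix with one column per taxon")
  colnames(beta_taxa) <- taxa
  if (!is.null(contaminant_runs)) {
    if (!all(names(contaminant_runs) %in% contaminant_taxa))
      stop("contaminant_runs names must be contaminant taxa")
  }
  structure(list(
    beta_flow = beta_flow, sigma_dog_flow = sigma_dog_flow,
    sigma_ig_dog = sigma_ig_dog, rho_dog = rho_dog,
    flow_trials = as.integer(flow_trials),
    taxa = taxa, beta_taxa = beta_taxa, sigma_dog_taxa = sigma_dog_taxa,
    depth_mean = depth_mean, contaminant_taxa = contaminant_taxa,
    contaminant_load = contaminant_load, contaminant_runs = contaminant_runs,
    control_depth = control_depth, seed = as.integer(seed)),
    class = "generator_params")
}

#' Default focal families of the synthetic community
#'
#' Eleven bacterial families commonly dominating the canine faecal
#' microbiota; everything else is the `other` reference category.
#' @return character vector of length 11.
#' @export
default_taxa <- function() {
  c("Lachnospiraceae", "Erysipelotrichaceae", "Clostridiaceae",
    "Ruminococcaceae", "Bacteroidaceae", "Prevotellaceae",
    "Fusobacteriaceae", "Enterobacteriaceae", "Veillonellaceae",
    "Coriobacteriaceae", "Peptostreptococcaceae")
}

#' Baseline-category coefficients from target proportions
#'
#' Converts a pre-sort composition and an Ig-bound composition into
#' intercepts and `fractionig_pos` effects of the baseline-category logit
#' parameterisation, so the generating enrichment ratio of taxon m is
#' exactly `bound[m] / presort[m]`.
#'
#' @param presort,bound named numeric vectors of focal-taxon proportions
#'   (same names, each summing to < 1; the remainder is `other`).
#' @return terms x taxa coefficient matrix usable as `beta_taxa`.
#' @export
taxa_betas_from_proportions <- function(presort, bound = presort) {
  stopifnot(identical(names(presort), names(bound)),
            sum(presort) < 1, sum(bound) < 1, all(presort > 0),
            all(bound > 0))
  p_other_pre <- 1 - sum(presort)
  p_other_bnd <- 1 - sum(bound)
  intercept <- log(presort / p_other_pre)
  pos_eff <- log(bound / p_other_bnd) - intercept
  out <- rbind("(Intercept)" = intercept, "fractionig_pos" = pos_eff)
  colnames(out) <- names(presort)
  out
}

default_beta_taxa <- function(taxa) {
  m <- length(taxa)
  # geometric-decay composition totalling ~85%; taxon 1 enriched 0.10 -> 0.30
  w <- 0.85 * 0.65^(seq_len(m) - 1)
  presort <- w / sum(w) * 0.85
  names(presort) <- taxa
  presort[1] <- 0.10
  bound <- presort
  bound[1] <- 0.30
  taxa_betas_from_proportions(presort, bound)
}

# design matrix used by the generators (treatment coding, fixed references)
generator_model_matrix <- function(md, with_fraction) {
  md$ig_class <- factor(md$ig_class, levels = c("IgA", "IgG"))
  md$cohort <- factor(md$cohort,
                      levels = intersect(c("healthy", "DRE", "ARE", "IRE"),
                                         unique(md$cohort)))
  md$stage <- factor(md$stage, levels = intersect(c("before", "after"),
                                                  unique(md$stage)))
  terms <- c(if (with_fraction) "fraction", "ig_class",
             if (nlevels(md$cohort) > 1) "cohort",
             if (nlevels(md$stage) > 1) "stage")
  if (with_fraction)
    md$fraction <- factor(md$fraction,
                          levels = intersect(c("presort", "ig_pos", "ig_neg"),
                                             unique(md$fraction)))
  f <- as.formula(paste("~", paste(terms, collapse = " * ")))
  model.matrix(f, md)
}

match_beta <- function(beta_named, X, what) {
  beta <- setNames(numeric(ncol(X)), colnames(X))
  if (length(beta_named)) {
    unknown <- setdiff(names(beta_named), colnames(X))
    if (length(unknown))
      stop(what, ": unknown coefficient name(s): ",
           paste(unknown, collapse = ", "))
    beta[names(beta_named)] <- beta_named
  }
  beta
}

#' Simulate flow-cytometry Ig-coating counts
#'
#' For each dog x stage x Ig-class record, draws a dog-level random
#' intercept `u_d ~ N(0, sigma_dog_flow)` and IgG slope
#' `v_d ~ N(0, sigma_ig_dog)` (bivariate-normal with correlation
#' `rho_dog`), computes the coating probability
#' `p = plogis(X beta + u_d + v_d * [IgG])`, and emits
#' `positive ~ Binomial(flow_trials, p)` with `total = flow_trials`.
#'
#' @param design a `cohort_design` from [simulate_cohort()].
#' @param params a `generator_params`.
#' @return data.frame (dog_id, cohort, stage, ig_class, positive, total,
#'   true_p) with attribute `truth` = list(u, v, beta, p).
#' @export
simulate_flow_counts <- function(design, params) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(params, "generator_params"))
  md <- design$metadata
  md <- unique(md[!md$is_control,
                  c("dog_id", "cohort", "stage", "ig_class")])
  rownames(md) <- NULL
  X <- generator_model_matrix(md, with_fraction = FALSE)
  beta <- match_beta(params$beta_flow, X, "beta_flow")

  with_seed(spawn_seed(params$seed, "flow"), {
    dogs <- design$dogs$dog_id
    su <- params$sigma_dog_flow; sv <- params$sigma_ig_dog
    z <- matrix(rnorm(2 * length(dogs)), ncol = 2)
    u <- su * z[, 1]
    v <- sv * (params$rho_dog * z[, 1] +
                 sqrt(1 - params$rho_dog^2) * z[, 2])
    names(u) <- names(v) <- dogs
    ig <- as.integer(md$ig_class == "IgG")
    eta <- drop(X %*% beta) + u[md$dog_id] + v[md$dog_id] * ig
    p <- plogis(eta)
    out <- data.frame(md, positive = rbinom(nrow(md), params$flow_trials, p),
                      total = params$flow_trials, true_p = p,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(u = u, v = v, beta = beta, p = p)
    out
  })
}

#' Simulate Ig-sorted 16S feature counts
#'
#' Per physical sample (metadata row), taxon probabilities come from the
#' baseline-category softmax of `X beta_m + u_{d,m}` with the implicit
#' `other` category at linear predictor 0; counts are
#' `Multinomial(depth, prob)` with `depth ~ Poisson(depth_mean)` truncated
#' at 1. The returned truth record carries the population-level (random
#' effects at zero) proportions per condition and the implied true
#' Ig-bound / pre-sort enrichment ratios, for downstream recovery tests.
#'
#' @inheritParams simulate_flow_counts
#' @return a [feature_table()] (rows = focal taxa + `other`) with attribute
#'   `truth` = list(proportions, enrichment, u, beta, depths).
#' @export
simulate_fraction_counts <- function(design, params) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(params, "generator_params"))
  md <- design$metadata[!design$metadata$is_control, ]
  rownames(md) <- NULL
  X <- generator_model_matrix(md, with_fraction = TRUE)
  M <- length(params$taxa)
  beta <- vapply(seq_len(M), function(m)
    match_beta(params$beta_taxa[, m], X, "beta_taxa"),
    numeric(ncol(X)))
  colnames(beta) <- params$taxa

  with_seed(spawn_seed(params$seed, "fractions"), {
    dogs <- design$dogs$dog_id
    u <- matrix(rnorm(length(dogs) * M, sd = params$sigma_dog_taxa),
                nrow = length(dogs), dimnames = list(dogs, params$taxa))
    eta <- X %*% beta + u[md$dog_id, , drop = FALSE]
    probs <- cbind(exp(eta), other = 1)
    probs <- probs / rowSums(probs)
    depth <- rpois(nrow(md), params$depth_mean)
    depth[depth < 1] <- 1L
    counts <- vapply(seq_len(nrow(md)), function(s)
      drop(rmultinom(1, depth[s], probs[s, ])), numeric(M + 1))
    dimnames(counts) <- list(c(params$taxa, "other"), md$sample_id)

    cond <- unique(md[, c("fraction", "ig_class", "cohort", "stage")])
    Xc <- generator_model_matrix(cond, with_fraction = TRUE)
    pc <- cbind(exp(Xc %*% beta), other = 1)
    pc <- pc / rowSums(pc)
    truth_prop <- data.frame(cond, pc, check.names = FALSE,
                             row.names = NULL)
    enr <- merge(
      truth_prop[truth_prop$fraction == "ig_pos", -1],
      truth_prop[truth_prop$fraction == "presort", -1],
      by = c("ig_class", "cohort", "stage"), suffixes = c(".pos", ".pre"))
    ratios <- as.matrix(enr[, paste0(c(params$taxa, "other"), ".pos")]) /
      as.matrix(enr[, paste0(c(params$taxa, "other"), ".pre")])
    colnames(ratios) <- c(params$taxa, "other")
    truth_enr <- data.frame(enr[, c("ig_class", "cohort", "stage")], ratios,
                            check.names = FALSE, row.names = NULL)

    out <- feature_table(counts)
    attr(out, "truth") <- list(proportions = truth_prop,
                               enrichment = truth_enr,
                               u = u, beta = beta, depths = depth)
    out
  })
}

#' Spike contaminant taxa into a feature table
#'
#' Emulates reagent/sheath-fluid contamination: negative-control columns are
#' replaced by pure contaminant profiles (depth ~ Poisson(control_depth)),
#' and every true sample receives, per contaminant taxon, a
#' `Poisson(contaminant_load * sample_depth / n_contaminants)` count.
#' With `contaminant_runs` set, a contaminant only occurs in columns
#' (controls and true samples) of its designated run.
#'
#' @param table a [feature_table()] whose columns cover the non-control
#'   samples in `metadata`; contaminant rows are appended (they must not
#'   already exist).
#' @param metadata metadata with control rows flagged.
#' @inheritParams simulate_flow_counts
#' @return feature_table including control columns and contaminant rows;
#'   attribute `truth` gains `contaminants` (names) and keeps any existing
#'   truth entries.
#' @export
spike_contaminants <- function(table, metadata, params) {
  stopifnot(is_feature_table(table), inherits(params, "generator_params"))
  validate_metadata(metadata)
  if (params$contaminant_load >= 1) stop("contaminant_load must be < 1")
  cont <- params$contaminant_taxa
  if (any(cont %in% rownames(table)))
    stop("contaminant taxa already present in table")
  ctrl_md <- metadata[metadata$is_control, ]
  true_md <- metadata[!metadata$is_control, ]
  if (!all(true_md$sample_id %in% colnames(table)))
    stop("table must contain all non-control samples in metadata")

  run_of <- function(taxon) {
    if (is.null(params$contaminant_runs)) return(NULL)
    unname(params$contaminant_runs[taxon])
  }

  with_seed(spawn_seed(params$seed, "contaminants"), {
    m <- ft_unclass(table)[, true_md$sample_id, drop = FALSE]
    depths <- colSums(m)
    add <- matrix(0, nrow = length(cont), ncol = ncol(m),
                  dimnames = list(cont, colnames(m)))
    for (tx in cont) {
      lam <- params$contaminant_load * depths / length(cont)
      if (!is.null(run_of(tx)))
        lam[true_md$run != run_of(tx)] <- 0
      add[tx, ] <- rpois(ncol(m), lam)
    }
    full <- rbind(m, add)

    if (nrow(ctrl_md) > 0) {
      cm <- matrix(0, nrow = nrow(full), ncol = nrow(ctrl_md),
                   dimnames = list(rownames(full), ctrl_md$sample_id))
      for (j in seq_len(nrow(ctrl_md))) {
        ok <- vapply(cont, function(tx) {
          r <- run_of(tx); is.null(r) || r == ctrl_md$run[j]
        }, logical(1))
        active <- cont[ok]
        if (length(active) == 0) next
        d <- max(1L, rpois(1, params$control_depth))
        cm[active, j] <- drop(rmultinom(1, d, rep(1, length(active))))
      }
      full <- cbind(full, cm)
    }
    out <- feature_table(full)
    truth <- attr(table, "truth") %||% list()
    truth$contaminants <- cont
    attr(out, "truth") <- truth
    out
  })
}

#' Write a generator truth record as JSON
#'
#' @param truth the `truth` attribute of a generated table.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor",
                       na = "null")
  invisible(path)
}
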