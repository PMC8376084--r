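#' Pipeline configuration
#'
#' Assembles and validates the configuration of [run_pipeline()]. Defaults
#' mirror the study's quoted settings (sample filter at 500 reads, feature
#' filter at 10, decontamination threshold 0.5 with run as batch factor,
#' rarefaction at 1000, top-11 family aggregation, N(0, 5) taxa priors,
#' 50/90/95% interval masses), so a default run is the study pipeline on
#' synthetic data. Unknown keys anywhere in the structure are rejected
#' before any computation.
#'
#' @param ... named overrides; nested sections can be partial lists, e.g.
#'   `preprocessing = list(min_reads = 200)`.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    paths = list(feature_table = NULL, metadata = NULL, flow_counts = NULL,
                 taxonomy = NULL),
    preprocessing = list(min_reads = 500, min_total = 10,
                         rarefaction_depth = 1000,
                         decontam_threshold = 0.5, batch_key = "run"),
    models = list(chains = 2, iter = 500, warmup = 500, seed = 1L,
                  prior_sd = 5, intervals = c(0.5, 0.9, 0.95)),
    taxa = list(top_k = 11, baseline = "presort"),
    simulation = NULL)
  over <- list(...)
  cfg <- merge_config(defaults, over, path = "config")
  stopifnot(cfg$preprocessing$min_reads >= 0,
            cfg$preprocessing$min_total >= 0,
            cfg$preprocessing$rarefaction_depth >= 1,
            cfg$preprocessing$decontam_threshold >= 0,
            cfg$preprocessing$decontam_threshold <= 1,
            cfg$models$chains >= 2, cfg$taxa$top_k >= 1)
  if (!cfg$taxa$baseline %in% c("presort", "ig_neg"))
    stop("taxa$baseline must be 'presort' or 'ig_neg'")
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(defaults, over, path) {
  if (is.null(over)) return(defaults)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) && !identical(path, "config$simulation"))
    stop("unknown config key(s) under ", path, ": ",
         paste(unknown, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- merge_config(defaults[[nm]], over[[nm]],
                                     paste0(path, "$", nm))
    else defaults[[nm]] <- over[[nm]]
  }
  defaults
}

#' Read a pipeline config from JSON
#' @param path JSON file whose top-level keys follow [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Validate pipeline inputs
#'
#' Cross-checks the feature table, metadata and flow counts: sample-id
#' coverage, factor-level domains, count integrality and non-negativity,
#' and the binomial constraint `positive <= total`. Returns every finding
#' rather than stopping at the first.
#'
#' @param table a [feature_table()] or `NULL`.
#' @param metadata metadata data.frame.
#' @param flow flow-count data.frame or `NULL`.
#' @return list: `ok` (logical), `findings` (character vector).
#' @export
validate_inputs <- function(table, metadata, flow = NULL) {
  findings <- character(0)
  note <- function(...) findings <<- c(findings, sprintf(...))
  md <- try(validate_metadata(metadata), silent = TRUE)
  if (inherits(md, "try-error")) {
    note("metadata: %s", conditionMessage(attr(md, "condition")))
    return(list(ok = FALSE, findings = findings))
  }
  real <- metadata[!metadata$is_control, ]
  bad_cohort <- setdiff(unique(real$cohort),
                        c("healthy", "DRE", "ARE", "IRE"))
  if (length(bad_cohort))
    note("metadata: cohort level(s) outside domain: %s",
         paste(bad_cohort, collapse = ", "))
  bad_stage <- setdiff(unique(real$stage), c("before", "after"))
  if (length(bad_stage))
    note("metadata: stage level(s) outside domain: %s",
         paste(bad_stage, collapse = ", "))
  bad_frac <- setdiff(unique(real$fraction),
                      c("presort", "ig_pos", "ig_neg"))
  if (length(bad_frac))
    note("metadata: fraction level(s) outside domain: %s",
         paste(bad_frac, collapse = ", "))
  if (!is.null(table)) {
    miss <- setdiff(colnames(table), metadata$sample_id)
    if (length(miss))
      note("table: %d sample(s) missing from metadata (e.g. %s)",
           length(miss), miss[1])
    if (any(table < 0)) note("table: negative counts")
    if (any(table != round(table))) note("table: non-integer counts")
  }
  if (!is.null(flow)) {
    if (any(flow$positive < 0) || any(flow$total < 1))
      note("flow: counts must be non-negative with total >= 1")
    if (any(flow$positive > flow$total))
      note("flow: positive exceeds total")
    bad_dog <- setdiff(unique(flow$dog_id), unique(real$dog_id))
    if (length(bad_dog))
      note("flow: dog id(s) missing from metadata: %s",
           paste(bad_dog, collapse = ", "))
  }
  list(ok = length(findings) == 0, findings = findings)
}

#' Run the end-to-end analysis
#'
#' Executes simulate (optional) -> validate -> preprocess -> flow model ->
#' taxa models (per Ig class) -> diversity, writing every stage report
#' into `out_dir` plus a JSON run manifest with per-stage row/feature
#' accounting and the seeds used. Deterministic for a fixed config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$models$seed
  manifest <- list(package_version = as.character(utils::packageVersion("igseqr")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = seed, stages = list())
  stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }

  # --- inputs ---
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    design <- simulate_cohort(sim$n_healthy %||% 11, sim$n_dre %||% 11,
                              sim$n_are %||% 8, sim$n_ire %||% 3,
                              seed = spawn_seed(seed, "design"))
    gp_args <- sim$params %||% list()
    gp_args$seed <- spawn_seed(seed, "generator")
    params <- do.call(generator_params, gp_args)
    flow <- simulate_flow_counts(design, params)
    tab <- simulate_fraction_counts(design, params)
    tab <- spike_contaminants(tab, design$metadata, params)
    metadata <- design$metadata
    taxonomy <- setNames(rownames(tab), rownames(tab))
    stage("simulate", dogs = nrow(design$dogs),
          samples = sum(!metadata$is_control),
          controls = sum(metadata$is_control),
          features = nrow(tab), seed = params$seed)
  } else {
    tab <- read_feature_table(config$paths$feature_table)
    metadata <- read_metadata(config$paths$metadata)
    flow <- read.delim(config$paths$flow_counts, stringsAsFactors = FALSE)
    taxonomy <- if (!is.null(config$paths$taxonomy)) {
      tx <- read.delim(config$paths$taxonomy, stringsAsFactors = FALSE)
      setNames(tx[[2]], tx[[1]])
    } else setNames(rownames(tab), rownames(tab))
    stage("load", samples = ncol(tab), features = nrow(tab))
  }

  val <- validate_inputs(tab, metadata, flow)
  stage("validate", ok = val$ok, findings = val$findings)
  if (!val$ok)
    stop("pipeline aborted at stage 'validate' [IGSEQR_E_VALIDATE]: ",
         paste(val$findings, collapse = "; "))

  # --- preprocess ---
  pp <- config$preprocessing
  n0 <- c(features = nrow(tab), samples = ncol(tab))
  tab1 <- filter_low_depth(tab, pp$min_reads)
  tab2 <- filter_rare_features(tab1, pp$min_total)
  dec <- prevalence_decontam(tab2, metadata, pp$decontam_threshold,
                             pp$batch_key)
  write.table(dec$scores, file.path(out_dir, "decontam_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tab3 <- dec$table
  keep <- colnames(tab3) %in% metadata$sample_id[!metadata$is_control]
  tab3 <- feature_table(ft_unclass(tab3)[, keep, drop = FALSE])
  merged <- merge_replicates(tab3, metadata)
  merged <- filter_rare_features(merged, 0, drop_singletons = TRUE)
  md_merged <- merged_metadata(metadata, colnames(merged))
  write_feature_table(merged, file.path(out_dir, "feature_table_clean.tsv"))
  stage("preprocess",
        input = as.list(n0),
        low_depth_dropped = length(attr(tab1, "dropped_samples")),
        rare_dropped = length(attr(tab2, "dropped_features")),
        contaminants_removed = sum(dec$scores$is_contaminant),
        merged_samples = ncol(merged),
        retained = list(features = nrow(merged), samples = ncol(merged)))

  # --- flow model ---
  mset <- config$models
  flow_fit <- fit_flow_model(flow, chains = mset$chains, iter = mset$iter,
                             warmup = mset$warmup,
                             seed = spawn_seed(seed, "flow_fit"),
                             prior_sd = 0)
  write_posterior_summary(flow_fit,
                          file.path(out_dir, "flow_posterior.tsv"), 0.9)
  pred <- predict_proportions(flow_fit, interval_mass = 0.9)
  write.table(pred, file.path(out_dir, "flow_predictions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  r2f <- glmm_r2(flow_fit)
  stage("flow_model", rows = nrow(flow),
        converged = flow_fit$meta$convergence$ok,
        r2_marginal = unname(r2f["marginal"]),
        r2_conditional = unname(r2f["conditional"]),
        seed = spawn_seed(seed, "flow_fit"))

  # --- taxa models, one per Ig class ---
  agg <- aggregate_top_taxa(merged, taxonomy, k = config$taxa$top_k)
  enr_all <- list()
  for (igc in c("IgA", "IgG")) {
    sel <- md_merged$sample_id[md_merged$ig_class == igc]
    sub <- feature_table(ft_unclass(agg)[, colnames(agg) %in% sel,
                                         drop = FALSE])
    fit <- fit_taxa_model(sub, md_merged, chains = mset$chains,
                          iter = mset$iter, warmup = mset$warmup,
                          seed = spawn_seed(seed, paste0("taxa_", igc)),
                          prior_sd = mset$prior_sd)
    conds <- unique(md_merged[md_merged$ig_class == igc,
                              c("cohort", "stage")])
    for (i in seq_len(nrow(conds))) {
      enr <- enrichment_ratio(
        fit,
        c(list(fraction = "ig_pos"), as.list(conds[i, ])),
        c(list(fraction = config$taxa$baseline), as.list(conds[i, ])))
      enr_all[[length(enr_all) + 1]] <-
        data.frame(ig_class = igc, conds[i, , drop = FALSE],
                   as.data.frame(enr), row.names = NULL)
    }
  }
  enr_tab <- do.call(rbind, enr_all)
  write.table(enr_tab, file.path(out_dir, "enrichment_ratios.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stage("taxa_model", taxa = nrow(agg) - 1, conditions = nrow(enr_tab))

  # --- diversity ---
  rar <- rarefy(merged, pp$rarefaction_depth,
                seed = spawn_seed(seed, "rarefy"))
  md_rar <- md_merged[match(colnames(rar), md_merged$sample_id), ]
  h <- sample_shannon(rar)
  lmm <- fit_shannon_lmm(h, md_rar)
  r2l <- lmm_r2(lmm)
  grid <- unique(md_rar[, c("ig_class", "stage")])
  emm <- marginal_means(lmm, grid, level = 0.95, exponentiate = TRUE)
  write.table(emm, file.path(out_dir, "shannon_marginal_means.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ait <- aitchison_distance(ft_unclass(rar), pseudocount = 1)
  perm <- permanova(ait, md_rar$cohort, n_perm = 999,
                    seed = spawn_seed(seed, "permanova"))
  write_distance_matrix(ait, file.path(out_dir, "aitchison_distance.tsv"))
  bc <- bray_curtis(ft_unclass(rar))
  tree <- upgma(bc)
  writeLines(upgma_newick(tree), file.path(out_dir, "upgma_braycurtis.nwk"))
  stage("diversity", samples = ncol(rar),
        rarefaction_dropped = length(attr(rar, "dropped_samples")),
        shannon_excluded = length(lmm$excluded),
        lmm_r2_marginal = unname(r2l["marginal"]),
        lmm_r2_conditional = unname(r2l["conditional"]),
        permanova_F = perm$pseudo_F, permanova_R2 = perm$R2,
        permanova_p = perm$p_value)

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

merged_metadata <- function(metadata, merged_ids) {
  md <- unique(metadata[!metadata$is_control,
                        c("dog_id", "cohort", "stage", "ig_class",
                          "fraction")])
  md$sample_id <- paste(md$dog_id, md$stage, md$ig_class, md$fraction,
                        sep = "_")
  md$run <- "merged"; md$replicate <- 1L; md$is_control <- FALSE
  md <- md[match(merged_ids, md$sample_id), metadata_columns]
  if (anyNA(md$sample_id)) stop("merged sample ids do not match metadata")
  rownames(md) <- NULL
  md
}
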