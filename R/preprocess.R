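#' Drop low-depth samples
#'
#' Removes samples whose total read count is strictly less than
#' `min_reads`. The boundary is literal: a sample with exactly `min_reads`
#' reads is retained.
#'
#' @param table a [feature_table()].
#' @param min_reads minimum column sum to retain (default 500).
#' @param allow_empty return an empty table instead of erroring when every
#'   sample is removed.
#' @return filtered feature_table; dropped sample ids in attribute
#'   `dropped_samples`.
#' @export
filter_low_depth <- function(table, min_reads = 500, allow_empty = FALSE) {
  stopifnot(is_feature_table(table), min_reads >= 0)
  keep <- colSums(table) >= min_reads
  if (!any(keep) && ncol(table) > 0 && !allow_empty)
    stop("all samples have fewer than ", min_reads,
         " reads; pass allow_empty = TRUE to keep an empty table")
  out <- feature_table(ft_unclass(table)[, keep, drop = FALSE])
  attr(out, "dropped_samples") <- colnames(table)[!keep]
  out
}

#' Drop rare features
#'
#' Removes features with total abundance (summed across samples) strictly
#' below `min_total`, and optionally prunes features that are absent or
#' present as singletons (row sum <= 1). Feature order is preserved.
#'
#' @param table a [feature_table()].
#' @param min_total minimum row sum to retain (default 10).
#' @param drop_singletons also drop features with row sum <= 1.
#' @return filtered feature_table; dropped ids in attribute
#'   `dropped_features`.
#' @export
filter_rare_features <- function(table, min_total = 10,
                                 drop_singletons = FALSE) {
  stopifnot(is_feature_table(table), min_total >= 0)
  rs <- rowSums(table)
  keep <- rs >= min_total
  if (drop_singletons) keep <- keep & rs > 1
  out <- feature_table(ft_unclass(table)[keep, , drop = FALSE])
  attr(out, "dropped_features") <- rownames(table)[!keep]
  out
}

#' Merge sequencing replicates and runs
#'
#' Sums counts of samples sharing all `group_keys` in the metadata (e.g.
#' merging duplicates and runs of one biological sample). Output column
#' names are the group labels, formed by joining the key values with `"_"`.
#'
#' @param table a [feature_table()].
#' @param metadata metadata covering every sample in `table`.
#' @param group_keys metadata columns defining a merge group.
#' @return merged feature_table with one column per group; the grouping is
#'   recorded in attribute `groups`.
#' @export
merge_replicates <- function(table, metadata,
                             group_keys = c("dog_id", "stage", "ig_class",
                                            "fraction")) {
  stopifnot(is_feature_table(table))
  miss <- setdiff(colnames(table), metadata$sample_id)
  if (length(miss))
    stop("samples absent from metadata: ", paste(miss, collapse = ", "))
  md <- metadata[match(colnames(table), metadata$sample_id), , drop = FALSE]
  bad <- setdiff(group_keys, names(md))
  if (length(bad)) stop("unknown group keys: ", paste(bad, collapse = ", "))
  label <- do.call(paste, c(md[group_keys], sep = "_"))
  groups <- factor(label, levels = unique(label))
  m <- ft_unclass(table)
  merged <- vapply(levels(groups), function(g)
    rowSums(m[, groups == g, drop = FALSE]), numeric(nrow(m)))
  if (nrow(m) == 1)
    merged <- matrix(merged, nrow = 1,
                     dimnames = list(rownames(m), levels(groups)))
  out <- feature_table(merged)
  attr(out, "groups") <- split(colnames(table), groups)
  out
}

#' Prevalence-based contaminant identification
#'
#' Classifies features as contaminants by comparing their prevalence
#' (presence/absence, presence = count >= 1) in negative-control samples
#' versus true samples. The score is the one-sided exact hypergeometric
#' (Fisher) tail probability of seeing at least the observed number of
#' positive controls given the feature's overall prevalence; small scores
#' mean "more prevalent in controls than expected", i.e. contaminant-like.
#' With a `batch_key` (e.g. sequencing run) scores are computed per batch
#' and combined by their minimum, so a feature contaminant-like in any one
#' run is flagged. A feature is classified a contaminant when its combined
#' score is strictly below `threshold`.
#'
#' Features absent from every sample and control have an undefined score
#' (`NA`): they are reported, not classified, and retained.
#'
#' @param table a [feature_table()] containing both true samples and
#'   negative controls.
#' @param metadata metadata with `is_control` flags (and the batch column).
#' @param threshold classification threshold on the combined score.
#' @param batch_key metadata column naming the batch factor, or `NULL`.
#' @return list with `scores` (data.frame: feature_id, score, per-batch
#'   columns, is_contaminant, undefined) and `table` (contaminants
#'   removed, control columns retained).
#' @export
prevalence_decontam <- function(table, metadata, threshold = 0.5,
                                batch_key = "run") {
  stopifnot(is_feature_table(table), threshold >= 0, threshold <= 1)
  validate_metadata(metadata)
  md <- metadata[match(colnames(table), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id))
    stop("all table samples must appear in metadata")
  present <- ft_unclass(table) >= 1

  batches <- if (is.null(batch_key)) rep("all", ncol(table)) else {
    if (!batch_key %in% names(md)) stop("unknown batch_key: ", batch_key)
    as.character(md[[batch_key]])
  }
  ub <- unique(batches)
  per_batch <- sapply(ub, function(b) {
    in_b <- batches == b
    ctrl <- in_b & md$is_control
    true <- in_b & !md$is_control
    if (sum(ctrl) < 1 || sum(true) < 1)
      stop("batch ", b, " needs at least one control and one true sample")
    a <- rowSums(present[, ctrl, drop = FALSE])
    k <- a + rowSums(present[, true, drop = FALSE])
    # P(X >= a), X ~ Hypergeom(k present, N - k absent, n_ctrl drawn)
    p <- phyper(a - 1, k, sum(in_b) - k, sum(ctrl), lower.tail = FALSE)
    p[k == 0] <- NA_real_
    p
  })
  per_batch <- matrix(per_batch, nrow = nrow(table),
                      dimnames = list(rownames(table), ub))
  score <- apply(per_batch, 1, function(x)
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  undefined <- is.na(score)
  is_cont <- !undefined & score < threshold

  scores <- data.frame(feature_id = rownames(table), score = score,
                       per_batch, is_contaminant = is_cont,
                       undefined = undefined, row.names = NULL,
                       check.names = FALSE)
  filtered <- feature_table(ft_unclass(table)[!is_cont, , drop = FALSE])
  list(scores = scores, table = filtered)
}

#' Rarefy samples to a fixed depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (multivariate hypergeometric); samples with fewer than `depth` reads are
#' dropped. A single seeded draw is taken (no averaging over draws).
#'
#' @param table a [feature_table()].
#' @param depth target reads per sample (default 1000).
#' @param seed integer seed; output is deterministic given the seed.
#' @return rarefied feature_table; dropped sample ids in attribute
#'   `dropped_samples`.
#' @export
rarefy <- function(table, depth = 1000, seed = 1L) {
  stopifnot(is_feature_table(table), depth >= 1)
  m <- ft_unclass(table)
  keep <- colSums(m) >= depth
  m <- m[, keep, drop = FALSE]
  out <- with_seed(seed, {
    vapply(seq_len(ncol(m)), function(j) {
      reads <- rep.int(seq_len(nrow(m)), m[, j])
      tabulate(reads[sample.int(length(reads), depth)], nbins = nrow(m))
    }, numeric(nrow(m)))
  })
  if (ncol(m) > 0) dimnames(out) <- dimnames(m)
  else out <- matrix(numeric(0), nrow = nrow(m), ncol = 0,
                     dimnames = list(rownames(m), character(0)))
  res <- feature_table(out)
  attr(res, "dropped_samples") <- colnames(table)[!keep]
  res
}

#' Aggregate features to the top-k families plus "other"
#'
#' Sums features within their taxonomic family, keeps the `k` families with
#' the largest grand totals as rows (in decreasing order of abundance), and
#' collapses the remaining families into one `other` row. Column sums are
#' conserved exactly. Unmapped features fall into an `unassigned` family.
#'
#' @param table a [feature_table()].
#' @param taxonomy named character vector mapping feature id -> family.
#' @param k number of families to keep (default 11).
#' @param other_label label of the remainder row.
#' @return aggregated feature_table with `k + 1` rows (or fewer families
#'   plus an all-zero `other` row when k exceeds the family count).
#' @export
aggregate_top_taxa <- function(table, taxonomy, k = 11,
                               other_label = "other") {
  stopifnot(is_feature_table(table), k >= 1)
  fam <- taxonomy[rownames(table)]
  fam[is.na(fam)] <- "unassigned"
  m <- ft_unclass(table)
  by_fam <- rowsum(m, group = fam, reorder = FALSE)
  totals <- rowSums(by_fam)
  keep <- rownames(by_fam)[order(-totals, rownames(by_fam))]
  keep <- keep[seq_len(min(k, length(keep)))]
  rest <- setdiff(rownames(by_fam), keep)
  other <- if (length(rest)) colSums(by_fam[rest, , drop = FALSE])
           else setNames(numeric(ncol(m)), colnames(m))
  out <- by_fam[setdiff(keep, other_label), , drop = FALSE]
  if (other_label %in% keep)   # a family literally named like the remainder
    other <- other + by_fam[other_label, ]
  out <- rbind(out, matrix(other, nrow = 1, dimnames = list(other_label, NULL)))
  colnames(out) <- colnames(m)
  feature_table(out)
}
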