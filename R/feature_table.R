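#' Feature count table
#'
#' A minimal container for an amplicon feature table: a non-negative integer
#' matrix with features (ASVs, or aggregated families) as rows and samples as
#' columns, with unique row and column names. This is the substrate of all
#' sequence-side processing; flow-cytometry counts live in a separate
#' data frame (see [simulate_flow_counts()]).
#'
#' @param counts numeric matrix, features x samples, non-negative, with
#'   unique rownames (feature ids) and colnames (sample ids).
#' @return An object of class `feature_table` (the validated matrix).
#' @export
feature_table <- function(counts) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("feature_table requires feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("feature and sample ids must be unique")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "double"
  class(counts) <- c("feature_table", "matrix", "array")
  counts
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples, total reads %s\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Test for the feature_table class
#' @param x object.
#' @return logical.
#' @export
is_feature_table <- function(x) inherits(x, "feature_table")

# strip the class so matrix subsetting never invalidates invariants mid-op
ft_unclass <- function(x) {
  class(x) <- c("matrix", "array")
  x
}

#' Read / write a feature table as TSV
#'
#' The TSV layout has the feature id in the first column (`feature_id`) and
#' one column per sample, matching common exports of BIOM tables.
#'
#' @param path file path.
#' @return `read_feature_table()` returns a `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  feature_table(m)
}

#' @param x a `feature_table`.
#' @rdname read_feature_table
#' @export
write_feature_table <- function(x, path) {
  stopifnot(is_feature_table(x))
  df <- data.frame(feature_id = rownames(x), ft_unclass(x),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a feature table as BIOM-style JSON
#'
#' Emits the sparse "biom" v1 JSON layout (rows/columns/data triplets) so the
#' table can be consumed by BIOM-aware tooling.
#'
#' @param x a `feature_table`.
#' @param path output path.
#' @export
write_feature_table_biom <- function(x, path) {
  stopifnot(is_feature_table(x))
  nz <- which(ft_unclass(x) != 0, arr.ind = TRUE)
  obj <- list(
    id = NULL, format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table", generated_by = "igseqr",
    matrix_type = "sparse", matrix_element_type = "int",
    shape = dim(x),
    rows = lapply(rownames(x), function(id) list(id = id, metadata = NULL)),
    columns = lapply(colnames(x), function(id) list(id = id, metadata = NULL)),
    data = lapply(seq_len(nrow(nz)), function(i)
      c(nz[i, 1] - 1L, nz[i, 2] - 1L, x[nz[i, 1], nz[i, 2]]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Read / write the sample metadata table
#'
#' Required columns: `sample_id`, `dog_id`, `cohort`, `stage`, `ig_class`,
#' `fraction`, `run`, `replicate`, `is_control`.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  md$is_control <- as.logical(md$is_control)
  validate_metadata(md)
  md
}

#' @param metadata metadata data.frame.
#' @rdname read_metadata
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

metadata_columns <- c("sample_id", "dog_id", "cohort", "stage", "ig_class",
                      "fraction", "run", "replicate", "is_control")

validate_metadata <- function(metadata) {
  miss <- setdiff(metadata_columns, names(metadata))
  if (length(miss))
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("metadata sample_id values must be unique")
  invisible(metadata)
}
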