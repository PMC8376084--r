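#' Build the fixed-effect design matrix
#'
#' Expands an ordered list of categorical factors into a treatment-coded
#' design with intercept, main effects, and all interactions (the `*`
#' expansion), using the stated reference levels. Factors observed at a
#' single level contribute no columns beyond the intercept. Also records
#' the dog index and the IgG indicator needed by the random-effect
#' structure.
#'
#' @param metadata data.frame with one row per observation, containing all
#'   `factors` plus `dog_id`.
#' @param factors ordered character vector of factor column names.
#' @param reference_levels named character vector mapping each factor to
#'   its reference level; a stated reference absent from both the map and
#'   the data is an error.
#' @return list of class `ig_design`: `fixed` (model matrix),
#'   `term_names`, `dog_index` (1-based), `dog_ids`, `ig` (0/1 IgG
#'   indicator, all-zero when `ig_class` is not among the factors),
#'   `factor_levels`, `formula`, `data`.
#' @export
build_design <- function(metadata,
                         factors = c("ig_class", "cohort", "stage"),
                         reference_levels = c(ig_class = "IgA",
                                              cohort = "healthy",
                                              stage = "before")) {
  miss <- setdiff(c(factors, "dog_id"), names(metadata))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  md <- metadata
  lev <- list()
  for (f in factors) {
    vals <- unique(as.character(md[[f]]))
    if (anyNA(md[[f]])) stop("factor ", f, " has missing values")
    ref <- reference_levels[[f]]
    if (is.null(ref) || is.na(ref))
      stop("no reference level stated for factor ", f)
    if (!ref %in% vals)
      stop("reference level '", ref, "' of factor ", f,
           " is absent from the data")
    lev[[f]] <- c(ref, sort(setdiff(vals, ref)))
    md[[f]] <- factor(md[[f]], levels = lev[[f]])
  }
  active <- factors[vapply(factors, function(f) nlevels(md[[f]]) > 1,
                           logical(1))]
  f <- if (length(active))
    as.formula(paste("~", paste(active, collapse = " * "))) else ~1
  X <- model.matrix(f, md)
  dog_ids <- unique(md$dog_id)
  structure(list(
    fixed = X, term_names = colnames(X),
    dog_index = match(md$dog_id, dog_ids), dog_ids = dog_ids,
    ig = if ("ig_class" %in% factors)
      as.integer(md$ig_class == "IgG") else integer(nrow(md)) ,
    factor_levels = lev, formula = f, data = md),
    class = "ig_design")
}

#' @export
print.ig_design <- function(x, ...) {
  cat(sprintf("ig_design: %d rows, %d fixed-effect columns, %d dogs\n",
              nrow(x$fixed), ncol(x$fixed), length(x$dog_ids)))
  invisible(x)
}

# model-matrix rows for a prediction grid, using the fitted factor levels
design_grid_matrix <- function(design, grid) {
  lev <- design$factor_levels
  gd <- as.data.frame(grid, stringsAsFactors = FALSE)
  for (f in names(lev)) {
    if (!f %in% names(gd)) {
      if (length(lev[[f]]) == 1) gd[[f]] <- lev[[f]]  # single-level factor
      else stop("grid must specify factor ", f)
    }
    bad <- setdiff(unique(as.character(gd[[f]])), lev[[f]])
    if (length(bad))
      stop("grid level(s) outside fitted levels for ", f, ": ",
           paste(bad, collapse = ", "))
    gd[[f]] <- factor(gd[[f]], levels = lev[[f]])
  }
  model.matrix(design$formula, gd)
}
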