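#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over the positive proportions of a count (or
#' proportion) vector, natural logarithm by default.
#'
#' @param x non-negative numeric vector with at least one positive entry.
#' @param base logarithm base (default `exp(1)`).
#' @return numeric scalar.
#' @export
shannon <- function(x, base = exp(1)) {
  if (any(x < 0) || !any(x > 0))
    stop("shannon requires non-negative input with a positive entry")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p, base = base))
}

#' Per-sample Shannon index of a feature table
#' @param table a [feature_table()] (features x samples).
#' @inheritParams shannon
#' @return named numeric vector, one value per sample.
#' @export
sample_shannon <- function(table, base = exp(1)) {
  stopifnot(is_feature_table(table))
  apply(ft_unclass(table), 2, shannon, base = base)
}

#' Centred log-ratio transform
#'
#' Per sample (column): `clr(x) = log((x + pseudocount) / g)` with `g` the
#' geometric mean of `x + pseudocount`. Each transformed sample sums to
#' zero. The pseudocount (default 1) makes zero counts transformable.
#'
#' @param counts numeric matrix, features x samples.
#' @param pseudocount positive offset added to every count.
#' @return real matrix of the same dimensions.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  m <- log(as.matrix(counts) + pseudocount)
  sweep(m, 2, colMeans(m), "-")
}

#' Aitchison distance between samples
#'
#' Euclidean distance between CLR-transformed samples; the standard metric
#' for compositional microbiome data.
#'
#' @inheritParams clr_transform
#' @return a symmetric distance matrix (base `matrix`, zero diagonal) with
#'   sample labels.
#' @export
aitchison_distance <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two samples")
  as.matrix(dist(t(clr_transform(counts, pseudocount))))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(a, b) = sum|a_i - b_i| / sum(a_i + b_i)`, in `[0, 1]` for
#' non-negative inputs; not a metric (triangle inequality can fail).
#'
#' @param counts non-negative numeric matrix, features x samples.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- counts[, i]; b <- counts[, j]
    d[i, j] <- d[j, i] <- sum(abs(a - b)) / sum(a + b)
  }
  d
}

check_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12) ||
      any(diag(d) != 0) || any(d < 0))
    stop("expected a symmetric non-negative distance matrix with zero diagonal")
  if (is.null(rownames(d))) dimnames(d) <- list(seq_len(nrow(d)),
                                                seq_len(nrow(d)))
  d
}

#' UPGMA hierarchical clustering
#'
#' Average-linkage (unweighted pair group method with arithmetic mean)
#' agglomeration of a distance matrix. At each step the pair of clusters
#' with the smallest average inter-cluster distance is merged at node
#' height `d/2`; heights are non-decreasing and the implied cophenetic
#' distances are ultrametric. Ties are broken deterministically by the
#' lexicographic order of the cluster leader labels.
#'
#' @param d symmetric distance matrix with labels.
#' @return object of class `c("upgma", "hclust")`: `merge`, `height`
#'   (merge distances, hclust convention), `node_height` (= height / 2),
#'   `labels`, `order`.
#' @export
upgma <- function(d) {
  d <- check_distance_matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least two leaves")
  labels <- rownames(d)
  # active clusters: id (negative = leaf, positive = internal node),
  # size, leader label (lexicographically smallest member, for tie-breaks)
  id <- -seq_len(n); size <- rep(1L, n); leader <- labels
  act <- seq_len(n)
  merge <- matrix(0L, n - 1, 2); height <- numeric(n - 1)
  members <- as.list(seq_len(n))
  D <- d
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bd <- Inf
    for (ii in seq_along(act)[-length(act)]) for (jj in (ii + 1):length(act)) {
      i <- act[ii]; j <- act[jj]
      dij <- D[i, j]
      if (dij < bd - 1e-12) { bd <- dij; best <- c(i, j) } else
      if (abs(dij - bd) <= 1e-12) {
        cand <- sort(c(leader[i], leader[j]))
        cur <- sort(c(leader[best[1]], leader[best[2]]))
        if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
          bd <- dij; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- bd
    # Lance-Williams update for average linkage
    for (k in setdiff(act, c(i, j))) {
      D[i, k] <- D[k, i] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    size[i] <- size[i] + size[j]
    leader[i] <- min(leader[i], leader[j])
    id[i] <- step
    act <- setdiff(act, j)
  }
  order <- members[[act]]
  structure(list(merge = merge, height = height,
                 node_height = height / 2, labels = labels, order = order,
                 method = "average", call = match.call(),
                 dist.method = "user"),
            class = c("upgma", "hclust"))
}

#' Export a UPGMA tree as a Newick string
#'
#' Branch lengths are differences of node heights (leaf height 0), so leaf
#' to root path lengths equal the root node height (ultrametric tree).
#'
#' @param tree an object from [upgma()].
#' @param digits significant digits for branch lengths.
#' @return Newick string, terminated by `;`.
#' @export
upgma_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "upgma"))
  h <- tree$node_height
  rec <- function(node) {
    if (node < 0) list(str = tree$labels[-node], h = 0)
    else {
      l <- rec(tree$merge[node, 1]); r <- rec(tree$merge[node, 2])
      bl <- function(child) format(h[node] - child$h, digits = digits)
      list(str = sprintf("(%s:%s,%s:%s)", l$str, bl(l), r$str, bl(r)),
           h = h[node])
    }
  }
  paste0(rec(nrow(tree$merge))$str, ";")
}

#' Cophenetic distance matrix of a UPGMA tree
#' @param tree an object from [upgma()].
#' @return symmetric matrix of tree distances (2 x node height of the
#'   lowest common ancestor), ultrametric by construction.
#' @export
upgma_cophenetic <- function(tree) {
  stopifnot(inherits(tree, "upgma"))
  n <- length(tree$labels)
  co <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  leaves <- function(node) {
    if (node < 0) -node
    else c(leaves(tree$merge[node, 1]), leaves(tree$merge[node, 2]))
  }
  for (k in seq_len(nrow(tree$merge))) {
    a <- leaves(tree$merge[k, 1]); b <- leaves(tree$merge[k, 2])
    co[a, b] <- co[b, a] <- 2 * tree$node_height[k]
  }
  co
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the total
#' sum of squared distances into among- and within-group components,
#' forms the pseudo-F statistic, and assesses it by free permutation of
#' the group labels. The p-value uses the `(1 + #exceedances) / (1 +
#' n_perm)` estimator and is therefore never exactly zero.
#'
#' @param d symmetric distance matrix.
#' @param groups factor (or coercible) of group labels, one per sample.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param strata optional factor restricting permutations to occur within
#'   its levels (e.g. permute within dog for repeated measures).
#' @param exhaustive enumerate all `n!` label permutations instead of
#'   sampling (only for small n; the p-value then is the exact fraction of
#'   permutations, identity included, with `F >= F_obs`).
#' @return list: `pseudo_F`, `R2`, `p_value`, `n_perm`, `df`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L, strata = NULL,
                      exhaustive = FALSE) {
  d <- check_distance_matrix(d)
  groups <- factor(groups)
  n <- nrow(d)
  stopifnot(length(groups) == n, n_perm >= 1)
  a <- nlevels(groups)
  if (a < 2) stop("need at least two groups")
  if (any(tabulate(groups) == n)) stop("a group equals the full sample set")
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- function(g) {
    s <- 0
    for (lev in levels(groups)) {
      idx <- which(g == lev)
      if (length(idx) > 1)
        s <- s + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    s
  }
  fstat <- function(g) {
    sw <- ss_within(g)
    sa <- ss_total - sw
    (sa / (a - 1)) / (sw / (n - a))
  }
  f_obs <- fstat(groups)
  r2 <- 1 - ss_within(groups) / ss_total
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8 samples")
    perms <- all_permutations(n)
    fs <- vapply(seq_len(nrow(perms)), function(i) fstat(groups[perms[i, ]]),
                 numeric(1))
    return(list(pseudo_F = f_obs, R2 = r2,
                p_value = mean(fs >= f_obs - 1e-12),
                n_perm = nrow(perms), df = c(among = a - 1, within = n - a)))
  }
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      perm <- if (is.null(strata)) sample.int(n) else {
        p <- seq_len(n)
        for (lev in unique(strata)) {
          idx <- which(strata == lev)
          p[idx] <- idx[sample.int(length(idx))]
        }
        p
      }
      fstat(groups[perm]) >= f_obs
    }, logical(1)))
  })
  list(pseudo_F = f_obs, R2 = r2,
       p_value = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm, df = c(among = a - 1, within = n - a))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Write a distance matrix as square TSV
#' @param d distance matrix.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  d <- check_distance_matrix(d)
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
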