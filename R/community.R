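#' Bray-Curtis dissimilarity between samples
#'
#' For sample profiles u, v: `d(u, v) = 1 - 2 * sum(min(u_i, v_i)) /
#' (sum(u) + sum(v))`, which is 0 for identical and 1 for completely
#' dissimilar (no shared taxa) samples.
#'
#' @param x A [profile_matrix] or a plain numeric matrix with taxa in rows
#'   and samples in columns.
#' @return A symmetric numeric matrix of class `dist_matrix` with zero
#'   diagonal and sample keys as dimnames.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "profile_matrix")) x$values else as.matrix(x)
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(m < 0)) stop("profiles must be non-negative", call. = FALSE)
  n <- ncol(m)
  s <- colSums(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- s[i] + s[j]
      if (tot == 0)
        stop(sprintf("distance undefined: samples %d and %d are both all-zero",
                     i, j), call. = FALSE)
      d[i, j] <- d[j, i] <- 1 - 2 * sum(pmin(m[, i], m[, j])) / tot
    }
  }
  structure(d, class = c("dist_matrix", "matrix"))
}

check_dist_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12 ||
      any(abs(diag(d)) > 1e-12))
    stop("not a valid distance matrix (square, symmetric, zero diagonal)",
         call. = FALSE)
  d
}

#' Principal coordinates analysis
#'
#' Metric embedding of a dissimilarity matrix: Gower double-centering of
#' `-D^2 / 2`, symmetric eigendecomposition, and coordinates given by the
#' eigenvectors scaled by the square root of their (positive) eigenvalues.
#' Negative eigenvalues, which arise for non-Euclidean dissimilarities such
#' as Bray-Curtis, are reported unchanged (no Cailliez/Lingoes correction);
#' explained-variance fractions are computed over the positive eigenvalues
#' only.
#'
#' @param d Distance matrix (from [bray_curtis()] or compatible).
#' @return A list of class `pcoa_result` with `coordinates` (samples x
#'   positive axes), `eigenvalues` (all, decreasing) and `explained`
#'   (fractions over positive eigenvalues).
#' @export
pcoa <- function(d) {
  d <- check_dist_matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  j <- diag(n) - matrix(1 / n, n, n)
  b <- j %*% a %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lam <- e$values
  pos <- which(lam > max(lam[1], 0) * 1e-12 & lam > 0)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(lam[pos]), length(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(coordinates = coords, eigenvalues = lam,
                 explained = lam[pos] / sum(lam[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(3L, ncol(x$coordinates))
  cat(sprintf("PCoA: %d samples, %d positive axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("  explained:",
      paste(sprintf("PCo%d %.1f%%", seq_len(k), 100 * x$explained[seq_len(k)]),
            collapse = ", "), "\n")
  if (any(x$eigenvalues < 0))
    cat(sprintf("  (%d negative eigenvalues, min %.3g)\n",
                sum(x$eigenvalues < 0), min(x$eigenvalues)))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities. With ranks taken over all off-diagonal
#' pairs, `R = (mean_between_rank - mean_within_rank) / (n(n-1)/4)`; R lies
#' in [-1, 1], positive R meaning intergroup variation dominates. The
#' p-value is by label permutation with the add-one convention
#' `p = (1 + #{R_perm >= R_obs}) / (1 + n_perm)`, so p is never 0.
#'
#' @param d Distance matrix.
#' @param groups Group labels, one per sample; at least two groups with at
#'   least two samples each.
#' @param n_perm Number of label permutations.
#' @param seed Optional RNG seed.
#' @return A list of class `anosim_result` with `R`, `p_value`,
#'   `n_permutations`, `permuted_R` and `seed`.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- check_dist_matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n)
    stop("'groups' must have one label per sample", call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(tab < 2L))
    stop("singleton group(s): ", paste(names(tab)[tab < 2], collapse = ", "),
         call. = FALSE)
  iu <- which(upper.tri(d))
  rk <- rank(d[iu])
  denom <- n * (n - 1) / 4
  r_stat <- function(g) {
    same <- outer(g, g, "==")[iu]
    (mean(rk[!same]) - mean(rk[same])) / denom
  }
  r_obs <- r_stat(groups)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) r_stat(sample(groups)),
                 numeric(1))
  structure(list(R = r_obs,
                 p_value = (1 + sum(perm >= r_obs)) / (1 + n_perm),
                 n_permutations = n_perm, permuted_R = perm, seed = seed),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
              x$R, x$p_value, x$n_permutations))
  invisible(x)
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates samples by unweighted average linkage: at every step the
#' pair of clusters with the smallest mean inter-cluster dissimilarity is
#' merged at that height. Ties are broken deterministically by the
#' lexicographically smallest pair of cluster representatives (the lowest
#' original sample label in each cluster). The result is a standard
#' `hclust` object, so `plot()`, `cutree()` and Newick export via
#' [as_newick()] all apply.
#'
#' @param d Distance matrix.
#' @return An object of class `hclust` (method `"average"`).
#' @export
hclust_average <- function(d) {
  d <- check_dist_matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  # active clusters: id (<0 leaf, >0 merge row), members, representative label
  act <- lapply(seq_len(n), function(i)
    list(id = -i, members = i, rep = labels[i]))
  cd <- d                     # current mean inter-cluster distances
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(act)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        h <- cd[i, j]
        pair <- sort(c(act[[i]]$rep, act[[j]]$rep))
        if (is.null(best) || h < best$h - 1e-15 ||
            (abs(h - best$h) <= 1e-15 &&
             (pair[1] < best$pair[1] ||
              (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best <- list(i = i, j = j, h = h, pair = pair)
        }
      }
    }
    i <- best$i; j <- best$j
    ids <- sort(c(act[[i]]$id, act[[j]]$id))
    merge[step, ] <- ids
    height[step] <- best$h
    si <- length(act[[i]]$members); sj <- length(act[[j]]$members)
    newd <- (si * cd[i, ] + sj * cd[j, ]) / (si + sj)
    newc <- list(id = step,
                 members = c(act[[i]]$members, act[[j]]$members),
                 rep = min(act[[i]]$rep, act[[j]]$rep))
    keep <- setdiff(seq_len(k), c(i, j))
    cd <- rbind(cbind(cd[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    act <- c(act[keep], list(newc))
  }
  order_of <- function(node) {
    if (node < 0) return(-node)
    c(order_of(merge[node, 1]), order_of(merge[node, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = order_of(n - 1L), labels = labels,
                 method = "average", call = match.call(),
                 dist.method = "user"),
            class = "hclust")
}

#' Export a dendrogram as a Newick string
#'
#' @param h An `hclust` object (e.g. from [hclust_average()]).
#' @param path Optional file to write the tree to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
as_newick <- function(h, path = NULL) {
  phy <- ape::as.phylo(h)
  if (is.null(path)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = path); invisible(path) }
}

#' Write a distance matrix to TSV
#'
#' @param d Distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(d, path) {
  d <- as.matrix(d)
  df <- data.frame(sample = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
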