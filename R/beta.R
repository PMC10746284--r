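#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over taxa; lies in
#' `[0, 1]` for non-negative data. Relative-state input is the usual choice
#' so that unequal sequencing depth does not masquerade as composition.
#'
#' @param table an [abundance_table()].
#' @return symmetric matrix of dissimilarities with sample-id dimnames.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  x <- table$values
  rs <- rowSums(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      denom <- rs[i] + rs[j]
      if (denom == 0)
        stop("samples '", rownames(x)[i], "' and '", rownames(x)[j],
             "' are both all-zero; Bray-Curtis undefined")
      d[i, j] <- d[j, i] <- sum(abs(x[i, ] - x[j, ])) / denom
    }
  }
  d
}

#' Unweighted UniFrac distance matrix
#'
#' Presence/absence phylogenetic dissimilarity: for each pair of samples,
#' the branch length covered by exactly one sample's taxon set divided by
#' the branch length covered by their union. A branch is covered by a sample
#' when any leaf descending from it is present in that sample.
#'
#' @param table an [abundance_table()]; presence is `value > 0`. Column
#'   labels must match tree tip labels for every taxon that is present
#'   somewhere.
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return symmetric matrix of distances in `[0, 1]`.
#' @export
unweighted_unifrac <- function(table, tree) {
  stopifnot(inherits(table, "abundance_table"), inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  x <- table$values
  present <- x > 0
  used <- colnames(x)[colSums(present) > 0]
  missing <- setdiff(used, tree$tip.label)
  if (length(missing) > 0)
    stop("taxa present in the table but absent from the tree: ",
         paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  S <- nrow(x)
  # node x sample coverage indicator, filled tips-first then postorder
  cov <- matrix(FALSE, ntip + nnode, S)
  tipmatch <- match(tree$tip.label, colnames(x))
  has <- !is.na(tipmatch)
  cov[which(has), ] <- t(present[, tipmatch[has], drop = FALSE])
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]
    ch <- po$edge[k, 2]
    cov[p, ] <- cov[p, ] | cov[ch, ]
  }
  # edge k is covered by sample s iff its child node is
  E <- cov[tree$edge[, 2], , drop = FALSE]
  len <- tree$edge.length
  both <- t(E * len) %*% E            # S x S branch length covered by both
  tot <- colSums(E * len)             # per-sample covered length
  union <- outer(tot, tot, "+") - both
  uniq <- outer(tot, tot, "+") - 2 * both
  d <- matrix(0, S, S, dimnames = list(rownames(x), rownames(x)))
  nz <- union > 0
  d[nz] <- uniq[nz] / union[nz]
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-D^2 / 2` (Gower) and eigendecomposes. Axes with
#' eigenvalue above `1e-10` are retained up to `n_axes`; the explained
#' fraction of each axis is its eigenvalue over the sum of positive
#' eigenvalues. Negative eigenvalues (non-Euclidean input) are reported
#' unchanged, with no correction.
#'
#' @param d symmetric distance matrix with sample-id dimnames.
#' @param n_axes number of axes to retain (>= 1).
#' @return list of class `pcoa_result`: `coordinates` (samples x axes),
#'   `explained` (per retained axis), `eigenvalues` (all, sorted
#'   decreasing).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- check_distance_matrix(d)
  if (n_axes < 1) stop("n_axes must be >= 1")
  n <- nrow(d)
  a <- -0.5 * d^2
  g <- sweep(a, 1, rowMeans(a))
  g <- sweep(g, 2, colMeans(g))
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-10)
  if (length(pos) == 0)
    stop("no positive eigenvalues; degenerate distance matrix")
  k <- min(n_axes, length(pos))
  lam <- e$values[pos[seq_len(k)]]
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(lam), k, k)
  dimnames(coords) <- list(rownames(d), paste0("PCo", seq_len(k)))
  structure(list(coordinates = coords,
                 explained = lam / sum(e$values[pos]),
                 eigenvalues = e$values),
            class = "pcoa_result")
}

#' One-way PERMANOVA on a distance matrix
#'
#' Anderson's permutational multivariate analysis of variance.
#' `SS_total = sum_{i<j} d^2 / N`, `SS_within` sums the analogous quantity
#' within each group, pseudo-F = `(SS_between/(a-1)) / (SS_within/(N-a))`
#' and `R^2 = SS_between / SS_total`. With two groups and at most 10,000
#' distinct label assignments the permutation distribution is enumerated
#' exactly; otherwise `n_permutations` seeded Monte Carlo shuffles are used
#' with the +1 correction, so the reported p is never zero.
#'
#' @param d symmetric distance matrix with sample-id dimnames.
#' @param metadata a [sample_metadata()] frame covering the samples of `d`.
#' @param n_permutations Monte Carlo permutation count (default 999).
#' @param seed integer seed for the permutations.
#' @return list of class `permanova_result`: `pseudo_f`, `r_squared`,
#'   `p_value`, `n_permutations` (actual draws or exact count), `seed`,
#'   `mode` (`"exact"` or `"monte_carlo"`).
#' @export
permanova <- function(d, metadata, n_permutations = 999, seed = 1) {
  d <- check_distance_matrix(d)
  md <- align_metadata(metadata, rownames(d))
  g <- droplevels(factor(md$group))
  a <- nlevels(g)
  if (a < 2)
    stop("group labels are constant; PERMANOVA needs >= 2 groups")
  if (any(table(g) < 2))
    stop("every group needs >= 2 samples")
  n <- nrow(d)
  d2 <- d^2
  sst <- sum(d2[upper.tri(d2)]) / n
  gi <- as.integer(g)
  fstat <- function(gidx) {
    ssw <- 0
    for (lev in seq_len(a)) {
      idx <- which(gidx == lev)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ssb <- sst - ssw
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- fstat(gi)
  ssw <- 0
  for (lev in seq_len(a)) {
    idx <- which(gi == lev)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  r2 <- (sst - ssw) / sst
  n1 <- sum(gi == 1L)
  exact <- a == 2 && choose(n, n1) <= 10000
  if (exact) {
    combos <- utils::combn(n, n1)
    fs <- apply(combos, 2, function(idx) {
      gg <- rep(2L, n)
      gg[idx] <- 1L
      fstat(gg)
    })
    p <- mean(fs >= f_obs - 1e-12)
    nper <- ncol(combos)
  } else {
    fs <- with_seed(seed, vapply(seq_len(n_permutations),
                                 function(i) fstat(sample(gi)), 0))
    p <- (1 + sum(fs >= f_obs - 1e-12)) / (1 + n_permutations)
    nper <- n_permutations
  }
  structure(list(pseudo_f = f_obs, r_squared = r2, p_value = p,
                 n_permutations = nper, seed = seed,
                 mode = if (exact) "exact" else "monte_carlo"),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%s, %d perms)\n",
              x$pseudo_f, x$r_squared, x$p_value, x$mode, x$n_permutations))
  invisible(x)
}
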