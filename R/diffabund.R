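#' Per-taxon Wilcoxon screen with BH correction
#'
#' Two-sided rank-sum test (see [compare_groups()]) for every taxon of a
#' relative-state table, Benjamini-Hochberg adjustment across all tested
#' taxa, and significance flags at `p < alpha` (and `q < fdr_q` when the
#' FDR tier is enabled).
#'
#' @param table an [abundance_table()] in the relative state.
#' @param metadata a [sample_metadata()] frame with exactly two group
#'   levels among the table's samples.
#' @param alpha per-taxon p-value threshold (default 0.05).
#' @param fdr_q BH q-value threshold, or `NA` to flag on p alone.
#' @return data.frame with columns `feature_id` (lineage), `mean_<group>`
#'   per group, `p_value`, `q_value`, `direction` (enriched group) and
#'   `significant`.
#' @export
wilcoxon_screen <- function(table, metadata, alpha = 0.05, fdr_q = 0.05) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$state != "relative")
    stop("wilcoxon_screen() expects a relative-state table")
  md <- align_metadata(metadata, rownames(table$values))
  g <- droplevels(factor(md$group))
  if (nlevels(g) != 2)
    stop("exactly two groups required; got ", nlevels(g))
  if (any(table(g) < 2))
    stop("each group needs at least 2 samples")
  lv <- levels(g)
  x <- table$values
  res <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    m1 <- mean(v[g == lv[1]])
    m2 <- mean(v[g == lv[2]])
    ts <- rank_sum_test(v[g == lv[1]], v[g == lv[2]])
    c(m1 = m1, m2 = m2, p = ts$p_value)
  })
  res <- do.call(rbind, res)
  q <- stats::p.adjust(res[, "p"], method = "BH")
  sig <- res[, "p"] < alpha
  if (!is.na(fdr_q)) sig <- sig & q < fdr_q
  out <- data.frame(feature_id = table$taxa$lineage,
                    res[, c("m1", "m2"), drop = FALSE],
                    p_value = res[, "p"], q_value = q,
                    direction = ifelse(res[, "m1"] >= res[, "m2"],
                                       lv[1], lv[2]),
                    significant = sig,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mean_", lv)
  out
}

#' LEfSe-style LDA effect-size screen
#'
#' Two-stage procedure on per-million-scaled relative abundances over one
#' or several taxonomic ranks: (1) a Kruskal-Wallis screen at `kw_alpha`;
#' (2) for the survivors, `n_boot` bootstrap rounds each drawing two thirds
#' of every group without replacement and measuring the class separation of
#' a one-dimensional linear discriminant on the feature (for a single
#' feature the discriminant-aligned separation equals the class-mean
#' difference, which is also LEfSe's regularization term). The effect size
#' is the mean separation over rounds, reported as
#' `sign * log10(max(|effect|, 1) + 1)` and filtered at
#' `|score| >= lda_threshold`.
#'
#' @param tables a relative-state [abundance_table()] or a list of them
#'   (e.g. genus- plus phylum-level) whose features are concatenated, the
#'   LEfSe convention.
#' @param metadata a [sample_metadata()] frame with two group levels.
#' @param kw_alpha stage-1 Kruskal-Wallis alpha (default 0.05).
#' @param lda_threshold minimum absolute log10 LDA score (3.5 for the 16S
#'   screen, 3.0 for ITS in this pipeline's reference use).
#' @param n_boot bootstrap rounds (default 30).
#' @param seed integer seed; results are reproducible and invariant to
#'   sample and taxon order (rounds subsample sample ids sorted within
#'   group).
#' @return data.frame with columns `feature_id`, `lda_score`,
#'   `enriched_group`, `kw_p_value`, sorted by decreasing `|lda_score|`.
#' @export
lefse_lda <- function(tables, metadata, kw_alpha = 0.05, lda_threshold = 3.5,
                      n_boot = 30, seed = 1) {
  if (inherits(tables, "abundance_table")) tables <- list(tables)
  if (n_boot < 1) stop("n_boot must be >= 1")
  for (tb in tables) {
    stopifnot(inherits(tb, "abundance_table"))
    if (tb$state != "relative")
      stop("lefse_lda() expects relative-state tables")
  }
  ids <- rownames(tables[[1]]$values)
  x <- do.call(cbind, lapply(tables, function(tb) {
    if (!identical(rownames(tb$values), ids))
      stop("all tables must share the same samples in the same order")
    tb$values * 1e6
  }))
  feats <- unlist(lapply(tables, function(tb) tb$taxa$lineage))
  colnames(x) <- feats
  md <- align_metadata(metadata, ids)
  g <- droplevels(factor(md$group))
  if (nlevels(g) != 2) stop("exactly two groups required")
  lv <- levels(g)

  kw_p <- vapply(seq_len(ncol(x)), function(j) {
    if (stats::sd(x[, j]) == 0) return(1)
    stats::kruskal.test(x[, j], g)$p.value
  }, 0)
  keep <- which(kw_p < kw_alpha)
  if (length(keep) == 0)
    return(data.frame(feature_id = character(0), lda_score = numeric(0),
                      enriched_group = character(0),
                      kw_p_value = numeric(0)))

  # bootstrap subsamples drawn over sorted sample ids, shared by all
  # features, so output does not depend on input ordering
  ord <- order(ids)
  xs <- x[ord, keep, drop = FALSE]
  gs <- g[ord]
  i1 <- which(gs == lv[1])
  i2 <- which(gs == lv[2])
  k1 <- max(2L, ceiling(2 / 3 * length(i1)))
  k2 <- max(2L, ceiling(2 / 3 * length(i2)))
  effects <- with_seed(seed, {
    acc <- matrix(0, n_boot, length(keep))
    for (b in seq_len(n_boot)) {
      s1 <- sample(i1, k1)
      s2 <- sample(i2, k2)
      acc[b, ] <- colMeans(xs[s1, , drop = FALSE]) -
        colMeans(xs[s2, , drop = FALSE])
    }
    colMeans(acc)
  })
  score <- sign(effects) * log10(pmax(abs(effects), 1) + 1)
  out <- data.frame(feature_id = feats[keep],
                    lda_score = score,
                    enriched_group = ifelse(effects >= 0, lv[1], lv[2]),
                    kw_p_value = kw_p[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[abs(out$lda_score) >= lda_threshold, , drop = FALSE]
  out[order(-abs(out$lda_score), out$feature_id), , drop = FALSE]
}
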