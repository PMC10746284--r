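#' Per-sample alpha diversity
#'
#' Computes, for every sample of a counts-state table: observed richness
#' (Sobs), the bias-corrected Chao1 estimator
#' `Sobs + F1 (F1 - 1) / (2 (F2 + 1))` with `F1`/`F2` the singleton and
#' doubleton counts, Shannon entropy in natural log, and the Gini-Simpson
#' index `1 - sum(p^2)` (higher = more diverse). Chao1 needs singleton
#' counts, so relative-state input is rejected.
#'
#' @param table an [abundance_table()] in the counts state.
#' @return data.frame with columns `sample_id`, `sobs`, `chao1`, `shannon`,
#'   `simpson`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$state != "counts")
    stop("alpha_diversity() is defined on counts, not relative abundances")
  x <- table$values
  if (any(rowSums(x) == 0))
    stop("all-zero sample(s): ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  res <- t(apply(x, 1, function(v) {
    v <- v[v > 0]
    sobs <- length(v)
    f1 <- sum(v == 1)
    f2 <- sum(v == 2)
    chao1 <- sobs + f1 * (f1 - 1) / (2 * (f2 + 1))
    p <- v / sum(v)
    c(sobs = sobs, chao1 = chao1,
      shannon = -sum(p * log(p)), simpson = 1 - sum(p^2))
  }))
  data.frame(sample_id = rownames(x), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-sample fungal-to-bacterial richness ratio (ITS/16S)
#'
#' The equilibrium statistic of the pipeline: observed fungal richness
#' divided by observed bacterial richness, sample by sample.
#'
#' @param fungal,bacterial alpha-diversity data.frames from
#'   [alpha_diversity()], over the same sample set.
#' @return data.frame with columns `sample_id`, `its16s_ratio`.
#' @export
its16s_ratio <- function(fungal, bacterial) {
  if (!setequal(fungal$sample_id, bacterial$sample_id))
    stop("fungal and bacterial tables cover different sample sets")
  b <- bacterial[match(fungal$sample_id, bacterial$sample_id), ]
  if (any(b$sobs == 0))
    stop("bacterial Sobs is zero for sample(s): ",
         paste(fungal$sample_id[b$sobs == 0], collapse = ", "))
  data.frame(sample_id = fungal$sample_id,
             its16s_ratio = fungal$sobs / b$sobs,
             stringsAsFactors = FALSE)
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Two-sided rank-sum test with average ranks for ties. With both group
#' sizes at most 8 the null distribution is enumerated exactly over all
#' label assignments (p = fraction of assignments whose rank sum deviates
#' from its null mean at least as much as the observed one); larger groups
#' use the normal approximation with tie correction.
#'
#' @param values numeric vector, one value per sample.
#' @param metadata a [sample_metadata()] frame whose `sample_id` order
#'   matches `values` (or pass `sample_id` via names of `values`).
#' @param group_pair character of length 2 selecting and ordering the two
#'   group levels; defaults to the first two levels.
#' @return list of class `group_comparison` with elements `statistic` (rank
#'   sum of the first group), `p_value`, `method`, `group_medians` (named),
#'   and `n` (per-group sizes).
#' @export
compare_groups <- function(values, metadata, group_pair = NULL) {
  if (length(values) != nrow(metadata))
    stop("`values` must have one entry per metadata row")
  g <- as.character(metadata$group)
  if (is.null(group_pair)) group_pair <- unique(g)[1:2]
  keep <- g %in% group_pair
  values <- values[keep]
  g <- factor(g[keep], levels = group_pair)
  n <- table(g)
  if (any(n < 2))
    stop("each group needs at least 2 samples; sizes: ",
         paste(n, collapse = ", "))
  x1 <- values[g == group_pair[1]]
  x2 <- values[g == group_pair[2]]
  res <- rank_sum_test(x1, x2)
  structure(list(statistic = res$statistic, p_value = res$p_value,
                 method = "wilcoxon_rank_sum",
                 group_medians = stats::setNames(
                   c(stats::median(x1), stats::median(x2)), group_pair),
                 n = stats::setNames(as.integer(n), group_pair)),
            class = "group_comparison")
}

# Rank-sum core: exact enumeration for small groups, tie-corrected normal
# approximation otherwise. Returns the rank sum of x1 and a two-sided p.
rank_sum_test <- function(x1, x2) {
  n1 <- length(x1)
  n2 <- length(x2)
  r <- rank(c(x1, x2))
  w <- sum(r[seq_len(n1)])
  ew <- n1 * (n1 + n2 + 1) / 2
  if (n1 <= 8 && n2 <= 8) {
    combos <- utils::combn(n1 + n2, n1)
    ws <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(ws - ew) >= abs(w - ew) - 1e-12)
  } else {
    n <- n1 + n2
    ties <- table(r)
    varw <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (varw == 0) {
      p <- 1
    } else {
      z <- (w - ew) / sqrt(varw)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  list(statistic = w, p_value = min(p, 1))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Wilcoxon rank-sum: W =", x$statistic, ", p =",
      format(x$p_value, digits = 4), "\n")
  cat("group medians:", paste(names(x$group_medians),
                              signif(x$group_medians, 4),
                              sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
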