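#' Preprocess a metabolite table (log, then unit-variance scale)
#'
#' Log-transforms positive intensities and autoscales every metabolite to
#' mean 0 and standard deviation 1. Idempotent: a table already in the
#' scaled state is returned unchanged.
#'
#' @param table a [metabolite_table()].
#' @return the table in the `log_uv_scaled` state.
#' @export
preprocess_metabolites <- function(table) {
  stopifnot(inherits(table, "metabolite_table"))
  if (table$state == "log_uv_scaled") return(table)
  x <- table$values
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-positive intensity before log at: ",
         paste(sprintf("(%s, %s)", rownames(x)[bad[, 1]],
                       colnames(x)[bad[, 2]])[seq_len(min(5, nrow(bad)))],
               collapse = ", "))
  lx <- log(x)
  sds <- apply(lx, 2, stats::sd)
  if (any(sds == 0))
    stop("constant metabolite(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  sc <- scale(lx)
  attr(sc, "scaled:center") <- NULL
  attr(sc, "scaled:scale") <- NULL
  metabolite_table(sc + 0, state = "log_uv_scaled")
}

#' Principal component analysis of a metabolite table
#'
#' SVD of the column-centered intensity matrix; explained fractions are the
#' squared singular values over their sum.
#'
#' @param table a [metabolite_table()] (any state; preprocessing is the
#'   caller's choice).
#' @param n_axes number of components to return.
#' @return list of class `metabolite_pca`: `scores`, `loadings`,
#'   `explained` (all components), `sdev`.
#' @export
metabolite_pca <- function(table, n_axes = 2) {
  stopifnot(inherits(table, "metabolite_table"))
  if (n_axes < 1) stop("n_axes must be >= 1")
  pc <- stats::prcomp(table$values, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_axes, ncol(pc$x))
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained = expl, sdev = pc$sdev),
            class = "metabolite_pca")
}

# One round of the O-PLS pipeline on centered y. Returns the filtered X,
# the orthogonal weights/loadings, and the final predictive component.
opls_core <- function(x, y, n_ortho) {
  w_ortho <- list()
  p_ortho <- list()
  t_ortho <- list()
  xf <- x
  for (k in seq_len(n_ortho)) {
    w <- drop(crossprod(xf, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("degenerate X'y; cannot extract a component")
    w <- w / nw
    tt <- drop(xf %*% w)
    p <- drop(crossprod(xf, tt)) / sum(tt^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10)
      stop("no orthogonal variation left at component ", k,
           "; lower n_ortho")
    wo <- wo / nwo
    to <- drop(xf %*% wo)
    po <- drop(crossprod(xf, to)) / sum(to^2)
    xf <- xf - tcrossprod(to, po)
    w_ortho[[k]] <- wo
    p_ortho[[k]] <- po
    t_ortho[[k]] <- to
  }
  w <- drop(crossprod(xf, y))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("degenerate X'y; cannot extract a component")
  w <- w / nw
  tt <- drop(xf %*% w)
  p <- drop(crossprod(xf, tt)) / sum(tt^2)
  cc <- sum(y * tt) / sum(tt^2)
  list(x_filtered = xf, w = w, t = tt, p = p, c = cc,
       w_ortho = w_ortho, p_ortho = p_ortho, t_ortho = t_ortho)
}

# Apply a fitted O-PLS filter to new data and predict centered y.
opls_predict <- function(fit, xnew) {
  xf <- xnew
  for (k in seq_along(fit$w_ortho)) {
    to <- drop(xf %*% fit$w_ortho[[k]])
    xf <- xf - tcrossprod(to, fit$p_ortho[[k]])
  }
  drop(xf %*% fit$w) * fit$c
}

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal signal correction (`n_ortho` components, Trygg-Wold O-PLS)
#' followed by a single predictive PLS component (NIPALS) against the
#' centered class code y = +/-1. `R2Y` is the fraction of class variance
#' explained on the training data; `Q2` comes from stratified k-fold
#' cross-validated predictions. VIP uses the standard weighted-loadings
#' formula over the predictive and orthogonal components, so the mean of
#' squared VIP over metabolites is identically 1. With `n_ortho = 0` the
#' model reduces to plain single-component PLS-DA.
#'
#' @param table a preprocessed [metabolite_table()] (`log_uv_scaled`).
#' @param metadata a [sample_metadata()] frame with two group levels.
#' @param n_ortho number of orthogonal components (default 1; must be
#'   below the rank of the data).
#' @param cv_folds folds for Q2 (default 7, stratified by group).
#' @param seed integer seed for the fold assignment.
#' @return list of class `opls_model`: `predictive_scores`,
#'   `predictive_loadings`, `orthogonal_scores`, `orthogonal_loadings`,
#'   `weights`, `r2y`, `q2`, `vip`, `groups`, `y`, plus the settings.
#' @export
oplsda_fit <- function(table, metadata, n_ortho = 1, cv_folds = 7, seed = 1) {
  stopifnot(inherits(table, "metabolite_table"))
  if (table$state != "log_uv_scaled")
    stop("oplsda_fit() expects a preprocessed (log_uv_scaled) table; ",
         "run preprocess_metabolites() first")
  x <- table$values
  md <- align_metadata(metadata, rownames(x))
  g <- droplevels(factor(md$group))
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (n_ortho < 0) stop("n_ortho must be >= 0")
  rk <- qr(x)$rank
  if (n_ortho >= rk)
    stop("n_ortho (", n_ortho, ") must be below the rank of X (", rk, ")")
  yraw <- ifelse(g == levels(g)[1], -1, 1)
  y <- yraw - mean(yraw)
  fit <- opls_core(x, y, n_ortho)
  yhat <- fit$t * fit$c
  ssy <- sum(y^2)
  r2y <- 1 - sum((y - yhat)^2) / ssy

  # stratified, seeded fold assignment
  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (lev in levels(g)) {
      idx <- sample(which(g == lev))
      f[idx] <- rep_len(seq_len(cv_folds), length(idx))
    }
    f
  })
  press <- 0
  for (k in sort(unique(folds))) {
    tr <- folds != k
    if (sum(tr) < 3 || length(unique(g[tr])) < 2) next
    ytr <- y[tr]
    cvfit <- opls_core(x[tr, , drop = FALSE], ytr, n_ortho)
    pred <- opls_predict(cvfit, x[!tr, , drop = FALSE])
    press <- press + sum((y[!tr] - pred)^2)
  }
  q2 <- 1 - press / ssy

  # VIP over predictive + orthogonal components, weighted by the y sum of
  # squares each component explains
  ws <- c(list(fit$w), fit$w_ortho)
  ssy_comp <- vapply(c(list(fit$t), fit$t_ortho), function(tt) {
    cc <- sum(y * tt) / sum(tt^2)
    cc^2 * sum(tt^2)
  }, 0)
  p_feat <- ncol(x)
  wsq <- vapply(ws, function(w) w^2, numeric(p_feat))
  vip <- sqrt(p_feat * drop(wsq %*% ssy_comp) / sum(ssy_comp))
  names(vip) <- colnames(x)

  structure(list(predictive_scores = stats::setNames(fit$t, rownames(x)),
                 predictive_loadings = stats::setNames(fit$p, colnames(x)),
                 weights = stats::setNames(fit$w, colnames(x)),
                 orthogonal_scores = do.call(cbind, fit$t_ortho),
                 orthogonal_loadings = do.call(cbind, fit$p_ortho),
                 r2y = r2y, q2 = q2, vip = vip,
                 groups = levels(g), y = y, n_ortho = n_ortho,
                 cv_folds = cv_folds, seed = seed),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("OPLS-DA (%d orthogonal): R2Y = %.3f, Q2 = %.3f\n",
              x$n_ortho, x$r2y, x$q2))
  invisible(x)
}

#' Permutation test of an OPLS-DA model
#'
#' Refits the model under `n_perm` seeded permutations of the class labels
#' and reports `p = (1 + #{permuted >= observed}) / (1 + n_perm)` for both
#' R2Y and Q2.
#'
#' @param table preprocessed [metabolite_table()].
#' @param metadata a [sample_metadata()] frame with two groups.
#' @param n_ortho,cv_folds model settings, as in [oplsda_fit()].
#' @param n_perm number of permutations (default 199).
#' @param seed integer seed.
#' @return list of class `opls_permutation`: `p_r2y`, `p_q2`,
#'   `observed_r2y`, `observed_q2`, `n_perm`, `seed`.
#' @export
oplsda_permutation_test <- function(table, metadata, n_ortho = 1,
                                    cv_folds = 7, n_perm = 199, seed = 1) {
  obs <- oplsda_fit(table, metadata, n_ortho = n_ortho, cv_folds = cv_folds,
                    seed = seed)
  md <- align_metadata(metadata, rownames(table$values))
  stats_perm <- with_seed(seed, {
    out <- matrix(NA_real_, n_perm, 2)
    for (i in seq_len(n_perm)) {
      pm <- md
      pm$group <- pm$group[sample(nrow(pm))]
      fit <- try(oplsda_fit(table, pm, n_ortho = n_ortho,
                            cv_folds = cv_folds, seed = seed),
                 silent = TRUE)
      if (!inherits(fit, "try-error")) out[i, ] <- c(fit$r2y, fit$q2)
    }
    out
  })
  ok <- !is.na(stats_perm[, 1])
  structure(list(
    p_r2y = (1 + sum(stats_perm[ok, 1] >= obs$r2y - 1e-12)) / (1 + sum(ok)),
    p_q2 = (1 + sum(stats_perm[ok, 2] >= obs$q2 - 1e-12)) / (1 + sum(ok)),
    observed_r2y = obs$r2y, observed_q2 = obs$q2,
    n_perm = sum(ok), seed = seed), class = "opls_permutation")
}

#' Screen differential metabolites (VIP plus univariate test, two tiers)
#'
#' Tier 1 keeps metabolites with `VIP > vip_min` and a univariate two-sided
#' p below `p_max`; tier 2 additionally requires the BH q-value (adjusted
#' across all metabolites) below `q_max`. The univariate test is Student's
#' t by default, or the rank-sum test.
#'
#' @param table preprocessed [metabolite_table()].
#' @param metadata a [sample_metadata()] frame with two groups.
#' @param model the fitted [oplsda_fit()] model supplying VIP.
#' @param vip_min VIP threshold (default 1.5).
#' @param p_max,q_max univariate and FDR thresholds (default 0.05 each).
#' @param test `"t"` (default) or `"wilcoxon"`.
#' @return data.frame with `feature_id`, per-group means of the scaled
#'   intensities, `p_value`, `q_value`, `vip`, `direction`, `tier1`,
#'   `tier2`.
#' @export
screen_metabolites <- function(table, metadata, model, vip_min = 1.5,
                               p_max = 0.05, q_max = 0.05,
                               test = c("t", "wilcoxon")) {
  stopifnot(inherits(table, "metabolite_table"),
            inherits(model, "opls_model"))
  test <- match.arg(test)
  x <- table$values
  md <- align_metadata(metadata, rownames(x))
  g <- droplevels(factor(md$group))
  lv <- levels(g)
  if (length(lv) != 2) stop("exactly two groups required")
  pv <- vapply(seq_len(ncol(x)), function(j) {
    a <- x[g == lv[1], j]
    b <- x[g == lv[2], j]
    if (test == "t") {
      if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
      stats::t.test(a, b)$p.value
    } else {
      rank_sum_test(a, b)$p_value
    }
  }, 0)
  qv <- stats::p.adjust(pv, method = "BH")
  m1 <- colMeans(x[g == lv[1], , drop = FALSE])
  m2 <- colMeans(x[g == lv[2], , drop = FALSE])
  vip <- model$vip[colnames(x)]
  tier1 <- vip > vip_min & pv < p_max
  tier2 <- tier1 & qv < q_max
  out <- data.frame(feature_id = colnames(x), m1 = m1, m2 = m2,
                    p_value = pv, q_value = qv, vip = unname(vip),
                    direction = ifelse(m1 >= m2, lv[1], lv[2]),
                    tier1 = tier1, tier2 = tier2,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mean_", lv)
  out
}
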