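#' Edge-inclusion parameters for trans-kingdom networks
#'
#' The construction criteria of the correlation network are deliberately
#' explicit and config-exposed: a genus enters the candidate set when it
#' occupies at least `min_prevalence` of the shared samples and its mean
#' relative abundance reaches `min_mean_abundance`; a pair becomes an edge
#' when the Spearman correlation passes `min_abs_rho` in magnitude and its
#' (optionally BH-adjusted) p-value passes `p_threshold`.
#'
#' @param min_prevalence fraction of samples a genus must occupy
#'   (default 0.2).
#' @param min_mean_abundance relative-abundance floor (default 1e-4).
#' @param min_abs_rho minimum absolute Spearman rho in (0, 1)
#'   (default 0.6).
#' @param p_threshold significance threshold (default 0.05).
#' @param adjust `"BH"` (default) applies Benjamini-Hochberg across all
#'   tested pairs before thresholding; `"none"` uses raw p.
#' @return list of class `network_params`.
#' @export
network_params <- function(min_prevalence = 0.2, min_mean_abundance = 1e-4,
                           min_abs_rho = 0.6, p_threshold = 0.05,
                           adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  if (min_prevalence < 0 || min_prevalence > 1)
    stop("min_prevalence must lie in [0, 1]")
  if (min_mean_abundance < 0) stop("min_mean_abundance must be >= 0")
  if (min_abs_rho <= 0 || min_abs_rho >= 1)
    stop("min_abs_rho must lie in (0, 1)")
  if (p_threshold <= 0 || p_threshold > 1)
    stop("p_threshold must lie in (0, 1]")
  structure(list(min_prevalence = min_prevalence,
                 min_mean_abundance = min_mean_abundance,
                 correlation = "spearman",
                 min_abs_rho = min_abs_rho,
                 p_threshold = p_threshold,
                 adjust = adjust),
            class = "network_params")
}

#' Build a trans-kingdom Spearman correlation network
#'
#' Filters genera of both kingdoms by prevalence and mean abundance on
#' their shared samples, computes Spearman rho (average ranks) for every
#' remaining pair -- within and across kingdoms -- with a t-approximation
#' p-value (exact enumeration below 10 samples), applies the edge criteria
#' of [network_params()], and drops isolated genera from the graph.
#'
#' @param bact,fungi relative-state [abundance_table()]s sharing at least
#'   4 samples.
#' @param params a [network_params()] object.
#' @return list of class `correlation_network`: `nodes` (data.frame `id`,
#'   `kingdom`, `mean_abundance`) and `edges` (data.frame `from`, `to`,
#'   `rho`, `p`, `q`, `sign`), plus `n_samples` and `params`.
#' @export
build_transkingdom_network <- function(bact, fungi, params = network_params()) {
  stopifnot(inherits(bact, "abundance_table"),
            inherits(fungi, "abundance_table"),
            inherits(params, "network_params"))
  if (bact$state != "relative" || fungi$state != "relative")
    stop("network construction expects relative-state tables")
  shared <- intersect(rownames(bact$values), rownames(fungi$values))
  if (length(shared) < 4)
    stop("need at least 4 shared samples for rank correlation; got ",
         length(shared))
  shared <- sort(shared)
  pick <- function(tb) {
    v <- tb$values[shared, , drop = FALSE]
    prev <- colMeans(v > 0)
    mab <- colMeans(v)
    keep <- prev >= params$min_prevalence & mab >= params$min_mean_abundance
    list(values = v[, keep, drop = FALSE],
         labels = tb$taxa$label[keep],
         mean_abundance = mab[keep])
  }
  b <- pick(bact)
  f <- pick(fungi)
  ids <- c(paste0("bacteria:", b$labels), paste0("fungi:", f$labels))
  kingdoms <- c(rep("bacteria", length(b$labels)),
                rep("fungi", length(f$labels)))
  x <- cbind(b$values, f$values)
  colnames(x) <- ids
  # stable column order so concatenation order of the kingdoms is moot
  ord <- order(ids)
  x <- x[, ord, drop = FALSE]
  kingdoms <- kingdoms[ord]
  mab <- c(b$mean_abundance, f$mean_abundance)[ord]
  ids <- ids[ord]
  p_feat <- ncol(x)
  if (p_feat < 2)
    return(structure(list(nodes = data.frame(id = character(0),
                                             kingdom = character(0),
                                             mean_abundance = numeric(0)),
                          edges = empty_edges(),
                          n_samples = length(shared), params = params),
                     class = "correlation_network"))
  rk <- apply(x, 2, rank)
  keepvar <- apply(rk, 2, stats::sd) > 0
  rho <- matrix(NA_real_, p_feat, p_feat)
  rho[keepvar, keepvar] <- stats::cor(rk[, keepvar, drop = FALSE])
  n <- length(shared)
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  pr <- rho[pairs]
  pv <- rep(NA_real_, nrow(pairs))
  ok <- !is.na(pr)
  if (n < 10) {
    pv[ok] <- vapply(which(ok), function(k) {
      spearman_p(pr[k], rk[, pairs[k, 1]], rk[, pairs[k, 2]])
    }, 0)
  } else {
    r <- pmin(pmax(pr[ok], -1), 1)
    tv <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    pv[ok] <- 2 * stats::pt(-abs(tv), df = n - 2)
    pv[ok][abs(r) >= 1] <- 0
  }
  qv <- rep(NA_real_, length(pv))
  qv[ok] <- stats::p.adjust(pv[ok], method = "BH")
  crit <- if (params$adjust == "BH") qv else pv
  sel <- ok & abs(pr) >= params$min_abs_rho & crit < params$p_threshold
  edges <- data.frame(from = ids[pairs[sel, 1]],
                      to = ids[pairs[sel, 2]],
                      rho = pr[sel], p = pv[sel], q = qv[sel],
                      sign = ifelse(pr[sel] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  used <- ids %in% c(edges$from, edges$to)
  nodes <- data.frame(id = ids[used], kingdom = kingdoms[used],
                      mean_abundance = mab[used],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, n_samples = n,
                 params = params),
            class = "correlation_network")
}

empty_edges <- function() {
  data.frame(from = character(0), to = character(0), rho = numeric(0),
             p = numeric(0), q = numeric(0), sign = character(0),
             stringsAsFactors = FALSE)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                directed = FALSE,
                                vertices = net$nodes$id)
}

#' Summarize a correlation network
#'
#' The summary parameters of a trans-kingdom network: node counts by
#' kingdom and their fungi:bacteria ratio, signed edge counts, relative
#' connectedness (edges per node), and the number of clusters (connected
#' components, so each dyad or triad detached from the main component
#' counts separately).
#'
#' @param net a [build_transkingdom_network()] result.
#' @return list of class `network_summary` with fields `n_nodes`,
#'   `n_fungal_nodes`, `n_bacterial_nodes`, `fungi_bacteria_ratio`,
#'   `n_edges`, `n_positive_edges`, `n_negative_edges`,
#'   `relative_connectedness`, `n_clusters`.
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "correlation_network"))
  if (nrow(net$nodes) == 0)
    stop("empty network: no nodes survive the edge criteria")
  nf <- sum(net$nodes$kingdom == "fungi")
  nb <- sum(net$nodes$kingdom == "bacteria")
  g <- as_igraph(net)
  structure(list(
    n_nodes = nrow(net$nodes),
    n_fungal_nodes = nf,
    n_bacterial_nodes = nb,
    fungi_bacteria_ratio = if (nb > 0) nf / nb else NA_real_,
    n_edges = nrow(net$edges),
    n_positive_edges = sum(net$edges$sign == "positive"),
    n_negative_edges = sum(net$edges$sign == "negative"),
    relative_connectedness = relative_connectedness(nrow(net$edges),
                                                    nrow(net$nodes)),
    n_clusters = igraph::components(g)$no), class = "network_summary")
}

#' Relative connectedness of a network
#'
#' Edges per node; the complexity parameter reported alongside node and
#' edge counts in trans-kingdom network summaries.
#'
#' @param n_edges,n_nodes edge and node counts (`n_nodes > 0`).
#' @return numeric.
#' @export
relative_connectedness <- function(n_edges, n_nodes) {
  if (n_nodes <= 0) stop("n_nodes must be positive")
  n_edges / n_nodes
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("nodes %d (fungi %d / bacteria %d, ratio %.2f)\n",
              x$n_nodes, x$n_fungal_nodes, x$n_bacterial_nodes,
              x$fungi_bacteria_ratio))
  cat(sprintf("edges %d (positive %d / negative %d)\n", x$n_edges,
              x$n_positive_edges, x$n_negative_edges))
  cat(sprintf("relative connectedness %.2f, clusters %d\n",
              x$relative_connectedness, x$n_clusters))
  invisible(x)
}

#' Detect network modules (connected components)
#'
#' Modules are the connected components of the correlation graph;
#' components smaller than `min_size` are discarded. Ordering is
#' deterministic: decreasing size, ties broken by the lexically smallest
#' member.
#'
#' @param net a [build_transkingdom_network()] result.
#' @param min_size minimum component size (default 3).
#' @return list of character vectors of node ids (each sorted).
#' @export
detect_modules <- function(net, min_size = 3) {
  stopifnot(inherits(net, "correlation_network"))
  if (nrow(net$nodes) == 0) return(list())
  comp <- igraph::components(as_igraph(net))
  mods <- split(names(comp$membership), comp$membership)
  mods <- lapply(mods, function(m) sort(unname(m)))
  mods <- mods[vapply(mods, length, 0L) >= min_size]
  if (length(mods) == 0) return(list())
  ord <- order(-vapply(mods, length, 0L),
               vapply(mods, `[`, "", 1))
  unname(mods[ord])
}

#' Per-sample module abundance profile
#'
#' The summary signal of a module: each member genus is z-scored across
#' samples and the per-sample mean of the standardized members is returned.
#'
#' @param module character vector of node ids (`kingdom:label`) or plain
#'   genus labels.
#' @param table the [abundance_table()] holding the members.
#' @return named numeric vector (one value per sample, mean 0).
#' @export
module_profile <- function(module, table) {
  stopifnot(inherits(table, "abundance_table"))
  labels <- sub("^(bacteria|fungi):", "", module)
  idx <- match(labels, table$taxa$label)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0)
    stop("no module member found in the table")
  z <- scale(table$values[, idx, drop = FALSE])
  if (any(is.nan(z)))
    stop("constant member abundance; cannot standardize")
  stats::setNames(rowMeans(z), rownames(table$values))
}

#' Partial Spearman correlation between two module profiles
#'
#' Rank-transforms both profiles and the covariate, residualizes the
#' profile ranks on the covariate ranks by least squares, and reports the
#' Pearson correlation of the residuals with a t-approximation p-value on
#' `n - 3` degrees of freedom. With a constant covariate this reduces to
#' the plain Spearman correlation.
#'
#' @param profile_a,profile_b aligned per-sample numeric vectors (n >= 5).
#' @param covariate per-sample numeric adjustment variable (e.g. alcohol
#'   intake in g/day).
#' @param covariate_name label stored in the result.
#' @return list of class `module_correlation`: `partial_rho`, `p_value`,
#'   `covariate_name`, `n`.
#' @export
module_correlation <- function(profile_a, profile_b, covariate,
                               covariate_name = "covariate") {
  n <- length(profile_a)
  if (length(profile_b) != n || length(covariate) != n)
    stop("profiles and covariate must be aligned")
  if (n < 5) stop("need at least 5 samples")
  if (stats::sd(profile_a) == 0 || stats::sd(profile_b) == 0)
    stop("constant profile; correlation undefined")
  ra <- rank(profile_a)
  rb <- rank(profile_b)
  rc <- rank(covariate)
  resid_on <- function(y) stats::lm.fit(cbind(1, rc), y)$residuals
  ea <- resid_on(ra)
  eb <- resid_on(rb)
  r <- stats::cor(ea, eb)
  r <- min(max(r, -1), 1)
  tval <- r * sqrt((n - 3) / pmax(1 - r^2, 1e-300))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tval), df = n - 3)
  structure(list(partial_rho = r, p_value = p,
                 covariate_name = covariate_name, n = n),
            class = "module_correlation")
}

#' Write a network as an edge-list TSV (and optionally GraphML)
#'
#' @param net a [build_transkingdom_network()] result.
#' @param path output TSV path (columns source, target, signed weight).
#' @param graphml optional GraphML path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, graphml = NULL) {
  stopifnot(inherits(net, "correlation_network"))
  utils::write.table(data.frame(source = net$edges$from,
                                target = net$edges$to,
                                weight = net$edges$rho),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml)) {
    g <- as_igraph(net)
    igraph::E(g)$weight <- net$edges$rho
    igraph::V(g)$kingdom <- net$nodes$kingdom[match(igraph::V(g)$name,
                                                    net$nodes$id)]
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}
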