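# Small fixtures built in code, shared across test files.

make_table <- function(values, genera = NULL, kingdom = "bacteria",
                       state = "counts", phylum = NULL) {
  if (is.null(genera)) genera <- paste0("G", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  king <- if (kingdom == "bacteria") "Bacteria" else "Fungi"
  if (is.null(phylum)) phylum <- rep("PhyA", length(genera))
  lin <- paste0("k__", king, ";p__", phylum, ";c__C1;o__O1;f__F1;g__", genera)
  abundance_table(values, lin, kingdom = kingdom, state = state)
}

two_group_metadata <- function(ids, n1, labels = c("CT", "AD")) {
  sample_metadata(ids, factor(rep(labels, c(n1, length(ids) - n1)),
                              levels = labels))
}

# Correlation-network object built directly from an edge list, for testing
# summaries and module detection without running the correlation machinery.
fake_network <- function(edges, kingdoms = NULL) {
  ids <- sort(unique(c(edges$from, edges$to)))
  if (is.null(kingdoms)) kingdoms <- rep("bacteria", length(ids))
  edges$rho <- if (is.null(edges$rho)) rep(0.9, nrow(edges)) else edges$rho
  edges$p <- rep(1e-4, nrow(edges))
  edges$q <- rep(1e-3, nrow(edges))
  edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  structure(list(nodes = data.frame(id = ids, kingdom = kingdoms,
                                    mean_abundance = rep(0.01, length(ids)),
                                    stringsAsFactors = FALSE),
                 edges = edges, n_samples = 30,
                 params = network_params()),
            class = "correlation_network")
}

# Minimal single-component NIPALS PLS1 on centered data: the independent
# reference for OPLS-DA with no orthogonal components.
nipals_pls1 <- function(x, y) {
  y <- y - mean(y)
  w <- drop(crossprod(x, y))
  w <- w / sqrt(sum(w^2))
  tt <- drop(x %*% w)
  cc <- sum(y * tt) / sum(tt^2)
  yhat <- tt * cc
  list(w = w, scores = tt, r2y = 1 - sum((y - yhat)^2) / sum(y^2))
}

# Group-wise subset of a cohort's kingdom table.
cohort_subset <- function(table, ids) {
  table$values <- table$values[ids, , drop = FALSE]
  table
}

# Relative connectedness of a group's trans-kingdom network within a
# cohort; an edgeless network counts as connectedness 0 and fungal ratio 0.
group_network_summary <- function(cohort, grp, params = network_params()) {
  ids <- cohort$metadata$sample_id[cohort$metadata$group == grp]
  net <- build_transkingdom_network(
    to_relative(cohort_subset(cohort$bacterial_table, ids)),
    to_relative(cohort_subset(cohort$fungal_table, ids)), params)
  if (nrow(net$nodes) == 0)
    return(list(relative_connectedness = 0, fungi_bacteria_ratio = 0,
                n_nodes = 0, net = net))
  s <- summarize_network(net)
  s$net <- net
  s
}
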