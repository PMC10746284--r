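#' Construct an abundance table
#'
#' The central container of the pipeline: a samples-by-taxa matrix of
#' non-negative counts or relative abundances, tagged with the kingdom the
#' marker gene profiles (16S bacteria or ITS fungi) and with a rank-prefixed
#' lineage for every taxon. Samples are always rows and taxa always columns.
#'
#' @param values numeric matrix, samples in rows, taxa in columns. Row names
#'   are sample identifiers; they must be unique.
#' @param lineages character vector of rank-prefixed, semicolon-separated
#'   lineage strings (`k__...;p__...;c__...;o__...;f__...;g__...`), one per
#'   column of `values`. Unassigned ranks keep the prefix with an empty
#'   suffix.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @param state `"counts"` (default) or `"relative"`. In the relative state
#'   every sample row must sum to 1.
#' @return An object of class `abundance_table`: a list with elements
#'   `values` (matrix), `taxa` (data.frame with `lineage`, `label`, `genus`,
#'   `kingdom`), `kingdom`, and `state`.
#' @export
abundance_table <- function(values, lineages, kingdom = c("bacteria", "fungi"),
                            state = c("counts", "relative")) {
  kingdom <- match.arg(kingdom)
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(values)))
    stop("`values` must have sample identifiers as row names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (length(lineages) != ncol(values))
    stop("need one lineage per taxon column: got ", length(lineages),
         " lineages for ", ncol(values), " columns")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative abundance at sample '", rownames(values)[neg[1, 1]],
         "', taxon column ", neg[1, 2])
  taxa <- parse_lineages(lineages)
  if (anyDuplicated(taxa$lineage))
    stop("duplicate taxon lineages: ",
         paste(unique(taxa$lineage[duplicated(taxa$lineage)]), collapse = ", "))
  colnames(values) <- taxa$label
  if (state == "relative") {
    rs <- rowSums(values)
    if (any(rs == 0))
      stop("all-zero sample(s) in relative state: ",
           paste(rownames(values)[rs == 0], collapse = ", "))
    if (any(abs(rs - 1) > 1e-9))
      stop("relative-state rows must sum to 1; offending sample(s): ",
           paste(rownames(values)[abs(rs - 1) > 1e-9], collapse = ", "))
  }
  structure(list(values = values, taxa = taxa, kingdom = kingdom,
                 state = state),
            class = "abundance_table")
}

rank_prefixes <- c("k", "p", "c", "o", "f", "g", "s")
rank_names <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                f = "family", g = "genus", s = "species")

#' Parse rank-prefixed lineage strings
#'
#' Lineages use the `k__/p__/c__/o__/f__/g__` dialect with semicolons between
#' ranks. Genus-level input carries 6 ranks (7 with species); truncated
#' prefixes produced by [aggregate_rank()] are also accepted.
#'
#' @param lineages character vector of lineage strings.
#' @return data.frame with columns `lineage`, `label` (last named rank),
#'   `genus` (suffix of the deepest rank) and `kingdom` (lower-cased `k__`
#'   suffix).
#' @export
parse_lineages <- function(lineages) {
  out <- lapply(seq_along(lineages), function(i) {
    ln <- lineages[[i]]
    parts <- strsplit(ln, ";", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    if (length(parts) < 1 || length(parts) > 7)
      stop("lineage ", i, " ('", ln, "') has ", length(parts),
           " ranks; expected 1-7 (kingdom down to genus/species)")
    pref <- substr(parts, 1, 3)
    expected <- paste0(rank_prefixes[seq_along(parts)], "__")
    bad <- which(pref != expected)
    if (length(bad) > 0)
      stop("lineage ", i, " ('", ln, "'): rank ", bad[1],
           " should start with '", expected[bad[1]], "'")
    suffix <- substring(parts, 4)
    named <- which(nzchar(suffix))
    label <- if (length(named) > 0) suffix[max(named)] else ln
    list(lineage = ln, label = label, genus = suffix[length(suffix)],
         kingdom = tolower(suffix[1]))
  })
  data.frame(lineage = vapply(out, `[[`, "", "lineage"),
             label = vapply(out, `[[`, "", "label"),
             genus = vapply(out, `[[`, "", "genus"),
             kingdom = vapply(out, `[[`, "", "kingdom"),
             stringsAsFactors = FALSE)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$values), "samples x", ncol(x$values),
      x$kingdom, "taxa (", x$state, ")\n")
  invisible(x)
}

#' Read an abundance table from TSV/CSV
#'
#' Expects a header row of lineage strings, with the first column holding
#' sample identifiers (one row per sample). The delimiter is inferred from
#' the file extension (`.csv` is comma-separated, anything else tab).
#'
#' @param path file path.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @param state `"counts"` or `"relative"`.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, kingdom = c("bacteria", "fungi"),
                                 state = c("counts", "relative")) {
  kingdom <- match.arg(kingdom)
  state <- match.arg(state)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 2)
    stop("'", path, "': need a sample-id column plus at least one taxon")
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stop("'", path, "': non-numeric abundance at row ", bad[1, 1],
         ", column ", bad[1, 2] + 1)
  }
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("'", path, "': negative value at sample '", ids[neg[1, 1]],
         "', taxon '", colnames(mat)[neg[1, 2]], "'")
  rownames(mat) <- ids
  abundance_table(mat, colnames(mat), kingdom = kingdom, state = state)
}

#' Write an abundance table to TSV/CSV
#'
#' Inverse of [read_abundance_table()]: first column `sample_id`, remaining
#' header cells are full lineage strings.
#'
#' @param table an [abundance_table()].
#' @param path output path; `.csv` writes comma-separated, else tab.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", table$taxa$lineage)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Total-sum scaling: every sample row is divided by its total, so rows sum
#' to one. Relative abundances are kept as proportions in `[0, 1]`.
#'
#' @param table an [abundance_table()] in the counts state.
#' @return The table in the relative state.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$state != "counts")
    stop("to_relative() expects a counts-state table")
  rs <- rowSums(table$values)
  if (any(rs == 0))
    stop("all-zero sample(s): ",
         paste(rownames(table$values)[rs == 0], collapse = ", "))
  out <- table
  out$values <- table$values / rs
  out$state <- "relative"
  out
}

#' Aggregate a table to a higher taxonomic rank
#'
#' Columns sharing an identical lineage prefix down to `rank` are summed and
#' the lineage is truncated at that rank. Aggregating at genus level is the
#' identity and total abundance is conserved at any rank.
#'
#' @param table an [abundance_table()].
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return An [abundance_table()] at the requested rank.
#' @export
aggregate_rank <- function(table, rank) {
  stopifnot(inherits(table, "abundance_table"))
  idx <- match(rank, rank_names)
  if (is.na(idx))
    stop("unknown rank '", rank, "'; expected one of: ",
         paste(rank_names, collapse = ", "))
  prefixes <- vapply(strsplit(table$taxa$lineage, ";", fixed = TRUE),
                     function(p) paste(trimws(p)[seq_len(min(idx, length(p)))],
                                       collapse = ";"),
                     "")
  groups <- factor(prefixes, levels = unique(prefixes))
  agg <- t(rowsum(t(table$values), groups))
  # rowsum keeps factor-level order = first appearance
  abundance_table(agg, levels(groups), kingdom = table$kingdom,
                  state = table$state)
}

#' Construct sample metadata
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group factor or character group labels (e.g. `AD` / `CT`).
#' @param ... named numeric covariates (e.g. `alcohol_gday`), one value per
#'   sample.
#' @return data.frame of class `sample_metadata` with columns `sample_id`,
#'   `group` and any covariates.
#' @export
sample_metadata <- function(sample_id, group, ...) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample identifiers in metadata")
  if (length(group) != length(sample_id))
    stop("`group` must have one label per sample")
  covs <- list(...)
  if (length(covs) > 0 && is.null(names(covs)))
    stop("covariates must be named")
  df <- data.frame(sample_id = sample_id,
                   group = factor(group),
                   stringsAsFactors = FALSE)
  for (nm in names(covs)) {
    if (length(covs[[nm]]) != length(sample_id))
      stop("covariate '", nm, "' must have one value per sample")
    df[[nm]] <- as.numeric(covs[[nm]])
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

# Align a metadata frame to a set of sample ids, erroring on mismatch.
align_metadata <- function(metadata, sample_ids) {
  m <- match(sample_ids, metadata$sample_id)
  if (anyNA(m))
    stop("samples missing from metadata: ",
         paste(sample_ids[is.na(m)], collapse = ", "))
  metadata[m, , drop = FALSE]
}

# Validate a square symmetric non-negative zero-diagonal distance matrix.
check_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix needs sample-id dimnames")
  if (any(d < 0)) stop("distances must be non-negative")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-12) stop("distance matrix diagonal must be zero")
  d
}
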