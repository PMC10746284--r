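#' Configuration for a synthetic two-group cohort
#'
#' Defines the generative conditions for a paired bacterial/fungal cohort
#' with a correlated metabolite layer and behavioral endpoints. The defaults
#' describe an alcohol-dependence-like contrast: strong cross-kingdom
#' coupling in the control group, weakened coupling and a fungal richness
#' deficit in the affected group, a location shift on the shared latent
#' factors sized so the metabolite layer supports a cross-validated
#' discriminant model, and a one-standard-deviation behavioral effect.
#'
#' @param n_per_group samples per group.
#' @param n_bact_genera,n_fung_genera taxon counts per kingdom.
#' @param n_latent number of shared latent factors coupling the kingdoms.
#' @param coupling_strength named numeric `c(control = , affected = )` in
#'   `[0, 1]`: the population correlation between two genera loading on the
#'   same latent factor, per group.
#' @param fungal_richness_deficit fraction in `[0, 1]` of the
#'   least-abundant fungal genera set to structural zero in the affected
#'   group.
#' @param group_location_shift mean shift (in latent-factor SD units) added
#'   to every latent factor in the affected group.
#' @param n_metabolites metabolite count; two metabolites per latent factor
#'   load on the factors, the rest are noise.
#' @param metabolite_loading correlation in `[0, 1]` between a loaded
#'   metabolite (log scale) and its latent factor.
#' @param behavior_effect standardized shift of the affected group on each
#'   behavioral endpoint, oriented toward higher anxiety/depression.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 30,
                          n_bact_genera = 90,
                          n_fung_genera = 40,
                          n_latent = 10,
                          coupling_strength = c(control = 0.8, affected = 0.2),
                          fungal_richness_deficit = 0.4,
                          group_location_shift = 1.5,
                          n_metabolites = 120,
                          metabolite_loading = 0.7,
                          behavior_effect = 1,
                          seed = 1) {
  counts <- c(n_per_group = n_per_group, n_bact_genera = n_bact_genera,
              n_fung_genera = n_fung_genera, n_latent = n_latent,
              n_metabolites = n_metabolites)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("configuration error: counts must be positive integers (",
         paste(names(counts)[counts <= 0 | counts != round(counts)],
               collapse = ", "), ")")
  if (n_latent > min(n_bact_genera, n_fung_genera))
    stop("configuration error: n_latent exceeds a kingdom's genus count")
  if (length(coupling_strength) != 2)
    stop("coupling_strength must give a control and an affected value")
  if (is.null(names(coupling_strength)))
    names(coupling_strength) <- c("control", "affected")
  fracs <- c(coupling_strength, fungal_richness_deficit = fungal_richness_deficit,
             metabolite_loading = metabolite_loading)
  if (any(fracs < 0 | fracs > 1))
    stop("configuration error: fractions must lie in [0, 1] (",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "), ")")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_bact_genera = as.integer(n_bact_genera),
                 n_fung_genera = as.integer(n_fung_genera),
                 n_latent = as.integer(n_latent),
                 coupling_strength = coupling_strength,
                 fungal_richness_deficit = fungal_richness_deficit,
                 group_location_shift = group_location_shift,
                 n_metabolites = as.integer(n_metabolites),
                 metabolite_loading = metabolite_loading,
                 behavior_effect = behavior_effect,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

make_lineages <- function(genera, kingdom, n_phyla = 4) {
  king <- if (kingdom == "bacteria") "Bacteria" else "Fungi"
  phy <- paste0(if (kingdom == "bacteria") "BactPhylum" else "FungPhylum",
                rep_len(seq_len(n_phyla), length(genera)))
  paste0("k__", king, ";p__", phy, ";c__", phy, "_c;o__", phy, "_o;f__",
         phy, "_f;g__", genera)
}

#' Generate a seeded synthetic cohort
#'
#' Counts follow a Poisson-log-normal scheme: per-sample latent Gaussian
#' factors (shifted in the affected group by `group_location_shift`) drive
#' log-scale genus abundances with per-group coupling, softmax composition
#' per kingdom, log-uniform library sizes over one order of magnitude, and
#' Poisson sampling. Fungal genus pairs sharing a latent factor have
#' latent correlation equal to the group's `coupling_strength` c, bacterial
#' pairs couple at `c^(1/2)` (a more persistent bacterial backbone) and
#' cross-kingdom pairs at `c^(3/4)`, all monotone in c and fully
#' independent at c = 0; the
#' `fungal_richness_deficit` fraction of the least-abundant fungal genera is
#' structurally zeroed in affected samples. Metabolites load on the same
#' latent factors; behavioral endpoints shift by `behavior_effect` SD in the
#' affected group, oriented toward higher anxiety.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `bacterial_table`,
#'   `fungal_table`, `tree`, `metadata`, `metabolite_table`, `behavior`,
#'   `truth` (planted parameters: factor assignments per genus, zeroed
#'   fungal genera, loaded metabolites, and the config).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_per_group
  ns <- 2 * n
  ids <- sprintf("S%03d", seq_len(ns))
  group <- rep(c("CT", "AD"), each = n)
  alcohol <- c(pmax(stats::rnorm(n, 9, 3), 0), stats::rnorm(n, 490, 30))
  metadata <- sample_metadata(ids, factor(group, levels = c("CT", "AD")),
                              alcohol_gday = alcohol)

  L <- config$n_latent
  shift <- ifelse(group == "AD", config$group_location_shift, 0)
  z <- matrix(stats::rnorm(ns * L), ns, L) + shift

  coup <- ifelse(group == "AD", config$coupling_strength[["affected"]],
                 config$coupling_strength[["control"]])

  # Fungal genera couple to their latent factor at the nominal per-group
  # strength c; bacterial genera couple at c^(1/2), a more robust backbone,
  # so weakening trans-kingdom coupling thins fungal and cross-kingdom
  # edges before the bacterial core (cross-kingdom correlation = c^(3/4),
  # still monotone in c, and c = 0 gives full independence).
  gen_kingdom <- function(n_gen, prefix, lib_range, corr_exponent) {
    genera <- sprintf("%s%03d", prefix, seq_len(n_gen))
    # first half of the genera load on latent factors, cycled
    fac <- rep(NA_integer_, n_gen)
    nl <- floor(n_gen / 2)
    fac[seq_len(nl)] <- rep_len(seq_len(L), nl)
    # factored genera sit at moderate base abundance (their amplitude is
    # large); the stable unfactored flora spans the wide dynamic range and
    # dominates the composition, keeping closure-induced correlation low
    base <- ifelse(is.na(fac), stats::rnorm(n_gen, 0, 2),
                   stats::rnorm(n_gen, 0, 1))
    # pin the first (factor-1-anchored) genus at the median log abundance
    # so planted-edge truth is observable, not censored by detection limits
    base[1] <- 0
    corr <- coup^corr_exponent
    eps <- matrix(stats::rnorm(ns * n_gen), ns, n_gen)
    eta <- matrix(base, ns, n_gen, byrow = TRUE)
    for (j in seq_len(n_gen)) {
      if (is.na(fac[j])) {
        eta[, j] <- eta[, j] + eps[, j]
      } else {
        # factored genera carry a larger biological amplitude (2 log
        # units, i.e. ~7-fold 1-sd swings) so planted correlations
        # dominate compositional-closure and Poisson sampling noise
        eta[, j] <- eta[, j] + 2 * (sqrt(corr) * z[, fac[j]] +
                                      sqrt(1 - corr) * eps[, j])
      }
    }
    p <- exp(eta)
    p <- p / rowSums(p)
    lib <- exp(stats::runif(ns, log(lib_range[1]), log(lib_range[2])))
    counts <- matrix(stats::rpois(ns * n_gen, t(p * lib)), n_gen, ns)
    counts <- t(counts)
    dimnames(counts) <- list(ids, genera)
    list(counts = counts, genera = genera, base = base, factor = fac)
  }

  bact <- gen_kingdom(config$n_bact_genera, "Bgen", c(2e4, 2e5), 0.5)
  fung <- gen_kingdom(config$n_fung_genera, "Fgen", c(5e3, 5e4), 1)

  n_zero <- floor(config$fungal_richness_deficit * config$n_fung_genera)
  zeroed <- character(0)
  if (n_zero > 0) {
    zeroed <- fung$genera[order(fung$base)][seq_len(n_zero)]
    fung$counts[group == "AD", zeroed] <- 0
  }

  bt <- abundance_table(bact$counts,
                        make_lineages(bact$genera, "bacteria"),
                        kingdom = "bacteria")
  ft <- abundance_table(fung$counts,
                        make_lineages(fung$genera, "fungi"),
                        kingdom = "fungi")

  tree <- generate_tree_impl(c(bact$genera, fung$genera))

  # metabolites: two per latent factor track the factors, rest are noise
  m <- config$n_metabolites
  met_ids <- sprintf("M%03d", seq_len(m))
  n_loaded <- min(2L * L, m)
  met_fac <- rep(NA_integer_, m)
  met_fac[seq_len(n_loaded)] <- rep_len(seq_len(L), n_loaded)
  lam <- config$metabolite_loading
  logint <- matrix(stats::rnorm(ns * m), ns, m)
  for (j in seq_len(n_loaded))
    logint[, j] <- lam * z[, met_fac[j]] + sqrt(1 - lam^2) * logint[, j]
  mu <- stats::rnorm(m, 10, 1)
  intensities <- exp(sweep(logint, 2, mu, "+"))
  dimnames(intensities) <- list(ids, met_ids)
  met <- metabolite_table(intensities)

  # behavioral endpoints; orientation per behavior_orientations()
  eff <- ifelse(group == "AD", config$behavior_effect, 0)
  behavior <- data.frame(
    animal_id = ids,
    center_time_s = stats::rnorm(ns, 60, 10) - 10 * eff,
    open_arm_time_s = stats::rnorm(ns, 90, 20) - 20 * eff,
    immobility_time_s = stats::rnorm(ns, 80, 15) + 15 * eff,
    stringsAsFactors = FALSE)

  truth <- list(config = config,
                bact_factor = stats::setNames(bact$factor, bact$genera),
                fung_factor = stats::setNames(fung$factor, fung$genera),
                zeroed_fungal_genera = zeroed,
                loaded_metabolites = stats::setNames(met_fac, met_ids))

  structure(list(bacterial_table = bt, fungal_table = ft, tree = tree,
                 metadata = metadata, metabolite_table = met,
                 behavior = behavior, truth = truth),
            class = "synthetic_cohort")
}

#' Orientation registry for the default behavioral endpoints
#'
#' `TRUE` means a higher raw value indicates more anxiety/depression
#' (immobility time); `FALSE` means higher is calmer (center time, open-arm
#' time), so the z-score composite flips its sign.
#'
#' @return named logical vector.
#' @export
behavior_orientations <- function() {
  c(center_time_s = FALSE, open_arm_time_s = FALSE, immobility_time_s = TRUE)
}

#' Generate a random rooted binary tree over genus labels
#'
#' Seeded wrapper for phylogeny simulation: a rooted binary topology with
#' strictly positive branch lengths, for UniFrac on synthetic cohorts.
#'
#' @param genus_labels unique tip labels (>= 2).
#' @param seed integer seed.
#' @return an [ape::phylo] tree.
#' @export
generate_tree <- function(genus_labels, seed = 1) {
  with_seed(seed, generate_tree_impl(genus_labels))
}

generate_tree_impl <- function(genus_labels) {
  if (length(genus_labels) < 2)
    stop("need at least 2 labels")
  if (anyDuplicated(genus_labels))
    stop("duplicate labels: ",
         paste(unique(genus_labels[duplicated(genus_labels)]),
               collapse = ", "))
  n <- length(genus_labels)
  ape::rtree(n, rooted = TRUE, tip.label = genus_labels,
             br = function(k) stats::runif(k, 0.05, 1))
}

#' Construct a metabolite intensity table
#'
#' @param values numeric matrix of positive intensities, samples in rows
#'   (row names = sample ids), metabolites in columns.
#' @param state `"raw"` or `"log_uv_scaled"`.
#' @return list of class `metabolite_table`.
#' @export
metabolite_table <- function(values, state = c("raw", "log_uv_scaled")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x metabolites)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs sample-id row names and metabolite-id column names")
  if (anyNA(values)) stop("missing intensities are not allowed")
  structure(list(values = values, state = state), class = "metabolite_table")
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits one abundance TSV per kingdom (lineage-string header), a metadata
#' TSV, a newick tree, a metabolite TSV, a behavior TSV, and the generating
#' configuration echoed as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_abundance_table(cohort$bacterial_table, file.path(dir, "bacteria.tsv"))
  write_abundance_table(cohort$fungal_table, file.path(dir, "fungi.tsv"))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(cohort$tree, file.path(dir, "tree.nwk"))
  met <- data.frame(sample_id = rownames(cohort$metabolite_table$values),
                    cohort$metabolite_table$values, check.names = FALSE)
  utils::write.table(met, file.path(dir, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$behavior, file.path(dir, "behavior.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$truth$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
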