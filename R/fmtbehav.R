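#' Build a transfer summary from genus set counts
#'
#' Engraftment bookkeeping: the transfer percentage is the share of donor
#' genera detected in the recipients, `100 * n_shared / n_donor_genera`.
#'
#' @param n_donor_genera,n_recipient_genera,n_shared non-negative integer
#'   counts; `n_shared` cannot exceed either set.
#' @return list of class `transfer_summary`.
#' @export
transfer_summary <- function(n_donor_genera, n_recipient_genera, n_shared) {
  if (n_donor_genera <= 0)
    stop("empty donor genus set")
  if (n_shared > min(n_donor_genera, n_recipient_genera))
    stop("n_shared exceeds a set size")
  structure(list(n_donor_genera = as.integer(n_donor_genera),
                 n_recipient_genera = as.integer(n_recipient_genera),
                 n_shared = as.integer(n_shared),
                 transfer_pct = 100 * n_shared / n_donor_genera),
            class = "transfer_summary")
}

#' FMT engraftment efficiency between donor and recipient tables
#'
#' A genus is "detected" in a group when its total count across that
#' group's samples reaches `min_count` (default 1, i.e. any non-zero
#' count). The summary partitions the donor and recipient genus sets and
#' reports the percentage of donor genera found in the recipients.
#'
#' @param donor_table,recipient_table counts-state [abundance_table()]s at
#'   the genus level.
#' @param min_count detection threshold on the summed count (default 1).
#' @return a [transfer_summary()].
#' @export
transfer_efficiency <- function(donor_table, recipient_table, min_count = 1) {
  stopifnot(inherits(donor_table, "abundance_table"),
            inherits(recipient_table, "abundance_table"))
  detected <- function(tb) tb$taxa$genus[colSums(tb$values) >= min_count]
  d <- unique(detected(donor_table))
  r <- unique(detected(recipient_table))
  if (length(d) == 0) stop("empty donor genus set")
  transfer_summary(length(d), length(r), length(intersect(d, r)))
}

#' @export
print.transfer_summary <- function(x, ...) {
  cat(sprintf("transfer: %d/%d donor genera engrafted (%.2f%%); recipients carry %d\n",
              x$n_shared, x$n_donor_genera, x$transfer_pct,
              x$n_recipient_genera))
  invisible(x)
}

#' Composite behavioral anxiety z-scores
#'
#' Each registered test is standardized against the control group
#' (`z = (x - mean_control) / sd_control`) and oriented so that higher
#' always means more anxious: measures where a higher raw value means
#' calmer (center time, open-arm time) are multiplied by -1. The composite
#' is the mean of the oriented per-test z-scores, so the control-group
#' composite mean is 0 by construction.
#'
#' @param behavior data.frame with an `animal_id` column and one numeric
#'   column per test.
#' @param control_ids character vector of control animal ids (>= 2).
#' @param orientations named logical vector over the test columns: `TRUE`
#'   if higher raw value = more anxious. Defaults to
#'   [behavior_orientations()] for the synthetic endpoints.
#' @return data.frame with `animal_id`, one `z_<test>` column per test
#'   (oriented), and `composite_z`.
#' @export
anxiety_zscore <- function(behavior, control_ids,
                           orientations = behavior_orientations()) {
  if (!"animal_id" %in% names(behavior))
    stop("behavior table needs an `animal_id` column")
  tests <- intersect(names(orientations), names(behavior))
  if (length(tests) == 0)
    stop("no registered test column found in the behavior table")
  ctrl <- behavior$animal_id %in% control_ids
  if (sum(ctrl) < 2) stop("need at least 2 control animals")
  zs <- sapply(tests, function(tn) {
    x <- behavior[[tn]]
    mu <- mean(x[ctrl])
    sdv <- stats::sd(x[ctrl])
    if (sdv == 0) stop("zero control-group SD for test '", tn, "'")
    z <- (x - mu) / sdv
    if (orientations[[tn]]) z else -z
  })
  zs <- matrix(zs, nrow = nrow(behavior),
               dimnames = list(NULL, paste0("z_", tests)))
  data.frame(animal_id = behavior$animal_id, zs,
             composite_z = rowMeans(zs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Alcohol preference ratio over a recording window
#'
#' Per animal, `sum(alcohol) / (sum(alcohol) + sum(water))` over all
#' recorded days (two-bottle free-choice convention; the ratio is the
#' alcohol share of total fluid intake).
#'
#' @param intake data.frame with columns `animal_id`, `alcohol_ml`,
#'   `water_ml`; one row per animal per day.
#' @return data.frame with `animal_id`, `alcohol_volume`, `water_volume`,
#'   `preference_ratio`.
#' @export
alcohol_preference_ratio <- function(intake) {
  need <- c("animal_id", "alcohol_ml", "water_ml")
  if (!all(need %in% names(intake)))
    stop("intake needs columns: ", paste(need, collapse = ", "))
  if (any(intake$alcohol_ml < 0 | intake$water_ml < 0))
    stop("volumes must be non-negative")
  alc <- tapply(intake$alcohol_ml, intake$animal_id, sum)
  wat <- tapply(intake$water_ml, intake$animal_id, sum)
  tot <- alc + wat
  if (any(tot == 0))
    stop("total intake is zero for animal(s): ",
         paste(names(tot)[tot == 0], collapse = ", "))
  data.frame(animal_id = names(alc),
             alcohol_volume = as.numeric(alc),
             water_volume = as.numeric(wat),
             preference_ratio = as.numeric(alc / tot),
             row.names = NULL, stringsAsFactors = FALSE)
}
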