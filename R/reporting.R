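#' Number of generated double-mutant combinations
#'
#' The ordered query x array cross: 38 queries against 91 array strains
#' generate 3,458 combinations; 14 against 279 generate 3,906.
#'
#' @param n_query,n_array Non-negative integers.
#' @return `n_query * n_array` as an integer.
#' @export
combination_count <- function(n_query, n_array) {
  stopifnot(n_query >= 0, n_array >= 0)
  as.integer(n_query) * as.integer(n_array)
}

#' Interaction frequency as a percentage
#'
#' `100 * n_hits / n_scored`, rounded half-even to 2 decimals (the printed
#' precision used in screen reports): 46 of 2,672 scored pairs is 1.72,
#' 195 of 3,906 is 4.99.
#'
#' @param n_hits Number of hit pairs (0 <= n_hits <= n_scored).
#' @param n_scored Number of scored pairs (> 0).
#' @return Percentage with 2 decimals.
#' @export
interaction_frequency <- function(n_hits, n_scored) {
  if (n_scored <= 0) stop("n_scored must be > 0", call. = FALSE)
  stopifnot(n_hits >= 0, n_hits <= n_scored)
  round(100 * n_hits / n_scored, 2)
}

canonical_pairs <- function(df) {
  pair_key(df[[1]], df[[2]])
}

#' Partition one screen's hits against another screen
#'
#' For each hit pair of screen A, decides whether it was `shared` (also a
#' hit in screen B), `not_identified` (tested in screen B but not a hit
#' there), or `not_comparable` (the double mutant was never created in
#' screen B). Pairs are unordered. The three classes are disjoint and cover
#' the hits of screen A.
#'
#' @param hits_a,hits_b Two-column data frames of hit pairs (query, array).
#' @param universe_b Two-column data frame of all pairs tested in screen B.
#' @return `hits_a` with an added `status` factor; counts are available via
#'   `dplyr::count(result, status)`.
#' @export
compare_screens <- function(hits_a, hits_b, universe_b) {
  ka <- canonical_pairs(hits_a)
  kb <- canonical_pairs(hits_b)
  ku <- canonical_pairs(universe_b)
  status <- ifelse(ka %in% kb, "shared",
                   ifelse(ka %in% ku, "not_identified", "not_comparable"))
  out <- tibble::as_tibble(hits_a)
  out$status <- factor(status,
                       levels = c("shared", "not_identified",
                                  "not_comparable"))
  out
}

#' Export interaction scores as a query x array matrix
#'
#' Builds the machine-readable twin of a screen heatmap: rows are array
#' strains, columns query strains, cells are scores rounded to 2 decimals
#' (full precision lives in the record table); linked, self-cross and
#' otherwise unscored cells are `NA`. Row and column order is lexicographic
#' unless an ordering is supplied.
#'
#' @param records Scored interaction records.
#' @param row_order,col_order Optional explicit orderings of array / query
#'   identifiers.
#' @param digits Decimal places for reported scores (default 2; use `NA`
#'   for full precision).
#' @return A tibble whose first column `array_id` names the rows.
#' @export
score_matrix <- function(records, row_order = NULL, col_order = NULL,
                         digits = 2) {
  x <- records
  x$score[excluded_from_scoring(x)] <- NA_real_
  if (!is.na(digits)) x$score <- round(x$score, digits)
  wide <- x |>
    dplyr::select("query_id", "array_id", "score") |>
    tidyr::pivot_wider(names_from = "query_id", values_from = "score")
  rows <- if (is.null(row_order)) sort(wide$array_id) else row_order
  cols <- if (is.null(col_order)) sort(setdiff(names(wide), "array_id"))
          else col_order
  wide <- wide[match(rows, wide$array_id), c("array_id", cols)]
  tibble::as_tibble(wide)
}

#' Read / write a score matrix TSV
#'
#' Round-trips exactly: `read_score_matrix(write_score_matrix(m))` equals
#' `m` byte for byte when re-exported.
#'
#' @param m A score matrix tibble from [score_matrix()].
#' @param file Path to a TSV file.
#' @return `write_score_matrix()` returns `file` invisibly;
#'   `read_score_matrix()` returns the matrix tibble.
#' @export
write_score_matrix <- function(m, file) {
  readr::write_tsv(m, file, na = "NA", progress = FALSE)
  invisible(file)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(file) {
  readr::read_tsv(file, col_types = readr::cols(
    array_id = readr::col_character(), .default = readr::col_double()
  ), na = "NA", progress = FALSE)
}

#' Summarize a scored screen
#'
#' Accounts for every generated (ordered) query x array combination:
#' reciprocal merging collapses two ordered combinations into one record,
#' and each record is then either scored or excluded by exactly one flag
#' (precedence: self-cross, then linkage, then low replicates, then control
#' defect), so `n_scored + exclusions + n_reciprocal_collapsed =
#' n_generated` always holds.
#'
#' @param records Hit-called interaction records.
#' @param n_query,n_array Size of the generated cross (defaults: distinct
#'   queries / arrays in `records`, counting merged pairs on both sides).
#' @return A one-row tibble with counts, the negative-hit frequency (in
#'   percent over scored pairs) and the threshold attribute if present.
#' @export
summarize_screen <- function(records, n_query = NULL, n_array = NULL) {
  flags <- c("self_cross", "linked", "low_replicates", "control_defect")
  for (fl in flags) if (!fl %in% names(records)) records[[fl]] <- FALSE
  if (!"reciprocal_merged" %in% names(records)) {
    records$reciprocal_merged <- FALSE
  }
  n_collapsed <- sum(records$reciprocal_merged)
  excl_self <- records$self_cross
  excl_link <- !excl_self & records$linked
  excl_low <- !excl_self & !excl_link & records$low_replicates
  excl_ctl <- !excl_self & !excl_link & !excl_low & records$control_defect
  scored <- !(excl_self | excl_link | excl_low | excl_ctl)
  n_neg <- sum(records$hit == "negative" & scored)
  n_pos <- sum(records$hit == "positive" & scored)
  if (is.null(n_query)) n_query <- dplyr::n_distinct(records$query_id)
  if (is.null(n_array)) n_array <- dplyr::n_distinct(records$array_id)
  tibble::tibble(
    n_query = n_query, n_array = n_array,
    n_generated_pairs = combination_count(n_query, n_array),
    n_records = nrow(records),
    n_reciprocal_collapsed = n_collapsed,
    n_excluded_self_cross = sum(excl_self),
    n_excluded_linked = sum(excl_link),
    n_excluded_low_replicates = sum(excl_low),
    n_excluded_control_defect = sum(excl_ctl),
    n_scored_pairs = sum(scored),
    n_hits_negative = n_neg,
    n_hits_positive = n_pos,
    frequency_percent = if (sum(scored) > 0) {
      interaction_frequency(n_neg, sum(scored))
    } else NA_real_,
    threshold = attr(records, "threshold") %||% NA_real_
  )
}

#' Write interaction records to TSV
#'
#' The machine-readable hit table: one row per pair with observed, expected
#' and score (rounded to 2 decimals, the reporting precision), replicate
#' count, a semicolon-joined `flags` field and the hit call.
#'
#' @param records Hit-called interaction records.
#' @param file Output path.
#' @param digits Decimal places for reported fitness/score values.
#' @return `file`, invisibly.
#' @export
write_interactions <- function(records, file, digits = 2) {
  flags <- c("linked", "self_cross", "reciprocal_merged", "low_replicates",
             "control_defect")
  present <- intersect(flags, names(records))
  flag_str <- apply(
    as.matrix(records[, present, drop = FALSE]), 1,
    function(v) paste(present[as.logical(v)], collapse = ";")
  )
  out <- tibble::tibble(
    query_id = records$query_id, array_id = records$array_id,
    observed = round(records$observed, digits),
    expected = round(records$expected, digits),
    score = round(records$score, digits),
    n = records$n, flags = flag_str, hit = records$hit
  )
  readr::write_tsv(out, file, na = "", progress = FALSE)
  invisible(file)
}
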