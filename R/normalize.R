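#' Normalization parameters
#'
#' @param reference_statistic `"median"` (default, robust to a minority of
#'   sick strains) or `"mean"`, computed over the per-strain medians of
#'   eligible interior array colonies.
#' @param do_row_col_correction Apply one-pass multiplicative median polish
#'   for row/column gradients (default `TRUE`).
#' @param do_edge_masking Exclude border-control colonies from reference
#'   statistics (default `TRUE`); the border strains exist to absorb edge
#'   growth artifacts, not to define the plate reference.
#' @param outlier_mad_multiplier Colonies deviating from their strain's
#'   within-plate median by more than this multiple of the (raw) median
#'   absolute deviation are flagged (default 5).
#' @param min_colony_size Sizes below this are treated as no-growth and set
#'   to 0 before normalization (default 0 = disabled).
#' @return A list of class `sga_norm_params`.
#' @export
norm_params <- function(reference_statistic = c("median", "mean"),
                        do_row_col_correction = TRUE,
                        do_edge_masking = TRUE,
                        outlier_mad_multiplier = 5,
                        min_colony_size = 0) {
  reference_statistic <- match.arg(reference_statistic)
  stopifnot(outlier_mad_multiplier > 0, min_colony_size >= 0)
  structure(list(reference_statistic = reference_statistic,
                 do_row_col_correction = do_row_col_correction,
                 do_edge_masking = do_edge_masking,
                 outlier_mad_multiplier = outlier_mad_multiplier,
                 min_colony_size = min_colony_size),
            class = "sga_norm_params")
}

ref_stat_fun <- function(params) {
  switch(params$reference_statistic, median = stats::median, mean = mean)
}

# Plate reference: the reference statistic over per-strain medians (one vote
# per strain), so the anchor is the median array *strain*, not the median
# colony. A per-colony median drifts into the lower tail of the wild-type
# size distribution as soon as a sizeable minority of colonies is sick; the
# strain-level reference is exact whenever more than half the strains on the
# plate are wild-type-like. Falls back to the colony statistic when strain
# assignments are unavailable.
plate_reference <- function(values, strain, params) {
  stat <- ref_stat_fun(params)
  ok <- !is.na(strain)
  if (any(ok)) {
    stat(as.vector(tapply(values[ok], strain[ok], stats::median)))
  } else {
    stat(values)
  }
}

# Eligibility for reference statistics: growing colonies at positions whose
# role may define the plate reference. Blanks and missing never count; zero
# colonies are biology (no growth) and are observations, not references.
eligible_mask <- function(size, role, params) {
  ok_role <- if (params$do_edge_masking) role == "array"
             else role %in% c("array", "border")
  ok_role & !is.na(size) & size > 0
}

#' Normalize one plate for spatial bias
#'
#' Converts raw colony sizes of a single plate into dimensionless relative
#' sizes with the plate reference at 1: (1) sizes below `min_colony_size`
#' are set to 0; (2) all sizes are divided by the plate reference -- the
#' reference statistic (default: median) over the per-strain medians of
#' eligible interior array colonies, so the anchor is the median array
#' strain, which the array design keeps wild-type-like; (3) when enabled,
#' multiplicative row and column effects, fitted by an alternating median
#' polish run to a fixed point, are divided out, which removes separable
#' row/column gradients exactly provided the median colony of every row and
#' column is wild-type-like (the standard dense-array assumption; see the
#' package vignette for the sparse-plate caveat); (4) a final rescale
#' pins the reference statistic of eligible colonies to exactly 1. Blank and
#' missing positions pass through unchanged (missing stays missing).
#'
#' @param plate A plate-grid tibble holding exactly one plate.
#' @param layout The plate layout (same grid dimensions).
#' @param params A [norm_params()] list.
#' @return The plate tibble with an added `relative_size` column.
#' @export
normalize_plate <- function(plate, layout, params = norm_params()) {
  if (dplyr::n_distinct(plate$plate_id) > 1) {
    stop("normalize_plate expects a single plate; use normalize_plates()",
         call. = FALSE)
  }
  pd <- density_dims(infer_density(max(plate$row), max(plate$col)))
  ld <- layout_dims(layout)
  if (pd[["n_rows"]] != ld[["n_rows"]] || pd[["n_cols"]] != ld[["n_cols"]]) {
    stop("plate and layout dimensions differ (",
         pd[["n_rows"]], " x ", pd[["n_cols"]], " vs ",
         ld[["n_rows"]], " x ", ld[["n_cols"]], ")", call. = FALSE)
  }
  x <- dplyr::left_join(plate, layout[, c("row", "col", "role", "strain_id")],
                        by = c("row", "col"))
  if (any(is.na(x$role))) {
    stop("plate positions not covered by the layout", call. = FALSE)
  }
  size <- x$size
  size[!is.na(size) & size < params$min_colony_size] <- 0
  stat <- ref_stat_fun(params)

  elig <- eligible_mask(size, x$role, params)
  ref <- plate_reference(size[elig], x$strain_id[elig], params)
  if (!sum(elig) || !is.finite(ref) || ref <= 0) {
    stop("plate ", plate$plate_id[1],
         ": reference statistic undefined (no usable growing colonies)",
         call. = FALSE)
  }
  rel <- size / ref

  if (params$do_row_col_correction) {
    # Alternating median fit of strain, row and column effects. The strain
    # effect is estimated (so that the composition of a row -- which strains
    # happen to sit in it -- never masquerades as a spatial effect) but only
    # the row/column effects are removed. Iterating to a fixed point makes
    # the correction exact on multiplicatively separable bias fields and
    # idempotent: at convergence the row and column medians of the
    # strain-centred residuals are 1, so renormalizing changes nothing.
    corr <- rep(1, length(rel))
    effect_of <- function(values, index, at) {
      e <- tapply(values, index, stat)
      out <- as.vector(e[match(at, names(e))])
      out[!is.finite(out) | is.na(out) | out <= 0] <- 1
      out
    }
    row_chr <- as.character(x$row)
    col_chr <- as.character(x$col)
    # The row/column medians stand in for the spatial field under the
    # array-design assumption that fewer than half the colonies in any
    # line are sick (so the median colony of a line is wild-type-like).
    for (iter in seq_len(25L)) {
      resid <- rel / corr
      dr <- effect_of(resid[elig], x$row[elig], row_chr)
      corr <- corr * dr
      resid <- resid / dr
      dc <- effect_of(resid[elig], x$col[elig], col_chr)
      corr <- corr * dc
      if (max(abs(dr - 1), abs(dc - 1)) < 1e-12) break
    }
    rel <- rel / corr
    ref2 <- plate_reference(rel[elig], x$strain_id[elig], params)
    if (is.finite(ref2) && ref2 > 0) rel <- rel / ref2
  }

  plate$relative_size <- rel
  plate
}

#' Normalize every plate of a screen set
#'
#' Applies [normalize_plate()] plate by plate.
#'
#' @param plates A plate-grid tibble (any number of plates).
#' @inheritParams normalize_plate
#' @return The plate tibble with a `relative_size` column.
#' @export
normalize_plates <- function(plates, layout, params = norm_params()) {
  plates |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::group_modify(~ normalize_plate(
      dplyr::mutate(.x, plate_id = .y$plate_id), layout, params
    ) |> dplyr::select(-"plate_id")) |>
    dplyr::ungroup() |>
    dplyr::relocate("plate_id")
}

#' Flag outlier replicate colonies
#'
#' Within each plate, a colony whose relative size deviates from the median
#' of its strain's replicate colonies on that plate by more than
#' `outlier_mad_multiplier` times the raw median absolute deviation is
#' flagged. With a MAD of zero (all other replicates identical) any
#' deviating colony is flagged. Strains with fewer than 3 replicate
#' colonies on a plate are never flagged. Flags are carried as a logical
#' `outlier` column -- colonies are excluded from aggregation downstream but
#' never silently removed.
#'
#' @param normalized Normalized plate tibble (from [normalize_plates()]).
#' @param layout The plate layout.
#' @param params A [norm_params()] list.
#' @return `normalized` with an added logical `outlier` column.
#' @export
flag_outlier_colonies <- function(normalized, layout,
                                  params = norm_params()) {
  x <- dplyr::left_join(
    normalized,
    layout[, c("row", "col", "role", "strain_id")],
    by = c("row", "col")
  )
  x <- x |>
    dplyr::group_by(.data$plate_id, .data$strain_id) |>
    dplyr::mutate(outlier = {
      v <- .data$relative_size
      use <- !is.na(v) & !is.na(.data$strain_id) & .data$role == "array"
      out <- rep(FALSE, length(v))
      if (sum(use) >= 3) {
        med <- stats::median(v[use])
        madv <- stats::median(abs(v[use] - med))
        out[use] <- abs(v[use] - med) > params$outlier_mad_multiplier * madv
      }
      out
    }) |>
    dplyr::ungroup()
  normalized$outlier <- x$outlier
  normalized
}
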