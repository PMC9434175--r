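#' Standard SGA plate densities
#'
#' The three colony densities used by robotic pinning, with their grid
#' dimensions: 384 = 16 x 24, 768 = 24 x 32, 1536 = 32 x 48. Coordinates are
#' 1-based with row 1 at the top and column 1 at the left.
#'
#' @return A tibble with columns `density`, `n_rows`, `n_cols`.
#' @export
#' @examples
#' plate_densities()
plate_densities <- function() {
  tibble::tibble(
    density = c(384L, 768L, 1536L),
    n_rows  = c(16L, 24L, 32L),
    n_cols  = c(24L, 32L, 48L)
  )
}

#' Grid dimensions for a standard density
#'
#' @param density One of 384, 768, 1536.
#' @return Named integer vector with elements `n_rows`, `n_cols`.
#' @export
density_dims <- function(density) {
  d <- plate_densities()
  i <- match(as.integer(density), d$density)
  if (is.na(i)) {
    stop("unknown plate density ", density,
         "; supported densities are 384, 768, 1536", call. = FALSE)
  }
  c(n_rows = d$n_rows[i], n_cols = d$n_cols[i])
}

# Smallest standard density whose grid contains the observed coordinates.
infer_density <- function(max_row, max_col) {
  d <- plate_densities()
  ok <- d$n_rows >= max_row & d$n_cols >= max_col
  if (!any(ok)) {
    stop("coordinates (", max_row, ", ", max_col,
         ") exceed the largest supported density (1536 = 32 x 48)",
         call. = FALSE)
  }
  d$density[which(ok)[1]]
}

plate_grid_cols <- c("plate_id", "screen_id", "condition", "replicate",
                     "row", "col", "size")

#' Read a plate-grid table
#'
#' Reads the tab-separated plate dialect with columns `plate_id`, `screen_id`,
#' `condition`, `replicate`, `row`, `col`, `size`. An empty field or `"."` in
#' `size` denotes a missing colony (failed pinning), which is distinct from a
#' size of 0 (no growth). One table may hold any number of plates; a plate is
#' identified by the combination (`plate_id`, `screen_id`, `condition`,
#' `replicate`).
#'
#' @param file Path to a TSV file (or any connection `readr::read_tsv()`
#'   accepts, e.g. a literal string via [I()]).
#' @param density Optional plate density (384, 768 or 1536). When given, rows
#'   outside that grid are an error; otherwise the smallest standard density
#'   containing the observed coordinates is assumed.
#' @return A tibble of colonies, one row per listed position, with `size`
#'   `NA` where the colony is missing.
#' @export
read_plate_table <- function(file, density = NULL) {
  # parsing problems are turned into errors below; muffle readr's warning
  tab <- withCallingHandlers(
    readr::read_tsv(
      file,
      col_types = readr::cols(
        plate_id  = readr::col_character(),
        screen_id = readr::col_character(),
        condition = readr::col_character(),
        replicate = readr::col_integer(),
        row       = readr::col_integer(),
        col       = readr::col_integer(),
        size      = readr::col_double()
      ),
      na = c("", "."),
      progress = FALSE
    ),
    warning = function(w) invokeRestart("muffleWarning")
  )
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    stop("malformed plate table row(s) at line(s) ",
         paste(utils::head(prob$row + 1L, 5), collapse = ", "),
         " of ", if (is.character(file)) file else "input", call. = FALSE)
  }
  missing_cols <- setdiff(plate_grid_cols, names(tab))
  if (length(missing_cols) > 0) {
    stop("plate table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_plate_grid(tab, density = density)
}

#' Validate a plate-grid tibble
#'
#' Checks the invariants of the plate dialect: no duplicated positions within
#' a plate, coordinates inside the declared (or inferred) standard density,
#' all present sizes finite and non-negative.
#'
#' @inheritParams read_plate_table
#' @param plates A plate-grid tibble.
#' @return `plates`, invisibly unchanged, for piping.
#' @export
validate_plate_grid <- function(plates, density = NULL) {
  stopifnot(is.data.frame(plates))
  if (nrow(plates) == 0) return(plates)
  if (any(is.na(plates$row)) || any(is.na(plates$col)) ||
      any(plates$row < 1) || any(plates$col < 1)) {
    stop("plate table contains invalid row/col coordinates", call. = FALSE)
  }
  dens <- if (is.null(density)) {
    infer_density(max(plates$row), max(plates$col))
  } else as.integer(density)
  dims <- density_dims(dens)
  bad <- plates$row > dims["n_rows"] | plates$col > dims["n_cols"]
  if (any(bad)) {
    stop("row/col outside the declared density ", dens, " (",
         dims["n_rows"], " x ", dims["n_cols"], ") at table row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(plates[, c("plate_id", "screen_id", "condition",
                               "replicate", "row", "col")])
  if (any(dup)) {
    stop("duplicate plate position(s), first at table row ",
         which(dup)[1], call. = FALSE)
  }
  present <- !is.na(plates$size)
  if (any(!is.finite(plates$size[present]) | plates$size[present] < 0)) {
    stop("colony sizes must be finite and >= 0", call. = FALSE)
  }
  plates
}

#' Write a plate-grid table
#'
#' Writes the same TSV dialect [read_plate_table()] reads; missing colonies
#' are written as empty fields so that read/write round-trips exactly.
#'
#' @param plates A plate-grid tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_plate_table <- function(plates, file) {
  readr::write_tsv(plates[, plate_grid_cols], file, na = "", progress = FALSE)
  invisible(file)
}
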