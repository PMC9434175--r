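#' @title Plate layouts
#' @description Layouts map every plate position to a role: a replicated
#'   array-strain position, a border-control position (a neutral strain such
#'   as the his5 deletion used to absorb edge growth artifacts), or a blank.
#'   A layout is a tibble with columns `row`, `col`, `role` (one of
#'   `"array"`, `"border"`, `"blank"`), `strain_id` (`NA` unless `role ==
#'   "array"`) and `replicate_index` (within-strain replicate number, `NA`
#'   unless `role == "array"`).
#' @name plate_layout
NULL

layout_cols <- c("row", "col", "role", "strain_id", "replicate_index")

new_layout <- function(df) {
  df <- df[order(df$row, df$col), layout_cols]
  tibble::as_tibble(df)
}

layout_dims <- function(layout) {
  c(n_rows = max(layout$row), n_cols = max(layout$col))
}

is_boundary <- function(row, col, n_rows, n_cols) {
  row == 1L | row == n_rows | col == 1L | col == n_cols
}

#' Build a replicated SL array layout
#'
#' Places each array strain at a fixed number of interior positions of a
#' standard-density plate, with every boundary position assigned to the
#' border-control strain and all leftover interior positions left blank.
#' Interior cells are filled in row-major order; the strain list is strided
#' across `replicates` passes, so a strain's replicates land in different
#' regions of the plate (replicate 1 of every strain first, then replicate 2,
#' and so on). The rule is deterministic, so layouts are stable fixtures.
#'
#' @param strain_ids Character vector of array strain identifiers (no
#'   duplicates).
#' @param replicates Number of interior positions per strain (the screen in
#'   this design uses 6 at 768 density before duplicate pinning).
#' @param density Plate density: 384, 768 or 1536.
#' @return A layout tibble (see [plate_layout]). At least one blank interior
#'   cell always remains.
#' @export
#' @examples
#' lay <- build_sl_layout(sprintf("tf%02d", 1:91), replicates = 6, density = 768)
#' table(lay$role)
build_sl_layout <- function(strain_ids, replicates = 6L, density = 768L) {
  strain_ids <- as.character(strain_ids)
  if (length(strain_ids) == 0) {
    stop("at least one array strain is required", call. = FALSE)
  }
  if (anyDuplicated(strain_ids)) {
    stop("duplicated strain_ids in array strain list", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  dims <- density_dims(density)
  nr <- dims[["n_rows"]]; nc <- dims[["n_cols"]]
  cells <- expand.grid(col = seq_len(nc), row = seq_len(nr))[, c("row", "col")]
  boundary <- is_boundary(cells$row, cells$col, nr, nc)
  interior <- cells[!boundary, , drop = FALSE]      # row-major order
  needed <- replicates * length(strain_ids)
  # keep >= 1 blank so the blank-spot invariant of the array design holds
  if (needed > nrow(interior) - 1L) {
    stop("layout capacity exceeded: ", needed, " positions required but only ",
         nrow(interior) - 1L, " interior cells available at density ",
         as.integer(density), " (one blank is always kept)", call. = FALSE)
  }
  strain <- rep(NA_character_, nrow(interior))
  repl <- rep(NA_integer_, nrow(interior))
  # spread the occupied positions evenly over the interior so blanks
  # interleave and no strain is confined to one plate region
  idx <- floor((seq_len(needed) - 1) * nrow(interior) / needed) + 1L
  strain[idx] <- rep(strain_ids, times = replicates)
  repl[idx] <- rep(seq_len(replicates), each = length(strain_ids))
  interior_df <- data.frame(
    row = interior$row, col = interior$col,
    role = ifelse(is.na(strain), "blank", "array"),
    strain_id = strain, replicate_index = repl,
    stringsAsFactors = FALSE
  )
  border_df <- data.frame(
    row = cells$row[boundary], col = cells$col[boundary],
    role = "border", strain_id = NA_character_,
    replicate_index = NA_integer_, stringsAsFactors = FALSE
  )
  new_layout(rbind(interior_df, border_df))
}

#' Build an SDL miniarray layout
#'
#' As [build_sl_layout()], but with the maximal uniform replicate multiplicity
#' that fits the interior of the plate (279 strains on a 384-density plate
#' gives multiplicity 1).
#'
#' @inheritParams build_sl_layout
#' @return A layout tibble.
#' @export
build_sdl_layout <- function(strain_ids, density = 384L) {
  strain_ids <- as.character(strain_ids)
  if (length(strain_ids) == 0) {
    stop("at least one array strain is required", call. = FALSE)
  }
  dims <- density_dims(density)
  interior_n <- (dims[["n_rows"]] - 2L) * (dims[["n_cols"]] - 2L)
  mult <- (interior_n - 1L) %/% length(strain_ids)
  if (mult < 1L) {
    stop("layout capacity exceeded: ", length(strain_ids),
         " strains do not fit the ", interior_n - 1L,
         " available interior cells at density ", as.integer(density),
         call. = FALSE)
  }
  build_sl_layout(strain_ids, replicates = mult, density = density)
}

#' Duplicate-pin a 768-density layout to 1536
#'
#' Models the robotic pinning step in which the whole 768-colony array is
#' pinned twice onto a single 1536-density plate, so every array strain's
#' multiplicity doubles (6 becomes 12). Each source cell (r, c) of the 24 x 32
#' grid maps to the two target cells (c, 2r - 1) and (c, 2r) of the 32 x 48
#' grid; the mapping is a fixed dialect of this package, covers the target
#' grid exactly, and preserves roles (a blank maps to two blanks, border to
#' border).
#'
#' @param layout A 768-density layout from [build_sl_layout()].
#' @return A 1536-density layout tibble.
#' @export
duplicate_pin <- function(layout) {
  dims <- layout_dims(layout)
  if (!(dims[["n_rows"]] == 24L && dims[["n_cols"]] == 32L) ||
      nrow(layout) != 768L) {
    stop("duplicate_pin requires a complete 768-density (24 x 32) layout",
         call. = FALSE)
  }
  half <- function(offset) {
    data.frame(
      row = layout$col,
      col = 2L * layout$row - 1L + offset,
      role = layout$role,
      strain_id = layout$strain_id,
      replicate_index = ifelse(is.na(layout$replicate_index), NA_integer_,
                               2L * layout$replicate_index - 1L + offset),
      stringsAsFactors = FALSE
    )
  }
  new_layout(rbind(half(0L), half(1L)))
}

#' Per-strain multiplicity of a layout
#'
#' @param layout A layout tibble.
#' @return A tibble with columns `strain_id`, `multiplicity`.
#' @export
layout_multiplicity <- function(layout) {
  layout |>
    dplyr::filter(.data$role == "array") |>
    dplyr::count(.data$strain_id, name = "multiplicity")
}

#' Read / write layout tables
#'
#' The layout TSV dialect has columns `row`, `col`, `role`, `strain_id`,
#' `replicate_index`; `strain_id` is empty for border and blank cells.
#'
#' @param file Path to a TSV file.
#' @return `read_layout()` returns a layout tibble; `write_layout()` returns
#'   `file` invisibly.
#' @export
read_layout <- function(file) {
  lay <- readr::read_tsv(
    file,
    col_types = readr::cols(
      row = readr::col_integer(), col = readr::col_integer(),
      role = readr::col_character(), strain_id = readr::col_character(),
      replicate_index = readr::col_integer()
    ),
    na = c("", "."), progress = FALSE
  )
  validate_layout(new_layout(as.data.frame(lay)))
}

#' @rdname read_layout
#' @param layout A layout tibble.
#' @export
write_layout <- function(layout, file) {
  readr::write_tsv(layout[, layout_cols], file, na = "", progress = FALSE)
  invisible(file)
}

#' Validate a layout
#'
#' Checks that all boundary cells are border controls, every array strain has
#' a constant multiplicity, at least one blank exists, and that roles and
#' strain assignments are consistent.
#'
#' @param layout A layout tibble.
#' @return `layout`, invisibly unchanged.
#' @export
validate_layout <- function(layout) {
  stopifnot(all(layout_cols %in% names(layout)))
  dims <- layout_dims(layout)
  if (nrow(layout) != dims[["n_rows"]] * dims[["n_cols"]]) {
    stop("layout does not cover the full ", dims[["n_rows"]], " x ",
         dims[["n_cols"]], " grid", call. = FALSE)
  }
  if (!all(layout$role %in% c("array", "border", "blank"))) {
    stop("layout roles must be one of 'array', 'border', 'blank'",
         call. = FALSE)
  }
  bnd <- is_boundary(layout$row, layout$col, dims[["n_rows"]], dims[["n_cols"]])
  if (!all(layout$role[bnd] == "border")) {
    stop("every boundary cell must be a border control", call. = FALSE)
  }
  if (!any(layout$role == "blank")) {
    stop("layout must contain at least one blank cell", call. = FALSE)
  }
  mult <- layout_multiplicity(layout)
  if (nrow(mult) > 0 && length(unique(mult$multiplicity)) != 1L) {
    stop("array strains must all share the same multiplicity", call. = FALSE)
  }
  layout
}
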