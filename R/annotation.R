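#' Strain genomic annotations
#'
#' Scoring needs the genomic coordinates of the deleted (or overexpressed)
#' gene behind each strain in order to apply the linkage-exclusion rule:
#' gene pairs that lie close together on the same chromosome are depleted in
#' double mutants by meiotic linkage rather than epistasis. Annotations are a
#' BED-like tibble with columns `strain_id`, `gene_id`, `chromosome`,
#' `start`, `end` (1-based, inclusive) and `role_tag` (`"query"`, `"array"`
#' or `"control_query"`).
#'
#' @param file Path to a TSV file. Header comment lines starting with `#`
#'   are ignored.
#' @return `read_annotations()` returns an annotation tibble;
#'   `write_annotations()` returns `file` invisibly.
#' @export
read_annotations <- function(file) {
  ann <- readr::read_tsv(
    file,
    col_types = readr::cols(
      strain_id = readr::col_character(), gene_id = readr::col_character(),
      chromosome = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), role_tag = readr::col_character()
    ),
    comment = "#", progress = FALSE
  )
  validate_annotations(tibble::as_tibble(ann))
}

#' @rdname read_annotations
#' @param annotations An annotation tibble.
#' @export
write_annotations <- function(annotations, file) {
  header <- "# strain annotations; coordinates are 1-based inclusive"
  writeLines(header, file)
  readr::write_tsv(annotations, file, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(file)
}

validate_annotations <- function(annotations) {
  need <- c("strain_id", "gene_id", "chromosome", "start", "end", "role_tag")
  stopifnot(all(need %in% names(annotations)))
  if (any(annotations$start > annotations$end)) {
    stop("annotation intervals must satisfy start <= end", call. = FALSE)
  }
  if (any(is.na(annotations$chromosome) | annotations$chromosome == "")) {
    stop("annotation chromosomes must be nonempty", call. = FALSE)
  }
  annotations
}

#' Genomic gap between two gene intervals
#'
#' Vectorised minimum gap between the intervals `[start1, end1]` and
#' `[start2, end2]` (0 if they overlap or touch). Used by
#' [linkage_filter()]; pairs on different chromosomes have no finite gap and
#' are never linked.
#'
#' @param start1,end1,start2,end2 Numeric vectors of 1-based inclusive
#'   coordinates.
#' @return Numeric vector of gaps in base pairs.
#' @export
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start1, start2) - pmin(end1, end2))
}

#' Generate synthetic strain annotations
#'
#' Places strains round-robin across a small number of chromosomes with a
#' fixed start-to-start spacing. With the default 250 kb spacing and 1.5 kb
#' gene length no two strains fall within the 200 kb linkage window, so
#' linkage structure, when wanted, is planted explicitly via `linked_pairs`
#' (those strain pairs are moved adjacent on the same chromosome, 50 kb
#' apart).
#'
#' @param strain_ids Character vector of strain identifiers.
#' @param n_chromosomes Number of chromosomes (fission yeast has 3).
#' @param spacing_bp Start-to-start spacing between consecutive genes on the
#'   same chromosome.
#' @param gene_length_bp Length of each gene interval.
#' @param linked_pairs Optional two-column data frame (`strain_a`,
#'   `strain_b`) of pairs to place within the linkage window.
#' @param role_tags Optional named character vector strain_id -> role_tag;
#'   defaults to `"array"`.
#' @return An annotation tibble.
#' @export
synthetic_annotations <- function(strain_ids, n_chromosomes = 3L,
                                  spacing_bp = 250000, gene_length_bp = 1500,
                                  linked_pairs = NULL, role_tags = NULL) {
  strain_ids <- as.character(strain_ids)
  n <- length(strain_ids)
  chrom <- paste0("chr", ((seq_len(n) - 1L) %% n_chromosomes) + 1L)
  idx_on_chrom <- ((seq_len(n) - 1L) %/% n_chromosomes)
  start <- 1 + idx_on_chrom * spacing_bp
  ann <- tibble::tibble(
    strain_id = strain_ids,
    gene_id = paste0(strain_ids, "_gene"),
    chromosome = chrom,
    start = start,
    end = start + gene_length_bp - 1,
    role_tag = if (is.null(role_tags)) "array" else
      dplyr::coalesce(unname(role_tags[strain_ids]), "array")
  )
  if (!is.null(linked_pairs) && nrow(linked_pairs) > 0) {
    for (i in seq_len(nrow(linked_pairs))) {
      a <- match(linked_pairs[[1]][i], ann$strain_id)
      b <- match(linked_pairs[[2]][i], ann$strain_id)
      if (is.na(a) || is.na(b)) {
        stop("linked_pairs refers to unknown strain(s)", call. = FALSE)
      }
      ann$chromosome[b] <- ann$chromosome[a]
      ann$start[b] <- ann$end[a] + 50000
      ann$end[b] <- ann$start[b] + gene_length_bp - 1
    }
  }
  validate_annotations(ann)
}
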