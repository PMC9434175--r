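#' @title Multiplicative-model interaction scoring
#' @description
#' The scoring stage turns normalized plates into fitness estimates and
#' genetic-interaction scores. The null model is multiplicative: the
#' expected fitness of a double mutant is the product of the two
#' single-mutant fitness values, and the interaction score is the observed
#' deviation from that product (`score = observed - expected`; negative =
#' sick/lethal). Because per-plate normalization pins each plate's reference
#' to 1, a query strain's own fitness defect -- which scales every colony on
#' its plates -- is absorbed by the plate reference; the scorer therefore
#' reattaches it by multiplying plate-relative double-mutant fitness by the
#' independently estimated query single-mutant fitness, which puts observed,
#' expected and score on the absolute fitness scale (wild type = 1). This
#' rests on the usual array assumption that the median array strain is
#' wild-type-like.
#' @name interaction_scoring
NULL

join_roles <- function(normalized, layout) {
  x <- dplyr::left_join(normalized,
                        layout[, c("row", "col", "role", "strain_id")],
                        by = c("row", "col"))
  if (!"outlier" %in% names(x)) x$outlier <- FALSE
  x
}

usable_array_colonies <- function(normalized, layout, screens,
                                  roles, condition_use = "selection") {
  join_roles(normalized, layout) |>
    dplyr::inner_join(screens, by = "screen_id") |>
    dplyr::filter(.data$query_role %in% roles,
                  .data$condition == condition_use,
                  .data$role == "array",
                  !is.na(.data$relative_size),
                  !.data$outlier)
}

aggregate_fitness <- function(df, keys, aggregate = "pool") {
  if (aggregate == "pool") {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(
        fitness = mean(.data$relative_size),
        n = dplyr::n(),
        dispersion = if (dplyr::n() > 1) stats::sd(.data$relative_size) else 0,
        screens = list(sort(unique(.data$screen_id))),
        .groups = "drop"
      )
  } else {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "screen_id",
                                                    "replicate")))) |>
      dplyr::summarise(m = mean(.data$relative_size), k = dplyr::n(),
                       .groups = "drop") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(
        fitness = mean(.data$m),
        n = sum(.data$k),
        dispersion = if (dplyr::n() > 1) stats::sd(.data$m) else 0,
        screens = list(sort(unique(.data$screen_id))),
        .groups = "drop"
      )
  }
}

#' Single-mutant fitness from the control-query cross
#'
#' Averages non-flagged normalized replicate colonies of each array strain
#' across the control-cross plates and replicate screens (the cross of a
#' neutral-marker query for SL, or the empty-vector query for SDL). With
#' the plate reference at 1, a wild-type-like strain has fitness close to 1.
#'
#' @param normalized Normalized, outlier-flagged plate tibble.
#' @param layout The plate layout.
#' @param screens Screen table (`screen_id`, `query_id`, `query_role`).
#' @param aggregate `"pool"` or `"screen_mean"` (see [screen_config()]).
#' @return A tibble with one row per array strain: `strain_id`, `fitness`,
#'   `n`, `dispersion`, `screens`. Strains without usable colonies get
#'   `n = 0` and `NA` fitness.
#' @export
single_mutant_fitness <- function(normalized, layout, screens,
                                  aggregate = "pool") {
  usable <- usable_array_colonies(normalized, layout, screens,
                                  roles = "control_query")
  res <- aggregate_fitness(usable, "strain_id", aggregate)
  all_strains <- unique(layout$strain_id[layout$role == "array"])
  missing <- setdiff(all_strains, res$strain_id)
  if (length(missing) > 0) {
    res <- dplyr::bind_rows(res, tibble::tibble(
      strain_id = missing, fitness = NA_real_, n = 0L, dispersion = NA_real_,
      screens = replicate(length(missing), character(), simplify = FALSE)
    ))
  }
  dplyr::arrange(res, .data$strain_id)
}

#' Query single-mutant fitness
#'
#' Two estimators are available. `"singles"` (SL default) reads the query's
#' fitness off the control-cross single-mutant table -- valid when query
#' strains are members of the array, as in a design whose queries are a
#' subset of the array collection. `"plate_ratio"` (SDL default, where the
#' query is an overexpression strain not present on the array) compares raw
#' plate reference statistics: the ratio of the query screen's plate
#' reference to the control screen's estimates how much the query genotype
#' scales the whole plate.
#'
#' @param singles Output of [single_mutant_fitness()].
#' @param screens Screen table.
#' @param method `"singles"` or `"plate_ratio"`.
#' @param plates Raw (unnormalized) plate tibble; needed for
#'   `"plate_ratio"`.
#' @param layout The plate layout; needed for `"plate_ratio"`.
#' @param params [norm_params()], defining the reference statistic and
#'   eligibility; needed for `"plate_ratio"`.
#' @return A tibble `query_id`, `fitness`.
#' @export
query_fitness <- function(singles, screens,
                          method = c("singles", "plate_ratio"),
                          plates = NULL, layout = NULL,
                          params = norm_params()) {
  method <- match.arg(method)
  q <- screens[screens$query_role == "query", , drop = FALSE]
  if (method == "singles") {
    f <- singles$fitness[match(q$query_id, singles$strain_id)]
    if (any(is.na(f))) {
      stop("query strain(s) not present in the single-mutant table: ",
           paste(q$query_id[is.na(f)], collapse = ", "),
           "; use method = \"plate_ratio\" for queries outside the array",
           call. = FALSE)
    }
    tibble::tibble(query_id = q$query_id, fitness = f)
  } else {
    if (is.null(plates) || is.null(layout)) {
      stop("plate_ratio query fitness needs the raw plates and layout",
           call. = FALSE)
    }
    refs <- join_roles(plates, layout) |>
      dplyr::inner_join(screens, by = "screen_id") |>
      dplyr::filter(.data$condition == "selection") |>
      dplyr::group_by(.data$screen_id, .data$query_id, .data$query_role,
                      .data$plate_id) |>
      dplyr::summarise(ref = {
        keep <- eligible_mask(.data$size, .data$role, params)
        plate_reference(.data$size[keep], .data$strain_id[keep], params)
      }, .groups = "drop")
    ctrl <- mean(refs$ref[refs$query_role == "control_query"])
    if (!is.finite(ctrl) || ctrl <= 0) {
      stop("control-query plates give no usable reference statistic",
           call. = FALSE)
    }
    refs |>
      dplyr::filter(.data$query_role == "query") |>
      dplyr::group_by(query_id = .data$query_id) |>
      dplyr::summarise(fitness = mean(.data$ref) / ctrl, .groups = "drop")
  }
}

#' Double-mutant fitness per (query, array) pair
#'
#' Pools the usable replicate colonies of each (query, array) combination
#' across plates and replicate screens and rescales the plate-relative mean
#' by the query's single-mutant fitness (see [interaction_scoring]). Pairs
#' of the full query x array cross that yield no usable colony are kept
#' with `n = 0` so downstream accounting stays exact.
#'
#' @inheritParams single_mutant_fitness
#' @param qfit Query fitness table from [query_fitness()].
#' @param condition_use Plate condition to aggregate (`"selection"` for
#'   scoring; `"control"` for the SDL +thiamin control plates, where the
#'   query factor is taken as 1).
#' @return A tibble `query_id`, `array_id`, `observed`, `n`, `dispersion`,
#'   `screens`.
#' @export
double_mutant_fitness <- function(normalized, layout, screens, qfit,
                                  aggregate = "pool",
                                  condition_use = "selection") {
  usable <- usable_array_colonies(normalized, layout, screens,
                                  roles = "query",
                                  condition_use = condition_use) |>
    dplyr::rename(array_id = "strain_id")
  res <- aggregate_fitness(usable, c("query_id", "array_id"), aggregate)
  fq <- if (condition_use == "control") {
    stats::setNames(rep(1, nrow(qfit)), qfit$query_id)
  } else {
    stats::setNames(qfit$fitness, qfit$query_id)
  }
  res$observed <- res$fitness * unname(fq[res$query_id])
  res$dispersion <- res$dispersion * unname(fq[res$query_id])
  res$fitness <- NULL
  full <- tidyr::expand_grid(
    query_id = screens$query_id[screens$query_role == "query"],
    array_id = unique(layout$strain_id[layout$role == "array"])
  )
  res <- dplyr::left_join(full, res, by = c("query_id", "array_id")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      dispersion = ifelse(.data$n == 0, NA_real_, .data$dispersion),
      screens = purrr::map(.data$screens,
                           ~ if (is.null(.x)) character() else .x)
    )
  dplyr::arrange(res, .data$query_id, .data$array_id)
}

#' Merge reciprocal crosses
#'
#' A pair screened in both directions -- (A, B) with A as query and (B, A)
#' with B as query -- measures the same double mutant; the two records are
#' pooled into a single unordered-pair record (equivalent to pooling the
#' underlying colonies: counts add, means are colony-weighted, dispersions
#' combine through the pooled sum of squares) and flagged
#' `reciprocal_merged`. The surviving record carries the lexicographically
#' smaller identifier as `query_id`. Unpaired records pass through
#' unflagged. Self-crosses (A, A) are flagged `self_cross`; they measure a
#' marker artifact, not an interaction.
#'
#' @param pairs Pair table from [double_mutant_fitness()].
#' @return The pair table with logical `reciprocal_merged` and `self_cross`
#'   columns, one row per unordered pair.
#' @export
merge_reciprocal <- function(pairs) {
  pairs <- pairs |>
    dplyr::mutate(.key = pair_key(.data$query_id, .data$array_id),
                  self_cross = .data$query_id == .data$array_id)
  merged <- pairs |>
    dplyr::group_by(.data$.key) |>
    dplyr::group_modify(function(g, k) {
      if (nrow(g) == 1) {
        g$reciprocal_merged <- FALSE
        return(g)
      }
      n <- sum(g$n)
      m <- if (n > 0) sum(g$n * dplyr::coalesce(g$observed, 0)) / n else NA_real_
      ss <- sum(ifelse(g$n > 1, (g$n - 1) * g$dispersion^2, 0) +
                  ifelse(g$n > 0, g$n * (dplyr::coalesce(g$observed, 0) - m)^2,
                         0))
      sdp <- if (n > 1) sqrt(ss / (n - 1)) else if (n > 0) 0 else NA_real_
      first <- order(g$query_id)[1]
      tibble::tibble(
        query_id = min(g$query_id), array_id = max(g$array_id),
        observed = if (n > 0) m else NA_real_,
        n = n, dispersion = sdp,
        screens = list(sort(unique(unlist(g$screens)))),
        self_cross = g$self_cross[first],
        reciprocal_merged = TRUE
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-".key")
  dplyr::arrange(merged, .data$query_id, .data$array_id)
}

#' Expected double-mutant fitness under the multiplicative model
#'
#' @param f_query,f_array Single-mutant fitness values (finite, >= 0).
#' @return `f_query * f_array`.
#' @export
expected_fitness <- function(f_query, f_array) {
  if (any(!is.finite(f_query)) || any(!is.finite(f_array)) ||
      any(f_query < 0) || any(f_array < 0)) {
    stop("single-mutant fitness must be finite and >= 0", call. = FALSE)
  }
  f_query * f_array
}

#' Interaction score
#'
#' Observed minus expected double-mutant fitness; negative values are the
#' sick/lethal direction.
#'
#' @param observed,expected Finite fitness values.
#' @return `observed - expected`.
#' @export
interaction_score <- function(observed, expected) {
  observed - expected
}

#' Attach expected fitness and scores to pair records
#'
#' @param pairs Pair table (after [merge_reciprocal()] for SL).
#' @param singles Single-mutant fitness table (array strains).
#' @param qfit Query fitness table.
#' @param min_replicates Pairs with fewer usable colonies are flagged
#'   `low_replicates` (as are pairs with no usable colony at all).
#' @return The pair table with `expected`, `score` and `low_replicates`
#'   columns.
#' @export
score_interactions <- function(pairs, singles, qfit, min_replicates = 6L) {
  fq <- stats::setNames(qfit$fitness, qfit$query_id)
  fa <- stats::setNames(singles$fitness, singles$strain_id)
  lookup_q <- function(id) {
    out <- unname(fq[id])
    miss <- is.na(out)
    out[miss] <- unname(fa[id[miss]])   # merged pairs: both sides are strains
    out
  }
  f1 <- lookup_q(pairs$query_id)
  f2 <- unname(fa[pairs$array_id])
  pairs$expected <- ifelse(is.finite(f1) & is.finite(f2), f1 * f2, NA_real_)
  pairs$score <- interaction_score(pairs$observed, pairs$expected)
  pairs$low_replicates <- pairs$n < min_replicates | is.na(pairs$score)
  pairs
}

#' Flag genomically linked pairs
#'
#' A pair is linked when both genes lie on the same chromosome and the
#' minimum gap between their intervals is strictly less than `window_bp`
#' (a gap of exactly the window size is retained). Linked pairs are
#' excluded from threshold derivation and hit lists because meiotic
#' linkage, not epistasis, depletes their double mutants.
#'
#' @param pairs Pair table.
#' @param annotations Annotation tibble covering every strain in `pairs`.
#' @param window_bp Linkage window (default 200,000 bp).
#' @return The pair table with a logical `linked` column.
#' @export
linkage_filter <- function(pairs, annotations, window_bp = 200000) {
  iq <- match(pairs$query_id, annotations$strain_id)
  ia <- match(pairs$array_id, annotations$strain_id)
  if (any(is.na(iq)) || any(is.na(ia))) {
    bad <- unique(c(pairs$query_id[is.na(iq)], pairs$array_id[is.na(ia)]))
    stop("no annotation for strain(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  same_chrom <- annotations$chromosome[iq] == annotations$chromosome[ia]
  gap <- interval_gap(annotations$start[iq], annotations$end[iq],
                      annotations$start[ia], annotations$end[ia])
  pairs$linked <- same_chrom & gap < window_bp
  pairs
}

#' Derive a mean - k SD score threshold
#'
#' @param scores Numeric vector of unflagged interaction scores (>= 2
#'   values).
#' @param k Number of sample standard deviations below the mean (default 2).
#' @return The threshold `mean(scores) - k * sd(scores)` (sample SD, n - 1
#'   denominator).
#' @export
#' @examples
#' derive_threshold(c(-0.1, 0, 0.1), k = 2)  # -0.2
derive_threshold <- function(scores, k = 2) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2) {
    stop("at least 2 finite scores are needed to derive a threshold",
         call. = FALSE)
  }
  mean(scores) - k * stats::sd(scores)
}

excluded_from_scoring <- function(pairs) {
  out <- rep(FALSE, nrow(pairs))
  for (fl in c("self_cross", "linked", "low_replicates", "control_defect")) {
    if (fl %in% names(pairs)) out <- out | pairs[[fl]]
  }
  out
}

#' Call interaction hits
#'
#' SL mode: negative hit when `score <= threshold`, where the threshold
#' defaults to mean - k SD of the unflagged scores (derived thresholds near
#' -0.2 on the fitness scale are typical). SDL mode: negative hit when
#' `score < -cutoff`, positive when `score > +cutoff` (positive calls are
#' reported for display only). Records flagged `self_cross`, `linked`,
#' `low_replicates` or `control_defect` always get `hit = "none"`.
#'
#' @param pairs Scored, filtered pair table.
#' @param mode `"sl"` or `"sdl"`.
#' @param k SL threshold multiplier (default 2).
#' @param cutoff SDL fixed cutoff (default 0.5).
#' @param threshold Optional explicit SL threshold, overriding derivation.
#' @return The pair table with a `hit` column (`"negative"`, `"positive"`,
#'   `"none"`); the threshold used (SL) is attached as attribute
#'   `"threshold"`.
#' @export
call_hits <- function(pairs, mode = c("sl", "sdl"), k = 2, cutoff = 0.5,
                      threshold = NULL) {
  mode <- match.arg(mode)
  excl <- excluded_from_scoring(pairs)
  hit <- rep("none", nrow(pairs))
  if (mode == "sl") {
    if (is.null(threshold)) {
      threshold <- derive_threshold(pairs$score[!excl], k = k)
    }
    # a score of exactly 0 is never sick, even when a degenerate score
    # distribution (zero spread) pushes the derived threshold up to 0
    hit[!excl & pairs$score <= threshold & pairs$score < 0] <- "negative"
  } else {
    threshold <- -cutoff
    hit[!excl & pairs$score < -cutoff] <- "negative"
    hit[!excl & pairs$score > cutoff] <- "positive"
  }
  pairs$hit <- hit
  attr(pairs, "threshold") <- threshold
  pairs
}

#' Flag SDL pairs sick on the control condition
#'
#' Combinations with a severe fitness defect on the +thiamin control plates
#' (promoter repressed) cannot be attributed to overexpression toxicity --
#' leaky expression or a marker effect is in play -- so they are flagged
#' `control_defect` and excluded from the confirmed SDL list, but reported.
#'
#' @param pairs SDL pair table.
#' @param control_fitness Pair table of fitness on the control-condition
#'   plates (from [double_mutant_fitness()] with `condition_use =
#'   "control"`), or any tibble with `query_id`, `array_id`, `observed`.
#' @param floor Fitness floor (default 0.5); pairs strictly below it are
#'   flagged.
#' @return The pair table with logical `control_defect` and
#'   `control_fitness` columns.
#' @export
flag_control_defect <- function(pairs, control_fitness, floor = 0.5) {
  cf <- control_fitness |>
    dplyr::select("query_id", "array_id", control_fitness = "observed")
  pairs <- dplyr::left_join(pairs, cf, by = c("query_id", "array_id"))
  pairs$control_defect <- !is.na(pairs$control_fitness) &
    pairs$control_fitness < floor
  pairs
}
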