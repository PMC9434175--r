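#' Score a complete SL or SDL screen
#'
#' Runs the full analysis in order: per-plate spatial normalization,
#' outlier flagging, array single-mutant fitness from the control cross,
#' query fitness, per-pair double-mutant fitness, reciprocal merging (SL),
#' multiplicative-model scores, linkage filtering, threshold derivation
#' (SL) or fixed cutoffs plus control-condition filtering (SDL), hit calls
#' and the screen summary. Every run carries a manifest with the per-stage
#' record counts, so reruns on identical inputs are identical and
#' auditable.
#'
#' @param plates Raw plate tibble (see [read_plate_table()]).
#' @param layout Plate layout tibble.
#' @param screens Screen table (`screen_id`, `query_id`, `query_role` with
#'   exactly the roles `"query"` / `"control_query"`).
#' @param annotations Strain annotation tibble.
#' @param config A [screen_config()].
#' @return An object of class `sga_result`: a list with `interactions`
#'   (the scored record table), `single_fitness`, `query_fitness`,
#'   `threshold`, `summary`, `manifest` and `config`.
#' @export
#' @examples
#' cfg <- screen_config("sl", query_ids = c("tf01", "tf02"),
#'                      array_ids = sprintf("tf%02d", 1:10),
#'                      bias = no_bias())
#' sim <- simulate_screen(cfg, seed = 1, interaction_frac = 0)
#' res <- score_screen(sim$plates, sim$layout, sim$screens,
#'                     sim$annotations, cfg)
#' glance(res)
score_screen <- function(plates, layout, screens, annotations, config) {
  stopifnot(inherits(config, "sga_config"))
  validate_plate_grid(plates)

  norm <- normalize_plates(plates, layout, config$normalization)
  norm <- flag_outlier_colonies(norm, layout, config$normalization)

  singles <- single_mutant_fitness(norm, layout, screens,
                                   aggregate = config$aggregate)
  qfit <- if (config$mode == "sl") {
    query_fitness(singles, screens, method = "singles")
  } else {
    query_fitness(singles, screens, method = "plate_ratio",
                  plates = plates, layout = layout,
                  params = config$normalization)
  }

  doubles <- double_mutant_fitness(norm, layout, screens, qfit,
                                   aggregate = config$aggregate)
  n_generated <- nrow(doubles)
  if (config$mode == "sl") {
    doubles <- merge_reciprocal(doubles)
  } else {
    doubles$self_cross <- doubles$query_id == doubles$array_id
    doubles$reciprocal_merged <- FALSE
  }

  rec <- score_interactions(doubles, singles, qfit,
                            min_replicates = config$min_replicates)
  rec <- linkage_filter(rec, annotations,
                        window_bp = config$linkage_window_bp)

  if (config$mode == "sdl") {
    ctrl <- double_mutant_fitness(norm, layout, screens, qfit,
                                  aggregate = config$aggregate,
                                  condition_use = "control")
    rec <- flag_control_defect(rec, ctrl,
                               floor = config$control_fitness_floor)
  }

  rec <- call_hits(rec, mode = config$mode, k = config$threshold_k,
                   cutoff = config$sdl_cutoff)
  threshold <- attr(rec, "threshold")

  summary <- summarize_screen(
    rec,
    n_query = sum(screens$query_role == "query"),
    n_array = dplyr::n_distinct(layout$strain_id[layout$role == "array"])
  )

  manifest <- list(
    mode = config$mode,
    n_plates = dplyr::n_distinct(plates$plate_id),
    n_colony_records = nrow(plates),
    n_missing_colonies = sum(is.na(plates$size)),
    n_outlier_colonies = sum(norm$outlier),
    n_array_strains = summary$n_array,
    n_queries = summary$n_query,
    n_generated_pairs = n_generated,
    n_records = nrow(rec),
    n_scored_pairs = summary$n_scored_pairs,
    n_hits_negative = summary$n_hits_negative,
    n_hits_positive = summary$n_hits_positive,
    threshold = threshold,
    config = config
  )

  structure(list(interactions = rec, single_fitness = singles,
                 query_fitness = qfit, threshold = threshold,
                 summary = summary, manifest = manifest, config = config),
            class = "sga_result")
}

#' @export
print.sga_result <- function(x, ...) {
  s <- x$summary
  cat("SGA", toupper(x$config$mode), "screen result\n")
  cat("  generated pairs:", s$n_generated_pairs,
      "| scored:", s$n_scored_pairs,
      "| reciprocal collapsed:", s$n_reciprocal_collapsed, "\n")
  cat("  excluded - self:", s$n_excluded_self_cross,
      "linked:", s$n_excluded_linked,
      "low replicates:", s$n_excluded_low_replicates,
      "control defect:", s$n_excluded_control_defect, "\n")
  cat("  threshold:", formatC(x$threshold, digits = 4, format = "g"),
      "| negative hits:", s$n_hits_negative,
      paste0("(", formatC(s$frequency_percent, format = "f", digits = 2),
             "%)"),
      "| positive hits:", s$n_hits_positive, "\n")
  invisible(x)
}

#' Tidy interaction records of a screen result
#'
#' @param x An `sga_result`.
#' @param ... Unused.
#' @return The interaction record tibble (one row per unordered pair).
#' @export
tidy.sga_result <- function(x, ...) {
  x$interactions
}

#' One-row summary of a screen result
#'
#' @param x An `sga_result`.
#' @param ... Unused.
#' @return The one-row summary tibble (counts, frequency, threshold).
#' @export
glance.sga_result <- function(x, ...) {
  x$summary
}

#' Plot a screen result
#'
#' `type = "matrix"` draws the score heatmap (arrays x queries, the
#' familiar cyan-to-yellow screen display; excluded cells are blank);
#' `type = "scores"` draws the score distribution with the hit threshold.
#'
#' @param object An `sga_result`.
#' @param type `"matrix"` or `"scores"`.
#' @param limit Symmetric colour/display limit for scores (default 0.5, the
#'   display threshold commonly used for SDL heatmaps).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sga_result <- function(object, type = c("matrix", "scores"),
                                limit = 0.5, ...) {
  type <- match.arg(type)
  rec <- object$interactions
  if (type == "matrix") {
    rec$score[excluded_from_scoring(rec)] <- NA_real_
    rec$score_capped <- pmax(pmin(rec$score, limit), -limit)
    ggplot2::ggplot(rec, ggplot2::aes(x = .data$query_id,
                                      y = .data$array_id,
                                      fill = .data$score_capped)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(low = "cyan3", mid = "black",
                                    high = "yellow", midpoint = 0,
                                    limits = c(-limit, limit),
                                    na.value = "grey85",
                                    name = "score") +
      ggplot2::labs(x = "query strain", y = "array strain") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5))
  } else {
    keep <- !excluded_from_scoring(rec) & is.finite(rec$score)
    ggplot2::ggplot(rec[keep, ], ggplot2::aes(x = .data$score)) +
      ggplot2::geom_histogram(bins = 40, fill = "grey40") +
      ggplot2::geom_vline(xintercept = object$threshold,
                          colour = "red", linetype = "dashed") +
      ggplot2::labs(x = "interaction score (observed - expected)",
                    y = "pairs") +
      ggplot2::theme_minimal()
  }
}
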