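#' Spatial bias parameters for the synthetic generator
#'
#' Multiplicative plate artifacts emulating what the normalization stage must
#' remove: an overall plate scale, linear row and column growth gradients,
#' enhanced growth near the plate edge (colonies within two positions of the
#' boundary face less competition for nutrients), and per-colony lognormal
#' size noise.
#'
#' @param plate_scale Overall multiplicative plate factor (> 0).
#' @param row_slope,col_slope Linear gradient per position, applied as
#'   `1 + slope * (coordinate - centre)`.
#' @param edge_factor Multiplier for cells within two positions of the
#'   boundary (> 0).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   per-colony noise (mean 1).
#' @return A list of class `sga_bias`.
#' @export
bias_params <- function(plate_scale = 1, row_slope = 0.01, col_slope = 0.01,
                        edge_factor = 1.1, noise_cv = 0.10) {
  stopifnot(plate_scale > 0, edge_factor > 0, noise_cv >= 0)
  structure(list(plate_scale = plate_scale, row_slope = row_slope,
                 col_slope = col_slope, edge_factor = edge_factor,
                 noise_cv = noise_cv),
            class = "sga_bias")
}

#' Neutral (identity) bias parameters
#' @return A `sga_bias` list with all multipliers 1 and no noise.
#' @export
no_bias <- function() {
  bias_params(plate_scale = 1, row_slope = 0, col_slope = 0,
              edge_factor = 1, noise_cv = 0)
}

bias_multiplier <- function(row, col, n_rows, n_cols, bias) {
  rc <- (n_rows + 1) / 2
  cc <- (n_cols + 1) / 2
  edge <- pmin(row - 1L, n_rows - row, col - 1L, n_cols - col) < 2L
  m <- bias$plate_scale *
    (1 + bias$row_slope * (row - rc)) *
    (1 + bias$col_slope * (col - cc)) *
    bias$edge_factor^edge
  if (any(m <= 0)) {
    stop("spatial bias parameters produce non-positive multipliers",
         call. = FALSE)
  }
  m
}

#' Apply deterministic spatial bias to a plate grid
#'
#' Scales every present colony size by
#' `plate_scale * (1 + row_slope (r - r_centre)) * (1 + col_slope (c - c_centre))
#' * edge_factor^[within 2 of boundary]`. Noise is not applied here; it
#' belongs to the stochastic part of the generator.
#'
#' @param plates A plate-grid tibble (may hold several plates; the grid
#'   dimensions are the smallest standard density containing the
#'   coordinates).
#' @param bias A [bias_params()] list.
#' @return The plate tibble with biased sizes.
#' @export
apply_spatial_bias <- function(plates, bias) {
  dims <- density_dims(infer_density(max(plates$row), max(plates$col)))
  m <- bias_multiplier(plates$row, plates$col,
                       dims[["n_rows"]], dims[["n_cols"]], bias)
  plates$size <- plates$size * m
  plates
}

#' Screen configuration
#'
#' One configuration object drives both the synthetic generator and the
#' scoring pipeline, so a simulated screen can be scored with exactly the
#' settings it was generated under.
#'
#' @param mode `"sl"` (double-deletion, derived mean - k SD threshold) or
#'   `"sdl"` (overexpression x deletion, fixed score cutoffs and a paired
#'   +thiamin control condition).
#' @param query_ids,array_ids Strain identifiers. For SL screens queries are
#'   deletion strains and should normally be a subset of the array (as in a
#'   screen whose 38 queries are among its 91 array strains), so their
#'   single-mutant fitness comes from the control cross.
#' @param control_query_id Identifier of the neutral control query (the
#'   marker-switched leu1 deletion for SL; the empty-vector strain for SDL).
#' @param n_screen_replicates Biological replicate screens (default 3).
#' @param density Plate density of the assembled array (768 for SL before
#'   pinning, 384 for the SDL miniarray).
#' @param replicates_per_strain Array positions per strain at `density`
#'   (6 for SL; `NULL` for SDL = maximal multiplicity that fits).
#' @param pin_duplicate Whether the array is duplicate-pinned to 1536
#'   density for the final readout (SL default `TRUE`, giving 12 colonies
#'   per strain per screen).
#' @param reference_size Mean colony area (arbitrary units) of a fitness-1
#'   colony before bias; all downstream quantities are ratios, so its value
#'   is immaterial.
#' @param bias A [bias_params()] list.
#' @param missing_rate Probability that a colony fails to pin (recorded as
#'   missing, not zero).
#' @param linkage_window_bp Linkage-exclusion window (default 200,000 bp).
#' @param threshold_k SL threshold policy: mean - k SD of unflagged scores
#'   (default k = 2).
#' @param sdl_cutoff Absolute fixed cutoff for SDL calls (default 0.5:
#'   negative below -0.5, positive above +0.5).
#' @param min_replicates Minimum usable colonies per pair before the record
#'   is flagged `low_replicates` (default 6, half the 12-colony design).
#' @param control_fitness_floor SDL only: pairs whose fitness on the
#'   +thiamin control plates falls below this floor are flagged
#'   `control_defect` (default 0.5).
#' @param normalization A [norm_params()] list.
#' @param aggregate `"pool"` (all colonies weighted equally across plates
#'   and screens, the default) or `"screen_mean"` (mean of per-screen
#'   means).
#' @return A list of class `sga_config`.
#' @export
screen_config <- function(mode = c("sl", "sdl"), query_ids, array_ids,
                          control_query_id = if (mode == "sl") "ctrl_leu1" else "empty_vector",
                          n_screen_replicates = 3L,
                          density = if (mode == "sl") 768L else 384L,
                          replicates_per_strain = if (mode == "sl") 6L else NULL,
                          pin_duplicate = (mode == "sl"),
                          reference_size = 1000,
                          bias = bias_params(),
                          missing_rate = 0,
                          linkage_window_bp = 200000,
                          threshold_k = 2,
                          sdl_cutoff = 0.5,
                          min_replicates = 6L,
                          control_fitness_floor = 0.5,
                          normalization = norm_params(),
                          aggregate = c("pool", "screen_mean")) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  stopifnot(length(query_ids) >= 1, length(array_ids) >= 1,
            n_screen_replicates >= 1, threshold_k > 0,
            linkage_window_bp >= 0, sdl_cutoff > 0)
  structure(list(
    mode = mode,
    query_ids = as.character(query_ids),
    array_ids = as.character(array_ids),
    control_query_id = control_query_id,
    n_screen_replicates = as.integer(n_screen_replicates),
    density = as.integer(density),
    replicates_per_strain = replicates_per_strain,
    pin_duplicate = pin_duplicate,
    reference_size = reference_size,
    bias = bias,
    missing_rate = missing_rate,
    linkage_window_bp = linkage_window_bp,
    threshold_k = threshold_k,
    sdl_cutoff = sdl_cutoff,
    min_replicates = as.integer(min_replicates),
    control_fitness_floor = control_fitness_floor,
    normalization = normalization,
    aggregate = aggregate
  ), class = "sga_config")
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Planted ground truth for a synthetic screen
#'
#' Draws single-mutant fitness values and pairwise interaction effects from
#' the current RNG stream. A configurable fraction of array strains carries a
#' fitness defect; the rest are wild-type-like (fitness exactly 1), which
#' keeps the median array strain at fitness 1 -- the assumption plate-median
#' normalization rests on. Interaction effects are planted additively on the
#' fitness scale: the double-mutant fitness of a planted pair is
#' `f_query * f_array + effect`, clipped at 0.
#'
#' @param config A [screen_config()].
#' @param frac_defect Fraction of array strains given a fitness defect
#'   (default 0.3, so the plate median stays wild-type-like).
#' @param defect_range Uniform range of defective single-mutant fitness.
#' @param interaction_frac Fraction of non-self query x array pairs given a
#'   planted effect (default 0.05).
#' @param interaction_effect Planted effect size (default -0.4, a strong
#'   negative interaction).
#' @param sdl_query_fitness_range SDL only: uniform range of the
#'   overexpression toxicity of query strains under induction.
#' @param control_defect_pairs Optional data frame (`query_id`, `array_id`,
#'   `factor`) of pairs whose fitness on SDL +thiamin control plates is
#'   multiplied by `factor` (models combinations sick even under promoter
#'   repression, e.g. through leaky expression).
#' @return A list of class `sga_truth` with elements `single_fitness`
#'   (tibble `strain_id`, `fitness`), `query_fitness` (tibble `query_id`,
#'   `fitness`), `pair_effects` (tibble `query_id`, `array_id`, `effect`)
#'   and `control_effects`.
#' @export
synthetic_truth <- function(config, frac_defect = 0.3,
                            defect_range = c(0.5, 0.9),
                            interaction_frac = 0.05,
                            interaction_effect = -0.4,
                            sdl_query_fitness_range = c(0.4, 0.9),
                            control_defect_pairs = NULL) {
  strains <- unique(c(config$array_ids,
                      if (config$mode == "sl") config$query_ids))
  n <- length(strains)
  f <- rep(1, n)
  n_def <- round(frac_defect * n)
  if (n_def > 0) {
    def <- sample.int(n, n_def)
    f[def] <- stats::runif(n_def, defect_range[1], defect_range[2])
  }
  single <- tibble::tibble(strain_id = strains, fitness = f)
  qf <- if (config$mode == "sl") {
    tibble::tibble(query_id = config$query_ids,
                   fitness = single$fitness[match(config$query_ids, strains)])
  } else {
    tibble::tibble(query_id = config$query_ids,
                   fitness = stats::runif(length(config$query_ids),
                                          sdl_query_fitness_range[1],
                                          sdl_query_fitness_range[2]))
  }
  cand <- tidyr::expand_grid(query_id = config$query_ids,
                             array_id = config$array_ids) |>
    dplyr::filter(.data$query_id != .data$array_id) |>
    dplyr::distinct(key = pair_key(.data$query_id, .data$array_id),
                    .keep_all = TRUE)
  n_int <- round(interaction_frac * nrow(cand))
  pe <- if (n_int > 0) {
    picked <- cand[sample.int(nrow(cand), n_int), c("query_id", "array_id")]
    picked$effect <- interaction_effect
    picked
  } else {
    tibble::tibble(query_id = character(), array_id = character(),
                   effect = double())
  }
  ce <- if (is.null(control_defect_pairs)) {
    tibble::tibble(query_id = character(), array_id = character(),
                   factor = double())
  } else tibble::as_tibble(control_defect_pairs)
  structure(list(single_fitness = single, query_fitness = qf,
                 pair_effects = tibble::as_tibble(pe),
                 control_effects = ce),
            class = "sga_truth")
}

truth_lookup <- function(truth) {
  sf <- stats::setNames(truth$single_fitness$fitness,
                        truth$single_fitness$strain_id)
  qf <- stats::setNames(truth$query_fitness$fitness,
                        truth$query_fitness$query_id)
  eff <- stats::setNames(truth$pair_effects$effect,
                         pair_key(truth$pair_effects$query_id,
                                  truth$pair_effects$array_id))
  ctl <- stats::setNames(truth$control_effects$factor,
                         pair_key(truth$control_effects$query_id,
                                  truth$control_effects$array_id))
  list(sf = sf, qf = qf, eff = eff, ctl = ctl)
}

# Expected (noise-free, bias-free) colony fitness for each layout cell.
cell_fitness <- function(layout, lk, query_id, query_role, condition,
                         mode) {
  f <- numeric(nrow(layout))
  f[layout$role == "border"] <- 1
  ai <- which(layout$role == "array")
  a <- layout$strain_id[ai]
  fa <- unname(lk$sf[a])
  if (any(is.na(fa))) {
    stop("strain(s) in layout absent from truth: ",
         paste(utils::head(unique(a[is.na(fa)]), 5), collapse = ", "),
         call. = FALSE)
  }
  if (query_role == "control_query") {
    f[ai] <- fa
  } else if (condition == "selection") {
    fq <- unname(lk$qf[query_id])
    if (is.na(fq)) stop("query ", query_id, " absent from truth", call. = FALSE)
    eps <- lk$eff[pair_key(query_id, a)]
    eps[is.na(eps)] <- 0
    f[ai] <- pmax(0, fq * fa + unname(eps))
  } else {
    # SDL +thiamin control condition: promoter repressed, overexpression
    # toxicity and interaction absent; optional planted control defects.
    ctl <- lk$ctl[pair_key(query_id, a)]
    ctl[is.na(ctl)] <- 1
    f[ai] <- fa * unname(ctl)
  }
  f
}

#' Simulate a complete SL or SDL screen
#'
#' Generates the full set of plate grids a real screen would produce: the
#' control-query cross (estimating array single-mutant fitness) and one
#' screen per query, each with `n_screen_replicates` replicate plates; in
#' SDL mode every query screen additionally gets paired +thiamin control
#' plates on which the overexpression is repressed. The expected colony size
#' at an interior position is `reference_size * fitness` (fitness 1 for
#' border controls, `f_array` for the control cross,
#' `max(0, f_query * f_array + effect)` for query crosses), multiplied by
#' the deterministic spatial bias field and per-colony lognormal noise.
#' Blank positions are size 0. Output is fully reproducible from `seed`.
#'
#' @param config A [screen_config()].
#' @param seed Integer seed controlling every random draw (truth included).
#' @param truth Optional [synthetic_truth()]; drawn from `config` when
#'   omitted.
#' @param linked_pairs Optional data frame of strain pairs to place within
#'   the linkage window (see [synthetic_annotations()]).
#' @param ... Passed to [synthetic_truth()] when `truth` is omitted.
#' @return A list of class `sga_sim` with elements `plates`, `layout`,
#'   `screens`, `annotations`, `truth`, `config`, `seed`.
#' @export
#' @examples
#' cfg <- screen_config("sl", query_ids = c("tf01", "tf02"),
#'                      array_ids = sprintf("tf%02d", 1:12))
#' sim <- simulate_screen(cfg, seed = 1)
#' dplyr::count(sim$plates, screen_id, replicate)
simulate_screen <- function(config, seed = 1L, truth = NULL,
                            linked_pairs = NULL, ...) {
  stopifnot(inherits(config, "sga_config"))
  set.seed(as.integer(seed))
  if (is.null(truth)) truth <- synthetic_truth(config, ...)
  lk <- truth_lookup(truth)

  layout <- if (config$mode == "sl") {
    l <- build_sl_layout(config$array_ids, config$replicates_per_strain,
                         config$density)
    if (config$pin_duplicate) duplicate_pin(l) else l
  } else {
    build_sdl_layout(config$array_ids, config$density)
  }
  dims <- layout_dims(layout)

  all_strains <- unique(c(config$array_ids, config$query_ids,
                          config$control_query_id))
  roles <- c(stats::setNames(rep("array", length(config$array_ids)),
                             config$array_ids),
             stats::setNames(rep("query", length(config$query_ids)),
                             config$query_ids),
             stats::setNames("control_query", config$control_query_id))
  annotations <- synthetic_annotations(all_strains,
                                       linked_pairs = linked_pairs,
                                       role_tags = roles)

  screens <- tibble::tibble(
    screen_id = c("S_ctrl", paste0("S_", config$query_ids)),
    query_id = c(config$control_query_id, config$query_ids),
    query_role = c("control_query", rep("query", length(config$query_ids)))
  )

  bias_m <- bias_multiplier(layout$row, layout$col,
                            dims[["n_rows"]], dims[["n_cols"]], config$bias)
  sdlog <- sqrt(log(1 + config$bias$noise_cv^2))

  one_plate <- function(screen_id, query_id, query_role, condition, rep_i) {
    f <- cell_fitness(layout, lk, query_id, query_role, condition,
                      config$mode)
    mu <- config$reference_size * f * bias_m
    size <- mu
    pos <- mu > 0
    if (sdlog > 0 && any(pos)) {
      size[pos] <- mu[pos] * stats::rlnorm(sum(pos), -sdlog^2 / 2, sdlog)
    }
    if (config$missing_rate > 0) {
      size[stats::runif(length(size)) < config$missing_rate] <- NA_real_
    }
    tibble::tibble(
      plate_id = paste(screen_id, condition, rep_i, sep = "."),
      screen_id = screen_id, condition = condition,
      replicate = as.integer(rep_i),
      row = layout$row, col = layout$col, size = size
    )
  }

  plates <- vector("list", 0)
  for (s in seq_len(nrow(screens))) {
    conditions <- if (config$mode == "sdl" &&
                      screens$query_role[s] == "query") {
      c("selection", "control")
    } else "selection"
    for (rep_i in seq_len(config$n_screen_replicates)) {
      for (cond in conditions) {
        plates[[length(plates) + 1L]] <-
          one_plate(screens$screen_id[s], screens$query_id[s],
                    screens$query_role[s], cond, rep_i)
      }
    }
  }
  plates <- dplyr::bind_rows(plates)

  structure(list(plates = plates, layout = layout, screens = screens,
                 annotations = annotations, truth = truth, config = config,
                 seed = as.integer(seed)),
            class = "sga_sim")
}

#' @export
print.sga_sim <- function(x, ...) {
  cat("Synthetic", toupper(x$config$mode), "screen:",
      length(x$config$query_ids), "queries x",
      length(x$config$array_ids), "array strains,",
      x$config$n_screen_replicates, "replicate screens,",
      dplyr::n_distinct(x$plates$plate_id), "plates,",
      nrow(x$plates), "colony records (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}
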