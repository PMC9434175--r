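test_that("expected fitness and interaction score follow the multiplicative model", {
  expect_equal(expected_fitness(1.0, 0.75), 0.75)
  expect_equal(expected_fitness(0.8, 0.5), 0.4)
  expect_equal(expected_fitness(0, 0.9), 0)
  expect_error(expected_fitness(NA_real_, 1), "finite")
  expect_error(expected_fitness(-0.1, 1), "finite")
  expect_equal(interaction_score(0.215, 0.400), -0.185)
  expect_equal(interaction_score(0.5, 0.5), 0)
  expect_equal(interaction_score(1.0, 0.75), 0.25)
})

test_that("fitness aggregation pools colonies with exact bookkeeping", {
  lay <- build_sl_layout(c("a", "b"), replicates = 6, density = 384)
  screens <- tibble::tibble(screen_id = c("S_ctrl", "S_q"),
                            query_id = c("ctrl", "qA"),
                            query_role = c("control_query", "query"))
  mk <- function(screen, rep, vals) {
    tibble::tibble(
      plate_id = paste0(screen, ".", rep), screen_id = screen,
      condition = "selection", replicate = rep,
      row = lay$row, col = lay$col,
      relative_size = dplyr::case_when(
        lay$strain_id %in% "a" ~ vals[1],
        lay$strain_id %in% "b" ~ vals[2],
        TRUE ~ 1),
      outlier = FALSE)
  }
  norm <- dplyr::bind_rows(
    mk("S_ctrl", 1L, c(1.0, 0.4)), mk("S_ctrl", 2L, c(1.0, 0.6)),
    mk("S_q", 1L, c(0.215, 0.215)), mk("S_q", 2L, c(0.215, 0.215)),
    mk("S_q", 3L, c(0.215, 0.215)))
  singles <- single_mutant_fitness(norm, lay, screens)
  expect_equal(singles$fitness[singles$strain_id == "a"], 1.0)
  expect_equal(singles$dispersion[singles$strain_id == "a"], 0)
  # replicates half 0.4 half 0.6 pool to 0.5
  expect_equal(singles$fitness[singles$strain_id == "b"], 0.5)
  expect_equal(singles$n[singles$strain_id == "b"], 12)

  qfit <- tibble::tibble(query_id = "qA", fitness = 1)
  doubles <- double_mutant_fitness(norm, lay, screens, qfit)
  da <- doubles[doubles$array_id == "a", ]
  expect_equal(da$observed, 0.215)
  expect_equal(da$n, 18L)                      # 6 colonies x 3 plates
  expect_equal(unlist(da$screens), "S_q")
  # permutation invariance of the colony order
  norm_perm <- norm[sample.int(nrow(norm)), ]
  d2 <- double_mutant_fitness(norm_perm, lay, screens, qfit)
  expect_equal(d2$observed, doubles$observed)
  expect_equal(d2$n, doubles$n)
})

test_that("reciprocal crosses pool at the colony level, self-crosses are flagged", {
  pairs <- tibble::tibble(
    query_id = c("A", "B", "A", "C"),
    array_id = c("B", "A", "A", "D"),
    observed = c(0.5, 0.7, 0.9, 0.3),
    n = c(36L, 36L, 36L, 36L),
    dispersion = c(0.1, 0.1, 0.05, 0.2),
    screens = list("S_A", "S_B", "S_A", "S_C")
  )
  merged <- merge_reciprocal(pairs)
  ab <- merged[merged$query_id == "A" & merged$array_id == "B", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$n, 72L)
  expect_equal(ab$observed, 0.6)     # colony-weighted mean of 0.5 and 0.7
  expect_true(ab$reciprocal_merged)
  # pooled sd equals the sd of the pooled colonies
  x1 <- 0.5 + 0.1 * scale(seq_len(36))[, 1]
  x2 <- 0.7 + 0.1 * scale(seq_len(36))[, 1]
  expect_equal(ab$dispersion, stats::sd(c(x1, x2)), tolerance = 1e-12)
  aa <- merged[merged$query_id == "A" & merged$array_id == "A", ]
  expect_true(aa$self_cross)
  cd <- merged[merged$query_id == "C", ]
  expect_false(cd$reciprocal_merged)
  expect_equal(cd$observed, 0.3)
})

test_that("linkage filtering uses a strict 200 kb interval-gap rule", {
  ann <- tibble::tibble(
    strain_id = c("q1", "a1", "a2", "a3", "a4"),
    gene_id = paste0(c("q1", "a1", "a2", "a3", "a4"), "_g"),
    chromosome = c("chr1", "chr1", "chr2", "chr1", "chr1"),
    start = c(100000, 250000, 250000, 301000, 302000),
    end   = c(101000, 251000, 251000, 302000, 303000),
    role_tag = c("query", rep("array", 4))
  )
  pairs <- tibble::tibble(query_id = "q1",
                          array_id = c("a1", "a2", "a3", "a4"),
                          observed = 1, n = 36L, dispersion = 0,
                          screens = list("s", "s", "s", "s"))
  out <- linkage_filter(pairs, ann, window_bp = 200000)
  # gap 149,000 on the same chromosome -> linked
  expect_true(out$linked[out$array_id == "a1"])
  # different chromosome, same coordinates -> never linked
  expect_false(out$linked[out$array_id == "a2"])
  # gap exactly 200,000 -> retained (strict inequality)
  expect_equal(ann$start[4] - ann$end[1], 200000)
  expect_false(out$linked[out$array_id == "a3"])
  # gap 200,001 -> not linked either; one bp closer -> linked
  expect_false(out$linked[out$array_id == "a4"])
  ann2 <- ann; ann2$start[5] <- 300999; ann2$end[5] <- 301999
  out2 <- linkage_filter(pairs, ann2, window_bp = 200000)
  expect_true(out2$linked[out2$array_id == "a4"])
  expect_error(linkage_filter(
    dplyr::mutate(pairs, array_id = paste0("x", array_id)), ann),
    "no annotation")
})

test_that("threshold derivation is mean minus k sample standard deviations", {
  expect_equal(derive_threshold(c(-0.1, 0, 0.1), k = 2), -0.2)
  s <- c(-0.1, 0, 0.1, 0.25)
  expect_equal(derive_threshold(s, k = 0), mean(s))
  expect_error(derive_threshold(0.1), "at least 2")
  # strictly decreasing in k whenever the scores have spread
  ks <- c(0, 0.5, 1, 2, 3)
  th <- vapply(ks, function(k) derive_threshold(s, k), numeric(1))
  expect_true(all(diff(th) < 0))
})

test_that("hit calling follows the mode-specific rules", {
  rec <- tibble::tibble(
    query_id = letters[1:6], array_id = LETTERS[1:6],
    observed = 1, expected = 1,
    score = c(-0.25, -0.10, 0.05, -0.45, -0.60, 0.60),
    n = 36L, low_replicates = FALSE, linked = FALSE, self_cross = FALSE
  )
  sl <- call_hits(rec, mode = "sl", threshold = -0.185)
  expect_equal(sl$hit, c("negative", "none", "none", "negative", "negative",
                         "none"))
  sdl <- call_hits(rec, mode = "sdl", cutoff = 0.5)
  # -0.45 sits between the -0.5 cutoff and the -0.3 reference: not a hit
  expect_equal(sdl$hit, c("none", "none", "none", "none", "negative",
                          "positive"))
  # excluded records never become hits
  rec$linked[5] <- TRUE
  expect_equal(call_hits(rec, "sdl")$hit[5], "none")
  expect_error(call_hits(rec, "both"), "arg")
})

test_that("SDL control-condition defects are flagged against the floor", {
  rec <- tibble::tibble(query_id = c("q", "q", "q"),
                        array_id = c("a", "b", "c"),
                        score = c(-0.6, -0.7, -0.8), n = 12L)
  ctrl <- tibble::tibble(query_id = c("q", "q", "q"),
                         array_id = c("a", "b", "c"),
                         observed = c(0.2, 1.0, 0.49))
  out <- flag_control_defect(rec, ctrl, floor = 0.5)
  expect_equal(out$control_defect, c(TRUE, FALSE, TRUE))
  out0 <- flag_control_defect(rec, ctrl, floor = 0)
  expect_false(any(out0$control_defect))
})

test_that("single-mutant fitness recovers planted values within tolerance", {
  cfg <- screen_config(
    "sl", query_ids = "tf01", array_ids = tf_ids(91),
    bias = bias_params(plate_scale = 1, row_slope = 0, col_slope = 0,
                       edge_factor = 1, noise_cv = 0.10))
  truth <- synthetic_truth(cfg, frac_defect = 0, interaction_frac = 0)
  truth$single_fitness$fitness[truth$single_fitness$strain_id == "tf05"] <- 0.7
  sim <- simulate_screen(cfg, seed = 21, truth = truth)
  norm <- normalize_plates(sim$plates, sim$layout, cfg$normalization) |>
    flag_outlier_colonies(sim$layout, cfg$normalization)
  singles <- single_mutant_fitness(norm, sim$layout, sim$screens)
  est <- singles$fitness[singles$strain_id == "tf05"]
  expect_lt(abs(est - 0.7), 0.03)
  expect_equal(singles$n[singles$strain_id == "tf05"], 36)
})

test_that("strains with no usable colonies are kept with n = 0 and flagged", {
  lay <- build_sl_layout(c("a", "b"), replicates = 6, density = 384)
  screens <- tibble::tibble(screen_id = c("S_ctrl", "S_q"),
                            query_id = c("ctrl", "qA"),
                            query_role = c("control_query", "query"))
  norm <- tibble::tibble(
    plate_id = "S_q.1", screen_id = "S_q", condition = "selection",
    replicate = 1L, row = lay$row, col = lay$col,
    relative_size = ifelse(lay$strain_id %in% "a", 1, NA_real_),
    outlier = FALSE)
  qfit <- tibble::tibble(query_id = "qA", fitness = 1)
  doubles <- double_mutant_fitness(norm, lay, screens, qfit)
  db <- doubles[doubles$array_id == "b", ]
  expect_equal(db$n, 0L)
  expect_true(is.na(db$observed))
  singles <- tibble::tibble(strain_id = c("a", "b", "qA"), fitness = 1)
  scored <- score_interactions(doubles, singles, qfit, min_replicates = 6)
  expect_true(scored$low_replicates[scored$array_id == "b"])
  expect_false(scored$low_replicates[scored$array_id == "a"])
})
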