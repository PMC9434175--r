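test_that("degenerate generator reproduces the reference size exactly", {
  cfg <- screen_config("sl", query_ids = "tf01", array_ids = tf_ids(10),
                       bias = no_bias(), reference_size = 1000)
  truth <- list(
    single_fitness = tibble::tibble(strain_id = tf_ids(10), fitness = 1),
    query_fitness = tibble::tibble(query_id = "tf01", fitness = 1),
    pair_effects = tibble::tibble(query_id = character(),
                                  array_id = character(), effect = double()),
    control_effects = tibble::tibble(query_id = character(),
                                     array_id = character(), factor = double())
  )
  class(truth) <- "sga_truth"
  sim <- simulate_screen(cfg, seed = 1, truth = truth)
  lay <- sim$layout
  interior <- dplyr::semi_join(
    sim$plates, dplyr::filter(lay, .data$role != "blank"),
    by = c("row", "col"))
  expect_true(all(interior$size == 1000))
  blanks <- dplyr::semi_join(sim$plates,
                             dplyr::filter(lay, .data$role == "blank"),
                             by = c("row", "col"))
  expect_true(all(blanks$size == 0))
})

test_that("generator output is byte-identical under the same seed", {
  cfg <- screen_config("sl", query_ids = c("tf01", "tf02"),
                       array_ids = tf_ids(12))
  s1 <- simulate_screen(cfg, seed = 9)
  s2 <- simulate_screen(cfg, seed = 9)
  expect_identical(s1$plates, s2$plates)
  expect_identical(s1$truth, s2$truth)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_plate_table(s1$plates, f1); write_plate_table(s2$plates, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_screen(cfg, seed = 10)
  expect_false(identical(s1$plates, s3$plates))
})

test_that("planted fitness and effect combine on the fitness scale", {
  # f_q = 0.8, f_a = 0.5, effect -0.185 -> colony = reference * 0.215
  cfg <- screen_config("sl", query_ids = "q", array_ids = c("q", "a"),
                       bias = no_bias(), reference_size = 1000)
  truth <- list(
    single_fitness = tibble::tibble(strain_id = c("q", "a"),
                                    fitness = c(0.8, 0.5)),
    query_fitness = tibble::tibble(query_id = "q", fitness = 0.8),
    pair_effects = tibble::tibble(query_id = "q", array_id = "a",
                                  effect = -0.185),
    control_effects = tibble::tibble(query_id = character(),
                                     array_id = character(), factor = double())
  )
  class(truth) <- "sga_truth"
  sim <- simulate_screen(cfg, seed = 1, truth = truth)
  qplate <- dplyr::filter(sim$plates, .data$screen_id == "S_q",
                          .data$replicate == 1)
  acells <- dplyr::semi_join(
    qplate, dplyr::filter(sim$layout, .data$strain_id == "a"),
    by = c("row", "col"))
  expect_equal(unique(acells$size), 1000 * (0.8 * 0.5 - 0.185))
})

test_that("spatial bias is the declared multiplicative field", {
  pl <- uniform_plate(size = 1)
  doubled <- apply_spatial_bias(pl, bias_params(plate_scale = 2, row_slope = 0,
                                                col_slope = 0, edge_factor = 1,
                                                noise_cv = 0))
  expect_true(all(doubled$size == 2))
  ident <- apply_spatial_bias(pl, no_bias())
  expect_identical(ident$size, pl$size)
  grad <- apply_spatial_bias(pl, bias_params(plate_scale = 1, row_slope = 0.01,
                                             col_slope = 0, edge_factor = 1,
                                             noise_cv = 0))
  row_means <- tapply(grad$size, grad$row, mean)
  expect_true(all(diff(row_means) > 0))   # monotone in the gradient direction
  expect_error(
    apply_spatial_bias(pl, bias_params(row_slope = 0.2)),
    "non-positive")
})

test_that("downstream results are invariant to the reference colony size", {
  base <- screen_config("sl", query_ids = c("tf01", "tf02"),
                        array_ids = tf_ids(15), reference_size = 1000)
  big <- screen_config("sl", query_ids = c("tf01", "tf02"),
                       array_ids = tf_ids(15), reference_size = 5000)
  s1 <- simulate_screen(base, seed = 3)
  s2 <- simulate_screen(big, seed = 3)
  r1 <- score_screen(s1$plates, s1$layout, s1$screens, s1$annotations, base)
  r2 <- score_screen(s2$plates, s2$layout, s2$screens, s2$annotations, big)
  expect_equal(r1$interactions$score, r2$interactions$score, tolerance = 1e-12)
})

test_that("SDL control plates suppress overexpression toxicity and effects", {
  cfg <- screen_config("sdl", query_ids = "q1", array_ids = sprintf("d%02d", 1:8),
                       bias = no_bias())
  truth <- list(
    single_fitness = tibble::tibble(strain_id = sprintf("d%02d", 1:8),
                                    fitness = 1),
    query_fitness = tibble::tibble(query_id = "q1", fitness = 0.5),
    pair_effects = tibble::tibble(query_id = "q1", array_id = "d01",
                                  effect = -0.5),
    control_effects = tibble::tibble(query_id = "q1", array_id = "d02",
                                     factor = 0.3)
  )
  class(truth) <- "sga_truth"
  sim <- simulate_screen(cfg, seed = 1, truth = truth)
  sel <- dplyr::filter(sim$plates, .data$screen_id == "S_q1",
                       .data$condition == "selection", .data$replicate == 1)
  ctl <- dplyr::filter(sim$plates, .data$screen_id == "S_q1",
                       .data$condition == "control", .data$replicate == 1)
  pos <- function(id) dplyr::filter(sim$layout, .data$strain_id == id)
  at <- function(pl, p) pl$size[pl$row == p$row[1] & pl$col == p$col[1]]
  # selection: toxicity 0.5 and planted effect -0.5 -> clipped at 0
  expect_equal(at(sel, pos("d01")), 0)
  # selection without effect: 0.5 * 1
  expect_equal(at(sel, pos("d03")), 1000 * 0.5)
  # control condition: promoter repressed, only the planted control defect
  expect_equal(at(ctl, pos("d01")), 1000)
  expect_equal(at(ctl, pos("d02")), 1000 * 0.3)
})
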