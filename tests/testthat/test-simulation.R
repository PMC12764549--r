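test_that("candidate proposals use the level set deterministically", {
  cfg <- simulation_config(n_media = 5, n_components = 8, levels = 5)
  set.seed(1); a <- propose_media(cfg)
  set.seed(1); b <- propose_media(cfg)
  expect_identical(a$values, b$values)
  expect_true(all(a$values %in% 0:4))
  cfg1 <- simulation_config(n_media = 3, n_components = 4, levels = 1)
  set.seed(2)
  expect_true(all(propose_media(cfg1)$values == 0))
})

test_that("the penalty orders hard violations above any soft count", {
  cfg <- simulation_config(n_media = 4, n_components = 4)
  # constant component column
  set.seed(3)
  vals <- matrix(sample(0:4, 16, TRUE), 4, 4)
  vals[, 2] <- 3
  p1 <- media_penalty(vals, cfg)
  expect_gte(p1$zero_variance, 1)
  expect_gte(p1$total, p1$high_weight)

  # identical columns: |r| = 1 > 0.9
  v2 <- cbind(c(0, 1, 2, 4), c(0, 1, 2, 4), c(4, 1, 0, 2), c(1, 3, 0, 2))
  p2 <- media_penalty(v2, cfg)
  expect_identical(p2$hard_pairs, 1L)
  expect_gte(p2$total, p2$high_weight)

  # constructed candidate with exactly one pair at r = 0.8: columns built
  # from mutually orthogonal centered directions z1, w, u so that
  # cor(col1, col2) = 0.8, cor(col2, col4) = 0.6, all other pairs 0
  z1 <- c(-3, -1, 1, 3); w <- c(1, -1, -1, 1); u <- c(1, -3, 3, -1)
  z2 <- 0.8 * z1 / sqrt(5) + 0.6 * w
  v3 <- cbind(z1 - min(z1), z2 - min(z2), u - min(u), w - min(w))
  expect_equal(cor(v3[, 1], v3[, 2]), 0.8, tolerance = 1e-12)
  p3 <- media_penalty(v3, cfg)
  expect_identical(p3$soft_pairs, 1L)
  expect_identical(p3$hard_pairs, 0L)
  expect_identical(p3$zero_variance, 0L)
  expect_equal(p3$total, 1)

  # the high weight exceeds any possible soft count for d <= 200
  expect_gt(200^2 + 1, choose(200, 2))
  expect_gt(p2$total, p3$total + choose(4, 2))
})

test_that("candidate screening improves with more draws and matches its reference path", {
  cfg <- simulation_config(n_media = 6, n_components = 15,
                           inner_iters = 30, inner_strategy = "regenerate")
  set.seed(4); a <- best_candidate(cfg)
  set.seed(4); b <- best_candidate(cfg, use_reference = TRUE)
  expect_identical(a$composition$values, b$composition$values)
  expect_equal(a$penalty$total, b$penalty$total)

  # single draw equals a single proposal
  cfg1 <- simulation_config(n_media = 6, n_components = 15, inner_iters = 1,
                            inner_strategy = "regenerate")
  set.seed(5); p <- propose_media(cfg1)
  set.seed(5); c1 <- best_candidate(cfg1)
  expect_identical(p$values, c1$composition$values)

  # more draws dominate in distribution (Monte-Carlo over seeds)
  pen_at <- function(iters, seeds) {
    vapply(seeds, function(s) {
      set.seed(s)
      best_candidate(simulation_config(n_media = 8, n_components = 20,
                                       inner_iters = iters,
                                       inner_strategy = "regenerate"))$penalty$total
    }, numeric(1))
  }
  expect_lte(mean(pen_at(200, 1:8)), mean(pen_at(5, 1:8)))

  # the swap strategy reaches at most the regenerate penalty on average
  pen_swap <- vapply(1:5, function(s) {
    set.seed(s)
    best_candidate(simulation_config(n_media = 8, n_components = 20,
                                     inner_iters = 200))$penalty$total
  }, numeric(1))
  expect_lte(mean(pen_swap), mean(pen_at(200, 1:5)))
})

test_that("mother-media simulation is reproducible and reduces to its parts", {
  cfg <- simulation_config(n_media = 6, n_components = 12, inner_iters = 40,
                           outer_iters = 3, n_conditions = 20,
                           design_iters = 150, seed = 6)
  s1 <- simulate_mother_media(cfg)
  s2 <- simulate_mother_media(cfg)
  expect_identical(s1$composition$values, s2$composition$values)
  expect_identical(s1$design$indices, s2$design$indices)
  expect_equal(s1$condition_metrics, s2$condition_metrics)
  expect_identical(s1$design$gram_det, max(s1$outer_dets))

  # outer_iters = 1 equals one candidate + one design run
  cfg1 <- simulation_config(n_media = 6, n_components = 12, inner_iters = 40,
                            outer_iters = 1, n_conditions = 20,
                            design_iters = 150, seed = 7)
  one <- simulate_mother_media(cfg1)
  set.seed(7)
  enum <- enumerate_blends(6, 6)
  cand <- best_candidate(cfg1)
  des <- design_blending(cand$composition, 20, iters = 150,
                         enumeration = enum)
  expect_identical(one$composition$values, cand$composition$values)
  expect_identical(one$design$indices, des$indices)

  expect_error(simulate_mother_media(
    simulation_config(n_media = 3, total_units = 2, n_conditions = 20)),
    "infeasible")
})

test_that("a single-cell sweep equals a direct simulation call", {
  cfg <- simulation_config(inner_iters = 30, outer_iters = 2,
                           n_conditions = 15, design_iters = 100)
  sw <- correlation_sweep(10, 5, cfg, seed = 40)
  expect_identical(nrow(sw), 1L)
  cell_cfg <- cfg
  cell_cfg$n_components <- 10L; cell_cfg$n_media <- 5L; cell_cfg$seed <- 41L
  direct <- simulate_mother_media(cell_cfg)
  expect_equal(sw$n_high_pairs, direct$condition_metrics$n_high)
  expect_equal(sw$mean_abs_r, direct$condition_metrics$mean_abs_r)
})

test_that("more mother media mean fewer highly correlated condition pairs", {
  frac_at <- function(m, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- simulation_config(n_media = m, n_components = 30,
                               inner_iters = 100, outer_iters = 5,
                               n_conditions = 40, design_iters = 400,
                               seed = s)
      simulate_mother_media(cfg)$condition_metrics$frac_high
    }, numeric(1)))
  }
  expect_gt(frac_at(4, 1:3), frac_at(12, 1:3))
})
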