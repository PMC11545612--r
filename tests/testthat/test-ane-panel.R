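test_that("median normalization is idempotent, removes chip scale, recovers factors", {
  m <- matrix(c(1, 2, 4, 8, 2, 4, 8, 16), nrow = 4,
              dimnames = list(paste0("m", 1:4), c("s1", "s2")))
  expr <- toy_expr(m)
  once <- normalize_expression(expr)
  twice <- normalize_expression(once)
  expect_equal(as.matrix(once[-1]), as.matrix(twice[-1]), tolerance = 1e-9)

  # scaling one sample by 10 is removed: between-sample ratios coincide
  scaled <- expr
  scaled$s2 <- scaled$s2 * 10
  norm_sc <- normalize_expression(scaled)
  expect_equal(norm_sc$s2 / norm_sc$s1, once$s2 / once$s1, tolerance = 1e-9)

  # generator-known per-chip factors recovered up to a common constant
  sim <- simulate_ane_experiment(sim_config(seed = 5, n_mirnas = 2000,
                                            noise_sigma = 0.05,
                                            n_common_up = 0, n_common_down = 0,
                                            n_discordant = 0))
  est <- attr(normalize_expression(sim$expr), "scale_factors")
  truth <- sim$truth$scale_factors[names(est)]
  rel <- (est / truth) / mean(est / truth)
  expect_true(all(abs(rel - 1) < 0.01))

  bad <- toy_expr(matrix(c(1, 1, 0, 0), 2, dimnames = list(c("a", "b"), c("x", "y"))))
  expect_error(normalize_expression(bad), "all-zero")
})

test_that("group ratios are geometric-mean ratios with singleton support", {
  m <- matrix(c(100, 50, 120, 60), nrow = 2,
              dimnames = list(c("a", "b"), c("pt1", "ane1")))
  annot <- tibble::tibble(sample = c("pt1", "ane1"), cell_line = "L1",
                          condition = c("parental", "exposed"))
  gr <- group_ratio(toy_expr(m), annot, "L1")
  expect_equal(gr$ratio, c(1.2, 1.2))
  expect_equal(gr$n_num, c(1L, 1L))

  # identical groups give exactly 1
  m2 <- cbind(m, pt2 = m[, 1], ane2 = m[, 1])
  annot2 <- tibble::tibble(
    sample = colnames(m2), cell_line = "L1",
    condition = c("parental", "exposed", "parental", "exposed")
  )
  m2[, "ane1"] <- m2[, "pt1"]
  gr2 <- group_ratio(toy_expr(m2), annot2, "L1")
  expect_equal(gr2$ratio, c(1, 1))

  expect_error(group_ratio(toy_expr(m), annot, "L9"), "L9")

  # planted 2.5x effect, sigma = 0.1, n = 3: estimate lands near truth.
  # the log-ratio sd is sqrt(2/3)*0.1, so [2.2, 2.8] captures ~86% of
  # draws; 200 replicates bound that coverage from below
  withr::with_seed(31, {
    hit <- replicate(200, {
      pt <- exp(log(200) + rnorm(3, 0, 0.1))
      ane <- exp(log(200 * 2.5) + rnorm(3, 0, 0.1))
      mm <- matrix(c(pt, ane), nrow = 1,
                   dimnames = list("x", c(paste0("p", 1:3), paste0("e", 1:3))))
      an <- tibble::tibble(sample = colnames(mm), cell_line = "L1",
                           condition = rep(c("parental", "exposed"), each = 3))
      r <- group_ratio(toy_expr(mm), an, "L1")$ratio
      r >= 2.2 && r <= 2.8
    })
    expect_gte(mean(hit), 0.8)
  })
})

test_that("dysregulation calls are inclusive at the threshold", {
  expect_identical(classify_dysregulation(c(1.2, 1 / 1.2, 1.0, 1.19, 0.84)),
                   c("up", "down", "none", "none", "none"))
  expect_error(classify_dysregulation(1.5, threshold = 1), "> 1")
  expect_error(classify_dysregulation(-1), "positive")
})

test_that("region assignment is the 3x3 grid minus center, a partition", {
  calls <- c("up", "down", "none")
  grid <- expand.grid(c1 = calls, c2 = calls, stringsAsFactors = FALSE)
  labels <- assign_region(grid$c1, grid$c2)
  # exactly 8 region labels, each used once, plus one center
  expect_setequal(labels, c(paste0("R", 1:8), "CENTER"))
  expect_equal(anyDuplicated(labels), 0)
  expect_identical(assign_region("up", "up"), "R2")
  expect_identical(assign_region("down", "down"), "R6")
  expect_identical(assign_region("none", "none"), "CENTER")
  # direction symmetry: flipping both calls mirrors the region pairing
  flip <- c(up = "down", down = "up", none = "none")
  mirrored <- assign_region(flip[grid$c1], flip[grid$c2])
  pairing <- c(R1 = "R5", R2 = "R6", R3 = "R7", R4 = "R8",
               R5 = "R1", R6 = "R2", R7 = "R3", R8 = "R4", CENTER = "CENTER")
  expect_identical(unname(pairing[labels]), mirrored)
  expect_error(assign_region("up", "sideways"), "calls")
})

test_that("a toy two-line panel matches hand-computed calls and identities", {
  # line1 ratios: 2 (up), 1/2 (down), 1 (none); line2: 2, 2, 1
  m <- matrix(c(
    100, 200, 100, 200, # mA: up in both
    100, 50, 100, 200,  # mB: down in L1, up in L2
    100, 100, 100, 100  # mC: flat
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("mA", "mB", "mC"),
                  c("L1_pt", "L1_ane", "L2_pt", "L2_ane")))
  annot <- tibble::tibble(
    sample = colnames(m),
    cell_line = rep(c("L1", "L2"), each = 2),
    condition = rep(c("parental", "exposed"), 2)
  )
  pan <- build_ane_panel(toy_expr(m), annot, normalize = FALSE)
  got <- tidy(pan)
  expect_equal(got$fc_L1, c(2, 0.5, 1))
  expect_equal(got$fc_L2, c(2, 2, 1))
  expect_identical(got$region, c("R2", "R4", "CENTER"))
  expect_setequal(pan$sets$common_up, "mA")
  expect_setequal(pan$sets$discordant, "mB")
  expect_error(build_ane_panel(toy_expr(m), annot, lines = "L1"), "2 cell lines")
})

test_that("region sets partition the miRNA universe on simulated data", {
  sim <- simulate_ane_experiment(sim_config(seed = 7))
  pan <- build_ane_panel(sim$expr, sim$annot)
  g <- glance(pan)
  expect_equal(
    g$n_up_any + g$n_down_any + g$n_discordant + g$n_center, g$n_mirnas
  )
  expect_setequal(unlist(pan$sets), pan$panel$mirna)
})

test_that("swapping exposure direction maps regions to their mirror images", {
  sim <- simulate_ane_experiment(sim_config(seed = 19, n_mirnas = 200))
  annot_sw <- sim$annot
  annot_sw$condition <- ifelse(annot_sw$condition == "parental", "exposed", "parental")
  pan <- build_ane_panel(sim$expr, sim$annot)
  pan_sw <- build_ane_panel(sim$expr, annot_sw)
  pairing <- c(R1 = "R5", R2 = "R6", R3 = "R7", R4 = "R8",
               R5 = "R1", R6 = "R2", R7 = "R3", R8 = "R4", CENTER = "CENTER")
  expect_identical(unname(pairing[pan$panel$region]), pan_sw$panel$region)
})

test_that("planted concordant effects are recovered at study noise levels", {
  sim <- simulate_ane_experiment(sim_config(seed = 3, noise_sigma = 0.05))
  pan <- build_ane_panel(sim$expr, sim$annot)
  expect_gte(length(intersect(pan$sets$common_up, sim$truth$planted_up)), 38)
  expect_gte(length(intersect(pan$sets$common_down, sim$truth$planted_down)), 38)

  # sensitivity at the published conditions (effect 2, sigma 0.1)
  sim2 <- simulate_ane_experiment(sim_config(seed = 4))
  pan2 <- build_ane_panel(sim2$expr, sim2$annot)
  recovered <- length(intersect(pan2$sets$up_any, sim2$truth$planted_up)) +
    length(intersect(pan2$sets$down_any, sim2$truth$planted_down))
  expect_gte(recovered / 80, 0.9)

  # an all-null experiment stays mostly in the center
  null_cfg <- sim_config(seed = 8, n_common_up = 0, n_common_down = 0,
                         n_discordant = 0)
  pan0 <- build_ane_panel(simulate_ane_experiment(null_cfg)$expr,
                          simulate_ane_experiment(null_cfg)$annot)
  expect_gt(length(pan0$sets$center), 0.8 * nrow(pan0$panel))
})
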