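test_that("single-sample rank enrichment is directional and rank-invariant", {
  v <- setNames(seq(200, 1), paste0("g", 1:200))
  top <- paste0("g", 1:20)
  bottom <- paste0("g", 181:200)
  expect_gt(ssgsea_score(v, top), 0)
  expect_lt(ssgsea_score(v, bottom), 0)
  # invariant to monotone transforms
  expect_equal(ssgsea_score(v, top), ssgsea_score(v^3 + 5, top))
  expect_equal(ssgsea_score(v, top), ssgsea_score(log(v), top))
  expect_error(ssgsea_score(v, paste0("g", 1:5)), "fewer than 10")
})

test_that("random gene sets score near zero on average", {
  v <- setNames(seq(300, 1), paste0("g", 1:300))
  withr::with_seed(13, {
    scores <- replicate(200, ssgsea_score(v, sample(names(v), 25)))
  })
  expect_lt(abs(mean(scores)), 2 * stats::sd(scores) / sqrt(200))
})

test_that("purity estimation is monotone and recovers mixtures on a grid", {
  # cohort spanning a contamination grid, admixture features planted
  grid <- seq(0.05, 1, length.out = 40)
  cfg <- sim_config(seed = 21, noise_sigma = 0.05)
  sc <- simulate_cohort(cfg, purity = grid)
  m <- as.matrix(sc$expr[-1])
  rownames(m) <- sc$expr$mirna
  tumors <- sc$annot$sample[sc$annot$tissue == "tumor"]
  normals <- sc$annot$sample[sc$annot$tissue == "normal"]
  scores <- admixture_scores(sc$expr, sc$truth$signatures)
  tsc <- scores$combined[match(tumors, scores$sample)]
  nsc <- scores$combined[match(normals, scores$sample)]
  # monotone: higher contamination -> higher combined score
  expect_gt(stats::cor(tsc, 1 - grid, method = "spearman"), 0.95)
  est <- estimate_purity(tsc, reference_score = mean(nsc))
  # monotone decreasing map score -> purity
  expect_true(all(diff(est[order(tsc)]) <= 1e-12))
  # the contamination-free sample is called nearly pure
  expect_gte(est[which.max(grid)], 0.95)
  # rank calibration on a cohort spanning the contamination range evenly
  # recovers the 50/50 mixture within 0.1
  est_rank <- estimate_purity(tsc, method = "rank")
  mid <- which.min(abs(grid - 0.5))
  expect_lt(abs(est_rank[mid] - 0.5), 0.1)
  expect_gte(est_rank[which.max(grid)], 0.95)
  expect_error(estimate_purity(tsc), "reference_score")
})

test_that("linear de-mixing inverts the mixture model exactly", {
  truth <- c(10, 4, 7)
  normal <- c(2, 8, 7)
  expect_equal(purity_adjust(truth, 1, normal), truth)
  obs <- 0.6 * truth + 0.4 * normal
  expect_equal(purity_adjust(obs, 0.6, normal), truth, tolerance = 1e-9)
  # matrix form with per-sample purity
  obs_m <- cbind(a = 0.3 * truth + 0.7 * normal, b = 0.9 * truth + 0.1 * normal)
  adj <- purity_adjust(obs_m, c(0.3, 0.9), normal)
  expect_equal(adj, cbind(a = truth, b = truth), tolerance = 1e-9)
  expect_error(purity_adjust(obs, 0, normal), "purity")

  # under noise, adjustment reduces error against tumor-intrinsic truth
  withr::with_seed(41, {
    base <- exp(rnorm(200, log(100), 1))
    tum <- base * exp(rnorm(200, 0, 0.3))
    improvements <- sapply(seq(0.3, 0.9, by = 0.2), function(p) {
      obs <- (p * tum + (1 - p) * base) * exp(rnorm(200, 0, 0.05))
      mae <- function(x) mean(abs(log(pmax(x, 1e-9)) - log(tum)))
      mae(obs) - mae(purity_adjust(obs, p, base))
    })
    expect_true(all(improvements > 0))
  })
})

test_that("unpaired t-test handles degenerate input and matches a hand oracle", {
  expect_equal(unpaired_t(c(3, 3, 3), c(3, 3, 3)), 1)
  expect_equal(unpaired_t(c(5, 5), c(9, 9)), 0)
  expect_error(unpaired_t(3, c(1, 2)), "at least 2")

  # textbook Welch case computed longhand from the statistic and df
  a <- c(5.1, 4.8, 6.0, 5.5, 5.2)
  b <- c(4.2, 4.9, 4.4, 4.1)
  la <- log2(a); lb <- log2(b)
  se2 <- stats::var(la) / 5 + stats::var(lb) / 4
  tt <- (mean(la) - mean(lb)) / sqrt(se2)
  df <- se2^2 / ((stats::var(la) / 5)^2 / 4 + (stats::var(lb) / 4)^2 / 3)
  expect_equal(unpaired_t(a, b), 2 * stats::pt(-abs(tt), df), tolerance = 1e-12)

  # Student variant pools the variance
  sp2 <- (4 * stats::var(la) + 3 * stats::var(lb)) / 7
  ts <- (mean(la) - mean(lb)) / sqrt(sp2 * (1 / 5 + 1 / 4))
  expect_equal(unpaired_t(a, b, variant = "student"),
               2 * stats::pt(-abs(ts), 7), tolerance = 1e-12)
})

test_that("null rejection rate sits near the nominal level", {
  withr::with_seed(17, {
    p <- replicate(500, unpaired_t(exp(rnorm(5, 5, 0.5)), exp(rnorm(5, 5, 0.5))))
  })
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("cohort screen recovers planted effects and partitions directions", {
  sc <- simulate_cohort(sim_config(seed = 2))
  cp <- build_cohort_panel(sc$expr, sc$annot)
  rec <- tidy(cp)
  expect_true(all(rec$direction[rec$selected] %in% c("over", "under")))
  expect_true(all(rec$direction[!rec$selected] == "none"))
  expect_equal(sum(rec$direction == "over") + sum(rec$direction == "under"),
               sum(rec$selected))
  mask <- unlist(sc$truth$signatures)
  metrics <- recovery_metrics(cp, sc$truth$planted_up, sc$truth$planted_down,
                              ignore = mask)
  expect_gte(metrics$sensitivity, 0.9)
  expect_lte(metrics$fdr, 0.1)
  expect_error(
    build_cohort_panel(sc$expr, dplyr::mutate(sc$annot, tissue = "tumor")),
    "normal"
  )
})

test_that("selection is monotone in its thresholds", {
  sc <- simulate_cohort(sim_config(seed = 9, cohort_n_mirnas = 150))
  sel <- function(fr, a) {
    cp <- build_cohort_panel(sc$expr, sc$annot, fr_threshold = fr, alpha = a)
    cp$records$mirna[cp$records$selected]
  }
  base <- sel(1.2, 0.05)
  expect_true(all(sel(1.5, 0.05) %in% base))
  expect_true(all(sel(1.2, 0.01) %in% base))
  expect_true(all(sel(2.0, 0.001) %in% sel(1.5, 0.01)))
})

test_that("purity calibration strictly improves recovery when dilution bites", {
  sens <- sapply(1:3, function(s) {
    cfg <- sim_config(seed = 300 + s, cohort_effect = c(1.3, 1.5, 2.0),
                      purity_shape = c(2, 2), admix_factor = 1)
    sc <- simulate_cohort(cfg)
    cal <- build_cohort_panel(sc$expr, sc$annot, calibrate = "supplied")
    unc <- build_cohort_panel(sc$expr, sc$annot, calibrate = "none")
    c(
      recovery_metrics(cal, sc$truth$planted_up, sc$truth$planted_down,
                       fdr_cap = 0.1)$sensitivity,
      recovery_metrics(unc, sc$truth$planted_up, sc$truth$planted_down,
                       fdr_cap = 0.1)$sensitivity
    )
  })
  expect_true(all(sens[1, ] > sens[2, ]))
})
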