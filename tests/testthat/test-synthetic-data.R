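test_that("generators are deterministic given the seed and need one", {
  cfg <- sim_config(seed = 81, n_mirnas = 60, cohort_n_mirnas = 120,
                    n_common_up = 8, n_common_down = 8, n_discordant = 2)
  expect_identical(simulate_ane_experiment(cfg), simulate_ane_experiment(cfg))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_identical(simulate_target_sources(cfg), simulate_target_sources(cfg))
  expect_identical(simulate_gmt(cfg, c("A", "B")), simulate_gmt(cfg, c("A", "B")))
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, effect = 0.5), "ratios >= 1")
})

test_that("noiseless paired experiments reproduce planted effects exactly", {
  cfg <- sim_config(seed = 82, noise_sigma = 0, chip_scale_sd = 0,
                    n_mirnas = 80, n_common_up = 10, n_common_down = 10,
                    n_discordant = 4)
  sim <- simulate_ane_experiment(cfg)
  pan <- build_ane_panel(sim$expr, sim$annot, normalize = FALSE)
  got <- setNames(pan$panel$fc_L1, pan$panel$mirna)
  conc <- setdiff(names(sim$truth$effect_sizes), sim$truth$planted_discordant)
  expect_equal(got[conc], sim$truth$effect_sizes[conc], tolerance = 1e-9)
  # discordant miRNAs flip direction between lines
  got2 <- setNames(pan$panel$fc_L2, pan$panel$mirna)
  disc <- sim$truth$planted_discordant
  expect_equal(got2[disc], 1 / got[disc], tolerance = 1e-9)
  expect_setequal(pan$sets$discordant, disc)
})

test_that("cohort mixtures dilute effects by the purity-weighted average", {
  # planted effect 2 at purity 0.5 measures ~1.5 uncalibrated
  cfg <- sim_config(seed = 83, noise_sigma = 0.02, n_tumor = 30)
  sc <- simulate_cohort(cfg, purity = rep(0.5, 30))
  unc <- build_cohort_panel(sc$expr, sc$annot, calibrate = "none")
  fr <- setNames(unc$records$tn_fr, unc$records$mirna)
  expect_equal(unname(mean(fr[sc$truth$planted_up])), 1.5, tolerance = 0.05)
  # purity 1 for all: observed is tumor-intrinsic plus noise only
  sc1 <- simulate_cohort(cfg, purity = rep(1, 30))
  m <- as.matrix(sc1$expr[-1])
  expected <- sc1$truth$tumor_intrinsic
  expect_lt(stats::sd(log(m[, 1]) - log(expected)), 0.03)
})

test_that("generator marginals match their configured distributions", {
  cfg <- sim_config(seed = 84, n_mirnas = 1000, replicates = 2,
                    n_common_up = 0, n_common_down = 0, n_discordant = 0)
  sim <- simulate_ane_experiment(cfg)
  m <- as.matrix(sim$expr[-1])
  # pooled replicate log-sd estimates noise sigma within 5%
  same_group <- log(m[, "L1_parental_1"]) - log(m[, "L1_parental_2"])
  expect_lt(abs(stats::sd(same_group) / sqrt(2) - 0.1), 0.005)

  cfgc <- sim_config(seed = 85, n_tumor = 400)
  sc <- simulate_cohort(cfgc)
  expect_lt(abs(mean(sc$truth$purity) - 0.8), 0.05)
})

test_that("planted source tables separate core and noise by vote count", {
  sim <- simulate_target_sources(sim_config(seed = 86))
  expect_true(all(sim$truth$core_edges$votes >= 4))
  expect_true(all(sim$truth$noise_edges$votes <= 3))
  # votes recorded in truth equal distinct sources in the tables
  a <- load_target_sources(sim$assertions)
  counts <- dplyr::count(a, mirna, gene)
  core_key <- paste(sim$truth$core_edges$mirna, sim$truth$core_edges$gene)
  expect_setequal(
    paste(counts$mirna, counts$gene)[counts$n >= 4], core_key
  )
  # zero noise: consensus equals the core exactly
  sim0 <- simulate_target_sources(sim_config(seed = 87, n_noise_edges = 0))
  got <- consensus_vote(load_target_sources(sim0$assertions),
                        sim0$truth$mirnas, 4)
  expect_equal(nrow(got), nrow(sim0$truth$core_edges))
})

test_that("simulated GMT collections round-trip and carry the planted pathway", {
  cfg <- sim_config(seed = 88, n_pathways = 6, pathway_size = 12)
  gmt <- simulate_gmt(cfg, sprintf("QG%02d", 1:20))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gmt$pathways, f)
  back <- read_gmt(f)
  expect_identical(back, gmt$pathways)
  expect_true(gmt$truth$enriched_pathway %in% names(gmt$pathways))
  expect_true(all(lengths(gmt$pathways) == 12))

  # at odds ratio 1 the planted pathway is not preferentially enriched:
  # its p beats every decoy only about as often as chance allows
  withr::with_seed(89, {
    wins <- replicate(40, {
      g <- simulate_gmt(sim_config(seed = sample.int(1e6, 1), odds_ratio = 1,
                                   n_pathways = 10),
                        sprintf("QG%02d", 1:40))
      ora <- run_ora(sprintf("QG%02d", 1:40), g$pathways, universe = g$universe)
      rec <- ora$records
      p_planted <- rec$p[rec$pathway == "planted_pathway"]
      length(p_planted) == 1 && all(p_planted < rec$p[rec$pathway != "planted_pathway"])
    })
    expect_lt(mean(wins), 0.3)
  })
})
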