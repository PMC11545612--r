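#' Simulation configuration
#'
#' One configuration object drives all generators. Defaults are the desk
#' scale the package is tested at: a paired two-line exposure experiment
#' with 500 miRNAs, 3 replicate chips per condition, log-scale noise sigma
#' 0.1, multiplicative effect 2.0, 40 planted common-up / 40 common-down /
#' 10 discordant miRNAs; a cohort of 40 tumors vs 10 normals (preserving
#' the ~10:1 imbalance of the clinical cohort it emulates) with 30 up / 30
#' down planted effects, purity drawn from Beta(8, 2) and 25 + 25
#' stromal/immune admixture-signature features; 11 target sources (3
#' validated, 8 predicted) with a 40-edge consensus core and 60 per-source
#' noise edges; a 20-pathway GMT with one planted enriched pathway.
#'
#' @param seed Integer seed (required; every generator is deterministic
#'   given the config).
#' @param n_mirnas,lines,replicates,noise_sigma,effect,n_common_up,n_common_down,n_discordant
#'   Paired-exposure experiment parameters; `chip_scale_sd` is the
#'   log-scale spread of random per-chip scale factors. `effect` (like
#'   `cohort_effect`) may be a vector: an effect grid recycled over the
#'   planted features. Effects are ratios >= 1; direction is encoded by
#'   the planted set.
#' @param cohort_n_mirnas,n_tumor,n_normal,cohort_up,cohort_down,cohort_effect,purity_shape,n_signature_features,admix_factor
#'   Cohort parameters; `purity_shape` are Beta shape parameters,
#'   `admix_factor` the fold-elevation of signature features in the
#'   non-malignant profile.
#' @param n_sources,n_validated,n_core_edges,n_noise_edges,min_votes,n_query_mirnas,n_genes
#'   Target-source parameters.
#' @param universe_size,n_pathways,pathway_size,odds_ratio GMT parameters;
#'   `odds_ratio` is the selection weight of query genes in the planted
#'   pathway (1 = null).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_mirnas = 500, lines = c("L1", "L2"), replicates = 3,
                       noise_sigma = 0.1, effect = 2.0, chip_scale_sd = 0.2,
                       n_common_up = 40, n_common_down = 40, n_discordant = 10,
                       cohort_n_mirnas = 300, n_tumor = 40, n_normal = 10,
                       cohort_up = 30, cohort_down = 30, cohort_effect = 2.0,
                       purity_shape = c(8, 2), n_signature_features = 25,
                       admix_factor = 6,
                       n_sources = 11, n_validated = 3, n_core_edges = 40,
                       n_noise_edges = 60, min_votes = 4,
                       n_query_mirnas = 8, n_genes = 300,
                       universe_size = 2000, n_pathways = 20,
                       pathway_size = 50, odds_ratio = 8) {
  if (missing(seed)) abort("a seed is required")
  cfg <- as.list(environment())
  stopifnot(
    n_mirnas >= 1, replicates >= 1, noise_sigma >= 0, length(lines) >= 2,
    n_tumor >= 2, n_normal >= 2, all(purity_shape > 0),
    n_sources >= min_votes, min_votes >= 1
  )
  if (any(c(effect, cohort_effect) < 1)) {
    abort("effects are ratios >= 1; direction is encoded separately")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a paired-exposure microarray experiment
#'
#' Log-normal baseline intensities per miRNA; exposed-condition samples of
#' planted miRNAs are multiplied by the configured effect (shared direction
#' across lines for concordant miRNAs, opposite directions for discordant
#' ones: up in the first line, down in the second). Each sample also
#' receives a random per-chip scale factor, which median normalization is
#' expected to remove.
#'
#' @param cfg A [sim_config()].
#' @return list(expr, annot, truth); truth holds planted_up, planted_down,
#'   planted_discordant, effect_sizes (mirna -> signed ratio, down as 1/e),
#'   and scale_factors.
#' @export
simulate_ane_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_planted <- cfg$n_common_up + cfg$n_common_down + cfg$n_discordant
  if (n_planted > cfg$n_mirnas) abort("more planted miRNAs than miRNAs")
  withr::with_seed(cfg$seed, {
    ids <- sprintf("mir-%04d", seq_len(cfg$n_mirnas))
    planted <- sample(ids, n_planted)
    up <- planted[seq_len(cfg$n_common_up)]
    down <- planted[cfg$n_common_up + seq_len(cfg$n_common_down)]
    disc <- planted[cfg$n_common_up + cfg$n_common_down + seq_len(cfg$n_discordant)]

    baseline <- exp(rnorm(cfg$n_mirnas, log(500), 1))
    names(baseline) <- ids
    eff_up <- rep(cfg$effect, length.out = length(up))
    eff_down <- rep(cfg$effect, length.out = length(down))
    eff_disc <- rep(cfg$effect, length.out = length(disc))
    effect_for <- function(line_index) {
      e <- rep(1, cfg$n_mirnas)
      names(e) <- ids
      e[up] <- eff_up
      e[down] <- 1 / eff_down
      e[disc] <- if (line_index == 1) eff_disc else 1 / eff_disc
      e
    }

    samples <- tidyr::expand_grid(
      cell_line = cfg$lines, condition = c("parental", "exposed"),
      rep = seq_len(cfg$replicates)
    ) |>
      mutate(sample = paste(.data$cell_line, .data$condition, .data$rep, sep = "_"))
    scale_factors <- setNames(exp(rnorm(nrow(samples), 0, cfg$chip_scale_sd)),
                              samples$sample)

    m <- vapply(seq_len(nrow(samples)), function(j) {
      li <- match(samples$cell_line[j], cfg$lines)
      eff <- if (samples$condition[j] == "exposed") effect_for(li) else rep(1, cfg$n_mirnas)
      baseline * eff * exp(rnorm(cfg$n_mirnas, 0, cfg$noise_sigma)) *
        scale_factors[j]
    }, numeric(cfg$n_mirnas))
    colnames(m) <- samples$sample
    rownames(m) <- ids

    effects <- setNames(rep(1, cfg$n_mirnas), ids)
    effects[up] <- eff_up
    effects[down] <- 1 / eff_down

    list(
      expr = matrix_to_expr(m),
      annot = samples |> select("sample", "cell_line", "condition"),
      truth = list(
        planted_up = up, planted_down = down, planted_discordant = disc,
        effect_sizes = effects, scale_factors = scale_factors
      )
    )
  })
}

#' Simulate a tumor/normal cohort with purity admixture
#'
#' Per-feature log-normal baseline; the tumor-intrinsic profile multiplies
#' planted features by the configured effect (up) or its reciprocal (down);
#' the non-malignant (normal) profile elevates the stromal/immune signature
#' features by `admix_factor`. Each observed tumor sample is the linear
#' mixture purity * tumor-intrinsic + (1 - purity) * normal profile with
#' multiplicative log-normal noise; purity is drawn from
#' Beta(`purity_shape`). Signature features are never planted as
#' differential truth — they are the composition confound that purity
#' calibration is meant to remove.
#'
#' @param cfg A [sim_config()].
#' @param purity Optional numeric vector overriding the Beta draw (length
#'   `n_tumor`), e.g. a fixed contamination grid.
#' @param planted Optional list(up=, down=) of feature identifiers
#'   overriding the random choice of planted features (must avoid the
#'   signature features), e.g. to align cohort effects with a paired
#'   exposure experiment on the same feature universe.
#' @return list(expr, annot, truth); annot carries the true purity per
#'   tumor sample; truth holds cohort_de (mirna -> signed ratio), purity,
#'   signatures (stromal/immune feature ids), normal_profile,
#'   tumor_intrinsic.
#' @export
simulate_cohort <- function(cfg, purity = NULL, planted = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$cohort_n_mirnas
  n_sig <- 2 * cfg$n_signature_features
  if (cfg$cohort_up + cfg$cohort_down + n_sig > n) {
    abort("planted + signature features exceed feature count")
  }
  withr::with_seed(cfg$seed, {
    ids <- sprintf("mir-%04d", seq_len(n))
    stromal <- ids[seq_len(cfg$n_signature_features)]
    immune <- ids[cfg$n_signature_features + seq_len(cfg$n_signature_features)]
    de_pool <- setdiff(ids, c(stromal, immune))
    if (is.null(planted)) {
      de <- sample(de_pool, cfg$cohort_up + cfg$cohort_down)
      up <- de[seq_len(cfg$cohort_up)]
      down <- de[cfg$cohort_up + seq_len(cfg$cohort_down)]
    } else {
      up <- planted$up
      down <- planted$down
      if (!all(c(up, down) %in% de_pool)) {
        abort("planted features must be non-signature features of the cohort universe")
      }
      de <- c(up, down)
    }

    baseline <- setNames(exp(rnorm(n, log(500), 1)), ids)
    normal_prof <- baseline
    normal_prof[c(stromal, immune)] <- normal_prof[c(stromal, immune)] * cfg$admix_factor
    effects <- setNames(rep(1, n), ids)
    effects[up] <- rep(cfg$cohort_effect, length.out = length(up))
    effects[down] <- 1 / rep(cfg$cohort_effect, length.out = length(down))
    tumor_int <- baseline * effects

    if (is.null(purity)) {
      purity <- rbeta(cfg$n_tumor, cfg$purity_shape[1], cfg$purity_shape[2])
      purity <- pmin(pmax(purity, 0.05), 1)
    }
    stopifnot(length(purity) == cfg$n_tumor, all(purity > 0), all(purity <= 1))

    tumor_names <- sprintf("tumor_%03d", seq_len(cfg$n_tumor))
    normal_names <- sprintf("normal_%03d", seq_len(cfg$n_normal))
    noise <- function() exp(rnorm(n, 0, cfg$noise_sigma))
    tumor_m <- vapply(seq_len(cfg$n_tumor), function(j) {
      (purity[j] * tumor_int + (1 - purity[j]) * normal_prof) * noise()
    }, numeric(n))
    normal_m <- vapply(seq_len(cfg$n_normal), function(j) {
      normal_prof * noise()
    }, numeric(n))
    m <- cbind(tumor_m, normal_m)
    rownames(m) <- ids
    colnames(m) <- c(tumor_names, normal_names)

    list(
      expr = matrix_to_expr(m),
      annot = tibble(
        sample = colnames(m),
        tissue = rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal)),
        purity = c(purity, rep(NA_real_, cfg$n_normal))
      ),
      truth = list(
        cohort_de = effects[de], planted_up = up, planted_down = down,
        purity = setNames(purity, tumor_names),
        signatures = list(stromal = stromal, immune = immune),
        normal_profile = normal_prof, tumor_intrinsic = tumor_int
      )
    )
  })
}

#' Simulate multi-source miRNA-target assertion tables
#'
#' A consensus core of miRNA-gene links is planted in at least `min_votes`
#' randomly chosen sources each; noise links appear in at most
#' `min_votes - 1` sources. The first `n_validated` sources carry the
#' "validated" evidence tag, the rest "predicted".
#'
#' @param cfg A [sim_config()].
#' @return list(assertions, truth); truth holds core_edges / noise_edges
#'   tibbles (mirna, gene, votes) and the query miRNA ids.
#' @export
simulate_target_sources <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    mirnas <- sprintf("miR-q%02d", seq_len(cfg$n_query_mirnas))
    genes <- sprintf("GENE%03d", seq_len(cfg$n_genes))
    sources <- sprintf("db%02d", seq_len(cfg$n_sources))
    validated <- sources[seq_len(cfg$n_validated)]

    n_pairs <- cfg$n_core_edges + cfg$n_noise_edges
    all_pairs <- tidyr::expand_grid(mirna = mirnas, gene = genes)
    pairs <- all_pairs[sample(nrow(all_pairs), n_pairs), ]
    core <- pairs[seq_len(cfg$n_core_edges), ]
    noise <- pairs[cfg$n_core_edges + seq_len(cfg$n_noise_edges), ]
    core$votes <- sample(cfg$min_votes:cfg$n_sources, nrow(core), replace = TRUE)
    noise$votes <- sample(seq_len(cfg$min_votes - 1), nrow(noise), replace = TRUE)

    assert_rows <- bind_rows(core, noise) |>
      mutate(in_sources = map(.data$votes, ~ sample(sources, .x))) |>
      tidyr::unnest("in_sources") |>
      transmute(
        source = .data$in_sources, mirna = .data$mirna, gene = .data$gene,
        evidence = ifelse(.data$in_sources %in% validated, "validated", "predicted")
      ) |>
      arrange(.data$source, .data$mirna, .data$gene)

    list(
      assertions = assert_rows,
      truth = list(core_edges = core, noise_edges = noise, mirnas = mirnas,
                   sources = sources, validated_sources = validated)
    )
  })
}

#' Simulate a GMT collection with one planted enriched pathway
#'
#' Decoy pathways draw genes uniformly from the universe; the planted
#' pathway draws with selection weight `odds_ratio` on the query genes
#' (weight 1 elsewhere), so `odds_ratio = 1` reduces to a decoy.
#'
#' @param cfg A [sim_config()].
#' @param query_genes Character vector of query genes (added to the
#'   universe if absent).
#' @return list(pathways, universe, truth); truth names the enriched
#'   pathway.
#' @export
simulate_gmt <- function(cfg, query_genes) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    universe <- unique(c(query_genes,
                         sprintf("UG%05d", seq_len(cfg$universe_size))))
    w <- ifelse(universe %in% query_genes, cfg$odds_ratio, 1)
    planted <- sample(universe, cfg$pathway_size, prob = w)
    decoys <- map(seq_len(cfg$n_pathways - 1), function(i) {
      sample(universe, cfg$pathway_size)
    })
    names(decoys) <- sprintf("decoy_%02d", seq_along(decoys))
    pathways <- c(list(planted_pathway = planted), decoys)
    list(
      pathways = pathways, universe = universe,
      truth = list(enriched_pathway = "planted_pathway",
                   odds_ratio = cfg$odds_ratio)
    )
  })
}
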