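#' Experiment configuration
#'
#' Bundles the genome, historical-phase, breeding, trait, scenario and model
#' settings of a full simulation experiment.  The defaults reproduce the
#' full-scale study design: 18 chromosomes of 100 cM with 3100 markers and 50
#' QTLs each, 300 historical generations from 200 + 200 founders, a base
#' population of 30 boars and 200 sows, 8 recent generations of 30 sires by
#' 300 dams with litter sizes 10/12/14/16/18 (probabilities
#' 0.02/0.14/0.68/0.14/0.02), 20 percent mortality, analysis data from
#' generations 5-8 with generation 8 as validation, and 40 replicates.
#' Running that design takes hours per replicate and several gigabytes; use
#' [scale_config()] for desk-scale work.
#'
#' @param trait trait preset name (`"T_4/4"`, `"T_2/4"`, `"T_2/2"`) or a
#'   [trait_architecture()].
#' @param scenarios genotyping scenarios, subset of
#'   `c("G_all", "G80_ran", "G_alive", "G_none")`.
#' @param models subset of `c("LM", "LG", "PM")` (identity, logit, probit).
#' @param n_replicates number of simulation replicates (default 40).
#' @param seed master seed; per-replicate sub-seeds are derived from it.
#' @param genome,history,base,breeding component settings, see
#'   [sim_marker_map()], [history_config()], [found_base_population()],
#'   [breeding_config()].
#' @param mortality truncation mortality rate.
#' @param omega blending weight for the genomic matrix (0.2).
#' @param reference_generations,validation_generation the validation split;
#'   their union is the analysis data (phenotypes entering REML and the
#'   whole-data fits).
#' @param keep_bundles keep per-replicate populations and fits in the result
#'   (memory heavy; default FALSE).
#' @param log_file optional JSON-lines log path for stage timings and seeds.
#' @return A list of class `pig_config`.
#' @export
experiment_config <- function(trait = "T_4/4",
                              scenarios = c("G_all", "G80_ran", "G_alive",
                                            "G_none"),
                              models = c("LM", "LG", "PM"),
                              n_replicates = 40, seed = 1,
                              genome = list(n_chr = 18, markers_per_chr = 3100,
                                            qtl_per_chr = 50,
                                            chr_length_cm = 100),
                              history = history_config(),
                              base = list(n_boars = 30, n_sows = 200),
                              breeding = breeding_config(),
                              mortality = 0.20, omega = 0.2,
                              reference_generations = 5:7,
                              validation_generation = 8,
                              keep_bundles = FALSE, log_file = NULL) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  models <- match.arg(models, several.ok = TRUE)
  assert_that(is_count(n_replicates), "n_replicates must be >= 1")
  arch <- if (inherits(trait, "trait_arch")) trait else trait_preset(trait)
  trait_label <- if (is.character(trait)) trait else
    sprintf("T_%g/%g", 100 * arch$h2_direct, 100 * arch$h2_maternal)
  assert_that(max(reference_generations) < validation_generation,
              "reference generations must precede the validation generation")
  assert_that(validation_generation <= breeding$n_generations,
              "validation generation beyond the simulated generations")
  structure(list(
    trait = trait_label, arch = arch, scenarios = scenarios, models = models,
    n_replicates = n_replicates, seed = seed, genome = genome,
    history = history, base = base, breeding = breeding,
    mortality = mortality, omega = omega,
    reference_generations = reference_generations,
    validation_generation = validation_generation,
    analysis_generations = sort(c(reference_generations,
                                  validation_generation)),
    keep_bundles = keep_bundles, log_file = log_file
  ), class = "pig_config")
}

#' Proportionally scaled-down experiment configuration
#'
#' Shrinks chromosomes, marker counts, population sizes and historical
#' generations by a common factor for desk-scale runs, with floors so the
#' design stays well formed (at least 1 chromosome, 2 QTLs, 2 sires...).
#' `scale = 1` reproduces the full design.
#'
#' @param scale factor in (0, 1].
#' @param n_generations recent generations (default 8; the validation split
#'   is the last generation against the three before it).
#' @param ... passed to [experiment_config()].
#' @return A `pig_config`.
#' @export
scale_config <- function(scale = 1, n_generations = 8, ...) {
  assert_that(scale > 0 && scale <= 1, "scale must be in (0, 1]")
  sc <- function(x, lo) max(lo, round(x * scale))
  n_sires <- sc(30, 2)
  ref_gens <- seq(n_generations - 3, n_generations - 1)
  experiment_config(
    genome = list(n_chr = sc(18, 1), markers_per_chr = sc(3100, 20),
                  qtl_per_chr = sc(50, 5), chr_length_cm = 100),
    history = history_config(n_founder_males = sc(200, 10),
                             n_founder_females = sc(200, 10),
                             n_historical_generations = sc(300, 10)),
    base = list(n_boars = sc(30, 2), n_sows = sc(200, 8)),
    breeding = breeding_config(n_sires = n_sires,
                               dams_per_sire = sc(10, 2),
                               n_generations = n_generations),
    reference_generations = ref_gens,
    validation_generation = n_generations,
    ...
  )
}

#' Assign a genotyping scenario mask
#'
#' Returns the ids of genotyped animals among the recent offspring
#' generations (the base population is never genotyped): `G_all` genotypes
#' everyone, `G80_ran` a uniform random 80 percent, `G_alive` exactly the
#' alive animals (80 percent by construction of the mortality truncation),
#' and `G_none` nobody.
#'
#' @param pedigree pedigree tibble with `generation` and `alive`.
#' @param scenario one of `"G_all"`, `"G80_ran"`, `"G_alive"`, `"G_none"`.
#' @param seed optional seed (used by `G80_ran`).
#' @return Integer vector of genotyped ids.
#' @export
apply_genotyping_scenario <- function(pedigree,
                                      scenario = c("G_all", "G80_ran",
                                                   "G_alive", "G_none"),
                                      seed = NULL) {
  scenario <- match.arg(scenario)
  set_seed_if(seed)
  off <- pedigree[pedigree$generation > 0L, ]
  switch(scenario,
    G_all = off$id,
    G80_ran = sort(sample(off$id, round(0.8 * nrow(off)))),
    G_alive = {
      assert_that(!anyNA(off$alive), "alive flags required for G_alive")
      off$id[off$alive == 1L]
    },
    G_none = integer(0)
  )
}

#' Simulate one replicate population with phenotypes
#'
#' Runs the historical phase, founds the base population, samples and
#' calibrates QTL effects on the base cohort, then breeds the recent
#' generations; each new generation receives liabilities (own direct TBV +
#' dam's maternal TBV + litter effect + residual), survival is scored by
#' truncation at the mortality rate, and the survivors form the parent pool
#' of the next generation.
#'
#' @param cfg a `pig_config`.
#' @param seed replicate seed.
#' @return List of class `pig_replicate`: `pop` (a `pig_pop` with `alive`
#'   filled), `phenotypes` (tibble incl. TBVs, liabilities, `y`), `tbv`
#'   (all animals), `effects`, `history_summary`.
#' @export
simulate_replicate <- function(cfg, seed = NULL) {
  set_seed_if(seed)
  map <- sim_marker_map(cfg$genome$n_chr, cfg$genome$markers_per_chr,
                        cfg$genome$qtl_per_chr, cfg$genome$chr_length_cm)
  hist <- simulate_history(map, cfg$history)
  pop <- found_base_population(hist, cfg$base$n_boars, cfg$base$n_sows)
  qtl_idx <- which(map$class == "qtl")

  effects <- sample_qtl_effects(length(qtl_idx), cfg$arch)
  base_dos <- dosage_matrix(pop, loci = qtl_idx)
  effects <- calibrate_qtl_effects(effects, base_dos, cfg$arch)
  tbv <- compute_tbv(base_dos, effects)

  phenos <- list()
  for (g in seq_len(cfg$breeding$n_generations)) {
    pop <- breed_generation(pop, cfg$breeding)
    new_ids <- pop$pedigree$id[pop$pedigree$generation == g]
    new_dos <- dosage_matrix(pop, loci = qtl_idx, ids = new_ids)
    tbv <- dplyr::bind_rows(tbv, compute_tbv(new_dos, effects))
    ph <- simulate_liability(pop$pedigree, tbv, cfg$arch, generations = g)
    ph <- threshold_survival(ph, cfg$mortality)
    pop$pedigree$alive[match(ph$id, pop$pedigree$id)] <- ph$y
    phenos[[g]] <- ph
  }
  structure(list(pop = pop, phenotypes = dplyr::bind_rows(phenos), tbv = tbv,
                 effects = effects, history_summary = hist$summary),
            class = "pig_replicate")
}

#' Run one full replicate of the experiment
#'
#' Simulates a population, estimates variance components per model from the
#' pedigree-based fit on the analysis generations, builds the per-scenario
#' relationship matrices, predicts breeding values from reference-generation
#' phenotypes, computes whole-data EBVs under the all-genotyped scenario for
#' the dispersion criterion, and scores accuracy, dispersion slopes and
#' selection differentials on the validation generation.  Variance
#' components from the pedigree-based fits are reused in all genotyping
#' scenarios.
#'
#' @param cfg a `pig_config`.
#' @param seed replicate seed.
#' @param replicate replicate index recorded in the output rows.
#' @return List with `results` (tidy tibble: replicate, trait, scenario,
#'   model, metric, effect, value), `varcomps` (tibble of REML estimates per
#'   model), `seed`, and optionally `bundle`.
#' @export
run_replicate <- function(cfg, seed = NULL, replicate = 1L) {
  rep_seed <- seed %||% derive_seed(cfg$seed, replicate)
  bundle <- simulate_replicate(cfg, rep_seed)
  ped <- bundle$pop$pedigree
  pheno_all <- bundle$phenotypes[bundle$phenotypes$generation %in%
                                   cfg$analysis_generations, ]
  pheno_ref <- pheno_all[pheno_all$generation %in%
                           cfg$reference_generations, ]
  val_ids <- ped$id[ped$generation == cfg$validation_generation]
  model_links <- c(LM = "identity", LG = "logit", PM = "probit")

  # pedigree-based variance components per model (the protocol: these are
  # reused for EBV prediction in every genotyped scenario).  The observed-
  # scale fit is always run first: its estimates, mapped through the
  # threshold transform, start the link-scale REMLs, whose restricted
  # likelihood is nearly flat in the maternal/litter direction at moderate
  # data sizes
  A <- build_A(ped)
  Ainv <- build_A_inverse(ped, F = diag(A) - 1)
  vc_lm <- estimate_varcomps_aireml(pheno_all, ped, link = "identity",
                                    K = A, Kinv = Ainv)
  vcs <- lapply(cfg$models, function(mod) {
    link <- model_links[[mod]]
    if (link == "identity") return(vc_lm)
    estimate_varcomps_aireml(pheno_all, ped, link = link, K = A, Kinv = Ainv,
                             start = link_scale_start(vc_lm, link,
                                                      1 - cfg$mortality))
  })
  names(vcs) <- cfg$models

  marker_dos <- NULL
  need_geno <- any(cfg$scenarios != "G_none")
  if (need_geno)
    marker_dos <- dosage_matrix(bundle$pop, loci = "marker",
                                ids = ped$id[ped$generation > 0L])

  # whole-data EBV (all phenotypes, everyone genotyped) per model, for the
  # dispersion regression; with only G_none requested the whole-data fit is
  # pedigree-based
  kin_all <- if (need_geno)
    scenario_kinship_cached(ped, marker_dos,
                            apply_genotyping_scenario(ped, "G_all"),
                            cfg$omega, A = A, Ainv = Ainv)
  else list(Kinv = Ainv, kind = "A", genotyped_ids = character(0), A = A)
  whole_fits <- lapply(cfg$models, function(mod) {
    fit_survival_model(pheno_all, ped, vcs[[mod]],
                       link = model_links[[mod]], Kinv = kin_all$Kinv)
  })
  names(whole_fits) <- cfg$models

  rows <- list()
  vc_rows <- list()
  for (mod in cfg$models) {
    h2 <- vcs[[mod]]$h2
    vc_rows[[mod]] <- tibble::tibble(
      replicate = replicate, trait = cfg$trait, model = mod,
      component = c(names(vcs[[mod]]$estimates), names(h2)),
      value = c(unname(vcs[[mod]]$estimates), unname(h2)),
      se = c(unname(vcs[[mod]]$se), rep(NA_real_, length(h2)))
    )
  }

  for (scen in cfg$scenarios) {
    gids <- apply_genotyping_scenario(ped, scen,
                                      seed = derive_seed(rep_seed, 777))
    kin <- if (scen == "G_all") kin_all else
      scenario_kinship_cached(ped, marker_dos, gids, cfg$omega, A = A,
                              Ainv = Ainv)
    for (mod in cfg$models) {
      fit_ref <- fit_survival_model(pheno_ref, ped, vcs[[mod]],
                                    link = model_links[[mod]],
                                    Kinv = kin$Kinv)
      acc <- prediction_accuracy(fit_ref$ebv, bundle$tbv, ids = val_ids)
      ew <- whole_fits[[mod]]$ebv[match(val_ids, whole_fits[[mod]]$ebv$id), ]
      er <- fit_ref$ebv[match(val_ids, fit_ref$ebv$id), ]
      slopes <- tibble::tibble(
        effect = c("a", "m", "total"),
        value = c(dispersion_slope(ew$ebv_a, er$ebv_a),
                  dispersion_slope(ew$ebv_m, er$ebv_m),
                  dispersion_slope(ew$ebv_total, er$ebv_total))
      )
      top1 <- selection_differential(fit_ref$ebv, bundle$tbv, 0.01, val_ids)
      top30 <- selection_differential(fit_ref$ebv, bundle$tbv, 0.30, val_ids)
      geno_val <- val_ids %in% as.integer(kin$genotyped_ids)
      acc_split <- list()
      if (any(geno_val) && any(!geno_val) && sum(geno_val) >= 3 &&
          sum(!geno_val) >= 3) {
        acc_split <- list(
          dplyr::mutate(prediction_accuracy(fit_ref$ebv, bundle$tbv,
                                            val_ids[geno_val]),
                        metric = "accuracy_genotyped"),
          dplyr::mutate(prediction_accuracy(fit_ref$ebv, bundle$tbv,
                                            val_ids[!geno_val]),
                        metric = "accuracy_nongenotyped")
        )
      }
      cell <- dplyr::bind_rows(
        dplyr::mutate(acc, metric = "accuracy", value = .data$accuracy,
                      accuracy = NULL),
        dplyr::mutate(slopes, metric = "slope"),
        dplyr::mutate(top1, metric = "top1_tbv", value = .data$mean_tbv,
                      mean_tbv = NULL),
        dplyr::mutate(top30, metric = "top30_tbv", value = .data$mean_tbv,
                      mean_tbv = NULL),
        dplyr::bind_rows(acc_split) |>
          (\(d) if (nrow(d)) dplyr::mutate(d, value = .data$accuracy,
                                           accuracy = NULL) else d)()
      )
      cell$replicate <- replicate
      cell$trait <- cfg$trait
      cell$scenario <- scen
      cell$model <- mod
      rows[[paste(scen, mod)]] <- cell
    }
  }
  results <- dplyr::bind_rows(rows)[, c("replicate", "trait", "scenario",
                                        "model", "metric", "effect", "value")]
  out <- list(results = results, varcomps = dplyr::bind_rows(vc_rows),
              seed = rep_seed)
  if (isTRUE(cfg$keep_bundles)) out$bundle <- bundle
  out
}

# kinship wrapper reusing precomputed A / Ainv
scenario_kinship_cached <- function(ped, marker_dos, gids, omega, A, Ainv) {
  g <- as.character(gids)
  if (length(g) == 0L)
    return(list(Kinv = Ainv, kind = "A", genotyped_ids = character(0), A = A))
  G <- build_G(marker_dos[g, , drop = FALSE])
  A11 <- A[g, g, drop = FALSE]
  Gw <- blend_G(adjust_G(G, A11), A11, omega)
  Hinv <- build_H_inverse(Ainv, Gw, A, g)
  list(Kinv = Hinv, kind = "H", genotyped_ids = g, A = A, Gomega = Gw,
       A11 = A11)
}

#' Run the full multi-replicate experiment
#'
#' @param cfg a `pig_config`.
#' @return Object of class `pig_experiment`: list with `results` (tidy tibble
#'   over all replicates), `varcomps`, `config`, `seeds`.
#' @export
run_experiment <- function(cfg) {
  assert_that(inherits(cfg, "pig_config"), "cfg must be a pig_config")
  reps <- purrr::map(seq_len(cfg$n_replicates), function(r) {
    t0 <- Sys.time()
    res <- run_replicate(cfg, replicate = r)
    log_stage(cfg$log_file, stage = "replicate", replicate = r,
              seed = res$seed,
              elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  })
  structure(list(
    results = dplyr::bind_rows(purrr::map(reps, "results")),
    varcomps = dplyr::bind_rows(purrr::map(reps, "varcomps")),
    seeds = purrr::map_int(reps, ~ as.integer(.x$seed)),
    bundles = if (isTRUE(cfg$keep_bundles)) purrr::map(reps, "bundle"),
    config = cfg
  ), class = "pig_experiment")
}

log_stage <- function(path, ...) {
  if (is.null(path)) return(invisible(NULL))
  line <- jsonlite::toJSON(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                ...),
                           auto_unbox = TRUE)
  cat(line, "\n", file = path, append = TRUE, sep = "")
  invisible(NULL)
}

#' Summarise an experiment into study-style tables
#'
#' Produces per-cell means (and standard errors for variance components),
#' significance letters from pairwise paired t-tests across scenarios at
#' alpha 0.05, and the relative accuracy gain of each genomic scenario over
#' the pedigree-only scenario, `(acc_scenario - acc_G_none) / acc_G_none`.
#'
#' @param x a `pig_experiment` or its tidy `results` tibble.
#' @param alpha significance level for the letters.
#' @return List of class `pig_summary` with tibbles `accuracy`, `slope`,
#'   `top1`, `top30`, `varcomps`, `gains`.
#' @export
summarize_experiment <- function(x, alpha = 0.05) {
  results <- if (inherits(x, "pig_experiment")) x$results else x
  varcomps <- if (inherits(x, "pig_experiment")) x$varcomps else NULL
  n_rep <- length(unique(results$replicate))
  if (n_rep < 2)
    warning("single replicate: significance letters suppressed")

  summarise_metric <- function(met) {
    d <- results[results$metric == met, ]
    if (nrow(d) == 0L) return(NULL)
    means <- d |>
      dplyr::group_by(.data$trait, .data$model, .data$effect,
                      .data$scenario) |>
      dplyr::summarise(mean = mean(.data$value),
                       se = stats::sd(.data$value) / sqrt(dplyr::n()),
                       n = dplyr::n(), .groups = "drop")
    if (n_rep >= 2) {
      letters_tbl <- d |>
        dplyr::group_by(.data$trait, .data$model, .data$effect) |>
        dplyr::group_modify(function(g, key) {
          wide <- tidyr::pivot_wider(g[, c("replicate", "scenario", "value")],
                                     names_from = "scenario",
                                     values_from = "value")
          wide <- wide[order(wide$replicate), , drop = FALSE]
          mat <- as.matrix(wide[, -1, drop = FALSE])
          if (nrow(mat) < 2 || ncol(mat) < 2)
            return(tibble::tibble(scenario = colnames(mat),
                                  letter = rep("a", ncol(mat))))
          lt <- significance_letters(mat, alpha = alpha)
          tibble::tibble(scenario = names(lt), letter = unname(lt))
        }) |>
        dplyr::ungroup()
      means <- dplyr::left_join(means, letters_tbl,
                                by = c("trait", "model", "effect",
                                       "scenario"))
    } else {
      means$letter <- NA_character_
    }
    means
  }

  acc <- summarise_metric("accuracy")
  gains <- NULL
  if (!is.null(acc) && "G_none" %in% acc$scenario) {
    base <- acc[acc$scenario == "G_none",
                c("trait", "model", "effect", "mean")]
    names(base)[4] <- "mean_gnone"
    gains <- acc |>
      dplyr::inner_join(base, by = c("trait", "model", "effect")) |>
      dplyr::filter(.data$scenario != "G_none") |>
      dplyr::mutate(gain_pct = 100 * (.data$mean - .data$mean_gnone) /
                      .data$mean_gnone) |>
      dplyr::select("trait", "model", "effect", "scenario", "gain_pct")
  }

  vc_sum <- NULL
  if (!is.null(varcomps)) {
    vc_sum <- varcomps |>
      dplyr::group_by(.data$trait, .data$model, .data$component) |>
      dplyr::summarise(mean = mean(.data$value),
                       se = stats::sd(.data$value) /
                         sqrt(dplyr::n()), .groups = "drop")
  }

  structure(list(accuracy = acc, slope = summarise_metric("slope"),
                 top1 = summarise_metric("top1_tbv"),
                 top30 = summarise_metric("top30_tbv"),
                 varcomps = vc_sum, gains = gains, n_replicates = n_rep),
            class = "pig_summary")
}

#' @export
print.pig_summary <- function(x, ...) {
  cat("<pig_summary>", x$n_replicates, "replicates\n")
  if (!is.null(x$accuracy)) {
    cat("\nAccuracy (EBV vs TBV), total genetic effect:\n")
    tot <- x$accuracy[x$accuracy$effect == "total", ]
    print(as.data.frame(tot), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.pig_config <- function(x, ...) {
  cat("<pig_config>", x$trait, "|", x$n_replicates, "replicates | scenarios:",
      paste(x$scenarios, collapse = ", "), "| models:",
      paste(x$models, collapse = ", "), "\n")
  cat("  genome:", x$genome$n_chr, "chr x", x$genome$markers_per_chr,
      "markers +", x$genome$qtl_per_chr, "QTL\n")
  cat("  breeding:", x$breeding$n_sires, "sires x", x$breeding$dams_per_sire,
      "dams,", x$breeding$n_generations, "generations; validation gen",
      x$validation_generation, "\n")
  invisible(x)
}
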