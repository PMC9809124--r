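test_that("the default configuration reproduces the full study design", {
  cfg <- scale_config(1)
  expect_equal(cfg$genome$n_chr, 18)
  expect_equal(cfg$genome$markers_per_chr, 3100)
  expect_equal(cfg$genome$qtl_per_chr, 50)
  expect_equal(cfg$history$n_founder_males, 200)
  expect_equal(cfg$history$n_historical_generations, 300)
  expect_equal(cfg$base, list(n_boars = 30, n_sows = 200))
  expect_equal(cfg$breeding$n_sires, 30)
  expect_equal(cfg$breeding$n_dams, 300)
  expect_equal(cfg$breeding$n_generations, 8)
  expect_equal(cfg$reference_generations, 5:7)
  expect_equal(cfg$validation_generation, 8)
  expect_equal(cfg$n_replicates, 40)
  expect_equal(cfg$omega, 0.2)
  expect_equal(cfg$mortality, 0.2)
  # scaled copies stay well formed
  small <- scale_config(0.1, n_generations = 5)
  expect_gte(small$breeding$n_sires, 2)
  expect_equal(small$validation_generation, 5)
})

test_that("a replicate is reproducible end to end from its seed", {
  cfg <- micro_config()
  r1 <- run_replicate(cfg, seed = 99)
  r2 <- run_replicate(cfg, seed = 99)
  expect_equal(r1$results, r2$results)
  expect_equal(r1$varcomps, r2$varcomps)
})

test_that("within a replicate scenarios share data and only masks differ", {
  cfg <- micro_config(scenarios = c("G_all", "G80_ran", "G_alive", "G_none"))
  cfg$keep_bundles <- TRUE
  ex <- run_experiment(cfg)
  expect_s3_class(ex, "pig_experiment")
  res <- ex$results
  # one row per scenario x metric x effect for the single replicate and model
  expect_setequal(unique(res$scenario),
                  c("G_all", "G80_ran", "G_alive", "G_none"))
  acc <- res[res$metric == "accuracy" & res$effect == "total", ]
  expect_equal(nrow(acc), 4L)
  expect_true(all(is.finite(acc$value)))
  expect_true(all(abs(acc$value) <= 1))
  b <- ex$bundles[[1]]
  expect_s3_class(b, "pig_replicate")
})

test_that("experiment summaries compute gains and letters", {
  # synthetic results: accuracies as printed in the study's headline cells
  reps <- 1:5
  mk <- function(scenario, value) tibble::tibble(
    replicate = reps, trait = "T_4/4", scenario = scenario, model = "LM",
    metric = "accuracy", effect = "total",
    value = value + c(-0.002, -0.001, 0, 0.001, 0.002))
  res <- dplyr::bind_rows(mk("G_all", 0.500), mk("G_none", 0.314))
  s <- summarize_experiment(res)
  gain <- s$gains$gain_pct[s$gains$scenario == "G_all"]
  # (0.500 - 0.314)/0.314 = 59.2%
  expect_equal(gain, 100 * (0.500 - 0.314) / 0.314, tolerance = 1e-8)
  expect_equal(round(gain, 1), 59.2)
  # clearly different scenarios get different letters
  acc <- s$accuracy
  expect_false(acc$letter[acc$scenario == "G_all"] ==
                 acc$letter[acc$scenario == "G_none"])
  # single replicate: letters suppressed with a warning
  expect_warning(s1 <- summarize_experiment(res[res$replicate == 1, ]),
                 "single replicate")
  expect_true(all(is.na(s1$accuracy$letter)))
})

test_that("experiment configurations round-trip through YAML", {
  cfg <- desk_config(models = c("LM", "PM"), n_replicates = 3, seed = 123)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(cfg, path)
  back <- read_experiment_config(path)
  for (field in c("trait", "scenarios", "models", "n_replicates", "seed",
                  "genome", "base", "mortality", "omega",
                  "reference_generations", "validation_generation")) {
    expect_equal(back[[field]], cfg[[field]], label = field)
  }
  expect_equal(unclass(back$breeding), unclass(cfg$breeding))
})

test_that("population files round-trip through their text formats", {
  cfg <- micro_config()
  b <- simulate_replicate(cfg, seed = 55)
  dir <- withr::local_tempdir()
  pp <- file.path(dir, "ped.csv")
  write_pedigree_file(b$pop$pedigree, pp)
  ped_back <- read_pedigree_file(pp)
  expect_equal(as.data.frame(ped_back),
               as.data.frame(b$pop$pedigree[, c("id", "sire", "dam", "sex",
                                                "generation", "litter",
                                                "alive")]))
  dp <- file.path(dir, "geno.raw")
  write_dosage_file(b$pop, dp, loci = "marker")
  dos_back <- read_dosage_file(dp)
  expect_equal(dos_back, dosage_matrix(b$pop, loci = "marker"))
})

test_that("experiment tidiers and plots work on small results", {
  cfg <- micro_config()
  ex <- run_experiment(cfg)
  td <- generics::tidy(ex)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("replicate", "scenario", "model", "metric", "effect",
                    "value") %in% names(td)))
  gl <- generics::glance(ex)
  expect_equal(gl$n_replicates, 1L)
  p <- ggplot2::autoplot(ex)
  expect_s3_class(p, "ggplot")
  ped <- random_pedigree(4, 6, 1)
  fit <- fit_linear(random_binary_phenotypes(ped, 2), ped,
                    list(sigma2_l = 0.03, sigma2_a = 0.05, sigma2_m = 0.04,
                         sigma_am = 0.01, sigma2_e = 0.88))
  tbv <- tibble::tibble(id = ped$id, tbv_a = rnorm(nrow(ped)),
                        tbv_m = rnorm(nrow(ped)))
  expect_s3_class(plot_ebv_tbv(fit, tbv), "ggplot")
})
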