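test_that("trait presets encode the three study architectures", {
  t44 <- trait_preset("T_4/4")
  expect_equal(t44$sigma2_a, 0.04)
  expect_equal(t44$sigma2_m, 0.04)
  expect_equal(t44$sigma2_l, 0.04)
  expect_equal(t44$sigma_am, 0.3 * 0.04)
  expect_equal(t44$sigma2_e, 1 - 0.12)
  t24 <- trait_preset("T_2/4")
  expect_equal(c(t24$sigma2_a, t24$sigma2_m, t24$sigma2_l),
               c(0.02, 0.04, 0.04))
  expect_equal(t24$sigma_am, 0.3 * sqrt(0.02 * 0.04))
  t22 <- trait_preset("T_2/2")
  expect_equal(c(t22$sigma2_a, t22$sigma2_m, t22$sigma2_l),
               c(0.02, 0.02, 0.02))
  expect_error(trait_architecture(0.5, 0.4, 0.2), "less than 1")
})

test_that("QTL effect pairs carry the configured genetic correlation", {
  arch <- trait_preset("T_4/4")
  # perfect correlation: maternal effects exactly proportional to direct
  arch1 <- trait_architecture(0.04, 0.04, r_am = 1)
  e1 <- sample_qtl_effects(50, arch1, seed = 1)
  expect_equal(stats::cor(e1$alpha_a, e1$alpha_m), 1)
  # large sample: correlation converges to 0.30
  e <- sample_qtl_effects(20000, arch, seed = 2)
  expect_equal(stats::cor(e$alpha_a, e$alpha_m), 0.30, tolerance = 0.02)
})

test_that("calibration makes realized TBV variances exact in the base cohort", {
  arch <- trait_preset("T_2/4")
  set.seed(3)
  dos <- matrix(stats::rbinom(200 * 30, 2, 0.5), 200, 30)
  eff <- sample_qtl_effects(30, arch, seed = 4)
  eff <- calibrate_qtl_effects(eff, dos, arch)
  rownames(dos) <- 1:200
  tbv <- compute_tbv(dos, eff)
  expect_equal(stats::var(tbv$tbv_a), arch$sigma2_a, tolerance = 1e-12)
  expect_equal(stats::var(tbv$tbv_m), arch$sigma2_m, tolerance = 1e-12)
  # centering makes TBVs mean zero in the scaling cohort
  expect_equal(mean(tbv$tbv_a), 0, tolerance = 1e-12)
})

test_that("TBVs are linear in QTL dosages", {
  eff <- tibble::tibble(alpha_a = 0.7, alpha_m = -0.2)
  class(eff) <- c("qtl_effects", class(eff))
  dos <- matrix(c(0L, 1L, 2L), 3, 1, dimnames = list(1:3, "Q1"))
  tbv <- compute_tbv(dos, eff)
  expect_equal(tbv$tbv_a, c(0, 0.7, 1.4))
  expect_equal(tbv$tbv_m, c(0, -0.2, -0.4))
  expect_error(compute_tbv(matrix(NA_integer_, 1, 1,
                                  dimnames = list("1", "Q1")), eff),
               "missing")
})

test_that("mean offspring TBV approaches the mid-parent value", {
  map <- sim_marker_map(2, 5, 10, seed = 5)
  hist <- simulate_history(map, history_config(10, 10, 5), seed = 6)
  arch <- trait_preset("T_4/4")
  qtl <- which(map$class == "qtl")
  eff <- sample_qtl_effects(length(qtl), arch, seed = 7)
  base <- found_base_population(hist, 5, 5, seed = 8)
  eff <- calibrate_qtl_effects(eff, dosage_matrix(base, loci = qtl), arch)
  chrs <- pigsurv:::map_chromosomes(map)
  set.seed(9)
  gs <- pigsurv:::make_gametes(base$haplo, rep(1L, 400), chrs)
  gd <- pigsurv:::make_gametes(base$haplo, rep(6L, 400), chrs)
  dos_off <- gs[, qtl] + gd[, qtl]
  rownames(dos_off) <- seq_len(400)
  a_off <- compute_tbv(dos_off, eff)$tbv_a
  parents <- compute_tbv(dosage_matrix(base, loci = qtl, ids = c(1L, 6L)), eff)
  midparent <- mean(parents$tbv_a)
  expect_lt(abs(mean(a_off) - midparent), 4 * stats::sd(a_off) / sqrt(400))
})

test_that("liability is assembled from its four components", {
  cfg <- micro_config()
  b <- simulate_replicate(cfg, seed = 12)
  ph <- b$phenotypes
  # reconstruction: liability = own a + dam m + litter effect + residual
  dam_m <- b$tbv$tbv_m[match(b$pop$pedigree$dam[match(ph$id, b$pop$pedigree$id)],
                             b$tbv$id)]
  expect_equal(ph$liability,
               ph$tbv_a + dam_m + ph$litter_effect + ph$residual)
  # litter mates share an identical litter effect
  per_litter <- tapply(ph$litter_effect, ph$litter,
                       function(x) length(unique(x)))
  expect_true(all(per_litter == 1))
})

test_that("degenerate variances reduce liability to the direct TBV", {
  ped <- ped6()
  tbv <- tibble::tibble(id = 1:6, tbv_a = c(0.3, -0.1, 0.2, 0.5, -0.4, 0.1),
                        tbv_m = 0)
  arch <- trait_preset("T_4/4")
  arch$sigma2_l <- 0
  arch$sigma2_e <- 0
  ph <- simulate_liability(ped, tbv, arch, generations = c(1L, 2L), seed = 1)
  expect_equal(ph$liability, ph$tbv_a)
})

test_that("full-sib liability correlation matches the component algebra", {
  arch <- trait_preset("T_4/4")
  cfg <- desk_config()
  b <- cached("fullsib_rep", simulate_replicate(cfg, seed = 77001))
  ph <- b$phenotypes
  # intraclass correlation within litters
  m <- stats::aov(liability ~ factor(litter), data = ph)
  ms <- summary(m)[[1]][["Mean Sq"]]
  k <- mean(table(ph$litter))
  icc <- (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
  expected <- (0.5 * arch$sigma2_a + arch$sigma2_m + arch$sigma2_l +
                 arch$sigma_am) /
    (arch$sigma2_a + arch$sigma2_m + arch$sigma2_l + arch$sigma2_e +
       arch$sigma_am)
  expect_lt(abs(icc - expected), 0.06)
})

test_that("survival truncation kills exactly the lowest-liability fraction", {
  ph <- tibble::tibble(id = 1:5, liability = c(5, 4, 3, 2, 1),
                       generation = 1L)
  out <- threshold_survival(ph, mortality = 0.20)
  expect_equal(out$y, c(1L, 1L, 1L, 1L, 0L))
  # ties: stable (liability, id) order still yields exactly 20% dead
  ph2 <- tibble::tibble(id = 1:10, liability = 1, generation = 1L)
  out2 <- threshold_survival(ph2, mortality = 0.20)
  expect_equal(sum(out2$y == 0L), 2L)
  expect_equal(which(out2$y == 0L), 1:2)
  # per-generation cohorts: realized mortality 20% in each generation
  cfg <- micro_config()
  b <- simulate_replicate(cfg, seed = 14)
  dead <- tapply(1 - b$phenotypes$y, b$phenotypes$generation, mean)
  expect_true(all(abs(dead - 0.2) < 0.01))
  expect_error(threshold_survival(ph[1:3, ]), "cohort too small")
})
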