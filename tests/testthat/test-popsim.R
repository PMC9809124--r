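test_that("meiosis on a zero-length chromosome copies one parental haplotype", {
  # loci essentially at one point: no recombination is possible
  map <- tibble::tibble(chr = 1L, locus_id = paste0("L", 1:6),
                        pos_cm = seq(0, 1e-6, length.out = 6),
                        class = "marker")
  h1 <- rep(0L, 6)
  h2 <- rep(1L, 6)
  set.seed(11)
  for (i in 1:50) {
    g <- meiosis(h1, h2, map)
    expect_true(all(g == 0L) || all(g == 1L))
  }
})

test_that("recombinant fractions follow the Haldane map function", {
  # two loci 100 cM apart: expected recombinant fraction (1 - exp(-2))/2
  map <- two_locus_map(100)
  chrs <- pigsurv:::map_chromosomes(map)
  haplo <- rbind(c(0L, 0L), c(1L, 1L))  # phase-known double heterozygote
  set.seed(21)
  gam <- pigsurv:::make_gametes(haplo, rep(1L, 50000), chrs)
  rec <- mean(gam[, 1] != gam[, 2])
  expect_equal(rec, (1 - exp(-2)) / 2, tolerance = 0.02)

  # two loci 0.01 cM apart: recombination is essentially absent
  map2 <- two_locus_map(0.01)
  chrs2 <- pigsurv:::map_chromosomes(map2)
  gam2 <- pigsurv:::make_gametes(haplo, rep(1L, 20000), chrs2)
  expect_lt(mean(gam2[, 1] != gam2[, 2]), 1e-3)
})

test_that("offspring alleles are Mendelian-consistent with their parents", {
  cfg <- micro_config()
  b <- simulate_replicate(cfg, seed = 9)
  pop <- b$pop
  ped <- pop$pedigree
  off <- ped[ped$generation > 0L, ]
  for (i in sample(seq_len(nrow(off)), 40)) {
    o <- off[i, ]
    oh1 <- pop$haplo[2L * o$id - 1L, ]  # paternal gamete
    oh2 <- pop$haplo[2L * o$id, ]       # maternal gamete
    sh <- pop$haplo[c(2L * o$sire - 1L, 2L * o$sire), ]
    dh <- pop$haplo[c(2L * o$dam - 1L, 2L * o$dam), ]
    expect_true(all(oh1 == sh[1, ] | oh1 == sh[2, ]))
    expect_true(all(oh2 == dh[1, ] | oh2 == dh[2, ]))
  }
})

test_that("breeding follows the litter-size law and the mating design", {
  cfg <- breeding_config(n_sires = 3, dams_per_sire = 4,
                         litter_size_support = c(10, 12, 14, 16, 18),
                         litter_size_probs = c(0, 0, 1, 0, 0),
                         n_generations = 1)
  expect_equal(cfg$n_dams, 12)
  hist <- simulate_history(sim_marker_map(1, 20, 2, seed = 1),
                           history_config(8, 16, 0), seed = 2)
  pop <- found_base_population(hist, n_boars = 4, n_sows = 14, seed = 3)
  pop2 <- breed_generation(pop, cfg, seed = 4)
  off <- pop2$pedigree[pop2$pedigree$generation == 1L, ]
  # degenerate law: every litter has exactly 14 piglets
  expect_true(all(table(off$litter) == 14))
  expect_equal(nrow(off), 12 * 14)
  # each dam has exactly one litter, each sire 4 dams
  expect_equal(length(unique(off$dam)), 12)
  expect_true(all(table(unique(off[, c("sire", "dam")])$sire) == 4))
  # parents come from the previous generation only
  expect_true(all(off$sire %in% pop$pedigree$id))
  # expected litter size of the default law is 14 piglets
  d <- breeding_config()
  expect_equal(sum(d$litter_size_support * d$litter_size_probs), 14)
})

test_that("breeding signals insufficient alive parents", {
  hist <- simulate_history(sim_marker_map(1, 10, 2, seed = 1),
                           history_config(6, 6, 0), seed = 2)
  pop <- found_base_population(hist, n_boars = 2, n_sows = 6, seed = 3)
  cfg <- breeding_config(n_sires = 5, dams_per_sire = 2, n_generations = 1)
  expect_error(breed_generation(pop, cfg, seed = 1), "insufficient alive males")
})

test_that("population simulation is reproducible from the seed", {
  cfg <- micro_config()
  b1 <- simulate_replicate(cfg, seed = 31)
  b2 <- simulate_replicate(cfg, seed = 31)
  expect_identical(b1$pop$pedigree, b2$pop$pedigree)
  expect_identical(b1$pop$haplo, b2$pop$haplo)
  expect_identical(b1$phenotypes, b2$phenotypes)
})

test_that("heterozygosity decays at the neutral drift rate", {
  # Ne = 20 (10 + 10, random union of gametes): E[H_t] = H_0 (1 - 1/(2Ne))^t
  map <- sim_marker_map(n_chr = 6, markers_per_chr = 10, qtl_per_chr = 1,
                        chr_length_cm = 100, seed = 5)
  cfg <- history_config(10, 10, n_historical_generations = 15,
                        mutation_rate = 0)
  het <- replicate(5, {
    h <- simulate_history(map, cfg, seed = sample.int(1e6, 1))
    freq <- colMeans(h$haplo)
    mean(2 * freq * (1 - freq))
  })
  expected <- 0.5 * (1 - 1 / 40)^15
  expect_equal(mean(het), expected, tolerance = 0.12)
})

test_that("linkage disequilibrium builds up over historical generations", {
  map <- sim_marker_map(n_chr = 1, markers_per_chr = 40, qtl_per_chr = 2,
                        chr_length_cm = 100, seed = 6)
  # brute-force r^2 from haplotype counts for close segregating pairs; the
  # distance cap keeps the long-run and short-run sets comparable, since
  # after many generations only a few, irregularly spaced loci segregate
  r2_vals <- function(haplo, max_cm = 10) {
    freq <- colMeans(haplo)
    seg <- which(freq > 0.1 & freq < 0.9)
    vals <- c()
    if (length(seg) < 2) return(vals)
    for (a in seq_len(length(seg) - 1)) for (b in (a + 1):length(seg)) {
      i <- seg[a]; j <- seg[b]
      if (map$pos_cm[j] - map$pos_cm[i] > max_cm) next
      pAB <- mean(haplo[, i] == 1 & haplo[, j] == 1)
      D <- pAB - freq[i] * freq[j]
      vals <- c(vals,
                D^2 / (freq[i] * (1 - freq[i]) * freq[j] * (1 - freq[j])))
    }
    vals
  }
  v300 <- c()
  v10 <- c()
  for (s in 1:6) {
    h300 <- simulate_history(map, history_config(30, 30, 300,
                                                 mutation_rate = 0),
                             seed = 100 * s + 1)
    h10 <- simulate_history(map, history_config(30, 30, 10,
                                                mutation_rate = 0),
                            seed = 100 * s + 2)
    v300 <- c(v300, r2_vals(h300$haplo))
    v10 <- c(v10, r2_vals(h10$haplo))
  }
  expect_gt(mean(v300), mean(v10))
})

test_that("base population selection keeps counts and is reproducible", {
  # synthetic final generation with exactly the full-scale sex counts
  map <- sim_marker_map(1, 5, 1, seed = 7)
  hist <- simulate_history(map, history_config(30, 200, 0), seed = 8)
  base <- found_base_population(hist, n_boars = 30, n_sows = 200, seed = 9)
  expect_equal(nrow(base$pedigree), 230)
  expect_equal(sum(base$pedigree$sex == "M"), 30)
  expect_equal(sum(base$pedigree$sex == "F"), 200)
  # exact counts: selection is the identity up to ordering
  expect_setequal(seq_len(230), base$pedigree$id)
  base2 <- found_base_population(hist, n_boars = 30, n_sows = 200, seed = 9)
  expect_identical(base$haplo, base2$haplo)
  expect_error(found_base_population(hist, n_boars = 31, n_sows = 201),
               "need 31 males")
})

test_that("history with zero generations applies no drift", {
  map <- sim_marker_map(1, 200, 5, seed = 10)
  h <- simulate_history(map, history_config(20, 20, 0), seed = 11)
  freq <- colMeans(h$haplo)
  # founder law: i.i.d. Bernoulli(0.5) alleles
  expect_equal(mean(freq), 0.5, tolerance = 0.02)
  expect_true(h$summary$n_segregating_markers > 190)
})
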