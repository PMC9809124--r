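#' Single meiosis under the Haldane model
#'
#' Produces one gamete from a parent's two phased haplotypes.  Crossovers per
#' chromosome are Poisson with mean equal to the map length in Morgans and are
#' placed uniformly (Haldane: no interference), so two loci d Morgans apart
#' recombine with probability (1 - exp(-2d))/2.
#'
#' @param hap1,hap2 integer 0/1 vectors, the parent's phased haplotypes over
#'   all loci of `map` (map order).
#' @param map a locus map from [sim_marker_map()].
#' @param seed optional seed.
#' @return Integer 0/1 vector: the gamete haplotype.
#' @export
meiosis <- function(hap1, hap2, map, seed = NULL) {
  assert_that(length(hap1) == nrow(map) && length(hap2) == nrow(map),
              "parent haplotypes must cover all loci of the map")
  set_seed_if(seed)
  chrs <- map_chromosomes(map)
  gamete <- integer(nrow(map))
  for (ch in chrs) {
    choice <- gamete_choice(ch$pos, ch$len_morgan)
    gamete[ch$idx] <- ifelse(choice == 0L, hap1[ch$idx], hap2[ch$idx])
  }
  gamete
}

# 0/1 vector saying which parental haplotype each locus comes from
gamete_choice <- function(pos_cm, len_morgan) {
  start <- sample.int(2L, 1L) - 1L
  n_xo <- stats::rpois(1L, len_morgan)
  if (n_xo == 0L) return(rep.int(start, length(pos_cm)))
  xo <- sort(stats::runif(n_xo, 0, len_morgan * 100))
  (start + findInterval(pos_cm, xo)) %% 2L
}

# Gametes for many offspring at once.  haplo holds two rows per individual
# (rows 2i-1, 2i); parent_idx gives the individual index within haplo for each
# gamete.  Returns a matrix with one gamete per row.  mutation_rate is the
# per-locus symmetric allele-flip probability per meiosis.
make_gametes <- function(haplo, parent_idx, chrs, mutation_rate = 0) {
  n_loci <- ncol(haplo)
  out <- matrix(0L, nrow = length(parent_idx), ncol = n_loci)
  for (g in seq_along(parent_idx)) {
    p <- parent_idx[g]
    h1 <- haplo[2L * p - 1L, ]
    h2 <- haplo[2L * p, ]
    gam <- integer(n_loci)
    for (ch in chrs) {
      choice <- gamete_choice(ch$pos, ch$len_morgan)
      gam[ch$idx] <- ifelse(choice == 0L, h1[ch$idx], h2[ch$idx])
    }
    out[g, ] <- gam
  }
  if (mutation_rate > 0) {
    n_mut <- stats::rbinom(1L, length(out), mutation_rate)
    if (n_mut > 0L) {
      at <- sample.int(length(out), n_mut)
      out[at] <- 1L - out[at]
    }
  }
  out
}

#' Configuration of the historical, LD-building phase
#'
#' Discrete non-overlapping generations of constant size with random union of
#' gametes, run to build linkage disequilibrium between markers and QTLs
#' before the recent pedigree starts.
#'
#' @param n_founder_males,n_founder_females founder counts (defaults 200/200).
#' @param n_historical_generations number of historical generations (300).
#' @param mutation_rate per-locus, per-meiosis symmetric allele-flip rate.
#'   The default keeps roughly 80 percent of QTLs segregating after 300
#'   generations at the default genome size.
#' @param founder_freq founder allele frequency; founder alleles are i.i.d.
#'   Bernoulli draws at this frequency.
#' @return A list of class `history_config`.
#' @export
history_config <- function(n_founder_males = 200, n_founder_females = 200,
                           n_historical_generations = 300,
                           mutation_rate = 2.5e-5, founder_freq = 0.5) {
  assert_that(is_count(n_founder_males) && is_count(n_founder_females),
              "founder counts must be positive integers")
  assert_that(n_historical_generations >= 0 &&
                n_historical_generations == round(n_historical_generations),
              "n_historical_generations must be a non-negative integer")
  assert_that(mutation_rate >= 0 && mutation_rate < 1, "invalid mutation rate")
  assert_that(founder_freq > 0 && founder_freq < 1,
              "founder_freq must be in (0, 1)")
  structure(list(n_founder_males = n_founder_males,
                 n_founder_females = n_founder_females,
                 n_historical_generations = n_historical_generations,
                 mutation_rate = mutation_rate,
                 founder_freq = founder_freq),
            class = "history_config")
}

#' Simulate the historical LD-building phase
#'
#' Starts from unrelated founders with i.i.d. allele draws and runs discrete
#' non-overlapping generations of constant size: each offspring takes one
#' recombinant gamete from a random male and one from a random female.
#' Recurrent symmetric mutation counteracts drift so that part of the loci
#' remain segregating.
#'
#' @param map locus map from [sim_marker_map()].
#' @param cfg a [history_config()].
#' @param seed integer seed.
#' @return A list of class `pig_history` with elements `haplo` (two rows per
#'   individual, final generation), `sex` (per individual), `map`, and
#'   `summary`, a one-row tibble with counts of segregating markers and QTLs.
#' @export
simulate_history <- function(map, cfg = history_config(), seed = NULL) {
  map <- validate_marker_map(map)
  assert_that(inherits(cfg, "history_config"), "cfg must be a history_config")
  set_seed_if(seed)
  nm <- cfg$n_founder_males
  nf <- cfg$n_founder_females
  n <- nm + nf
  n_loci <- nrow(map)
  chrs <- map_chromosomes(map)

  haplo <- matrix(stats::rbinom(2L * n * n_loci, 1L, cfg$founder_freq),
                  nrow = 2L * n, ncol = n_loci)
  sex <- rep(c("M", "F"), c(nm, nf))

  for (g in seq_len(cfg$n_historical_generations)) {
    sires <- sample(which(sex == "M"), n, replace = TRUE)
    dams <- sample(which(sex == "F"), n, replace = TRUE)
    gam_s <- make_gametes(haplo, sires, chrs, cfg$mutation_rate)
    gam_d <- make_gametes(haplo, dams, chrs, cfg$mutation_rate)
    haplo[seq(1L, 2L * n, by = 2L), ] <- gam_s
    haplo[seq(2L, 2L * n, by = 2L), ] <- gam_d
    # constant sex ratio, constant size
    sex <- rep(c("M", "F"), c(nm, nf))
  }

  freq <- colMeans(haplo)
  seg <- freq > 0 & freq < 1
  summary <- tibble::tibble(
    n_segregating_markers = sum(seg & map$class == "marker"),
    n_segregating_qtl = sum(seg & map$class == "qtl"),
    n_markers = sum(map$class == "marker"),
    n_qtl = sum(map$class == "qtl")
  )
  if (!any(seg)) warning("all loci are fixed after the historical phase")
  structure(list(haplo = haplo, sex = sex, map = map, summary = summary),
            class = "pig_history")
}

#' Found the base population from the last historical generation
#'
#' Randomly selects `n_boars` males and `n_sows` females from the final
#' historical generation; their haplotypes are carried over unchanged.  The
#' base population is generation 0 of the recent pedigree.
#'
#' @param history a `pig_history` from [simulate_history()].
#' @param n_boars,n_sows numbers of base boars and sows (defaults 30 and 200).
#' @param seed optional seed.
#' @return A population object of class `pig_pop`: a list with `pedigree`
#'   (tibble: id, sire, dam, sex, generation, litter, alive), `haplo` (two
#'   rows per pedigree row, same order), and `map`.
#' @export
found_base_population <- function(history, n_boars = 30, n_sows = 200,
                                  seed = NULL) {
  assert_that(inherits(history, "pig_history"), "history must be a pig_history")
  set_seed_if(seed)
  males <- which(history$sex == "M")
  females <- which(history$sex == "F")
  assert_that(length(males) >= n_boars,
              sprintf("need %d males in the last historical generation, have %d",
                      n_boars, length(males)))
  assert_that(length(females) >= n_sows,
              sprintf("need %d females in the last historical generation, have %d",
                      n_sows, length(females)))
  boars <- sort(sample(males, n_boars))
  sows <- sort(sample(females, n_sows))
  sel <- c(boars, sows)
  rows <- as.vector(rbind(2L * sel - 1L, 2L * sel))
  ped <- tibble::tibble(
    id = seq_along(sel),
    sire = 0L, dam = 0L,
    sex = rep(c("M", "F"), c(n_boars, n_sows)),
    generation = 0L,
    litter = NA_integer_,
    alive = 1L
  )
  structure(list(pedigree = ped, haplo = history$haplo[rows, , drop = FALSE],
                 map = history$map),
            class = "pig_pop")
}

#' Configuration of the recent breeding structure
#'
#' @param n_sires sires selected per generation (30).
#' @param dams_per_sire dams mated to each sire (10).
#' @param litter_size_support,litter_size_probs the litter-size law
#'   (defaults 10/12/14/16/18 with probabilities 0.02/0.14/0.68/0.14/0.02,
#'   mean 14 piglets).
#' @param n_generations recent non-overlapping generations (8).
#' @return A list of class `breeding_config`; `n_dams` is derived as
#'   `n_sires * dams_per_sire`.
#' @export
breeding_config <- function(n_sires = 30, dams_per_sire = 10,
                            litter_size_support = c(10, 12, 14, 16, 18),
                            litter_size_probs = c(0.02, 0.14, 0.68, 0.14, 0.02),
                            n_generations = 8) {
  assert_that(is_count(n_sires) && is_count(dams_per_sire),
              "n_sires and dams_per_sire must be positive integers")
  assert_that(length(litter_size_support) == length(litter_size_probs),
              "litter size support and probabilities must match")
  assert_that(abs(sum(litter_size_probs) - 1) < 1e-12,
              "litter_size_probs must sum to 1")
  assert_that(is_count(n_generations), "n_generations must be positive")
  structure(list(n_sires = n_sires, dams_per_sire = dams_per_sire,
                 n_dams = n_sires * dams_per_sire,
                 litter_size_support = litter_size_support,
                 litter_size_probs = litter_size_probs,
                 n_generations = n_generations),
            class = "breeding_config")
}

#' Breed one more generation onto a population
#'
#' Selects sires and dams at random from the alive animals of the newest
#' generation, assigns dams to sires (each dam produces one litter), draws
#' litter sizes from the configured law, assigns sexes 1:1, and produces
#' offspring haplotypes by meiosis.  If the parent generation has fewer alive
#' females than the configured number of dams (as in the base generation,
#' which has 200 sows against 300 configured dams), all alive females are used
#' and dams are spread over the sires as evenly as possible.
#'
#' @param pop a `pig_pop`.
#' @param cfg a [breeding_config()].
#' @param seed optional seed.
#' @return The population with one generation appended (new animals have
#'   `alive = NA` until survival is scored).
#' @export
breed_generation <- function(pop, cfg, seed = NULL) {
  assert_that(inherits(pop, "pig_pop"), "pop must be a pig_pop")
  assert_that(inherits(cfg, "breeding_config"), "cfg must be a breeding_config")
  set_seed_if(seed)
  ped <- pop$pedigree
  gen <- max(ped$generation)
  cand <- ped[ped$generation == gen & !is.na(ped$alive) & ped$alive == 1L, ]
  males <- cand$id[cand$sex == "M"]
  females <- cand$id[cand$sex == "F"]
  if (length(males) < cfg$n_sires)
    stop(sprintf("insufficient alive males in generation %d: need %d, have %d",
                 gen, cfg$n_sires, length(males)), call. = FALSE)
  n_dams <- min(cfg$n_dams, length(females))
  if (length(females) < cfg$n_dams && gen > 0L)
    stop(sprintf("insufficient alive females in generation %d: need %d, have %d",
                 gen, cfg$n_dams, length(females)), call. = FALSE)

  sires <- sample(males, cfg$n_sires)
  dams <- sample(females, n_dams)
  # even round-robin assignment of dams to sires
  mate_sire <- rep(sires, length.out = n_dams)

  sizes <- sample(cfg$litter_size_support, n_dams, replace = TRUE,
                  prob = cfg$litter_size_probs)
  n_off <- sum(sizes)
  litter0 <- max(c(0L, ped$litter), na.rm = TRUE)
  id0 <- max(ped$id)

  off <- tibble::tibble(
    id = id0 + seq_len(n_off),
    sire = rep(mate_sire, sizes),
    dam = rep(dams, sizes),
    sex = ifelse(stats::rbinom(n_off, 1L, 0.5) == 1L, "M", "F"),
    generation = gen + 1L,
    litter = litter0 + rep(seq_len(n_dams), sizes),
    alive = NA_integer_
  )

  chrs <- map_chromosomes(pop$map)
  gam_s <- make_gametes(pop$haplo, off$sire, chrs)
  gam_d <- make_gametes(pop$haplo, off$dam, chrs)
  new_haplo <- matrix(0L, nrow = 2L * n_off, ncol = ncol(pop$haplo))
  new_haplo[seq(1L, 2L * n_off, by = 2L), ] <- gam_s
  new_haplo[seq(2L, 2L * n_off, by = 2L), ] <- gam_d

  pop$pedigree <- dplyr::bind_rows(ped, off)
  pop$haplo <- rbind(pop$haplo, new_haplo)
  pop
}

#' Allele dosages of a population
#'
#' @param pop a `pig_pop`.
#' @param loci optional locus subset (indices into the map, or a class name
#'   `"marker"`/`"qtl"`).
#' @param ids optional animal ids (default all).
#' @return Integer matrix of 0/1/2 dosages, rows named by animal id, columns
#'   by locus id.
#' @export
dosage_matrix <- function(pop, loci = NULL, ids = NULL) {
  assert_that(inherits(pop, "pig_pop"), "pop must be a pig_pop")
  if (is.character(loci) && length(loci) == 1L && loci %in% c("marker", "qtl"))
    loci <- which(pop$map$class == loci)
  if (is.null(loci)) loci <- seq_len(nrow(pop$map))
  if (is.null(ids)) ids <- pop$pedigree$id
  row_i <- match(ids, pop$pedigree$id)
  assert_that(!anyNA(row_i), "unknown animal id")
  d <- pop$haplo[2L * row_i - 1L, loci, drop = FALSE] +
    pop$haplo[2L * row_i, loci, drop = FALSE]
  dimnames(d) <- list(as.character(ids), pop$map$locus_id[loci])
  d
}

#' @export
print.pig_pop <- function(x, ...) {
  ped <- x$pedigree
  cat("<pig_pop> ", nrow(ped), " animals, generations ",
      min(ped$generation), "-", max(ped$generation), ", ",
      nrow(x$map), " loci (", sum(x$map$class == "qtl"), " QTL)\n", sep = "")
  invisible(x)
}
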