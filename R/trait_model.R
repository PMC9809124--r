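#' Trait architecture on the liability scale
#'
#' Defines the variance components of the latent liability to survival.  The
#' liability of a piglet is the sum of its own direct breeding value, its
#' dam's maternal breeding value, a litter environmental effect shared by
#' litter mates, and an independent residual.  Heritabilities and the litter
#' proportion are interpreted as proportions of the summed variance
#' components, so the residual variance is `1 - (h2_direct + h2_maternal +
#' lit2)` and the component sum is 1; the direct-maternal covariance is not
#' added to that denominator.
#'
#' @param h2_direct direct heritability on the liability scale.
#' @param h2_maternal maternal heritability on the liability scale.
#' @param lit2 litter variance proportion; defaults to `h2_maternal`, the
#'   study condition that litter variance equals maternal genetic variance.
#' @param r_am genetic correlation between direct and maternal effects (0.30).
#' @return A list of class `trait_arch` with elements `sigma2_a`, `sigma2_m`,
#'   `sigma_am`, `sigma2_l`, `sigma2_e`, `r_am` and the input proportions.
#' @export
trait_architecture <- function(h2_direct, h2_maternal, lit2 = h2_maternal,
                               r_am = 0.30) {
  assert_that(h2_direct > 0 && h2_direct < 1, "h2_direct must be in (0,1)")
  assert_that(h2_maternal > 0 && h2_maternal < 1, "h2_maternal must be in (0,1)")
  assert_that(lit2 >= 0 && lit2 < 1, "lit2 must be in [0,1)")
  assert_that(abs(r_am) <= 1, "r_am must be in [-1,1]")
  s2e <- 1 - (h2_direct + h2_maternal + lit2)
  assert_that(s2e > 0, "variance proportions must sum to less than 1")
  structure(list(
    h2_direct = h2_direct, h2_maternal = h2_maternal, lit2 = lit2, r_am = r_am,
    sigma2_a = h2_direct, sigma2_m = h2_maternal,
    sigma_am = r_am * sqrt(h2_direct * h2_maternal),
    sigma2_l = lit2, sigma2_e = s2e
  ), class = "trait_arch")
}

#' Preset trait architectures
#'
#' The three study traits: `"T_4/4"` (direct and maternal heritability 0.04),
#' `"T_2/4"` (0.02 and 0.04) and `"T_2/2"` (0.02 and 0.02), all with litter
#' proportion equal to the maternal heritability and direct-maternal genetic
#' correlation 0.30.
#'
#' @param name one of `"T_4/4"`, `"T_2/4"`, `"T_2/2"`.
#' @return A [trait_architecture()] object.
#' @export
trait_preset <- function(name = c("T_4/4", "T_2/4", "T_2/2")) {
  name <- match.arg(name)
  switch(name,
    "T_4/4" = trait_architecture(0.04, 0.04),
    "T_2/4" = trait_architecture(0.02, 0.04),
    "T_2/2" = trait_architecture(0.02, 0.02)
  )
}

#' Sample correlated direct and maternal QTL effects
#'
#' Effect pairs are drawn from a bivariate normal with correlation
#' `arch$r_am`.  The raw effects are later rescaled (see
#' [calibrate_qtl_effects()]) so that realized breeding-value variances in the
#' scaling cohort hit the architecture's targets exactly.
#'
#' @param n_qtl number of QTLs (>= 2).
#' @param arch a [trait_architecture()].
#' @param seed optional seed.
#' @return A tibble of class `qtl_effects` with columns `alpha_a`, `alpha_m`
#'   (one row per QTL, map order of QTL loci).
#' @export
sample_qtl_effects <- function(n_qtl, arch, seed = NULL) {
  assert_that(is_count(n_qtl) && n_qtl >= 2, "need at least 2 QTLs")
  assert_that(inherits(arch, "trait_arch"), "arch must be a trait_arch")
  set_seed_if(seed)
  z1 <- stats::rnorm(n_qtl)
  z2 <- stats::rnorm(n_qtl)
  r <- arch$r_am
  eff <- tibble::tibble(alpha_a = z1, alpha_m = r * z1 + sqrt(1 - r^2) * z2)
  class(eff) <- c("qtl_effects", class(eff))
  eff
}

#' Scale QTL effects against a base cohort
#'
#' Computes per-locus dosage centers (base-cohort mean dosage) and scaling
#' constants such that the variance of direct and maternal true breeding
#' values over the scaling cohort equals `sigma2_a` and `sigma2_m` exactly
#' (sample variance, denominator n - 1).
#'
#' @param effects a `qtl_effects` tibble.
#' @param base_dosages QTL dosage matrix of the scaling cohort (individuals x
#'   QTL).
#' @param arch the [trait_architecture()].
#' @return The effects with columns rescaled and attributes `centers` (per-QTL
#'   dosage centers) and `scale` (the two multipliers applied).
#' @export
calibrate_qtl_effects <- function(effects, base_dosages, arch) {
  assert_that(nrow(effects) == ncol(base_dosages),
              "one dosage column per QTL required")
  centers <- colMeans(base_dosages)
  z <- sweep(base_dosages, 2L, centers)
  raw_a <- as.vector(z %*% effects$alpha_a)
  raw_m <- as.vector(z %*% effects$alpha_m)
  va <- stats::var(raw_a)
  vm <- stats::var(raw_m)
  assert_that(va > 0 && vm > 0,
              "raw breeding values are constant in the scaling cohort; cannot scale")
  k <- c(a = sqrt(arch$sigma2_a / va), m = sqrt(arch$sigma2_m / vm))
  effects$alpha_a <- effects$alpha_a * k[["a"]]
  effects$alpha_m <- effects$alpha_m * k[["m"]]
  attr(effects, "centers") <- centers
  attr(effects, "scale") <- k
  effects
}

#' True breeding values from QTL dosages
#'
#' Direct and maternal true breeding values are linear in the centered QTL
#' dosages: `a_i = sum_q (d_iq - c_q) alpha_a_q`, and analogously for the
#' maternal effect.  Centering at the base-cohort mean dosage (stored on the
#' calibrated effects) gives TBVs with mean near zero; it shifts all animals
#' equally so variances and rankings are unaffected.
#'
#' @param qtl_dosages dosage matrix (individuals x QTL), rows named by id.
#' @param effects calibrated `qtl_effects`.
#' @return Tibble with columns `id`, `tbv_a`, `tbv_m`.
#' @export
compute_tbv <- function(qtl_dosages, effects) {
  assert_that(ncol(qtl_dosages) == nrow(effects),
              "dosage columns must match the QTL effect rows")
  assert_that(!anyNA(qtl_dosages), "missing QTL dosage")
  centers <- attr(effects, "centers") %||% rep(0, nrow(effects))
  z <- sweep(qtl_dosages, 2L, centers)
  tibble::tibble(
    id = as.integer(rownames(qtl_dosages)),
    tbv_a = as.vector(z %*% effects$alpha_a),
    tbv_m = as.vector(z %*% effects$alpha_m)
  )
}

#' Simulate liabilities for a set of offspring
#'
#' For each offspring, liability = own direct TBV + dam's maternal TBV +
#' litter effect + residual, with one litter effect drawn per litter
#' (`N(0, sigma2_l)`) and i.i.d. residuals (`N(0, sigma2_e)`).
#'
#' @param pedigree pedigree tibble (id, sire, dam, sex, generation, litter).
#' @param tbv tibble (id, tbv_a, tbv_m) covering the offspring and their dams.
#' @param arch the [trait_architecture()].
#' @param generations which generations to phenotype (default: all > 0; base
#'   animals have no dam in the pedigree and receive no phenotype).
#' @param seed optional seed.
#' @return Tibble: id, generation, litter, tbv_a, tbv_m (the individual's own
#'   values), litter_effect, residual, liability.
#' @export
simulate_liability <- function(pedigree, tbv, arch, generations = NULL,
                               seed = NULL) {
  assert_that(inherits(arch, "trait_arch"), "arch must be a trait_arch")
  set_seed_if(seed)
  if (is.null(generations)) generations <- setdiff(unique(pedigree$generation), 0L)
  ped <- pedigree[pedigree$generation %in% generations, ]
  assert_that(all(ped$dam > 0), "phenotyped individuals must have a known dam")
  own <- tbv[match(ped$id, tbv$id), ]
  dam_m <- tbv$tbv_m[match(ped$dam, tbv$id)]
  assert_that(!anyNA(dam_m), "every phenotyped individual needs a dam with a maternal TBV")
  lit <- factor(ped$litter)
  lit_eff <- stats::rnorm(nlevels(lit), 0, sqrt(arch$sigma2_l))[as.integer(lit)]
  resid <- stats::rnorm(nrow(ped), 0, sqrt(arch$sigma2_e))
  tibble::tibble(
    id = ped$id, generation = ped$generation, litter = ped$litter,
    tbv_a = own$tbv_a, tbv_m = own$tbv_m,
    litter_effect = lit_eff, residual = resid,
    liability = own$tbv_a + dam_m + lit_eff + resid
  )
}

#' Score binary survival by liability truncation
#'
#' Within each cohort, the `round(mortality * n)` individuals with the lowest
#' liabilities are scored dead (0) and the rest alive (1), so the realized
#' mortality is the target rate up to integer rounding.  Ties are broken by a
#' stable sort on (liability, id).
#'
#' @param phenotypes tibble with columns `id`, `liability` and the cohort
#'   column.
#' @param mortality target mortality (default 0.20).
#' @param cohort name of the column defining thresholding cohorts (default
#'   `"generation"`: ranking is applied within generation, keeping the parent
#'   pool at exactly 80 percent of each cohort).
#' @return The input with a `y` column (0 dead / 1 alive) appended.
#' @export
threshold_survival <- function(phenotypes, mortality = 0.20,
                               cohort = "generation") {
  assert_that(mortality >= 0 && mortality < 1, "mortality must be in [0,1)")
  assert_that(all(c("id", "liability") %in% names(phenotypes)),
              "phenotypes must have id and liability columns")
  grp <- if (cohort %in% names(phenotypes)) phenotypes[[cohort]] else
    rep(1L, nrow(phenotypes))
  y <- integer(nrow(phenotypes))
  for (g in unique(grp)) {
    i <- which(grp == g)
    assert_that(length(i) >= 5, "thresholding cohort too small (need >= 5)")
    n_dead <- round(mortality * length(i))
    ord <- i[order(phenotypes$liability[i], phenotypes$id[i])]
    y[ord] <- rep(c(0L, 1L), c(n_dead, length(i) - n_dead))
  }
  phenotypes$y <- y
  phenotypes
}
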