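# small fixtures shared across test files

# two-locus map at a given genetic distance (cM)
two_locus_map <- function(d_cm, chr = 1L) {
  tibble::tibble(chr = chr, locus_id = c("L1", "L2"),
                 pos_cm = c(0, d_cm), class = "marker")
}

# a deterministic 6-animal pedigree: 3 founders, one full-sib pair, and an
# inbred offspring of a half-sib-like mating
ped6 <- function() {
  tibble::tibble(
    id = 1:6,
    sire = c(0L, 0L, 0L, 1L, 1L, 4L),
    dam = c(0L, 0L, 0L, 2L, 3L, 5L),
    sex = c("M", "F", "F", "M", "F", "M"),
    generation = c(0L, 0L, 0L, 1L, 1L, 2L),
    litter = c(NA, NA, NA, 1L, 2L, 3L),
    alive = 1L
  )
}

# random valid pedigree: n_founder unrelated animals then offspring with
# parents drawn from earlier animals of the right sex
random_pedigree <- function(n_founder, n_offspring, seed) {
  set.seed(seed)
  sex <- c(rep(c("M", "F"), length.out = n_founder),
           sample(c("M", "F"), n_offspring, replace = TRUE))
  id <- seq_len(n_founder + n_offspring)
  sire <- dam <- integer(n_founder + n_offspring)
  gen <- c(rep(0L, n_founder), rep(1L, n_offspring))
  for (i in n_founder + seq_len(n_offspring)) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    sire[i] <- if (length(males) == 1L) males else sample(males, 1L)
    dam[i] <- if (length(females) == 1L) females else sample(females, 1L)
    gen[i] <- max(gen[sire[i]], gen[dam[i]]) + 1L
  }
  tibble::tibble(id = id, sire = sire, dam = dam, sex = sex,
                 generation = gen,
                 litter = ifelse(gen > 0L, id, NA_integer_), alive = 1L)
}

# expected pairwise IBD relationship by gene dropping (Monte Carlo oracle)
gene_drop_A <- function(ped, n_drop = 5000, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  acc <- matrix(0, n, n)
  for (r in seq_len(n_drop)) {
    al <- matrix(0L, n, 2L)
    next_allele <- 1L
    for (i in seq_len(n)) {
      al[i, 1L] <- if (si[i] > 0L) al[si[i], sample.int(2L, 1L)] else {
        next_allele <- next_allele + 1L; next_allele
      }
      al[i, 2L] <- if (di[i] > 0L) al[di[i], sample.int(2L, 1L)] else {
        next_allele <- next_allele + 1L; next_allele
      }
    }
    # coancestry: P(random allele of i IBD to random allele of j); twice the
    # coancestry estimates A everywhere, including the diagonal (1 + F)
    f <- (outer(al[, 1L], al[, 1L], "==") + outer(al[, 1L], al[, 2L], "==") +
            outer(al[, 2L], al[, 1L], "==") + outer(al[, 2L], al[, 2L], "==")) / 4
    acc <- acc + 2 * f
  }
  acc / n_drop
}

# dense GLS/BLUP oracle for the maternal-effects model on a small fixture:
# solves the conditional mean from the full multivariate covariance
gls_blup_oracle <- function(phenotypes, pedigree, vc) {
  A <- build_A(pedigree)
  ids <- pedigree$id
  n <- nrow(phenotypes)
  ia <- match(phenotypes$id, ids)
  im <- match(pedigree$dam[ia], ids)
  lit <- factor(phenotypes$litter)
  W <- outer(as.integer(lit), seq_len(nlevels(lit)), "==") * 1
  Vy <- vc$sigma2_a * A[ia, ia] + vc$sigma2_m * A[im, im] +
    vc$sigma_am * (A[ia, im] + t(A[ia, im])) +
    vc$sigma2_l * tcrossprod(W) + vc$sigma2_e * diag(n)
  X <- matrix(1, n, 1)
  Vi <- solve(Vy)
  beta <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% phenotypes$y))
  r <- phenotypes$y - as.vector(X %*% beta)
  Vir <- as.vector(Vi %*% r)
  Za <- outer(ia, seq_along(ids), "==") * 1
  Zm <- outer(im, seq_along(ids), "==") * 1
  cov_a <- vc$sigma2_a * A %*% t(Za) + vc$sigma_am * A %*% t(Zm)
  cov_m <- vc$sigma_am * A %*% t(Za) + vc$sigma2_m * A %*% t(Zm)
  cov_l <- vc$sigma2_l * t(W)
  list(mu = as.numeric(beta),
       ebv_a = as.vector(cov_a %*% Vir),
       ebv_m = as.vector(cov_m %*% Vir),
       litter = as.vector(cov_l %*% Vir))
}

# binary phenotypes on the offspring of a random pedigree
random_binary_phenotypes <- function(ped, seed) {
  set.seed(seed)
  off <- ped[ped$generation > 0L, ]
  tibble::tibble(id = off$id, litter = off$litter,
                 generation = off$generation,
                 y = stats::rbinom(nrow(off), 1L, 0.8))
}
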