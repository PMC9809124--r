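#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds Wright's numerator relationship matrix A by the tabular method,
#' including inbreeding: the diagonal is 1 + F with F half the relationship
#' between the parents.
#'
#' @param pedigree tibble with columns `id`, `sire`, `dam` (0 = unknown),
#'   sorted so that parents precede their offspring.
#' @return Dense symmetric matrix with dimnames set to the ids.
#' @export
build_A <- function(pedigree) {
  ped <- check_pedigree(pedigree)
  n <- nrow(ped)
  s <- ped$si
  d <- ped$di
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s[i] > 0L) row <- row + 0.5 * A[j, s[i]]
      if (d[i] > 0L) row <- row + 0.5 * A[j, d[i]]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  dimnames(A) <- list(as.character(ped$id), as.character(ped$id))
  A
}

# validate and index a pedigree: adds si/di (row positions of parents, 0 if
# unknown); errors if an animal appears before its parents
check_pedigree <- function(pedigree) {
  ped <- tibble::as_tibble(pedigree)
  assert_that(all(c("id", "sire", "dam") %in% names(ped)),
              "pedigree needs id, sire, dam columns")
  assert_that(!anyDuplicated(ped$id), "duplicated animal ids")
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  assert_that(all(ped$sire == 0L | si > 0L) && all(ped$dam == 0L | di > 0L),
              "parent id not present in the pedigree")
  rows <- seq_len(nrow(ped))
  assert_that(all(si < rows) && all(di < rows),
              "pedigree must list parents before their offspring")
  ped$si <- si
  ped$di <- di
  ped
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes the diagonal of A as the sum over ancestors of squared path
#' contributions times Mendelian sampling variances, without forming A.
#'
#' @inheritParams build_A
#' @return Numeric vector of inbreeding coefficients F, named by id.
#' @export
inbreeding_coefficients <- function(pedigree) {
  ped <- check_pedigree(pedigree)
  n <- nrow(ped)
  s <- ped$si
  d <- ped$di
  F <- numeric(n)
  for (i in seq_len(n)) {
    if (s[i] == 0L || d[i] == 0L) {
      F[i] <- 0
      next
    }
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * diag_d(F, s[j], d[j])
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * L[j]
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * L[j]
    }
    F[i] <- aii - 1
  }
  stats::setNames(F, as.character(ped$id))
}

F_at <- function(F, i) if (i > 0L) F[i] else 0

# Mendelian sampling variance d_j given parent knowledge
diag_d <- function(F, sj, dj) {
  if (sj > 0L && dj > 0L) 0.5 - 0.25 * (F[sj] + F[dj])
  else if (sj > 0L || dj > 0L) 0.75 - 0.25 * F_at(F, max(sj, dj))
  else 1
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Henderson's rules with inbreeding: A-inverse is assembled from the
#' Mendelian sampling variances `d_i = 0.5 - 0.25 (F_s + F_d)` (both parents
#' known; 0.75 - 0.25 F with one parent; 1 with none).
#'
#' @inheritParams build_A
#' @param F optional precomputed inbreeding coefficients (vector over rows).
#' @return A sparse symmetric [Matrix::dgCMatrix-class] with id dimnames.
#' @export
build_A_inverse <- function(pedigree, F = NULL) {
  ped <- check_pedigree(pedigree)
  n <- nrow(ped)
  s <- ped$si
  d <- ped$di
  if (is.null(F)) F <- unname(inbreeding_coefficients(pedigree))
  di <- vapply(seq_len(n), function(i) diag_d(F, s[i], d[i]), numeric(1))
  alpha <- 1 / di
  # each animal contributes at most 9 triplets
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k2 <- 0L
  add <- function(i, j, x) {
    k2 <<- k2 + 1L
    ii[k2] <<- i; jj[k2] <<- j; xx[k2] <<- x
  }
  for (k in seq_len(n)) {
    a <- alpha[k]
    par <- c(s[k], d[k])
    par <- par[par > 0L]
    add(k, k, a)
    for (p in par) {
      add(p, k, -a / 2)
      add(k, p, -a / 2)
    }
    if (length(par) == 2L) {
      add(par[1], par[2], a / 4)
      add(par[2], par[1], a / 4)
      add(par[1], par[1], a / 4)
      add(par[2], par[2], a / 4)
    } else if (length(par) == 1L) {
      add(par[1], par[1], a / 4)
    }
  }
  ii <- ii[seq_len(k2)]; jj <- jj[seq_len(k2)]; xx <- xx[seq_len(k2)]
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(as.character(ped$id),
                                               as.character(ped$id)))
  Matrix::forceSymmetric(Ainv)
}

#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 sum_j p_j (1 - p_j))` with `Z` the dosage matrix centered at
#' twice the allele frequencies.  By default the frequencies are observed
#' frequencies of the genotyped set itself; the subsequent rescaling against
#' the pedigree block absorbs the resulting level shift.
#'
#' @param dosages matrix of 0/1/2 dosages (individuals x markers), rows named
#'   by id.
#' @param allele_freq optional vector of allele frequencies per marker.
#' @return Dense symmetric matrix with id dimnames and attribute
#'   `allele_freq`.
#' @export
build_G <- function(dosages, allele_freq = NULL) {
  assert_that(nrow(dosages) >= 2, "need at least two genotyped individuals")
  p <- allele_freq %||% (colMeans(dosages) / 2)
  denom <- 2 * sum(p * (1 - p))
  assert_that(denom > 0, "all markers are monomorphic; G denominator is zero")
  Z <- sweep(dosages, 2L, 2 * p)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(dosages), rownames(dosages))
  attr(G, "allele_freq") <- p
  G
}

avg_offdiag <- function(M) {
  n <- nrow(M)
  if (n < 2L) return(NA_real_)
  (sum(M) - sum(diag(M))) / (n * (n - 1))
}

#' Rescale G to the pedigree block averages
#'
#' Solves for `beta` and `alpha` in `G* = G beta + alpha` such that the
#' average diagonal and average off-diagonal of `G*` equal those of the
#' pedigree block `A11` over the genotyped animals.
#'
#' @param G genomic relationship matrix.
#' @param A11 pedigree relationship block over the same animals, same order.
#' @return `G*`, with attributes `beta` and `alpha`.
#' @export
adjust_G <- function(G, A11) {
  assert_that(all(dim(G) == dim(A11)), "G and A11 must be conformable")
  if (!is.null(dimnames(G)[[1]]) && !is.null(dimnames(A11)[[1]]))
    assert_that(identical(rownames(G), rownames(A11)),
                "G and A11 must share the same id order")
  dg <- mean(diag(G)); og <- avg_offdiag(G)
  da <- mean(diag(A11)); oa <- avg_offdiag(A11)
  assert_that(abs(dg - og) > 1e-12,
              "Avg.diag(G) equals Avg.offdiag(G); rescaling system is singular")
  beta <- (da - oa) / (dg - og)
  alpha <- da - dg * beta
  Gs <- G * beta + alpha
  attr(Gs, "beta") <- beta
  attr(Gs, "alpha") <- alpha
  attr(Gs, "allele_freq") <- attr(G, "allele_freq")
  Gs
}

#' Blend the rescaled G with the pedigree block
#'
#' `G_omega = (1 - omega) G* + omega A11`; the default weight `omega = 0.2`
#' guarantees invertibility and positive definiteness of the genomic block.
#'
#' @param Gstar rescaled genomic matrix from [adjust_G()].
#' @param A11 pedigree block over the genotyped animals.
#' @param omega blending weight in `[0, 1]`.
#' @return The blended matrix.
#' @export
blend_G <- function(Gstar, A11, omega = 0.2) {
  assert_that(omega >= 0 && omega <= 1, "omega must be in [0,1]")
  assert_that(all(dim(Gstar) == dim(A11)), "matrices must be conformable")
  Gw <- (1 - omega) * Gstar + omega * A11
  attr(Gw, "omega") <- omega
  Gw
}

#' Dense single-step relationship matrix H (block formula)
#'
#' Combines pedigree and genomic information for genotyped and non-genotyped
#' animals jointly.  With genotyped block 1 and non-genotyped block 2:
#' `H11 = G_omega`, `H12 = G_omega A11^-1 A12`,
#' `H22 = A21 A11^-1 G_omega A11^-1 A12 + A22 - A21 A11^-1 A12`.
#' This dense construction is the testing oracle; production fits use the
#' sparse inverse from [build_H_inverse()].
#'
#' @param A full pedigree relationship matrix with id dimnames.
#' @param Gomega blended genomic matrix over the genotyped ids.
#' @param genotyped_ids character or integer ids of the genotyped animals.
#' @return Dense H in the original id order of `A`.
#' @export
build_H <- function(A, Gomega, genotyped_ids) {
  ids <- rownames(A)
  g <- as.character(genotyped_ids)
  assert_that(all(g %in% ids), "genotyped ids must appear in A")
  if (length(g) == 0L) return(A)
  ng <- setdiff(ids, g)
  A11 <- A[g, g, drop = FALSE]
  H <- A
  if (length(ng) == 0L) {
    H[g, g] <- Gomega[g, g]
    return(H)
  }
  A12 <- A[g, ng, drop = FALSE]
  A11i_A12 <- solve(A11, A12)
  Gw <- Gomega[g, g]
  H[g, g] <- Gw
  H12 <- Gw %*% A11i_A12
  H[g, ng] <- H12
  H[ng, g] <- t(H12)
  H[ng, ng] <- A[ng, ng] + crossprod(A11i_A12, (Gw - A11) %*% A11i_A12)
  H
}

#' Sparse single-step H inverse
#'
#' `H^-1 = A^-1 + [[G_omega^-1 - A11^-1, 0], [0, 0]]` on the genotyped block.
#' If the genomic block cannot be factorized, `1e-8` is added to its diagonal
#' (with a message); with the default blending weight this safeguard should
#' never trigger.
#'
#' @param Ainv sparse pedigree A-inverse with id dimnames.
#' @param Gomega blended genomic matrix over the genotyped ids.
#' @param A11 pedigree relationship block over the genotyped ids.
#' @param genotyped_ids ids of the genotyped animals.
#' @return Sparse symmetric H-inverse in the id order of `Ainv`.
#' @export
build_H_inverse <- function(Ainv, Gomega, A11, genotyped_ids) {
  ids <- rownames(Ainv)
  g <- as.character(genotyped_ids)
  assert_that(all(g %in% ids), "genotyped ids must appear in Ainv")
  if (length(g) == 0L) return(Ainv)
  Gw <- as.matrix(Gomega)[g, g, drop = FALSE]
  Gwi <- tryCatch(chol2inv(chol(Gw)), error = function(e) {
    message("genomic block not positive definite; adding 1e-8 to its diagonal")
    chol2inv(chol(Gw + diag(1e-8, nrow(Gw))))
  })
  A11i <- chol2inv(chol(as.matrix(A11)[g, g, drop = FALSE]))
  corr <- Gwi - A11i
  gi <- match(g, ids)
  n <- nrow(Ainv)
  corr_sp <- Matrix::sparseMatrix(
    i = rep(gi, each = length(gi)), j = rep(gi, times = length(gi)),
    x = as.vector(t(corr)), dims = c(n, n), dimnames = dimnames(Ainv)
  )
  Matrix::forceSymmetric(Ainv + corr_sp)
}

#' Relationship matrix inverse for a genotyping scenario
#'
#' Convenience wrapper for the single-step machinery: computes A-inverse and,
#' when any animal is genotyped, the VanRaden G over the genotyped subset,
#' its rescaling to the pedigree block, the omega-blend, and the sparse
#' H-inverse.  With nobody genotyped the result is A-inverse; with everybody
#' genotyped H-inverse equals the inverse of the blended genomic matrix.
#'
#' @param pedigree pedigree tibble (parents before offspring).
#' @param marker_dosages dosage matrix over the genotyped animals (rows named
#'   by id); may cover more animals than the mask.
#' @param genotyped_ids ids to treat as genotyped (possibly empty).
#' @param omega blending weight (default 0.2).
#' @return A list with `Kinv` (sparse), `kind` (`"A"` or `"H"`),
#'   `genotyped_ids`, and for genomic scenarios `Gomega` and `A11`.
#' @export
scenario_kinship <- function(pedigree, marker_dosages = NULL,
                             genotyped_ids = integer(0), omega = 0.2) {
  ped <- pedigree
  A <- build_A(ped)
  Ainv <- build_A_inverse(ped, F = diag(A) - 1)
  g <- as.character(genotyped_ids)
  if (length(g) == 0L)
    return(list(Kinv = Ainv, kind = "A", genotyped_ids = character(0), A = A))
  assert_that(!is.null(marker_dosages), "marker dosages required when genotyped")
  assert_that(all(g %in% rownames(marker_dosages)),
              "dosages missing for some genotyped ids")
  G <- build_G(marker_dosages[g, , drop = FALSE])
  A11 <- A[g, g, drop = FALSE]
  Gs <- adjust_G(G, A11)
  Gw <- blend_G(Gs, A11, omega)
  Hinv <- build_H_inverse(Ainv, Gw, A, g)
  list(Kinv = Hinv, kind = "H", genotyped_ids = g, A = A, Gomega = Gw,
       A11 = A11)
}
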