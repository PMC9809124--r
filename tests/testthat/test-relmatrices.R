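test_that("pedigree A reproduces textbook relationship values", {
  founders <- tibble::tibble(id = 1:3, sire = 0L, dam = 0L)
  expect_equal(unname(build_A(founders)), diag(3))
  ped <- ped6()
  A <- build_A(ped)
  expect_equal(A["1", "4"], 0.5)            # parent-offspring
  expect_equal(A["4", "5"], 0.25)           # half sibs (shared sire)
  # full sibs from non-inbred parents
  fs <- tibble::tibble(id = 1:4, sire = c(0L, 0L, 1L, 1L),
                       dam = c(0L, 0L, 2L, 2L))
  expect_equal(build_A(fs)["3", "4"], 0.5)
  # offspring of a mating between relatives with a(4,5) = 0.25: F = 0.125
  expect_equal(A["6", "6"], 1.125)
  expect_true(isSymmetric(A))
})

test_that("A equals the gene-dropping IBD expectation on random pedigrees", {
  for (seed in c(101, 202)) {
    ped <- random_pedigree(4, 6, seed)
    A <- build_A(ped)
    Ad <- gene_drop_A(ped, n_drop = 4000, seed = seed)
    expect_lt(max(abs(A - Ad)), 0.06)
  }
})

test_that("pedigree order is validated", {
  bad <- tibble::tibble(id = c(2L, 1L), sire = c(1L, 0L), dam = c(0L, 0L))
  expect_error(build_A(bad), "parents before")
})

test_that("Henderson A-inverse matches the dense inverse, with inbreeding", {
  ped <- ped6()
  expect_equal(max(abs(as.matrix(build_A_inverse(ped)) -
                         solve(build_A(ped)))), 0, tolerance = 1e-10)
  for (seed in c(7, 8)) {
    ped <- random_pedigree(4, 8, seed)
    expect_equal(max(abs(as.matrix(build_A_inverse(ped)) -
                           solve(build_A(ped)))), 0, tolerance = 1e-9)
  }
})

test_that("Meuwissen-Luo inbreeding equals the tabular diagonal", {
  for (seed in c(3, 4)) {
    ped <- random_pedigree(4, 10, seed)
    expect_equal(unname(inbreeding_coefficients(ped)),
                 unname(diag(build_A(ped)) - 1), tolerance = 1e-12)
  }
})

test_that("VanRaden G evaluates the closed-form example", {
  dos <- matrix(c(0L, 2L, 2L, 0L), 2, 2,
                dimnames = list(c("1", "2"), c("m1", "m2")))
  G <- build_G(dos, allele_freq = c(0.5, 0.5))
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2),
               ignore_attr = TRUE)
  # identical genotypes: equal rows and G_ij = G_ii
  dos2 <- rbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L), c = c(2L, 1L, 0L))
  G2 <- build_G(dos2)
  expect_equal(G2["a", ], G2["b", ])
  expect_equal(G2["a", "b"], G2["a", "a"])
  expect_error(build_G(matrix(rep(c(0L, 2L), each = 6), 3, 4)),
               "monomorphic")
})

test_that("G diagonal averages one under Hardy-Weinberg genotypes", {
  set.seed(15)
  p <- stats::runif(800, 0.1, 0.9)
  dos <- sapply(p, function(pp) stats::rbinom(300, 2, pp))
  rownames(dos) <- 1:300
  G <- build_G(dos, allele_freq = p)
  expect_equal(mean(diag(G)), 1, tolerance = 0.02)
})

test_that("G rescaling solves the two averaging constraints", {
  # Avg.diag(G) = 2, Avg.offdiag(G) = -2 against A11 = I: beta 0.25, alpha 0.5
  G <- matrix(c(2, -2, -2, 2), 2)
  Gs <- adjust_G(G, diag(2))
  expect_equal(attr(Gs, "beta"), 0.25)
  expect_equal(attr(Gs, "alpha"), 0.5)
  # fixed point: G already matching A11 averages
  A11 <- build_A(ped6())[4:6, 4:6]
  Gs2 <- adjust_G(A11, A11)
  expect_equal(attr(Gs2, "beta"), 1)
  expect_equal(attr(Gs2, "alpha"), 0, tolerance = 1e-14)
  # postcondition holds to machine precision on arbitrary input
  set.seed(16)
  Z <- matrix(rnorm(25), 5)
  Gr <- tcrossprod(Z) / 5
  A11r <- diag(5) + 0.1
  Gsr <- adjust_G(Gr, A11r)
  expect_equal(mean(diag(Gsr)), mean(diag(A11r)), tolerance = 1e-13)
  off <- function(M) (sum(M) - sum(diag(M))) / (nrow(M) * (nrow(M) - 1))
  expect_equal(off(Gsr), off(A11r), tolerance = 1e-13)
  expect_error(adjust_G(matrix(1, 2, 2) * 1.0, diag(2)), "singular")
})

test_that("blending behaves at its boundary weights and keeps PSD", {
  G <- matrix(c(1.2, 0.3, 0.3, 0.9), 2)
  A11 <- diag(2)
  expect_equal(blend_G(G, A11, 1), A11, ignore_attr = TRUE)
  expect_equal(blend_G(G, A11, 0), G, ignore_attr = TRUE)
  expect_equal(blend_G(A11, A11, 0.2), A11, ignore_attr = TRUE)
  # blended matrix stays PSD for omega > 0 with PSD A11
  set.seed(17)
  Z <- matrix(stats::rbinom(40 * 60, 2, 0.4), 40)
  rownames(Z) <- 1:40
  Gr <- build_G(Z)
  Gw <- blend_G(adjust_G(Gr, diag(40)), diag(40), 0.2)
  expect_gt(min(eigen(Gw, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
})

test_that("single-step H obeys its block structure and inverse identity", {
  ped <- ped6()
  A <- build_A(ped)
  g <- c("2", "4", "6")
  set.seed(18)
  dos <- matrix(stats::rbinom(3 * 40, 2, 0.5), 3, dimnames = list(g, NULL))
  Gw <- blend_G(adjust_G(build_G(dos), A[g, g]), A[g, g], 0.2)
  H <- build_H(A, Gw, g)
  # genotyped block equals G_omega exactly
  expect_equal(H[g, g], Gw[g, g], ignore_attr = TRUE)
  # dense block formula inverts the sparse single-step H-inverse
  Hinv <- build_H_inverse(build_A_inverse(ped), Gw, A, g)
  expect_lt(max(abs(solve(as.matrix(Hinv)) - H)), 1e-10)
  # no genomic information: H collapses to A
  expect_equal(build_H(A, Gw, character(0)), A)
  expect_equal(as.matrix(build_H_inverse(build_A_inverse(ped), Gw, A,
                                         character(0))),
               solve(A), ignore_attr = TRUE, tolerance = 1e-10)
  # genomic block equal to the pedigree block: H degenerates to A
  expect_equal(build_H(A, A[g, g], g), A, tolerance = 1e-12)
  # everyone genotyped: H equals G_omega
  gall <- rownames(A)
  dos_all <- matrix(stats::rbinom(6 * 40, 2, 0.5), 6,
                    dimnames = list(gall, NULL))
  Gw_all <- blend_G(adjust_G(build_G(dos_all), A), A, 0.2)
  expect_equal(build_H(A, Gw_all, gall), Gw_all, ignore_attr = TRUE)
})

test_that("scenario kinship wrapper picks A or H appropriately", {
  ped <- ped6()
  set.seed(19)
  dos <- matrix(stats::rbinom(6 * 30, 2, 0.5), 6,
                dimnames = list(as.character(1:6), NULL))
  k0 <- scenario_kinship(ped, dos, integer(0))
  expect_equal(k0$kind, "A")
  expect_equal(as.matrix(k0$Kinv), as.matrix(build_A_inverse(ped)),
               ignore_attr = TRUE)
  kall <- scenario_kinship(ped, dos, 1:6)
  expect_equal(kall$kind, "H")
  expect_equal(as.matrix(solve(as.matrix(kall$Kinv))),
               unname(as.matrix(kall$Gomega)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("relationship matrices round-trip through sparse text", {
  A <- build_A(ped6())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_relmat_file(A, path)
  back <- read_relmat_file(path)
  expect_equal(back[rownames(A), colnames(A)], A, ignore_attr = TRUE)
})
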