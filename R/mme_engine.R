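#' Assemble Henderson's mixed-model equations
#'
#' Builds the coefficient matrix and right-hand side for the maternal-effects
#' animal model `y = 1 mu + W l + Z_a a + Z_m m + e` with correlated direct
#' and maternal effects: `[a; m] ~ N(0, Gamma kron K)` where
#' `Gamma = [[sigma2_a, sigma_am], [sigma_am, sigma2_m]]`, litter effects
#' `l ~ N(0, I sigma2_l)` and heteroscedastic residuals
#' `e ~ N(0, diag(1/weights) * phi)`.
#'
#' The solution vector is ordered `[mu, l (n_litter), a (n_animal),
#' m (n_animal)]` with animals in pedigree order.
#'
#' @param y response (observed 0/1 or a working variate).
#' @param W,Za,Zm sparse incidence matrices (observations by litters/animals).
#' @param Kinv inverse relationship matrix (sparse or dense, animals in
#'   pedigree order).
#' @param vc named list/vector with `sigma2_l`, `sigma2_a`, `sigma2_m`,
#'   `sigma_am`, `sigma2_e`.
#' @param weights residual weights (default 1).
#' @param phi residual dispersion multiplying `1/weights` (for the identity
#'   link this is `sigma2_e`; for working-variate fits it is 1).
#' @return List with `C` (sparse coefficient matrix), `rhs`, and the index
#'   blocks `i_mu`, `i_l`, `i_a`, `i_m`.
#' @export
assemble_mme <- function(y, W, Za, Zm, Kinv, vc, weights = NULL, phi = NULL) {
  n_obs <- length(y)
  n_lit <- ncol(W)
  n_ani <- ncol(Za)
  assert_that(ncol(Zm) == n_ani, "Za and Zm must span the same animals")
  assert_that(nrow(Kinv) == n_ani, "Kinv dimension must match the animal count")
  weights <- weights %||% rep(1, n_obs)
  phi <- phi %||% vc$sigma2_e
  gam <- matrix(c(vc$sigma2_a, vc$sigma_am, vc$sigma_am, vc$sigma2_m), 2L)
  assert_that(det(gam) > 0 && vc$sigma2_a > 0 && vc$sigma2_m > 0,
              "genetic (co)variance matrix must be positive definite")
  gi <- solve(gam)

  r <- weights / phi
  X <- Matrix::Matrix(1, n_obs, 1, sparse = TRUE)
  T <- cbind(X, W, Za, Zm)
  Tr <- T * r  # row-scaled
  C <- Matrix::crossprod(T, Tr)
  rhs <- as.vector(Matrix::crossprod(Tr, y))

  C <- C + mme_ridge(n_lit, Kinv, vc)

  list(C = C, rhs = rhs, i_mu = 1L, i_l = 1L + seq_len(n_lit),
       i_a = 1L + n_lit + seq_len(n_ani),
       i_m = 1L + n_lit + n_ani + seq_len(n_ani))
}

# the data-independent penalty part of the MME coefficient matrix:
# block-diagonal [0, I/sigma2_l, Gamma^-1 kron Kinv]
mme_ridge <- function(n_lit, Kinv, vc) {
  gam <- matrix(c(vc$sigma2_a, vc$sigma_am, vc$sigma_am, vc$sigma2_m), 2L)
  gi <- solve(gam)
  Kinv <- methods::as(Matrix::Matrix(Kinv, sparse = TRUE), "generalMatrix")
  gen_block <- rbind(cbind(gi[1, 1] * Kinv, gi[1, 2] * Kinv),
                     cbind(gi[2, 1] * Kinv, gi[2, 2] * Kinv))
  Matrix::bdiag(Matrix::Matrix(0, 1, 1, sparse = TRUE),
                Matrix::Diagonal(n_lit, 1 / vc$sigma2_l),
                gen_block)
}

# solve a symmetric positive definite system; sparse Cholesky when the
# system is genuinely sparse (pedigree-only MME), dense Cholesky below
# `direct_max` equations, Jacobi-preconditioned conjugate gradients above
solve_spd <- function(C, rhs, direct_max = 5000, tol = 1e-10, x0 = NULL,
                      max_iter = 5000) {
  n <- length(rhs)
  density <- if (methods::is(C, "sparseMatrix"))
    length(C@x) / (as.numeric(n)^2) else 1
  if (density < 0.05) {
    Cs <- Matrix::forceSymmetric(C)
    ch <- tryCatch(Matrix::Cholesky(Cs, LDL = FALSE, perm = TRUE),
                   error = function(e) NULL)
    if (!is.null(ch))
      return(list(x = as.vector(Matrix::solve(ch, rhs)), method = "sparse",
                  iterations = 1L, rel_resid = 0))
  }
  if (n <= direct_max) {
    Cd <- as.matrix(C)
    ch <- tryCatch(chol(Cd), error = function(e)
      chol(Cd + diag(1e-10 * mean(diag(Cd)), n)))
    return(list(x = backsolve(ch, forwardsolve(t(ch), rhs)), method = "direct",
                iterations = 1L, rel_resid = 0))
  }
  pcg_solve(C, rhs, tol = tol, x0 = x0, max_iter = max_iter)
}

# Jacobi-preconditioned conjugate gradient for sparse SPD systems
pcg_solve <- function(C, b, tol = 1e-10, x0 = NULL, max_iter = 5000) {
  n <- length(b)
  Minv <- 1 / Matrix::diag(C)
  x <- x0 %||% numeric(n)
  r <- b - as.vector(C %*% x)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  for (it in seq_len(max_iter)) {
    Cp <- as.vector(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    rel <- sqrt(sum(r^2)) / bnorm
    if (rel < tol) {
      return(list(x = x, method = "pcg", iterations = it, rel_resid = rel))
    }
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  warning(sprintf("PCG did not reach tolerance %.1e (relative residual %.2e)",
                  tol, rel))
  list(x = x, method = "pcg", iterations = max_iter, rel_resid = rel)
}

# incidence matrices for a phenotype table against a pedigree
build_design <- function(phenotypes, pedigree) {
  ids <- pedigree$id
  n_obs <- nrow(phenotypes)
  ai <- match(phenotypes$id, ids)
  di <- match(pedigree$dam[ai], ids)
  assert_that(!anyNA(ai), "phenotyped animal not in pedigree")
  assert_that(!anyNA(di), "phenotyped animal without a pedigree dam")
  lit <- factor(phenotypes$litter)
  W <- Matrix::sparseMatrix(i = seq_len(n_obs), j = as.integer(lit), x = 1,
                            dims = c(n_obs, nlevels(lit)))
  Za <- Matrix::sparseMatrix(i = seq_len(n_obs), j = ai, x = 1,
                             dims = c(n_obs, length(ids)))
  Zm <- Matrix::sparseMatrix(i = seq_len(n_obs), j = di, x = 1,
                             dims = c(n_obs, length(ids)))
  list(W = W, Za = Za, Zm = Zm, litter_levels = levels(lit), animal_ids = ids)
}

#' Fit the maternal-effects animal model
#'
#' Solves the mixed-model equations for the binary survival trait under an
#' identity (linear model), logit, or probit link.  The identity link is a
#' single BLUP solve on the observed 0/1 scale; logit and probit use
#' penalized quasi-likelihood, iterating a working variate and binomial
#' weights around the linear solve until the solutions stabilise.  Breeding
#' values are returned for every animal in the pedigree, genotyped or not.
#'
#' @param phenotypes tibble with columns `id`, `litter`, `y` (0/1).
#' @param pedigree pedigree tibble (parents before offspring); defines the
#'   animal order and the dam links for maternal effects.
#' @param vc variance components (named list or `surv_vc`): `sigma2_l`,
#'   `sigma2_a`, `sigma2_m`, `sigma_am`, `sigma2_e`.
#' @param link `"identity"`, `"logit"`, or `"probit"`.
#' @param Kinv inverse relationship matrix over the pedigree (defaults to the
#'   pedigree A-inverse).
#' @param max_iter maximum PQL iterations (identity link: 1).
#' @param tol relative-change convergence tolerance for the PQL solutions.
#' @return An object of class `surv_fit` with elements `mu`, `litter`
#'   (tibble), `ebv` (tibble: id, generation, ebv_a, ebv_m, ebv_total),
#'   `link`, `vc`, `converged`, `iterations`, `solver`.
#' @export
fit_survival_model <- function(phenotypes, pedigree, vc,
                               link = c("identity", "logit", "probit"),
                               Kinv = NULL, max_iter = 50, tol = 1e-8) {
  link <- match.arg(link)
  assert_that(all(phenotypes$y %in% c(0, 1)), "y must be binary 0/1")
  if (is.null(Kinv)) Kinv <- build_A_inverse(pedigree)
  des <- build_design(phenotypes, pedigree)
  y <- phenotypes$y
  n_obs <- length(y)
  vc <- as_vc_list(vc)

  if (link == "identity") {
    sys <- assemble_mme(y, des$W, des$Za, des$Zm, Kinv, vc)
    sol <- solve_spd(sys$C, sys$rhs)
    out <- make_surv_fit(sol$x, sys, des, pedigree, link, vc,
                         converged = TRUE, iterations = 1L,
                         solver = sol$method)
    return(out)
  }

  # PQL for logit/probit
  linkfun <- switch(link, logit = stats::qlogis, probit = stats::qnorm)
  linkinv <- switch(link, logit = stats::plogis, probit = stats::pnorm)
  dmu_deta <- switch(link,
    logit = function(eta) {
      m <- stats::plogis(eta); pmax(m * (1 - m), 1e-10)
    },
    probit = function(eta) pmax(stats::dnorm(eta), 1e-10)
  )

  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  if (p0 %in% c(1e-6, 1 - 1e-6))
    warning("complete separation: all responses equal; intercept capped")
  eta <- rep(linkfun(p0), n_obs)
  T <- cbind(Matrix::Matrix(1, n_obs, 1, sparse = TRUE), des$W, des$Za, des$Zm)
  ridge <- mme_ridge(ncol(des$W), Kinv, vc)
  n_lit <- ncol(des$W); n_ani <- ncol(des$Za)
  sys <- list(i_mu = 1L, i_l = 1L + seq_len(n_lit),
              i_a = 1L + n_lit + seq_len(n_ani),
              i_m = 1L + n_lit + n_ani + seq_len(n_ani))
  sol_x <- NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    mu <- pmin(pmax(linkinv(eta), 1e-8), 1 - 1e-8)
    dd <- dmu_deta(eta)
    w <- dd^2 / (mu * (1 - mu))
    z <- eta + (y - mu) / dd
    Tr <- T * w
    C <- Matrix::crossprod(T, Tr) + ridge
    rhs <- as.vector(Matrix::crossprod(Tr, z))
    sol <- solve_spd(C, rhs, x0 = sol_x)
    x_new <- sol$x
    if (!is.null(sol_x)) {
      rel <- max(abs(x_new - sol_x)) / max(1, max(abs(x_new)))
      if (rel < tol) {
        sol_x <- x_new
        converged <- TRUE
        break
      }
    }
    sol_x <- x_new
    eta <- as.vector(T %*% sol_x)
  }
  if (!converged && max_iter > 1L)
    warning(sprintf("PQL did not converge in %d iterations", max_iter))
  make_surv_fit(sol_x, sys, des, pedigree, link, vc, converged = converged,
                iterations = it, solver = sol$method)
}

as_vc_list <- function(vc) {
  if (inherits(vc, "surv_vc")) vc <- as.list(vc$estimates)
  vc <- as.list(vc)
  need <- c("sigma2_l", "sigma2_a", "sigma2_m", "sigma_am", "sigma2_e")
  assert_that(all(need %in% names(vc)),
              paste("vc must contain", paste(need, collapse = ", ")))
  vc
}

make_surv_fit <- function(x, sys, des, pedigree, link, vc, converged,
                          iterations, solver) {
  structure(list(
    mu = x[sys$i_mu],
    litter = tibble::tibble(litter = des$litter_levels, effect = x[sys$i_l]),
    ebv = tibble::tibble(
      id = pedigree$id,
      generation = pedigree$generation %||% NA_integer_,
      ebv_a = x[sys$i_a],
      ebv_m = x[sys$i_m],
      ebv_total = x[sys$i_a] + x[sys$i_m]
    ),
    link = link, vc = vc, converged = converged, iterations = iterations,
    solver = solver, n_obs = nrow(des$W), n_eq = length(x)
  ), class = "surv_fit")
}

#' @rdname fit_survival_model
#' @param ... passed on to [fit_survival_model()].
#' @export
fit_linear <- function(phenotypes, pedigree, vc, ...) {
  fit_survival_model(phenotypes, pedigree, vc, link = "identity", ...)
}

#' @rdname fit_survival_model
#' @export
fit_glmm <- function(phenotypes, pedigree, vc, link = c("logit", "probit"),
                     ...) {
  link <- match.arg(link)
  fit_survival_model(phenotypes, pedigree, vc, link = link, ...)
}

#' @export
print.surv_fit <- function(x, ...) {
  cat("<surv_fit> link =", x$link, "|", x$n_obs, "observations,",
      nrow(x$ebv), "animals\n")
  cat("  mu =", format(x$mu, digits = 4),
      if (x$link != "identity") sprintf("(%d PQL iterations%s)", x$iterations,
        if (x$converged) "" else ", NOT converged") else "", "\n")
  invisible(x)
}
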