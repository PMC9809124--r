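#' Estimate variance components by AI-REML
#'
#' Restricted maximum likelihood for the maternal-effects animal model, using
#' average-information (Newton-type) updates on the parameter vector
#' `(sigma2_l, sigma2_a, sigma2_m, sigma_am, sigma2_e)`.  The likelihood is
#' evaluated in observation space: `V = sigma2_l M_l + sigma2_a M_a +
#' sigma_am (M_am + M_am') + sigma2_m M_m + sigma2_e D`, where the `M`
#' matrices are relationship blocks induced by the design and `D` carries
#' residual weights.  The AI step is blended with an
#' expectation-maximisation step on the first iterations (30 percent EM
#' weight) and falls back to EM updates whenever an AI step leaves the
#' parameter space; the direct-maternal covariance is kept inside the
#' positive-definite cone.
#'
#' For the logit and probit links the estimation runs penalized
#' quasi-likelihood outer iterations: the model is fitted at the current
#' components, a working variate and binomial weights are formed at the
#' fitted values, and REML is applied to the working variate with the
#' residual dispersion fixed at 1 (so components are on the link scale).
#' Reported link-scale heritabilities use the conventional implicit residual
#' variance pi^2/3 (logit) or 1 (probit).
#'
#' @param phenotypes tibble with `id`, `litter`, `y`.
#' @param pedigree pedigree tibble (parents before offspring).
#' @param link `"identity"`, `"logit"`, or `"probit"`.
#' @param K optional dense relationship matrix over all pedigree animals
#'   (defaults to the pedigree A).  Supplying a single-step H here reproduces
#'   genomic REML.
#' @param Kinv optional inverse of `K` for the PQL fitting step (computed if
#'   missing).
#' @param start optional named starting values.
#' @param free named logical vector saying which of the five parameters are
#'   estimated; fixed parameters keep their starting value.  The residual is
#'   always fixed for logit/probit.
#' @param max_iter,tol_loglik,tol_par convergence controls: stop when both
#'   the log-likelihood change and the maximum relative parameter change fall
#'   below the tolerances.
#' @param n_outer outer PQL rounds for the non-identity links.
#' @param verbose print the iteration trajectory.
#' @return An object of class `surv_vc`: list with `estimates` (named
#'   vector), `se`, `h2` (litter proportion, direct and maternal heritability,
#'   `r_am` on the model's scale), `loglik`, `trajectory`, `converged`,
#'   `n_iter`, `link`, `boundary` flags.
#' @export
estimate_varcomps_aireml <- function(phenotypes, pedigree,
                                     link = c("identity", "logit", "probit"),
                                     K = NULL, Kinv = NULL, start = NULL,
                                     free = NULL, max_iter = 50,
                                     tol_loglik = 1e-6, tol_par = 1e-6,
                                     n_outer = 4, verbose = FALSE) {
  link <- match.arg(link)
  if (link != "identity")
    assert_that(all(phenotypes$y %in% c(0, 1)),
                "y must be binary 0/1 for the logit and probit links")
  ped <- pedigree
  K_supplied <- !is.null(K)
  if (is.null(K)) K <- build_A(ped)
  assert_that(nrow(K) == nrow(ped), "K must cover the whole pedigree")

  # relationship blocks over the observations
  ids <- ped$id
  ia <- match(phenotypes$id, ids)
  im <- match(ped$dam[ia], ids)
  assert_that(!anyNA(ia) && !anyNA(im), "phenotypes must map to pedigree ids and dams")
  M_a <- K[ia, ia, drop = FALSE]
  M_m <- K[im, im, drop = FALSE]
  M_am0 <- K[ia, im, drop = FALSE]
  M_am <- M_am0 + t(M_am0)
  lit <- as.integer(factor(phenotypes$litter))
  M_l <- outer(lit, lit, "==") * 1
  y <- phenotypes$y

  par_names <- c("sigma2_l", "sigma2_a", "sigma2_m", "sigma_am", "sigma2_e")
  free_v <- stats::setNames(rep(TRUE, 5L), par_names)
  if (!is.null(free)) free_v[names(free)] <- free
  if (link != "identity") free_v["sigma2_e"] <- FALSE

  v0 <- stats::var(y)
  if (link != "identity") v0 <- switch(link, logit = pi^2 / 3, probit = 1)
  default_start <- c(sigma2_l = 0.1 * v0, sigma2_a = 0.1 * v0,
                     sigma2_m = 0.1 * v0,
                     sigma_am = 0.03 * v0, sigma2_e = 0.7 * v0)
  if (link != "identity") default_start["sigma2_e"] <- 1
  theta <- default_start
  if (!is.null(start)) theta[names(start)] <- unlist(start)

  q_lev <- c(sigma2_l = length(unique(lit)),
             sigma2_a = length(unique(c(ia, im))),
             sigma2_m = length(unique(c(ia, im))),
             sigma_am = length(unique(c(ia, im))),
             sigma2_e = length(y))

  if (link == "identity") {
    res <- reml_core(y, M_l, M_a, M_m, M_am, D = rep(1, length(y)),
                     theta = theta, free = free_v, q_lev = q_lev,
                     max_iter = max_iter,
                     tol_loglik = tol_loglik, tol_par = tol_par,
                     verbose = verbose)
  } else {
    if (is.null(Kinv)) {
      Kinv <- if (K_supplied) solve(K) else build_A_inverse(ped)
    }
    res <- NULL
    for (outer in seq_len(n_outer)) {
      fit <- fit_survival_model(phenotypes, ped, as_vc_list(as.list(theta)),
                                link = link, Kinv = Kinv)
      eta <- fitted_eta(fit, phenotypes, ped)
      mu <- pmin(pmax(if (link == "logit") stats::plogis(eta) else
        stats::pnorm(eta), 1e-8), 1 - 1e-8)
      dd <- if (link == "logit") pmax(mu * (1 - mu), 1e-10) else
        pmax(stats::dnorm(eta), 1e-10)
      w <- dd^2 / (mu * (1 - mu))
      z <- eta + (y - mu) / dd
      theta_old <- theta
      # the working variate is refreshed every outer round, so the inner
      # REML only needs to be solved to moderate depth before re-linearising
      res <- reml_core(z, M_l, M_a, M_m, M_am, D = 1 / w, theta = theta,
                       free = free_v, q_lev = q_lev,
                       max_iter = min(max_iter, 25),
                       tol_loglik = tol_loglik, tol_par = tol_par,
                       verbose = verbose)
      theta <- res$theta
      rel <- max(abs(theta - theta_old) / pmax(abs(theta_old), 1e-8))
      if (rel < 1e-3) break
    }
  }

  est <- res$theta
  resid_link <- switch(link, identity = est[["sigma2_e"]],
                       logit = pi^2 / 3, probit = 1)
  denom <- est[["sigma2_l"]] + est[["sigma2_a"]] + est[["sigma2_m"]] +
    resid_link
  h2 <- c(lit2 = est[["sigma2_l"]] / denom,
          h2_a = est[["sigma2_a"]] / denom,
          h2_m = est[["sigma2_m"]] / denom,
          r_am = est[["sigma_am"]] /
            sqrt(est[["sigma2_a"]] * est[["sigma2_m"]]))
  structure(list(
    estimates = est, se = res$se, h2 = h2, loglik = res$loglik,
    trajectory = res$trajectory, converged = res$converged,
    n_iter = res$n_iter, link = link, boundary = res$boundary,
    n_obs = length(y)
  ), class = "surv_vc")
}

# linear predictor of a fit for given observations
fitted_eta <- function(fit, phenotypes, pedigree) {
  li <- match(as.character(phenotypes$litter), fit$litter$litter)
  ai <- match(phenotypes$id, fit$ebv$id)
  di <- match(pedigree$dam[match(phenotypes$id, pedigree$id)], fit$ebv$id)
  fit$mu + fit$litter$effect[li] + fit$ebv$ebv_a[ai] + fit$ebv$ebv_m[di]
}

# AI-REML core on a working response with fixed derivative matrices
reml_core <- function(y, M_l, M_a, M_m, M_am, D, theta, free, q_lev,
                      max_iter = 50,
                      tol_loglik = 1e-6, tol_par = 1e-6, em_iters = 3,
                      em_weight = 0.3, verbose = FALSE) {
  n <- length(y)
  Dm <- diag(D, n)
  V_list <- list(sigma2_l = M_l, sigma2_a = M_a, sigma2_m = M_m,
                 sigma_am = M_am, sigma2_e = Dm)
  X <- matrix(1, n, 1)
  par_names <- names(theta)
  free_idx <- which(free)
  boundary <- stats::setNames(rep(FALSE, 5L), par_names)
  lower <- 1e-8 * max(stats::var(y), 1e-8)

  # restricted log-likelihood, score and average-information at a point
  eval_point <- function(th, need_grad = TRUE) {
    V <- th[["sigma2_l"]] * M_l + th[["sigma2_a"]] * M_a +
      th[["sigma2_m"]] * M_m + th[["sigma_am"]] * M_am +
      th[["sigma2_e"]] * Dm
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      V <- V + diag(1e-8 * mean(diag(V)), n)
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
    }
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    XVX <- XtVi %*% X
    P <- Vi - crossprod(XtVi, solve(XVX, XtVi))
    Py <- as.vector(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XVX)$modulus[1] +
                    sum(y * Py))
    if (!need_grad) return(list(ll = ll))
    U <- vapply(V_list[free_idx], function(Vk) as.vector(Vk %*% Py),
                numeric(n))
    PU <- P %*% U
    quad <- as.vector(crossprod(U, Py))
    trPV <- vapply(V_list[free_idx], function(Vk) sum(P * Vk), numeric(1))
    list(ll = ll, score = 0.5 * (quad - trPV), AI = 0.5 * crossprod(U, PU),
         quad = quad, trPV = trPV)
  }

  # project a proposal into the parameter space (variances positive, genetic
  # covariance inside the PD cone); EM values replace negative variances
  guard <- function(prop, em) {
    vari <- c("sigma2_l", "sigma2_a", "sigma2_m", "sigma2_e")
    bad <- vari[prop[vari] < lower & free[vari]]
    if (length(bad) > 0L) {
      prop[bad] <- pmax(em[bad], lower)
      boundary[bad] <<- prop[bad] <= lower * 1.01
    }
    # keep the direct-maternal correlation strictly inside the PD cone; 0.98
    # bounds the condition number of the 2x2 genetic covariance so that
    # downstream mixed-model equations stay well conditioned when the
    # correlation is weakly identified
    bound_am <- 0.98 * sqrt(prop[["sigma2_a"]] * prop[["sigma2_m"]])
    if (abs(prop[["sigma_am"]]) > bound_am) {
      prop[["sigma_am"]] <- sign(prop[["sigma_am"]]) * bound_am
      boundary["sigma_am"] <<- TRUE
    }
    prop
  }

  cur <- eval_point(theta)
  assert_that(!is.null(cur), "V not positive definite at the starting values")
  traj <- list(c(loglik = cur$ll, theta))
  converged <- FALSE
  lambda <- 0
  it <- 0L
  n_stall <- 0L
  for (it in seq_len(max_iter)) {
    if (verbose)
      message(sprintf("it %d  ll=%.6f  lambda=%.1e  %s", it, cur$ll, lambda,
                      paste(sprintf("%s=%.5g", par_names, theta),
                            collapse = " ")))
    # EM reference step (guaranteed uphill direction component-wise)
    em <- theta
    for (k in free_idx) {
      nm <- par_names[k]
      if (nm == "sigma_am") next
      i <- match(k, free_idx)
      em[k] <- theta[k] + theta[k]^2 * (cur$quad[i] - cur$trPV[i]) / q_lev[nm]
    }
    accepted <- FALSE
    prop <- theta
    nxt <- NULL
    for (try in 1:12) {
      damp <- diag(lambda * pmax(diag(cur$AI), 1e-12),
                   nrow = length(free_idx))
      step <- tryCatch(solve(cur$AI + damp, cur$score), error = function(e)
        cur$score / pmax(diag(cur$AI), 1e-12))
      prop <- theta
      prop[free_idx] <- theta[free_idx] + step
      if (length(traj) <= em_iters)
        prop[free_idx] <- (1 - em_weight) * prop[free_idx] +
          em_weight * em[free_idx]
      prop <- guard(prop, em)
      nxt <- eval_point(prop)
      if (!is.null(nxt) && nxt$ll >= cur$ll - 1e-10) {
        accepted <- TRUE
        lambda <- lambda / 10
        break
      }
      lambda <- if (lambda == 0) 0.01 else lambda * 10
    }
    if (!accepted) {
      # damped AI exhausted: try a pure EM step
      prop <- guard(em, em)
      nxt <- eval_point(prop)
      if (is.null(nxt) || nxt$ll < cur$ll - 1e-10) {
        converged <- TRUE  # no uphill move found; treat as stationary
        break
      }
    }
    # parameter changes are judged relative to the parameter itself or, for
    # components pinned near zero, to the overall variance scale
    scale_ref <- 1e-4 * max(sum(abs(theta[free_idx])), 1e-8)
    rel_change <- max(abs(prop - theta) / pmax(abs(theta), scale_ref))
    dll <- nxt$ll - cur$ll
    theta <- prop
    cur <- nxt
    traj[[length(traj) + 1L]] <- c(loglik = cur$ll, theta)
    n_stall <- if (abs(dll) < tol_loglik) n_stall + 1L else 0L
    if ((abs(dll) < tol_loglik && rel_change < tol_par) || n_stall >= 3L) {
      converged <- TRUE
      break
    }
  }
  se <- stats::setNames(rep(NA_real_, 5L), par_names)
  Vai <- tryCatch(solve(cur$AI), error = function(e) NULL)
  if (!is.null(Vai)) se[free_idx] <- sqrt(pmax(diag(Vai), 0))
  list(theta = theta, se = se, loglik = cur$ll,
       trajectory = do.call(rbind, traj),
       converged = converged, n_iter = it, boundary = boundary)
}

#' @export
print.surv_vc <- function(x, ...) {
  cat("<surv_vc> link =", x$link,
      if (x$converged) sprintf("(converged in %d iterations)", x$n_iter)
      else sprintf("(NOT converged after %d iterations)", x$n_iter), "\n")
  print(round(x$estimates, 6))
  cat("h2:", paste(sprintf("%s=%.4f", names(x$h2), x$h2), collapse = "  "),
      "\n")
  invisible(x)
}

#' Heritability transformations between observed and liability scale
#'
#' For a binary trait created by truncating a normal liability at survival
#' fraction `p`, observed-scale and liability-scale heritability are linked
#' by `h2_obs = h2_liab * z^2 / (p (1 - p))` with `z` the standard normal
#' density at the truncation threshold.  At `p = 0.8` the factor is 0.49, so a
#' liability heritability of 0.04 appears as about 0.020 on the 0/1 scale.
#'
#' @param h2 heritability on the input scale.
#' @param p survival fraction (proportion of ones), strictly inside (0, 1).
#' @return The transformed heritability.
#' @export
h2_liability_to_observed <- function(h2, p) {
  assert_that(p > 0 && p < 1, "p must be strictly between 0 and 1")
  z <- stats::dnorm(stats::qnorm(p))
  h2 * z^2 / (p * (1 - p))
}

#' Map observed-scale variance components to a link scale
#'
#' Starting values for link-scale REML derived from observed-scale (0/1)
#' estimates via the liability threshold transform: components are divided by
#' the squared normal density at the truncation point (observed to liability/
#' probit scale) and, for the logit link, additionally multiplied by its
#' implicit residual variance pi^2/3.
#'
#' @param vc a `surv_vc` from an identity-link fit (or a named list of
#'   components on the observed scale).
#' @param link `"logit"` or `"probit"`.
#' @param p survival fraction used for the threshold transform.
#' @return Named list of starting values on the link scale.
#' @export
link_scale_start <- function(vc, link = c("logit", "probit"), p = 0.8) {
  link <- match.arg(link)
  est <- if (inherits(vc, "surv_vc")) as.list(vc$estimates) else as.list(vc)
  z2 <- stats::dnorm(stats::qnorm(p))^2
  k <- switch(link, probit = 1, logit = pi^2 / 3) / z2
  list(sigma2_l = est$sigma2_l * k, sigma2_a = est$sigma2_a * k,
       sigma2_m = est$sigma2_m * k, sigma_am = est$sigma_am * k,
       sigma2_e = switch(link, probit = 1, logit = pi^2 / 3))
}

#' @rdname h2_liability_to_observed
#' @export
h2_observed_to_liability <- function(h2, p) {
  assert_that(p > 0 && p < 1, "p must be strictly between 0 and 1")
  z <- stats::dnorm(stats::qnorm(p))
  h2 * p * (1 - p) / z^2
}
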