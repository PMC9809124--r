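#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted survival animal model
#'
#' @param x a `surv_fit`.
#' @param ... unused.
#' @return The EBV tibble: one row per pedigree animal with `id`,
#'   `generation`, `ebv_a`, `ebv_m`, `ebv_total`.
#' @exportS3Method generics::tidy
tidy.surv_fit <- function(x, ...) {
  x$ebv
}

#' @rdname tidy.surv_fit
#' @return `glance()` returns a one-row tibble with the link, intercept,
#'   problem sizes and convergence state.
#' @exportS3Method generics::glance
glance.surv_fit <- function(x, ...) {
  tibble::tibble(link = x$link, mu = x$mu, n_obs = x$n_obs, n_eq = x$n_eq,
                 iterations = x$iterations, converged = x$converged,
                 solver = x$solver)
}

#' Tidy REML variance component estimates
#'
#' @param x a `surv_vc`.
#' @param ... unused.
#' @return Tibble with one row per component: `component`, `estimate`, `se`,
#'   `boundary`.
#' @exportS3Method generics::tidy
tidy.surv_vc <- function(x, ...) {
  tibble::tibble(component = names(x$estimates),
                 estimate = unname(x$estimates),
                 se = unname(x$se[names(x$estimates)]),
                 boundary = unname(x$boundary[names(x$estimates)]))
}

#' @rdname tidy.surv_vc
#' @exportS3Method generics::glance
glance.surv_vc <- function(x, ...) {
  tibble::tibble(link = x$link, loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, n_obs = x$n_obs,
                 h2_a = x$h2[["h2_a"]], h2_m = x$h2[["h2_m"]],
                 lit2 = x$h2[["lit2"]], r_am = x$h2[["r_am"]])
}

#' Tidy an experiment
#'
#' @param x a `pig_experiment`.
#' @param ... unused.
#' @return The tidy results tibble (one row per replicate x scenario x model
#'   x metric x effect).
#' @exportS3Method generics::tidy
tidy.pig_experiment <- function(x, ...) {
  x$results
}

#' @rdname tidy.pig_experiment
#' @exportS3Method generics::glance
glance.pig_experiment <- function(x, ...) {
  acc <- x$results[x$results$metric == "accuracy" &
                     x$results$effect == "total", ]
  tibble::tibble(
    trait = x$config$trait,
    n_replicates = x$config$n_replicates,
    n_scenarios = length(x$config$scenarios),
    n_models = length(x$config$models),
    mean_accuracy_total = mean(acc$value)
  )
}
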