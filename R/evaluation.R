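#' Accuracy of genomic prediction
#'
#' Pearson correlation between estimated and true breeding values over a
#' validation set, computed separately for the direct effect, the maternal
#' effect, and their sum.
#'
#' @param ebv tibble with `id`, `ebv_a`, `ebv_m`, `ebv_total` (e.g.
#'   `fit$ebv`).
#' @param tbv tibble with `id`, `tbv_a`, `tbv_m`.
#' @param ids validation ids (default: all ids present in both).
#' @return Tibble with columns `effect` (`"a"`, `"m"`, `"total"`) and
#'   `accuracy`.
#' @export
prediction_accuracy <- function(ebv, tbv, ids = NULL) {
  ids <- ids %||% intersect(ebv$id, tbv$id)
  assert_that(length(ids) >= 3, "need at least 3 validation individuals")
  e <- ebv[match(ids, ebv$id), ]
  t <- tbv[match(ids, tbv$id), ]
  pairs <- list(a = cbind(e$ebv_a, t$tbv_a),
                m = cbind(e$ebv_m, t$tbv_m),
                total = cbind(e$ebv_total, t$tbv_a + t$tbv_m))
  acc <- vapply(pairs, function(p) {
    assert_that(stats::sd(p[, 1]) > 0 && stats::sd(p[, 2]) > 0,
                "constant EBV or TBV vector; accuracy undefined")
    stats::cor(p[, 1], p[, 2])
  }, numeric(1))
  tibble::tibble(effect = names(acc), accuracy = unname(acc))
}

#' Dispersion-bias regression slope
#'
#' Ordinary least-squares slope of the whole-data EBV (all phenotypes, all
#' animals genotyped) on the reference-data EBV for the same validation
#' individuals.  A slope of 1 indicates unbiased dispersion; the comparison
#' uses the fuller EBV rather than the true breeding value because the EBV
#' scale differs from the liability scale under the observed-scale and link
#' models.
#'
#' @param ebv_whole,ebv_reference numeric vectors over the same validation
#'   individuals (same order).
#' @return The regression slope (scalar).
#' @export
dispersion_slope <- function(ebv_whole, ebv_reference) {
  assert_that(length(ebv_whole) == length(ebv_reference),
              "EBV vectors must have equal length")
  v <- stats::var(ebv_reference)
  assert_that(v > 0, "reference EBV has zero variance; slope undefined")
  stats::cov(ebv_whole, ebv_reference) / v
}

#' Realized selection differential
#'
#' Selects the `ceiling(fraction * n)` validation individuals with the
#' highest total EBV and returns the mean true breeding value (direct,
#' maternal, total) of the selected group.  One percent mimics boar
#' selection intensity, thirty percent sow selection.
#'
#' @param ebv tibble with `id`, `ebv_total`.
#' @param tbv tibble with `id`, `tbv_a`, `tbv_m`.
#' @param fraction selected fraction, e.g. 0.01 or 0.30.
#' @param ids candidate ids (default: all in `ebv`).
#' @return Tibble with `effect` and `mean_tbv` plus attribute `n_selected`.
#' @export
selection_differential <- function(ebv, tbv, fraction, ids = NULL) {
  ids <- ids %||% ebv$id
  n_sel <- ceiling(fraction * length(ids))
  assert_that(n_sel >= 1, "selection fraction leaves nobody selected")
  e <- ebv[match(ids, ebv$id), ]
  ord <- order(-e$ebv_total, e$id)
  sel_ids <- e$id[ord[seq_len(n_sel)]]
  t <- tbv[match(sel_ids, tbv$id), ]
  out <- tibble::tibble(
    effect = c("a", "m", "total"),
    mean_tbv = c(mean(t$tbv_a), mean(t$tbv_m), mean(t$tbv_a + t$tbv_m))
  )
  attr(out, "n_selected") <- n_sel
  out
}

#' Paired t-test with degenerate-case conventions
#'
#' Classical paired t statistic `t = mean(d) / (sd(d) / sqrt(n))`.  Two
#' degenerate cases are resolved by convention: identical vectors give
#' `t = 0, p = 1`; nonzero constant differences give an infinite statistic
#' and `p = 0`, flagged as degenerate.
#'
#' @param x,y paired numeric vectors (e.g. per-replicate accuracies of two
#'   scenarios).
#' @return Tibble with `estimate` (mean difference), `statistic`, `p_value`,
#'   `df`, `degenerate`.
#' @export
paired_t_test <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 2,
              "need at least two paired replicates")
  d <- x - y
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (all(d == 0))
      return(tibble::tibble(estimate = 0, statistic = 0, p_value = 1,
                            df = n - 1, degenerate = TRUE))
    return(tibble::tibble(estimate = mean(d),
                          statistic = sign(mean(d)) * Inf, p_value = 0,
                          df = n - 1, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(estimate = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value, df = unname(tt$parameter),
                 degenerate = FALSE)
}

#' Significance grouping letters for ordered means
#'
#' Assigns compact letters to groups from pairwise paired t-tests at a given
#' alpha, assuming differences are monotone in the group means (the usual
#' situation for scenario comparisons): groups are sorted by mean and letters
#' cover maximal consecutive runs with no significant internal pair.
#'
#' @param values matrix or data frame: one column per group, one row per
#'   replicate.
#' @param alpha significance level (default 0.05, no multiplicity
#'   correction).
#' @return Named character vector of letters per group (original column
#'   order).
#' @export
significance_letters <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  k <- ncol(values)
  if (k == 1L) return(stats::setNames("a", colnames(values)))
  means <- colMeans(values)
  ord <- order(-means)
  p <- matrix(1, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      p[i, j] <- p[j, i] <- paired_t_test(values[, ord[i]],
                                          values[, ord[j]])$p_value
    }
  }
  # for each sorted group, the furthest group it does not differ from
  ends <- vapply(seq_len(k), function(i) {
    j <- i
    while (j < k && p[i, j + 1] >= alpha) j <- j + 1L
    j
  }, integer(1))
  runs <- lapply(seq_len(k), function(i) i:ends[i])
  # drop runs contained in an earlier, longer run
  keep <- vapply(seq_len(k), function(i) {
    !any(vapply(seq_len(k), function(j) j != i &&
                  runs[[i]][1] >= runs[[j]][1] &&
                  ends[i] <= ends[j] &&
                  length(runs[[j]]) > length(runs[[i]]), logical(1)))
  }, logical(1))
  runs <- unique(runs[keep])
  letters_out <- rep("", k)
  for (r in seq_along(runs)) {
    letters_out[runs[[r]]] <- paste0(letters_out[runs[[r]]], letters[r])
  }
  out <- stats::setNames(rep("", k), colnames(values))
  out[ord] <- letters_out
  out
}
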