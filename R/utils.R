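# internal helpers

.pkg_cache <- new.env(parent = emptyenv())

`%||%` <- function(x, y) if (is.null(x)) y else x

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}

# deterministic sub-seed stream derived from one master seed; kept < 2^31
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 100003 + 17) %%
    2147483587)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == round(x)
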