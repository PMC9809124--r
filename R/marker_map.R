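#' Build a marker and QTL map
#'
#' Lays out a genome of `n_chr` chromosomes of `chr_length_cm` centimorgans
#' each.  Markers are equally spaced along every chromosome; QTL positions are
#' drawn uniformly and kept distinct from marker positions, so a locus is
#' either a neutral marker (used for the genomic relationship matrix) or a
#' causal QTL (used for true breeding values), never both.
#'
#' @param n_chr number of chromosomes.
#' @param markers_per_chr markers per chromosome.
#' @param qtl_per_chr QTLs per chromosome.
#' @param chr_length_cm chromosome length in centimorgans.
#' @param seed optional integer seed for the QTL placement.
#'
#' @return A tibble with one row per locus and columns `chr`, `locus_id`,
#'   `pos_cm`, `class` (`"marker"` or `"qtl"`), ordered by chromosome and
#'   position.
#' @export
sim_marker_map <- function(n_chr = 18, markers_per_chr = 3100,
                           qtl_per_chr = 50, chr_length_cm = 100,
                           seed = NULL) {
  assert_that(is_count(n_chr), "n_chr must be a positive integer")
  assert_that(is_count(markers_per_chr), "markers_per_chr must be positive")
  assert_that(is_count(qtl_per_chr), "qtl_per_chr must be positive")
  assert_that(chr_length_cm >= 0, "chr_length_cm must be non-negative")
  set_seed_if(seed)

  per_chr <- lapply(seq_len(n_chr), function(ch) {
    mpos <- if (markers_per_chr == 1L) chr_length_cm / 2 else
      seq(0, chr_length_cm, length.out = markers_per_chr)
    qpos <- stats::runif(qtl_per_chr, 0, chr_length_cm)
    while (anyDuplicated(c(mpos, qpos)) > 0L) {
      dup <- duplicated(c(mpos, qpos))[markers_per_chr + seq_len(qtl_per_chr)]
      qpos[dup] <- stats::runif(sum(dup), 0, chr_length_cm)
    }
    tibble::tibble(
      chr = ch,
      pos_cm = c(mpos, qpos),
      class = rep(c("marker", "qtl"), c(markers_per_chr, qtl_per_chr))
    )
  })
  map <- dplyr::bind_rows(per_chr)
  map <- dplyr::arrange(map, .data$chr, .data$pos_cm)
  map$locus_id <- sprintf("%s%d_%d", ifelse(map$class == "qtl", "Q", "M"),
                          map$chr, stats::ave(map$chr, map$chr, FUN = seq_along))
  validate_marker_map(map[, c("chr", "locus_id", "pos_cm", "class")])
}

#' Validate a marker map
#'
#' Checks the structural invariants of a locus map: required columns, strictly
#' increasing positions within chromosome, and recognised locus classes.
#'
#' @param map a tibble as returned by [sim_marker_map()].
#' @return The map, invisibly coerced to a tibble, if valid; otherwise an error.
#' @export
validate_marker_map <- function(map) {
  map <- tibble::as_tibble(map)
  assert_that(all(c("chr", "locus_id", "pos_cm", "class") %in% names(map)),
              "map must have columns chr, locus_id, pos_cm, class")
  assert_that(all(map$class %in% c("marker", "qtl")),
              "locus class must be 'marker' or 'qtl'")
  ok <- vapply(split(map$pos_cm, map$chr),
               function(p) all(diff(p) > 0), logical(1))
  assert_that(all(ok), "positions must be strictly increasing within chromosome")
  map
}

# split map into per-chromosome locus indices/positions for fast meiosis
map_chromosomes <- function(map) {
  idx <- split(seq_len(nrow(map)), map$chr)
  lapply(idx, function(i) list(idx = i, pos = map$pos_cm[i],
                               len_morgan = max(map$pos_cm[i]) / 100))
}
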