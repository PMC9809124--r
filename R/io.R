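#' Read and write the standard text formats
#'
#' Locus maps are written in a PLINK `.map`-style dialect (chromosome, locus
#' id, position in cM, locus index) with a `class` column distinguishing
#' markers from QTLs; genotypes as a PLINK `.raw`-style dosage table (one row
#' per individual, one column per locus, plus the id); pedigrees and
#' phenotypes as plain CSV; relationship matrices as three-column sparse
#' text.
#'
#' @param map,pop,pedigree,phenotypes,mat objects to write.
#' @param path file path.
#' @param loci optional locus subset for dosages (see [dosage_matrix()]).
#' @param tol entries with absolute value below `tol` are dropped from the
#'   sparse matrix text.
#' @return The written path (write functions, invisibly) or the parsed
#'   object (read functions).
#' @name pigsurv-io
NULL

#' @rdname pigsurv-io
#' @export
write_map_file <- function(map, path) {
  out <- tibble::tibble(chr = map$chr, locus_id = map$locus_id,
                        pos_cm = map$pos_cm, index = seq_len(nrow(map)),
                        class = map$class)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname pigsurv-io
#' @export
read_map_file <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  validate_marker_map(d[, c("chr", "locus_id", "pos_cm", "class")])
}

#' @rdname pigsurv-io
#' @export
write_dosage_file <- function(pop, path, loci = NULL) {
  d <- dosage_matrix(pop, loci = loci)
  out <- tibble::as_tibble(as.data.frame(d))
  out <- dplyr::bind_cols(tibble::tibble(id = as.integer(rownames(d))), out)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname pigsurv-io
#' @export
read_dosage_file <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d$id)
  storage.mode(m) <- "integer"
  m
}

#' @rdname pigsurv-io
#' @export
write_pedigree_file <- function(pedigree, path) {
  readr::write_csv(pedigree[, c("id", "sire", "dam", "sex", "generation",
                                "litter", "alive")], path)
  invisible(path)
}

#' @rdname pigsurv-io
#' @export
read_pedigree_file <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(sex = readr::col_character()))
}

#' @rdname pigsurv-io
#' @export
write_phenotype_file <- function(phenotypes, path) {
  # TBVs are simulation ground truth, retained for validation only
  readr::write_csv(phenotypes, path)
  invisible(path)
}

#' @rdname pigsurv-io
#' @export
write_relmat_file <- function(mat, path, tol = 0) {
  m <- as.matrix(mat)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  idx <- which(upper.tri(m, diag = TRUE) & abs(m) > tol, arr.ind = TRUE)
  out <- tibble::tibble(id_i = ids[idx[, 1]], id_j = ids[idx[, 2]],
                        value = m[idx])
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname pigsurv-io
#' @export
read_relmat_file <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- unique(c(d$id_i, d$id_j))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(match(d$id_i, ids), match(d$id_j, ids))] <- d$value
  m[cbind(match(d$id_j, ids), match(d$id_i, ids))] <- d$value
  m
}

#' Round-trip an experiment configuration through YAML
#'
#' @param cfg a `pig_config`.
#' @param path file path.
#' @return `write_experiment_config` returns the path invisibly;
#'   `read_experiment_config` a `pig_config`.
#' @export
write_experiment_config <- function(cfg, path) {
  x <- list(
    trait = cfg$trait, scenarios = cfg$scenarios, models = cfg$models,
    n_replicates = cfg$n_replicates, seed = cfg$seed, genome = cfg$genome,
    history = unclass(cfg$history),
    base = cfg$base,
    breeding = unclass(cfg$breeding)[c("n_sires", "dams_per_sire",
                                       "litter_size_support",
                                       "litter_size_probs", "n_generations")],
    mortality = cfg$mortality, omega = cfg$omega,
    reference_generations = cfg$reference_generations,
    validation_generation = cfg$validation_generation
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  experiment_config(
    trait = x$trait, scenarios = x$scenarios, models = x$models,
    n_replicates = x$n_replicates, seed = x$seed, genome = x$genome,
    history = do.call(history_config, x$history),
    base = x$base,
    breeding = do.call(breeding_config, x$breeding),
    mortality = x$mortality, omega = x$omega,
    reference_generations = x$reference_generations,
    validation_generation = x$validation_generation
  )
}
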