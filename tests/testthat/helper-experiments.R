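# the desk-scale study configuration used by the statistical checks: a
# proportionally reduced version of the full design (2 chromosomes, 4 sires
# by 5 dams, 4 reference + 1 validation generations) sized so the whole
# suite runs on one CPU
desk_config <- function(models = "LM", n_replicates = 8, seed = 20260926,
                        trait = "T_4/4", ...) {
  experiment_config(
    trait = trait, models = models, n_replicates = n_replicates, seed = seed,
    genome = list(n_chr = 2, markers_per_chr = 150, qtl_per_chr = 15,
                  chr_length_cm = 100),
    history = history_config(n_founder_males = 40, n_founder_females = 40,
                             n_historical_generations = 40),
    base = list(n_boars = 4, n_sows = 20),
    breeding = breeding_config(n_sires = 4, dams_per_sire = 5,
                               n_generations = 5),
    reference_generations = 2:4, validation_generation = 5, ...
  )
}

# a much smaller configuration for plumbing tests (determinism, io)
micro_config <- function(models = "LM", scenarios = c("G_all", "G_none"),
                         n_replicates = 1, seed = 5) {
  experiment_config(
    trait = "T_4/4", models = models, scenarios = scenarios,
    n_replicates = n_replicates, seed = seed,
    genome = list(n_chr = 1, markers_per_chr = 40, qtl_per_chr = 6,
                  chr_length_cm = 100),
    history = history_config(n_founder_males = 10, n_founder_females = 10,
                             n_historical_generations = 8),
    base = list(n_boars = 2, n_sows = 8),
    breeding = breeding_config(n_sires = 2, dams_per_sire = 4,
                               n_generations = 3),
    reference_generations = 1:2, validation_generation = 3
  )
}

# experiments shared across acceptance checks, computed once per session
cached <- function(key, expr) {
  cache <- pigsurv:::.pkg_cache
  if (is.null(cache[[key]])) cache[[key]] <- force(expr)
  cache[[key]]
}

desk_lm_experiment <- function() {
  cached("desk_lm", run_experiment(desk_config(models = "LM",
                                               n_replicates = 8,
                                               seed = 20260926)))
}

desk_3model_experiment <- function() {
  cached("desk_3model", run_experiment(desk_config(models = c("LM", "LG", "PM"),
                                                   n_replicates = 4,
                                                   seed = 77)))
}

desk_replicate <- function() {
  cached("desk_rep", simulate_replicate(desk_config(), seed = 424242))
}
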