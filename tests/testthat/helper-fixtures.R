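# Shared fixtures, generated in code.

rand_intervals <- function(n, seed, chroms = c("chr1", "chr2"),
                           max_pos = 1e5, max_width = 500) {
  set.seed(seed)
  start <- floor(runif(n, 0, max_pos))
  width <- ceiling(runif(n, 1, max_width))
  intervals(sample(chroms, n, replace = TRUE), start, start + width)
}

# a small, fast study for unit tests (~1.5 s)
small_config <- function(seed = 42) {
  simulation_config(seed = seed, n_chrom = 1, chrom_length = 1.5e6,
                    n_genes = 60, n_up = 12, n_down = 4,
                    n_planted_enhancers = 10, cells_per_sample = 30,
                    n_features_sc = 40, sc_depth = 500)
}

small_study_cache <- new.env()
small_study <- function() {
  if (is.null(small_study_cache$s))
    small_study_cache$s <- simulate_study(small_config())
  small_study_cache$s
}

consensus_by_genotype <- function(study, mark) {
  lapply(split(study$samples$sample_id, study$samples$genotype),
         function(ids) {
           combine_replicates(lapply(ids, function(s)
             study$peak_sets[[s]][[mark]]))
         })
}

ets_like_pwm <- function() {
  # GGAA-core motif
  counts <- rbind(c(10, 10, 60, 20),
                  c(2, 2, 94, 2),
                  c(2, 2, 94, 2),
                  c(90, 4, 2, 4),
                  c(90, 4, 2, 4),
                  c(10, 30, 30, 30))
  pwm_from_counts(counts, name = "ETS_like")
}
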