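# Shared fixtures: all generated in code, sized for fast tests.

mini_two_chrom <- function() {
  karyotype(dplyr::bind_rows(
    chromosome_spec("A", 4e5, 2e5),
    chromosome_spec("B", 3e5, 1e5)
  ))
}

# A deterministic synthetic ensemble over a toy bead table: points drawn
# uniformly in the nucleus, for statistics oracles that do not need
# polymer physics.
uniform_ensemble <- function(n_beads = 50, n_conf = 200, seed = 1,
                             r_nuc = 1000, kar = NULL, beads = NULL) {
  set.seed(seed)
  if (is.null(beads)) {
    kar <- kar %||% karyotype(chromosome_spec("U", n_beads * 3200, 3200))
    beads <- build_bead_chains(kar)
  }
  n <- nrow(beads)
  confs <- lapply(seq_len(n_conf), function(i) {
    m <- matrix(stats::rnorm(n * 3), n, 3)
    u <- stats::runif(n)^(1 / 3) * r_nuc
    m * (u / sqrt(rowSums(m^2)))
  })
  as_nuc_ensemble(confs, beads, kar)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cached short mini-karyotype simulation shared across simulator tests.
cached_mini_ensemble <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      kar <- mini_two_chrom()
      cache <<- run_ensemble(
        kar, reduced_schedule(n_replicates = 20,
                              production_duration = 900, sample_every = 30),
        seed = 101)
    }
    cache
  }
})
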