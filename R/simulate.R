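#' @useDynLib yeastnuc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

# Shared driver: runs Langevin dynamics on a conformation, in reduced units
# (1 length unit = sigma), returning nm coordinates.
.run_dynamics <- function(conf, duration, schedule, forcefield, geometry,
                          sample_every = 0, seed = conf$seed,
                          restraints_on = TRUE) {
  stopifnot(inherits(conf, "nuc_conformation"))
  beads <- conf$beads
  s <- forcefield$sigma
  n_steps <- round(duration / schedule$dt)
  samp_steps <- if (sample_every > 0) round(sample_every / schedule$dt) else 0L

  if (n_steps == 0) {
    return(list(samples = list(), final = conf$positions))
  }

  geom <- geometry %||% nuclear_geometry()
  chain_id <- match(beads$chain, unique(beads$chain))
  res <- .langevin_run_cpp(
    pos0 = conf$positions / s,
    chain_id = as.integer(chain_id),
    is_cen = beads$is_centromere,
    is_rdna = beads$is_rdna,
    is_term = beads$is_terminal,
    kappa = .kappa_per_bead(beads, forcefield),
    fene_k = forcefield$fene_k,
    fene_r0 = forcefield$fene_r0 / s,
    wall_eps = forcefield$telomere_wall_epsilon,
    wall_cut = forcefield$telomere_wall_cutoff / s,
    r_nuc = geom$r_nuc / s,
    c_spb = geom$c_spb / s,
    r_spb = geom$r_spb / s,
    c_nucl = geom$c_nucl / s,
    r_nucl = geom$r_nucl / s,
    indent_k = geom$indent_k,
    f_cap = forcefield$indent_force_cap,
    restraints_on = restraints_on,
    dt = schedule$dt, gamma = schedule$gamma,
    temp = schedule$temperature,
    n_steps = as.integer(n_steps),
    sample_every = as.integer(samp_steps),
    seed = as.integer(seed %% .Machine$integer.max)
  )
  res$samples <- lapply(res$samples, function(m) m * s)
  res$final <- res$final * s
  res
}

#' Preliminary restraint-satisfaction run
#'
#' Short Langevin run (60 tau_LJ at the defaults) with all restraints
#' active, after which centromere beads sit at the SPB sphere, rDNA beads in
#' the nucleolar lens, and non-rDNA beads outside it. Because restraint
#' forces are capped for integrator stability, an awkward placement can
#' need more than one pass: compliance is checked after each pass and the
#' run extends in further `prelim_duration` rounds (up to `max_rounds`,
#' then a warning) until the landmarks comply. A zero-duration run returns
#' the input unchanged.
#'
#' @param conf A `nuc_conformation` from [place_chromosomes()].
#' @param schedule A [simulation_schedule()].
#' @param forcefield A [force_field()].
#' @param geometry A [nuclear_geometry()].
#' @param max_rounds Maximum number of `prelim_duration` passes.
#' @return A relaxed `nuc_conformation`.
#' @export
preliminary_relax <- function(conf, schedule = simulation_schedule(),
                              forcefield = force_field(),
                              geometry = nuclear_geometry(),
                              max_rounds = 10) {
  if (schedule$prelim_duration == 0) return(conf)
  beads <- conf$beads
  tol <- forcefield$sigma
  compliant <- function(pos) {
    cen <- pos[beads$is_centromere, , drop = FALSE]
    dn <- sqrt(rowSums(sweep(pos, 2, geometry$c_nucl)^2))
    all(sqrt(rowSums(sweep(cen, 2, geometry$c_spb)^2)) <=
          geometry$r_spb + tol) &&
      all(dn[beads$is_rdna] <= geometry$r_nucl + tol) &&
      mean(dn[!beads$is_rdna] >= geometry$r_nucl - tol) >= 0.99
  }
  for (round in seq_len(max_rounds)) {
    res <- .run_dynamics(conf, schedule$prelim_duration, schedule,
                         forcefield, geometry, sample_every = 0,
                         seed = conf$seed + round)
    conf$positions <- res$final
    if (compliant(conf$positions)) return(conf)
  }
  warning("landmark restraints not fully satisfied after ", max_rounds,
          " preliminary rounds (seed ", conf$seed, ")")
  conf
}

#' Production Langevin run
#'
#' Relaxes the system for `production_duration` tau_LJ with all restraints in
#' place, retaining one conformation every `sample_every` tau_LJ (10 per
#' trajectory at the full-scale defaults).
#'
#' @inheritParams preliminary_relax
#' @param restraints_on Set `FALSE` to run a free chain (no confinement, no
#'   landmark restraints), e.g. for persistence-length checks.
#' @return List of `nuc_conformation` samples.
#' @export
production_run <- function(conf, schedule = simulation_schedule(),
                           forcefield = force_field(),
                           geometry = nuclear_geometry(),
                           restraints_on = TRUE) {
  res <- .run_dynamics(conf, schedule$production_duration, schedule,
                       forcefield, geometry,
                       sample_every = schedule$sample_every,
                       seed = conf$seed + 101L, restraints_on = restraints_on)
  purrr::imap(res$samples, function(m, i) {
    out <- conf
    out$positions <- m
    out$sample <- i
    out
  })
}

#' Simulate a conformational ensemble
#'
#' Runs `n_replicates` independent trajectories (placement, preliminary
#' relaxation, production sampling) with per-replicate seeds derived from the
#' master seed, and collects all retained conformations into an ensemble.
#' Failed replicates are dropped with a warning and recorded in the
#' provenance.
#'
#' @param kar A [karyotype()] (e.g. [strain_karyotype()]).
#' @param schedule A [simulation_schedule()] (use [reduced_schedule()] for
#'   desk-scale runs).
#' @param forcefield A [force_field()].
#' @param geometry A [nuclear_geometry()].
#' @param seed Master seed; replicate r uses `seed + r * 10007`.
#' @param bp_per_bead Bead size in bp.
#' @param progress Print per-replicate progress.
#' @return A `nuc_ensemble`: `beads`, `karyotype`, `conformations` (list of
#'   n x 3 nm matrices), `meta` (replicate, sample, seed per conformation)
#'   and `provenance`.
#' @examples
#' \donttest{
#' kar <- make_mini_karyotype(2, c(2e5, 1.5e5))$karyotype
#' ens <- run_ensemble(kar, reduced_schedule(n_replicates = 2), seed = 1)
#' length(ens$conformations)  # 2 x 10
#' }
#' @export
run_ensemble <- function(kar, schedule = simulation_schedule(),
                         forcefield = force_field(),
                         geometry = nuclear_geometry(),
                         seed = 1, bp_per_bead = 3200, progress = FALSE) {
  confs <- list()
  meta <- list()
  failed <- integer(0)
  for (r in seq_len(schedule$n_replicates)) {
    rseed <- as.integer((seed + r * 10007) %% 2147483647L)
    res <- tryCatch({
      conf <- place_chromosomes(kar, geometry, seed = rseed,
                                bp_per_bead = bp_per_bead,
                                sigma = forcefield$sigma)
      conf$replicate <- r
      conf <- preliminary_relax(conf, schedule, forcefield, geometry)
      production_run(conf, schedule, forcefield, geometry)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("replicate ", r, " failed: ", conditionMessage(res))
      failed <- c(failed, r)
      next
    }
    for (cf in res) {
      confs[[length(confs) + 1]] <- cf$positions
      meta[[length(meta) + 1]] <- tibble::tibble(
        replicate = r, sample = cf$sample, seed = rseed)
    }
    if (progress) {
      message(sprintf("replicate %d/%d done", r, schedule$n_replicates))
    }
  }
  beads <- build_bead_chains(kar, bp_per_bead)
  structure(list(
    beads = beads, karyotype = kar, conformations = confs,
    meta = dplyr::bind_rows(meta),
    provenance = list(forcefield = forcefield, schedule = schedule,
                      geometry = geometry, master_seed = seed,
                      bp_per_bead = bp_per_bead,
                      failed_replicates = failed,
                      package_version = as.character(utils::packageVersion("yeastnuc")))
  ), class = "nuc_ensemble")
}

#' @export
print.nuc_ensemble <- function(x, ...) {
  cat(sprintf("<nuc_ensemble> %d conformations x %d beads (%d chains)\n",
              length(x$conformations), nrow(x$beads),
              length(unique(x$beads$chain))))
  invisible(x)
}

#' Assemble an ensemble from raw conformations
#'
#' Mainly for tests and synthetic oracles: wraps a list of coordinate
#' matrices (nm) over a known bead table into a `nuc_ensemble`.
#'
#' @param conformations List of n x 3 matrices.
#' @param beads Bead table ([build_bead_chains()]).
#' @param karyotype Optional [karyotype()].
#' @param meta Optional meta tibble (replicate, sample, seed rows).
#' @export
as_nuc_ensemble <- function(conformations, beads, karyotype = NULL,
                            meta = NULL) {
  stopifnot(all(vapply(conformations, nrow, 1L) == nrow(beads)))
  if (is.null(meta)) {
    meta <- tibble::tibble(replicate = seq_along(conformations),
                           sample = 1L, seed = NA_integer_)
  }
  structure(list(beads = beads, karyotype = karyotype,
                 conformations = conformations, meta = meta,
                 provenance = list()),
            class = "nuc_ensemble")
}

#' Long-format coordinates of an ensemble
#'
#' @param x A `nuc_ensemble`.
#' @param ... Unused.
#' @return Tibble: `conformation`, `chain`, `bead`, `index`, `x`, `y`, `z`
#'   (nm), plus the radial distance `r`.
#' @export
tidy.nuc_ensemble <- function(x, ...) {
  n <- nrow(x$beads)
  purrr::imap_dfr(x$conformations, function(m, i) {
    tibble::tibble(conformation = i, chain = x$beads$chain,
                   bead = x$beads$bead, index = x$beads$index,
                   x = m[, 1], y = m[, 2], z = m[, 3],
                   r = sqrt(rowSums(m^2)))
  })
}

#' Ensemble summary
#'
#' @param x A `nuc_ensemble`.
#' @param ... Unused.
#' @return One-row tibble: conformation/bead/chain counts, replicate count,
#'   longest bond observed (nm), and fraction of beads inside the nucleus.
#' @export
glance.nuc_ensemble <- function(x, ...) {
  geom <- x$provenance$geometry %||% nuclear_geometry()
  same_chain <- x$beads$chain[-1] == x$beads$chain[-nrow(x$beads)]
  max_bond <- max(vapply(x$conformations, function(m) {
    d <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
    max(d[same_chain])
  }, numeric(1)))
  frac_in <- mean(vapply(x$conformations, function(m) {
    mean(rowSums(m^2) <= geom$r_nuc^2)
  }, numeric(1)))
  tibble::tibble(
    n_conformations = length(x$conformations),
    n_beads = nrow(x$beads),
    n_chains = length(unique(x$beads$chain)),
    n_replicates = length(unique(x$meta$replicate)),
    max_bond_nm = max_bond,
    frac_inside_nucleus = frac_in
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
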