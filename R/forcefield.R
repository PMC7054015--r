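#' Bead-and-spring force field parameters
#'
#' Physical parameters of the chromatin chain model. Lengths in nm, energies
#' in kT. Excluded volume is a purely repulsive (WCA) Lennard-Jones sphere of
#' diameter `sigma`; chain connectivity is a FENE bond with maximum extension
#' `fene_r0`; bending follows a Kratky-Porod potential with stiffness set
#' from the persistence length (61.7 nm for internal chromatin, 195 nm over
#' the 20-kb telomeric regions); terminal beads feel a truncated 12-6
#' attraction to the nuclear envelope out to `telomere_wall_cutoff` nm.
#'
#' `telomere_wall_epsilon` is the depth (kT) of the telomere-wall attraction.
#' The default was calibrated on reduced wild-type ensembles so that roughly
#' 40% of telomere observations fall outside the peripheral shell (the
#' remainder being peripheral), the behaviour the restraint is meant to
#' capture.
#'
#' @param sigma Bead diameter in nm (excluded-volume scale).
#' @param epsilon Repulsive energy scale in kT.
#' @param fene_r0 Maximum bond extension in nm.
#' @param fene_k FENE spring constant in epsilon/sigma^2 (reduced).
#' @param lp_internal,lp_terminal Persistence lengths (nm).
#' @param telomere_wall_epsilon Telomere-NE attraction depth in kT.
#' @param telomere_wall_cutoff Attraction range from the NE in nm.
#' @param indent_force_cap Cap on restraint-force magnitude (reduced units),
#'   a numerical guard that lets large initial violations relax smoothly.
#' @param bending_map How persistence length maps to the discrete bending
#'   constant; see [bending_constant_from_persistence()].
#' @return A `nuc_forcefield` list.
#' @export
force_field <- function(sigma = 30, epsilon = 1, fene_r0 = 45, fene_k = 30,
                        lp_internal = 61.7, lp_terminal = 195.0,
                        telomere_wall_epsilon = 4.75,
                        telomere_wall_cutoff = 126,
                        indent_force_cap = 6,
                        bending_map = c("ratio", "langevin")) {
  bending_map <- match.arg(bending_map)
  stopifnot(fene_r0 > sigma, lp_terminal > lp_internal,
            telomere_wall_epsilon >= 0)
  structure(list(
    sigma = sigma, epsilon = epsilon, fene_r0 = fene_r0, fene_k = fene_k,
    lp_internal = lp_internal, lp_terminal = lp_terminal,
    kappa_internal = bending_constant_from_persistence(lp_internal, sigma,
                                                       bending_map),
    kappa_terminal = bending_constant_from_persistence(lp_terminal, sigma,
                                                       bending_map),
    telomere_wall_epsilon = telomere_wall_epsilon,
    telomere_wall_cutoff = telomere_wall_cutoff,
    indent_force_cap = indent_force_cap,
    bending_map = bending_map
  ), class = "nuc_forcefield")
}

#' Discrete bending constant from a persistence length
#'
#' Worm-like-chain discretization: with bond length `b`, the Kratky-Porod
#' stiffness is `kappa = Lp / b` in kT units (`map = "ratio"`, the standard
#' coarse-grained identification). `map = "langevin"` instead inverts the
#' exact freely-rotating relation `<cos theta> = coth(kappa) - 1/kappa =
#' exp(-b/Lp)`, which matters at low stiffness.
#'
#' @param lp Persistence length (nm), > 0.
#' @param bond Bond length (nm), > 0.
#' @param map `"ratio"` or `"langevin"`.
#' @return Bending constant in kT.
#' @examples
#' bending_constant_from_persistence(61.7, 30)   # ~2.057
#' bending_constant_from_persistence(195, 30)    # 6.5
#' @export
bending_constant_from_persistence <- function(lp, bond = 30,
                                              map = c("ratio", "langevin")) {
  map <- match.arg(map)
  stopifnot(lp > 0, bond > 0)
  if (map == "ratio") return(lp / bond)
  target <- exp(-bond / lp)
  f <- function(k) 1 / tanh(k) - 1 / k - target
  stats::uniroot(f, c(1e-6, 1e4), tol = 1e-10)$root
}

#' Langevin dynamics schedule
#'
#' Time is measured in tau_LJ (the Lennard-Jones time unit,
#' `sigma * sqrt(m / epsilon)` with m = 1). The full-scale study protocol is
#' a 60 tau_LJ preliminary restraint-satisfaction run, then a 30,000 tau_LJ
#' production run sampled every 3000 tau_LJ (10 conformations per
#' trajectory), replicated 1000 times for 10,000 conformations per strain.
#'
#' @param dt Integrator timestep in tau_LJ.
#' @param gamma Langevin friction in 1/tau_LJ.
#' @param temperature Thermostat temperature in epsilon/kB.
#' @param prelim_duration Preliminary relaxation length (tau_LJ).
#' @param production_duration Production length (tau_LJ).
#' @param sample_every Sampling interval (tau_LJ); must divide the
#'   production duration.
#' @param n_replicates Independent trajectories.
#' @return A `nuc_schedule` list with `samples_per_replicate` filled in.
#' @export
simulation_schedule <- function(dt = 0.01, gamma = 0.25, temperature = 1.0,
                                prelim_duration = 60,
                                production_duration = 30000,
                                sample_every = 3000,
                                n_replicates = 1000) {
  stopifnot(dt > 0, gamma > 0, prelim_duration >= 0,
            production_duration > 0, sample_every > 0,
            production_duration %% sample_every == 0)
  structure(list(
    dt = dt, gamma = gamma, temperature = temperature,
    prelim_duration = prelim_duration,
    production_duration = production_duration,
    sample_every = sample_every,
    n_replicates = n_replicates,
    samples_per_replicate = production_duration / sample_every
  ), class = "nuc_schedule")
}

#' Reduced-scale schedule for desk-sized ensembles
#'
#' Same integrator settings as [simulation_schedule()] but with a short
#' production run, used for test-scale ensembles where full decorrelation
#' between samples is traded for runtime.
#'
#' @param n_replicates Independent trajectories.
#' @param production_duration,sample_every Production length and sampling
#'   interval (tau_LJ).
#' @export
reduced_schedule <- function(n_replicates = 10, production_duration = 300,
                             sample_every = 30) {
  simulation_schedule(production_duration = production_duration,
                      sample_every = sample_every,
                      n_replicates = n_replicates)
}

#' Measure the persistence length of simulated chains
#'
#' Estimates the persistence length from the tangent-tangent correlation
#' decay `<t_i . t_{i+s}> = exp(-s b / Lp)` over sampled conformations of a
#' single chain, fitting the stated bond lags. Short lags (the default 1:2)
#' probe the bending rigidity itself; at longer lags excluded volume adds a
#' slowly decaying (power-law) contribution that inflates exponential fits,
#' so long-lag estimates exceed the bare bending value for any
#' self-avoiding chain.
#'
#' @param conformations List of `nuc_conformation`s (or bare n x 3
#'   coordinate matrices) of one chain.
#' @param lags Bond lags used in the log-linear fit.
#' @return One-row tibble: `lp_nm`, `mean_bond_nm`, `n_frames`.
#' @export
persistence_length <- function(conformations, lags = 1:2) {
  mats <- lapply(conformations, function(cf) {
    if (is.matrix(cf)) cf else cf$positions
  })
  stopifnot(length(mats) > 0, nrow(mats[[1]]) > max(lags) + 1)
  cors <- sapply(mats, function(m) {
    b <- diff(m)
    th <- b / sqrt(rowSums(b^2))
    vapply(lags, function(s) {
      mean(rowSums(th[1:(nrow(th) - s), , drop = FALSE] *
                     th[(1 + s):nrow(th), , drop = FALSE]))
    }, numeric(1))
  })
  mean_cos <- if (length(lags) == 1) mean(cors) else rowMeans(cors)
  mean_bond <- mean(vapply(mats, function(m) {
    mean(sqrt(rowSums(diff(m)^2)))
  }, numeric(1)))
  slope <- if (length(lags) == 1) {
    log(mean_cos) / lags
  } else {
    unname(stats::coef(stats::lm(log(mean_cos) ~ lags))[2])
  }
  tibble::tibble(lp_nm = -mean_bond / slope, mean_bond_nm = mean_bond,
                 n_frames = length(mats))
}

# Per-bead bending constants: the angle centred on bead j is stiffened to
# the terminal value only when the whole angle lies in telomeric-region beads.
.kappa_per_bead <- function(beads, ff) {
  n <- nrow(beads)
  kap <- rep(ff$kappa_internal, n)
  if (n >= 3) {
    tel3 <- beads$is_telomeric &
      dplyr::lag(beads$is_telomeric, default = FALSE) &
      dplyr::lead(beads$is_telomeric, default = FALSE) &
      beads$chain == dplyr::lag(beads$chain, default = "") &
      beads$chain == dplyr::lead(beads$chain, default = "")
    kap[tel3] <- ff$kappa_terminal
  }
  kap
}
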