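test_that("bending constants map persistence lengths to kT units", {
  expect_equal(bending_constant_from_persistence(30, 30), 1)
  expect_equal(bending_constant_from_persistence(61.7, 30), 61.7 / 30)
  expect_equal(bending_constant_from_persistence(195, 30), 6.5)
  # exact freely-rotating inversion is stiffer at low kappa and converges
  # to the ratio at high stiffness
  k_exact <- bending_constant_from_persistence(61.7, 30, "langevin")
  expect_gt(k_exact, 61.7 / 30)
  expect_equal(bending_constant_from_persistence(3000, 30, "langevin"),
               100, tolerance = 0.01)
})

test_that("solenoid rods satisfy spacing, radius and overlap bounds", {
  expect_equal(build_solenoid(1), matrix(0, 1, 3))
  for (n in c(2, 10, 313, 619)) {
    rod <- build_solenoid(n)
    bond <- sqrt(rowSums((rod[-1, , drop = FALSE] -
                            rod[-n, , drop = FALSE])^2))
    expect_true(all(bond < 45))
    # radial distance from the rod axis (z) never exceeds the rod radius
    expect_true(all(sqrt(rod[, 1]^2 + rod[, 2]^2) <= 150 + 1e-9))
    if (n <= 313) {
      d <- as.matrix(stats::dist(rod))
      diag(d) <- Inf
      expect_gt(min(d), 0.9 * 30)
    }
  }
  expect_error(build_solenoid(5, rod_radius = 5, spacing = 40), "too large")
})

test_that("placement is deterministic, clash-free and longest-first", {
  kar <- mini_two_chrom()
  c1 <- place_chromosomes(kar, seed = 5)
  c2 <- place_chromosomes(kar, seed = 5)
  expect_identical(c1$positions, c2$positions)
  c3 <- place_chromosomes(kar, seed = 6)
  expect_false(identical(c1$positions, c3$positions))

  expect_equal(attr(c1, "placement_order"), c("A", "B"))  # A is longer

  a <- c1$positions[c1$beads$chain == "A", ]
  b <- c1$positions[c1$beads$chain == "B", ]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  expect_gt(sqrt(min(d2)), 30 - 1e-9)
  expect_true(all(rowSums(c1$positions^2) <= 1000^2))
  # impossible placement rejected with a diagnostic
  big <- karyotype(dplyr::bind_rows(
    chromosome_spec("L1", 3e6, 1.5e6), chromosome_spec("L2", 3e6, 1.5e6),
    chromosome_spec("L3", 3e6, 1.5e6)))
  expect_error(
    place_chromosomes(big, nuclear_geometry(r_nuc = 300), seed = 1,
                      max_retries = 5),
    "failed to place")
})

test_that("preliminary relaxation satisfies the landmark restraints", {
  # centromere and rDNA sit at opposite nuclear poles ~1.2 um apart, so the
  # chain needs enough contour length between them (as chromosome XII has)
  kar <- karyotype(dplyr::bind_rows(
    chromosome_spec("A", 4e5, 2e5),
    chromosome_spec("R", 6e5, 5e4, rdna_start = 4e5, rdna_end = 5.5e5)))
  g <- nuclear_geometry()
  ff <- force_field()
  sch <- reduced_schedule(n_replicates = 1)
  set.seed(1)
  confs <- lapply(1:5, function(i) {
    conf <- place_chromosomes(kar, g, seed = 200 + i)
    preliminary_relax(conf, sch, ff, g)
  })
  beads <- confs[[1]]$beads
  frac <- function(sel, test) {
    mean(unlist(lapply(confs, function(cf) test(cf$positions[sel, , drop = FALSE]))))
  }
  # centromeres at the SPB sphere (within one bead diameter of tolerance)
  expect_gte(frac(beads$is_centromere, function(p) {
    sqrt(rowSums(sweep(p, 2, g$c_spb)^2)) <= g$r_spb + ff$sigma
  }), 0.95)
  # rDNA inside the nucleolar lens, non-rDNA outside it
  expect_gte(frac(beads$is_rdna, function(p) {
    sqrt(rowSums(sweep(p, 2, g$c_nucl)^2)) <= g$r_nucl + ff$sigma
  }), 0.95)
  expect_gte(frac(!beads$is_rdna, function(p) {
    sqrt(rowSums(sweep(p, 2, g$c_nucl)^2)) >= g$r_nucl - ff$sigma
  }), 0.95)

  # zero-duration run is the identity
  sch0 <- simulation_schedule(prelim_duration = 0, n_replicates = 1)
  conf <- place_chromosomes(kar, g, seed = 300)
  expect_identical(preliminary_relax(conf, sch0, ff, g)$positions,
                   conf$positions)
})

test_that("production sampling: counts, chain integrity, confinement,
           excluded volume, determinism", {
  ens <- cached_mini_ensemble()
  sch <- reduced_schedule(n_replicates = 20, production_duration = 900,
                          sample_every = 30)
  expect_equal(length(ens$conformations),
               20 * sch$samples_per_replicate)

  beads <- ens$beads
  same_chain <- beads$chain[-1] == beads$chain[-nrow(beads)]
  n_close <- 0; n_pairs <- 0
  for (m in ens$conformations) {
    bond <- sqrt(rowSums((m[-1, ] - m[-nrow(m), ])^2))[same_chain]
    expect_true(all(bond < 45))                      # FENE hard bound
    expect_true(all(rowSums(m^2) <= (1000 + 30)^2))  # confinement
    d <- stats::dist(m)
    n_close <- n_close + sum(d < 0.8 * 30)
    n_pairs <- n_pairs + length(d)
  }
  expect_lt(n_close / n_pairs, 1e-4)

  # determinism: rerunning a replicate reproduces coordinates bit for bit
  kar <- mini_two_chrom()
  sch1 <- reduced_schedule(n_replicates = 1)
  e1 <- run_ensemble(kar, sch1, seed = 77)
  e2 <- run_ensemble(kar, sch1, seed = 77)
  expect_identical(e1$conformations, e2$conformations)
  e3 <- run_ensemble(kar, sch1, seed = 78)
  expect_false(identical(e1$conformations, e3$conformations))
})

test_that("radial distributions are stable between production halves", {
  ens <- cached_mini_ensemble()
  # compare the two halves of the equilibrated window (after 300 tau of
  # burn-in from the rod initial state)
  h1 <- ens$meta$sample > 10 & ens$meta$sample <= 20
  h2 <- ens$meta$sample > 20
  r1 <- unlist(lapply(ens$conformations[h1], function(m) sqrt(rowSums(m^2))))
  r2 <- unlist(lapply(ens$conformations[h2], function(m) sqrt(rowSums(m^2))))
  ks <- suppressWarnings(stats::ks.test(r1, r2)$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("terminal beads are peripherally enriched over matched internal
           beads", {
  ens <- cached_mini_ensemble()
  g <- nuclear_geometry()
  occ <- shell_occupancy(ens, g)
  term <- occ$is_terminal
  internal <- !occ$is_telomeric
  set.seed(2)
  matched <- sample(which(internal), sum(term))
  n_conf <- length(ens$conformations)
  x_term <- round(sum(occ$frac_peripheral[term]) * n_conf)
  n_term <- sum(term) * n_conf
  p_int <- mean(occ$frac_peripheral[matched])
  bt <- stats::binom.test(x_term, n_term, p = max(p_int, 1e-6),
                          alternative = "greater")
  expect_lt(bt$p.value, 0.01)
  expect_gte(n_conf, 100)
})

test_that("a free chain recovers its persistence length within 15%", {
  kar <- karyotype(chromosome_spec("F", 200 * 3200, 320000))
  beads <- build_bead_chains(kar)
  ff <- force_field()
  rod <- build_solenoid(200)
  conf <- structure(list(positions = rod, beads = beads, karyotype = kar,
                         replicate = 1L, sample = NA_integer_, seed = 421L),
                    class = "nuc_conformation")
  sch <- simulation_schedule(production_duration = 2000, sample_every = 20,
                             n_replicates = 1)
  samps <- production_run(conf, sch, ff, geometry = nuclear_geometry(),
                          restraints_on = FALSE)
  keep <- samps[26:100]  # discard the rod-to-coil transient
  lp_hat <- persistence_length(keep)$lp_nm
  expect_lt(abs(lp_hat - ff$lp_internal) / ff$lp_internal, 0.15)
  # the long-lag estimate is inflated by excluded-volume swelling, an
  # expected property of self-avoiding chains
  lp_long <- persistence_length(keep, lags = 1:8)$lp_nm
  expect_gt(lp_long, lp_hat)
})
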