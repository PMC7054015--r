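# Ensemble statistics checked against brute-force recomputation on toy
# ensembles and against sampling oracles on uniform-random ensembles.

test_that("shell occupancy: fractions sum to one, match the uniform oracle,
           and are rotation invariant", {
  ens <- uniform_ensemble(n_beads = 40, n_conf = 400, seed = 3)
  occ <- shell_occupancy(ens)
  expect_true(all(abs(occ$frac_central + occ$frac_middle +
                        occ$frac_peripheral - 1) < 1e-9))
  # uniform points: each fraction 1/3 within binomial CI (pooled over beads)
  se <- sqrt(1 / 3 * 2 / 3 / (400 * 40))
  expect_lt(abs(mean(occ$frac_peripheral) - 1 / 3), 4 * se)

  # single conformation: fractions are 0 or 1
  one <- as_nuc_ensemble(ens$conformations[1], ens$beads)
  occ1 <- shell_occupancy(one)
  expect_true(all(occ1$frac_peripheral %in% c(0, 1)))

  # global rotation leaves occupancy unchanged
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ens_rot <- as_nuc_ensemble(lapply(ens$conformations, function(m) m %*% rot),
                             ens$beads)
  expect_equal(shell_occupancy(ens_rot)$pct_peripheral, occ$pct_peripheral)
})

test_that("gene percent peripheral averages constitutive beads", {
  kar <- karyotype(chromosome_spec("U", 20 * 3200, 3200))
  beads <- build_bead_chains(kar)
  # one fabricated conformation pattern: beads alternate shells
  g <- nuclear_geometry()
  r_per <- (g$shell_r2 + g$r_nuc) / 2
  r_mid <- (g$shell_r1 + g$shell_r2) / 2
  mk_conf <- function(peripheral_mask) {
    r <- ifelse(peripheral_mask, r_per, r_mid)
    cbind(r, 0, 0)
  }
  # bead 1 peripheral in 20% of conformations, bead 2 in 40%
  confs <- lapply(1:10, function(i) {
    mk_conf(c(i <= 2, i <= 4, rep(FALSE, 18)))
  })
  ens <- as_nuc_ensemble(confs, beads, kar)
  occ <- shell_occupancy(ens)
  genes <- tibble::tibble(gene_id = c("one_bead", "two_beads"),
                          chrom = "U", start = c(100, 100),
                          end = c(3000, 6000))
  gp <- gene_percent_peripheral(occ, genes, kar)
  expect_equal(gp$pct_peripheral[gp$gene_id == "one_bead"], 20)
  expect_equal(gp$pct_peripheral[gp$gene_id == "two_beads"], 30)  # mean(20, 40)
})

test_that("10-kb NE displacement: zero on identical ensembles, exact under
           radial shifts, and equal to the brute-force mean", {
  ens <- uniform_ensemble(n_beads = 20, n_conf = 5, seed = 11, r_nuc = 500)
  d0 <- locus_ne_displacement_10kb(ens, ens)
  expect_true(all(abs(d0$displacement) < 1e-12))
  # loci are triples with a trailing remainder
  expect_equal(sort(unique(d0$locus)), 1:7)

  # rigid radial expansion by +50 nm moves every locus 50 nm closer to NE
  scale_out <- function(m) {
    r <- sqrt(rowSums(m^2))
    m * ((r + 50) / r)
  }
  ens_b <- as_nuc_ensemble(lapply(ens$conformations, scale_out), ens$beads)
  db <- locus_ne_displacement_10kb(ens, ens_b)
  expect_equal(db$displacement, rep(-50, nrow(db)), tolerance = 1e-9)

  # brute force: mean over beads and conformations of r_nuc - |x|
  g <- nuclear_geometry()
  brute <- mean(sapply(ens$conformations, function(m) {
    mean(g$r_nuc - sqrt(rowSums(m[4:6, ]^2)))
  }))
  expect_equal(db$ne_dist_a[db$locus == 2], brute)
})

test_that("SPB displacement sign convention and brute-force equality", {
  ens <- uniform_ensemble(n_beads = 15, n_conf = 8, seed = 13, r_nuc = 400)
  z <- spb_distance_difference(ens, ens)
  expect_true(all(z$difference == 0))
  # translate along +x (away from the SPB at (-850, 0, 0)) -> positive
  ens_t <- as_nuc_ensemble(
    lapply(ens$conformations, function(m) sweep(m, 2, c(120, 0, 0), "+")),
    ens$beads)
  dt <- spb_distance_difference(ens, ens_t)
  expect_true(all(dt$difference > 0))
  # brute force per bead
  g <- nuclear_geometry()
  brute <- rowMeans(sapply(ens$conformations, function(m) {
    sqrt(rowSums(sweep(m, 2, g$c_spb)^2))
  }))
  expect_equal(dt$spb_dist_wt, unname(brute))
})

test_that("pair distance stats reduce to medians/means of bead distances", {
  kar <- karyotype(chromosome_spec("U", 10 * 3200, 3200))
  beads <- build_bead_chains(kar)
  confs <- list(
    matrix(rep(c(0, 0, 0), each = 10), 10, 3),
    matrix(rep(c(100, 0, 0), each = 10), 10, 3),
    matrix(rep(c(300, 0, 0), each = 10), 10, 3))
  ens <- as_nuc_ensemble(confs, beads, kar)
  # locus to itself
  self <- pair_distance_stats(ens, 2:3, 2:3)
  expect_equal(self$mean, 0)
  # to the NE: 1000 - x for the three conformations; median is middle value
  ne <- pair_distance_stats(ens, 1, "NE")
  expect_equal(ne$median, 900)
  expect_equal(ne$mean, mean(c(1000, 900, 700)))
  spb <- pair_distance_stats(ens, 1, "SPB")
  expect_equal(spb$median, 950)

  # telomere-pair medians equal brute-force medians
  ens2 <- uniform_ensemble(n_beads = 12, n_conf = 7, seed = 17)
  tm <- telomere_pair_medians(ens2)
  idx <- ens2$beads$index[ens2$beads$is_terminal]
  brute <- apply(utils::combn(idx, 2), 2, function(pr) {
    stats::median(sapply(ens2$conformations, function(m) {
      sqrt(sum((m[pr[1], ] - m[pr[2], ])^2))
    }))
  })
  expect_equal(tm$median_nm, brute)
})

test_that("2D density map: grid geometry, kernel conservation, and peak
           location", {
  kar <- karyotype(chromosome_spec("U", 3200, 1600))
  beads <- build_bead_chains(kar)
  ens <- as_nuc_ensemble(list(matrix(0, 1, 3)), beads, kar)
  dm <- density_map_2d(ens)
  expect_equal(dim(dm$values), c(200, 200))
  expect_equal(max(dm$values), 1)
  # peak at the origin pixel: a ~ 0 -> index 101, rho ~ 0 -> index 1
  peak <- which(dm$values == 1, arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(101, 1))
  # radial symmetry in a about the kernel-centre column
  expect_equal(dm$values[101 + 5, 1], dm$values[101 - 5, 1],
               tolerance = 1e-9)

  # mass conservation before normalization (kernels away from the rho >= 0
  # boundary): n_obs x kernel mass
  ens2 <- as_nuc_ensemble(
    list(matrix(c(0, 100, 0, 200, 150, 0), 2, 3, byrow = TRUE)),
    build_bead_chains(karyotype(chromosome_spec("V", 6400, 3200))))
  dm2 <- density_map_2d(ens2, normalize = FALSE)
  hw <- ceiling(3 * 30 / 10)
  kmass <- sum(exp(-0.5 * outer((-hw:hw)^2, (-hw:hw)^2, "+") * (10 / 30)^2))
  expect_equal(sum(dm2$values), 2 * kmass, tolerance = 1e-6)
})

test_that("contact map: symmetry, unit diagonal, adjacency, and binning", {
  kar <- mini_two_chrom()
  ens <- cached_mini_ensemble()
  cm <- contact_map(ens)
  expect_equal(cm$values, t(cm$values))
  expect_true(all(diag(cm$values) == 1))
  expect_true(all(cm$values >= 0 & cm$values <= 1))
  # 10 beads = 32 kb per bin
  expect_equal(cm$bins$end[1] - cm$bins$start[1], 32000)
  # bonded beads are always within 120 nm: adjacent bins in contact
  nb <- nrow(cm$values)
  adj <- cm$values[cbind(1:(nb - 1), 2:nb)]
  same <- cm$bins$chain[1:(nb - 1)] == cm$bins$chain[2:nb]
  expect_true(all(adj[same] == 1))
  # contact frequency decays with genomic distance on average (chain A)
  a_bins <- cm$bins$bin[cm$bins$chain == "A"]
  va <- cm$values[a_bins, a_bins]
  n <- length(a_bins)
  mean_at <- sapply(1:(n - 1), function(s) {
    mean(va[cbind(1:(n - s), (1 + s):n)])
  })
  expect_lt(mean(diff(mean_at) > 0), 0.5)
  expect_gt(mean_at[1], mean_at[n - 1])
})

test_that("matrix distance correlation: identity, shuffle null, coverage", {
  ens <- cached_mini_ensemble()
  cm <- contact_map(ens)
  self <- matrix_distance_correlation(cm, cm)
  expect_true(all(abs(self$correlation[self$n_pairs >= 3] - 1) < 1e-9,
                  na.rm = TRUE))
  # strata cover all intra-chromosomal off-diagonal distances
  nA <- sum(cm$bins$chain == "A"); nB <- sum(cm$bins$chain == "B")
  expect_equal(max(self$stratum, na.rm = TRUE), max(nA, nB) - 1)

  set.seed(99)
  shuf <- cm
  perm <- sample(nrow(shuf$values))
  shuf$values <- shuf$values[perm, perm]
  null <- matrix_distance_correlation(cm, shuf)
  overall <- null$correlation[is.na(null$stratum)]
  expect_lt(abs(overall), 0.25)
  expect_error(matrix_distance_correlation(cm$values, cm$values[-1, -1]),
               "bin schemes")
})
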