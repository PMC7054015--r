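test_that("bead tiling follows the ceiling rule with flags", {
  # exact division: 320 kb at 3.2 kb/bead -> 100 beads
  b <- build_bead_chain(chromosome_spec("X", 320000, 160000))
  expect_equal(nrow(b), 100)
  expect_equal(sum(b$is_centromere), 1)
  expect_true(b$is_centromere[b$start <= 160000 & b$end > 160000])
  expect_equal(sum(b$is_terminal), 2)

  # 20-kb telomeric region: ceiling(20000/3200) = 7 beads at each free end,
  # cross-checked by brute-force interval overlap
  tel_left <- which(b$is_telomeric & b$bead <= 50)
  expect_equal(tel_left, 1:7)
  tel_right <- which(b$is_telomeric & b$bead > 50)
  brute <- which(b$start < 320000 & b$end > 320000 - 20000)
  expect_equal(tel_right, intersect(brute, 51:100))
  expect_equal(length(tel_right), 7)

  # remainder bp on the final bead
  b2 <- build_bead_chain(chromosome_spec("Y", 10001, 5000))
  expect_equal(nrow(b2), ceiling(10001 / 3200))
  expect_equal(b2$end[nrow(b2)] - b2$start[nrow(b2)], 10001 %% 3200)

  expect_error(build_bead_chain(chromosome_spec("Z", 1, 0.5), 0),
               "bp_per_bead")
})

test_that("wild-type genome totals 4062 beads with 16 chromosomes", {
  kar <- yeast_karyotype()
  s <- karyotype_summary(kar)
  expect_equal(s$n_chromosomes, 16L)
  expect_equal(s$n_telomeres, 32L)
  expect_equal(s$n_beads, 4062L)
  beads <- build_bead_chains(kar)
  expect_equal(nrow(beads), 4062)
  expect_equal(sum(beads$is_centromere), 16)
  expect_equal(sum(beads$is_terminal), 32)
  expect_true(any(beads$is_rdna & beads$chain == "XII"))
  expect_false(any(beads$is_rdna & beads$chain != "XII"))
  # bead intervals tile each chromosome without overlap
  for (ch in c("I", "XII")) {
    cb <- beads[beads$chain == ch, ]
    expect_equal(cb$start[-1], cb$end[-nrow(cb)])
    expect_equal(cb$start[1], 0)
  }
})

test_that("fusion plans update chromosome, telomere and centromere counts", {
  kar <- yeast_karyotype()

  ev <- fusion_event("IV", "XII", retained_centromere = "IV")
  fc1 <- apply_fusion_plan(kar, ev)
  s1 <- karyotype_summary(fc1)
  expect_equal(s1$n_chromosomes, 15L)
  expect_equal(s1$n_telomeres, 30L)
  fused <- fc1$chromosomes[[which(purrr::map_chr(fc1$chromosomes, "name") == "IV:XII")]]
  fb <- build_bead_chain(fused, specs = kar$specs)
  expect_equal(sum(fb$is_centromere), 1)

  # the four-way fusion of the largest strain: 13 chromosomes, 26 telomeres
  fc4 <- apply_fusion_plan(kar, fc_fusion_plan("FC(IV:V:VII:XV)CEN4"))
  s4 <- karyotype_summary(fc4)
  expect_equal(s4$n_chromosomes, 13L)
  expect_equal(s4$n_centromeres, 13L)
  expect_equal(s4$n_telomeres, 26L)

  # junction beads are internal: no terminal/telomeric flags
  bf <- build_bead_chains(fc4)
  jb <- bf[bf$chain == "IV:V:VII:XV" & bf$source == "IV", ]
  expect_false(any(jb$is_telomeric[jb$src_start > 100000]))
  expect_equal(sum(bf$is_terminal[bf$chain == "IV:V:VII:XV"]), 2)

  # reusing a consumed end is rejected
  expect_error(
    apply_fusion_plan(fc1, fusion_event("IV", "XII")),
    "same chromosome")
  expect_error(
    apply_fusion_plan(kar, fusion_event("I", "II", retained_centromere = "III")),
    "retained_centromere")
})

test_that("bead count is conserved across fusions minus junction deletions", {
  kar <- yeast_karyotype()
  n0 <- nrow(build_bead_chains(kar))
  for (strain in c("FC(IV:XII)CEN4", "FC(IV:XV:V)CEN5", "FC(IV:V:VII:XV)CEN7")) {
    fc <- apply_fusion_plan(kar, fc_fusion_plan(strain))
    expect_equal(nrow(build_bead_chains(fc)), n0)
    s <- karyotype_summary(fc)
    expect_equal(s$n_telomeres, 2L * s$n_chromosomes)
  }
  # deleting exactly two beads' worth of sequence at the junction
  fc <- apply_fusion_plan(kar, fusion_event(
    "I", "II", deleted_bp_recipient = 3200, deleted_bp_donor = 3200))
  expect_equal(nrow(build_bead_chains(fc)), n0 - 2)
})

test_that("longest fused arm equals the brute-force segment sum", {
  kar <- yeast_karyotype()
  fc <- apply_fusion_plan(kar, fc_fusion_plan("FC(IV:XV:V)CEN4"))
  s <- karyotype_summary(fc)
  # CEN4 retained: the right arm runs from CEN4 to the far end of V
  expected <- (.SC_LENGTHS[["IV"]] - .SC_CENTROMERES[["IV"]]) +
    .SC_LENGTHS[["XV"]] + .SC_LENGTHS[["V"]]
  expect_equal(s$longest_arm_bp, unname(expected))
  # empty karyotype: all counts zero
  empty <- karyotype(chromosome_spec("tmp", 10, 5))
  empty$chromosomes <- list()
  expect_equal(karyotype_summary(empty)$n_beads, 0L)
})

test_that("karyotype YAML round-trip reproduces bead annotations", {
  kar <- apply_fusion_plan(yeast_karyotype(), fc_fusion_plan("FC(IV:XII)CEN12"))
  tmp <- tempfile(fileext = ".yaml")
  write_karyotype_yaml(kar, tmp)
  back <- read_karyotype_yaml(tmp)
  expect_equal(build_bead_chains(back), build_bead_chains(kar))
})

test_that("gene mapping respects fusions and junction deletions", {
  kar <- yeast_karyotype()
  fc <- apply_fusion_plan(kar, fusion_event(
    "I", "III", deleted_bp_recipient = 6400, deleted_bp_donor = 0))
  genes <- tibble::tibble(
    gene_id = c("keep", "lost", "donor_side"),
    chrom = c("I", "I", "III"),
    start = c(1000, 230218 - 5000, 500),
    end = c(2500, 230218 - 1000, 2000))
  m <- map_genes_to_beads(fc, genes)
  expect_false(any(m$deleted[m$gene_id == "keep"]))
  expect_true(all(m$deleted[m$gene_id == "lost"]))
  expect_false(any(m$deleted[m$gene_id == "donor_side"]))
  # mapped beads overlap the gene in source coordinates
  beads <- build_bead_chains(fc)
  hit <- beads[m$index[m$gene_id == "keep"], ]
  expect_true(all(hit$src_start < 2500 & hit$src_end > 1000))
})

test_that("deleted-telomere distances follow the replayed fusion plan", {
  kar <- yeast_karyotype()
  fc <- apply_fusion_plan(kar, fc_fusion_plan("FC(IV:XV)CEN4"))
  genes <- tibble::tibble(
    gene_id = c("iv_right", "xv_left", "xv_right", "vii_any"),
    chrom = c("IV", "XV", "XV", "VII"),
    start = c(1531933 - 11000, 9000, 1091291 - 11000, 500000),
    end = c(1531933 - 9000, 11000, 1091291 - 9000, 501500))
  d <- gene_genomic_distances(genes, kar, fc)
  # junction consumed IV right and XV left ends
  expect_equal(d$dist_deleted_telomere_kb[d$gene_id == "iv_right"], 10)
  expect_equal(d$dist_deleted_telomere_kb[d$gene_id == "xv_left"], 10)
  # XV right telomere survives; distance measured to the deleted left end
  expect_equal(d$dist_deleted_telomere_kb[d$gene_id == "xv_right"],
               (1091291 - 10000) / 1000)
  expect_true(is.na(d$dist_deleted_telomere_kb[d$gene_id == "vii_any"]))
  expect_false(any(d$cen_lost[d$gene_id == "iv_right"]))
  expect_true(all(d$cen_lost[d$chrom == "XV"]))
  expect_true(all(d$on_fused[d$chrom %in% c("IV", "XV")]))
  expect_false(any(d$on_fused[d$chrom == "VII"]))
})
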