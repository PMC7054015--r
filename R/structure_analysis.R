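#' Per-bead shell occupancy over an ensemble
#'
#' Classifies every bead of every conformation into the three equal-volume
#' concentric shells and returns, per bead, the fraction of conformations
#' spent in each. Beads found outside the nucleus (a restraint-tolerance
#' effect) are counted as peripheral and a warning is raised.
#'
#' @param ensemble A `nuc_ensemble`.
#' @param geometry A [nuclear_geometry()]; taken from the ensemble's
#'   provenance when available.
#' @return Tibble: bead columns plus `frac_central`, `frac_middle`,
#'   `frac_peripheral`, `pct_peripheral` (0-100) and `n_conformations`.
#' @export
shell_occupancy <- function(ensemble, geometry = NULL) {
  stopifnot(inherits(ensemble, "nuc_ensemble"),
            length(ensemble$conformations) > 0)
  geometry <- geometry %||% ensemble$provenance$geometry %||% nuclear_geometry()
  n <- nrow(ensemble$beads)
  counts <- matrix(0L, n, 3,
                   dimnames = list(NULL, c("central", "middle", "peripheral")))
  n_out <- 0
  for (m in ensemble$conformations) {
    r <- sqrt(rowSums(m^2))
    cls <- 1L + (r > geometry$shell_r1) + (r > geometry$shell_r2)
    n_out <- n_out + sum(r > geometry$r_nuc)
    for (k in 1:3) counts[, k] <- counts[, k] + (cls == k)
  }
  if (n_out > 0) {
    warning(n_out, " bead observations outside the nucleus counted as peripheral")
  }
  nc <- length(ensemble$conformations)
  dplyr::bind_cols(
    ensemble$beads,
    tibble::tibble(
      frac_central = counts[, 1] / nc,
      frac_middle = counts[, 2] / nc,
      frac_peripheral = counts[, 3] / nc,
      pct_peripheral = 100 * counts[, 3] / nc,
      n_conformations = nc
    )
  )
}

#' Per-gene percentage peripheral
#'
#' Maps genes onto beads (any-overlap) and averages the per-bead peripheral
#' fractions (unweighted mean over a gene's constitutive beads). Genes
#' deleted by the karyotype's fusion plan are flagged and carry NA.
#'
#' @param occupancy Output of [shell_occupancy()].
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, source
#'   coordinates).
#' @param kar The karyotype the occupancy was computed on.
#' @param bp_per_bead Bead size in bp.
#' @return Tibble: `gene_id`, `pct_peripheral`, `n_beads`, `deleted`.
#' @export
gene_percent_peripheral <- function(occupancy, genes, kar,
                                    bp_per_bead = 3200) {
  g2b <- map_genes_to_beads(kar, genes, bp_per_bead)
  occ <- occupancy[, c("index", "frac_peripheral")]
  g2b |>
    dplyr::left_join(occ, by = "index") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      pct_peripheral = ifelse(any(.data$deleted), NA_real_,
                              100 * mean(.data$frac_peripheral)),
      n_beads = sum(!is.na(.data$bead)),
      deleted = any(.data$deleted),
      .groups = "drop"
    )
}

#' Gene position table: wild-type vs strain
#'
#' Combines per-gene percentage peripheral in the wild-type and one fused
#' strain with the genomic covariates used downstream: the change
#' `delta_pct_peripheral = strain - WT` (percentage points; negative =
#' displaced away from the periphery), distance to the nearest wild-type
#' telomere and to the centromere, distance to the nearest telomere deleted
#' by the fusion plan, and the centromere-lost flag. Deleted genes are
#' excluded.
#'
#' @param occ_wt,occ_strain [shell_occupancy()] tables for the two ensembles.
#' @param genes Gene tibble in source coordinates.
#' @param kar_wt,kar_strain The two karyotypes.
#' @param strain Strain label carried in the output.
#' @param bp_per_bead Bead size in bp.
#' @return Tibble with one row per retained gene.
#' @export
gene_position_table <- function(occ_wt, occ_strain, genes, kar_wt, kar_strain,
                                strain = "FC", bp_per_bead = 3200) {
  pw <- gene_percent_peripheral(occ_wt, genes, kar_wt, bp_per_bead) |>
    dplyr::select("gene_id", pct_peripheral_wt = "pct_peripheral")
  ps <- gene_percent_peripheral(occ_strain, genes, kar_strain, bp_per_bead) |>
    dplyr::select("gene_id", pct_peripheral_strain = "pct_peripheral",
                  "deleted")
  dists <- gene_genomic_distances(genes, kar_wt, kar_strain)
  out <- pw |>
    dplyr::inner_join(ps, by = "gene_id") |>
    dplyr::inner_join(dists, by = "gene_id") |>
    dplyr::filter(!.data$deleted) |>
    dplyr::mutate(
      strain = strain,
      delta_pct_peripheral = .data$pct_peripheral_strain -
        .data$pct_peripheral_wt
    ) |>
    dplyr::select(-"deleted")
  out
}

#' NE displacement of 10-kb loci between two ensembles
#'
#' Chromosomes are partitioned into groups of three consecutive beads
#' (about 10 kb; a trailing remainder of one or two beads forms a final
#' short locus). For each locus the distance to the nuclear envelope
#' (`r_nuc - |position|`, bead centre convention) is averaged over the
#' locus beads and over conformations in each ensemble; the displacement is
#' `ensemble_b - ensemble_a` (positive = moved away from the NE in b).
#' Loci are matched through shared source-chromosome bead coordinates, so a
#' wild-type and a fused ensemble can be compared bead for bead.
#'
#' @param ens_a,ens_b Two `nuc_ensemble`s over the same source genome.
#' @param geometry A [nuclear_geometry()].
#' @return Tibble: `source`, `locus`, `start`, `end` (source bp),
#'   `ne_dist_a`, `ne_dist_b`, `displacement` (nm).
#' @export
locus_ne_displacement_10kb <- function(ens_a, ens_b,
                                       geometry = nuclear_geometry()) {
  mean_ne <- function(ens) {
    acc <- numeric(nrow(ens$beads))
    for (m in ens$conformations) {
      acc <- acc + (geometry$r_nuc - sqrt(rowSums(m^2)))
    }
    acc / length(ens$conformations)
  }
  key <- function(b) paste(b$source, b$src_start, sep = ":")
  a <- tibble::tibble(key = key(ens_a$beads), ne_a = mean_ne(ens_a),
                      source = ens_a$beads$source,
                      src_start = ens_a$beads$src_start,
                      src_end = ens_a$beads$src_end)
  b <- tibble::tibble(key = key(ens_b$beads), ne_b = mean_ne(ens_b))
  dplyr::inner_join(a, b, by = "key") |>
    dplyr::arrange(.data$source, .data$src_start) |>
    dplyr::group_by(.data$source) |>
    dplyr::mutate(locus = (dplyr::row_number() - 1) %/% 3 + 1) |>
    dplyr::group_by(.data$source, .data$locus) |>
    dplyr::summarise(
      start = min(.data$src_start), end = max(.data$src_end),
      ne_dist_a = mean(.data$ne_a), ne_dist_b = mean(.data$ne_b),
      .groups = "drop"
    ) |>
    dplyr::mutate(displacement = .data$ne_dist_b - .data$ne_dist_a)
}

#' Per-bead SPB distance difference between two ensembles
#'
#' Mean bead-to-SPB distance per ensemble, matched on source coordinates;
#' the difference `ens_fc - ens_wt` is positive when a bead typically sits
#' further from the SPB in the second (fusion) ensemble.
#'
#' @param ens_wt,ens_fc Two `nuc_ensemble`s over the same source genome.
#' @param geometry A [nuclear_geometry()].
#' @return Tibble: `source`, `src_start`, `src_end`, `spb_dist_wt`,
#'   `spb_dist_fc`, `difference` (nm).
#' @export
spb_distance_difference <- function(ens_wt, ens_fc,
                                    geometry = nuclear_geometry()) {
  mean_spb <- function(ens) {
    acc <- numeric(nrow(ens$beads))
    for (m in ens$conformations) {
      acc <- acc + sqrt(rowSums(sweep(m, 2, geometry$c_spb)^2))
    }
    acc / length(ens$conformations)
  }
  key <- function(b) paste(b$source, b$src_start, sep = ":")
  a <- tibble::tibble(key = key(ens_wt$beads),
                      source = ens_wt$beads$source,
                      src_start = ens_wt$beads$src_start,
                      src_end = ens_wt$beads$src_end,
                      spb_dist_wt = mean_spb(ens_wt))
  b <- tibble::tibble(key = key(ens_fc$beads), spb_dist_fc = mean_spb(ens_fc))
  dplyr::inner_join(a, b, by = "key") |>
    dplyr::mutate(difference = .data$spb_dist_fc - .data$spb_dist_wt) |>
    dplyr::select(-"key")
}

#' Distance statistics between two loci (or a locus and SPB/NE)
#'
#' A locus is a set of bead indices; its per-conformation distance is the
#' mean of its beads' distances to the target (another locus, the SPB point
#' or the NE surface). Returns the mean, SD and median over conformations.
#'
#' @param ensemble A `nuc_ensemble`.
#' @param locus_a Integer bead indices (rows of `ensemble$beads`).
#' @param locus_b Integer bead indices, or `"SPB"` or `"NE"`.
#' @param geometry A [nuclear_geometry()].
#' @return One-row tibble: `mean`, `sd`, `median` (nm), `n_conformations`.
#' @export
pair_distance_stats <- function(ensemble, locus_a, locus_b,
                                geometry = nuclear_geometry()) {
  per_conf <- vapply(ensemble$conformations, function(m) {
    pa <- m[locus_a, , drop = FALSE]
    if (identical(locus_b, "SPB")) {
      mean(sqrt(rowSums(sweep(pa, 2, geometry$c_spb)^2)))
    } else if (identical(locus_b, "NE")) {
      mean(geometry$r_nuc - sqrt(rowSums(pa^2)))
    } else {
      pb <- m[locus_b, , drop = FALSE]
      # mean over corresponding particle pairs (recycled to equal length)
      k <- max(nrow(pa), nrow(pb))
      ia <- rep_len(seq_len(nrow(pa)), k); ib <- rep_len(seq_len(nrow(pb)), k)
      mean(sqrt(rowSums((pa[ia, , drop = FALSE] - pb[ib, , drop = FALSE])^2)))
    }
  }, numeric(1))
  tibble::tibble(mean = mean(per_conf), sd = stats::sd(per_conf),
                 median = stats::median(per_conf),
                 n_conformations = length(per_conf))
}

#' Median distances for all telomere pairs
#'
#' Median over conformations of the distance between every pair of terminal
#' beads (the model telomeres).
#'
#' @param ensemble A `nuc_ensemble`.
#' @return Tibble: `telomere_a`, `telomere_b` (bead indices), `median_nm`.
#' @export
telomere_pair_medians <- function(ensemble) {
  idx <- ensemble$beads$index[ensemble$beads$is_terminal]
  pairs <- utils::combn(idx, 2)
  d <- matrix(0, length(ensemble$conformations), ncol(pairs))
  for (ci in seq_along(ensemble$conformations)) {
    m <- ensemble$conformations[[ci]]
    a <- m[pairs[1, ], , drop = FALSE]
    b <- m[pairs[2, ], , drop = FALSE]
    d[ci, ] <- sqrt(rowSums((a - b)^2))
  }
  tibble::tibble(telomere_a = pairs[1, ], telomere_b = pairs[2, ],
                 median_nm = apply(d, 2, stats::median))
}

#' 2D localization probability density map
#'
#' Projects bead positions of one chromosome (or all) onto the axial/radial
#' frame `(a, rho) = (x, sqrt(y^2 + z^2))`, accumulates a Gaussian kernel
#' (sigma 30 nm) per observation on a 2 x 2 micrometre grid of 10-nm pixels,
#' and normalizes the map to \[0, 1\].
#'
#' @param ensemble A `nuc_ensemble`.
#' @param chain Chain name to map, or `NULL` for all beads.
#' @param grid_nm Grid extent (square side) in nm.
#' @param pixel_nm Pixel size in nm.
#' @param blur_sigma Gaussian kernel SD in nm.
#' @param normalize Scale the map to a maximum of 1.
#' @return A `density_map_2d` object: list with `values` (axial x radial
#'   matrix), `a_breaks`, `rho_breaks`.
#' @export
density_map_2d <- function(ensemble, chain = NULL, grid_nm = 2000,
                           pixel_nm = 10, blur_sigma = 30,
                           normalize = TRUE) {
  stopifnot(length(ensemble$conformations) > 0)
  npx <- round(grid_nm / pixel_nm)
  sel <- if (is.null(chain)) rep(TRUE, nrow(ensemble$beads))
         else ensemble$beads$chain == chain
  if (!any(sel)) stop("no beads in chain '", chain, "'")
  vals <- matrix(0, npx, npx)  # rows: axial a in [-grid/2, grid/2); cols: rho in [0, grid)
  hw <- ceiling(3 * blur_sigma / pixel_nm)
  ker_off <- -hw:hw
  kern <- exp(-0.5 * (outer(ker_off^2, ker_off^2, "+")) *
                (pixel_nm / blur_sigma)^2)
  for (m in ensemble$conformations) {
    a <- m[sel, 1]
    rho <- sqrt(m[sel, 2]^2 + m[sel, 3]^2)
    ia <- floor((a + grid_nm / 2) / pixel_nm) + 1
    ir <- floor(rho / pixel_nm) + 1
    ok <- ia >= 1 & ia <= npx & ir >= 1 & ir <= npx
    for (p in which(ok)) {
      ra <- ia[p] + ker_off; rr <- ir[p] + ker_off
      ka <- which(ra >= 1 & ra <= npx); kr <- which(rr >= 1 & rr <= npx)
      vals[ra[ka], rr[kr]] <- vals[ra[ka], rr[kr]] + kern[ka, kr]
    }
  }
  if (normalize && max(vals) > 0) vals <- vals / max(vals)
  structure(list(values = vals,
                 a_breaks = seq(-grid_nm / 2, grid_nm / 2, by = pixel_nm),
                 rho_breaks = seq(0, grid_nm, by = pixel_nm),
                 chain = chain %||% "all"),
            class = "density_map_2d")
}

#' In-silico contact map
#'
#' Bead pairs closer than `cutoff` nm in a conformation are contacts; bins
#' of `beads_per_bin` consecutive beads per chain (10 beads = 32 kb at the
#' default bead size) are in contact in a conformation when at least one of
#' their bead pairs is. The map holds, per bin pair, the fraction of
#' conformations with a contact (`mode = "frequency"`, bounded in \[0, 1\]
#' with unit diagonal) or the mean raw contacting-pair count
#' (`mode = "count"`).
#'
#' @param ensemble A `nuc_ensemble`.
#' @param cutoff Contact distance cutoff in nm.
#' @param beads_per_bin Beads per genomic bin.
#' @param mode `"frequency"` or `"count"`.
#' @return A `contact_map` object: list with symmetric `values`, and `bins`
#'   (tibble: `bin`, `chain`, `start`, `end`).
#' @export
contact_map <- function(ensemble, cutoff = 120, beads_per_bin = 10,
                        mode = c("frequency", "count")) {
  mode <- match.arg(mode)
  stopifnot(length(ensemble$conformations) > 0)
  beads <- ensemble$beads
  bin_of <- beads |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(.bin_in = (.data$bead - 1) %/% beads_per_bin) |>
    dplyr::ungroup()
  bin_key <- paste(bin_of$chain, bin_of$.bin_in)
  bin_id <- match(bin_key, unique(bin_key))
  nb <- max(bin_id)
  bins <- bin_of |>
    dplyr::mutate(bin = bin_id) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(chain = .data$chain[1], start = min(.data$start),
                     end = max(.data$end), .groups = "drop")
  acc <- matrix(0, nb, nb)
  cut2 <- cutoff^2
  for (m in ensemble$conformations) {
    d2 <- as.matrix(stats::dist(m))^2
    hit <- d2 <= cut2
    # bin-pair contact indicator (any contacting bead pair)
    agg <- rowsum(t(rowsum(hit + 0, bin_id)), bin_id)
    if (mode == "frequency") acc <- acc + (agg > 0) else acc <- acc + agg
  }
  vals <- acc / length(ensemble$conformations)
  vals <- (vals + t(vals)) / 2  # numerically symmetric
  if (mode == "frequency") diag(vals) <- 1
  structure(list(values = vals, bins = bins, cutoff = cutoff,
                 beads_per_bin = beads_per_bin, mode = mode),
            class = "contact_map")
}

#' Stratified correlation between two contact maps
#'
#' Spearman correlation of matrix elements grouped by genomic distance
#' (in bins), within chromosomes, plus the overall off-diagonal correlation.
#' Both maps must share the same binning.
#'
#' @param map_a,map_b `contact_map` objects (or plain matrices with matching
#'   dimensions, in which case all strata are |i - j| based).
#' @param max_stratum Largest genomic distance (in bins) reported.
#' @return Tibble: `stratum` (bins; NA for the overall row), `correlation`,
#'   `n_pairs`.
#' @export
matrix_distance_correlation <- function(map_a, map_b, max_stratum = Inf) {
  va <- if (inherits(map_a, "contact_map")) map_a$values else map_a
  vb <- if (inherits(map_b, "contact_map")) map_b$values else map_b
  if (!all(dim(va) == dim(vb))) stop("contact maps have different bin schemes")
  same_chain <- if (inherits(map_a, "contact_map")) {
    outer(map_a$bins$chain, map_a$bins$chain, "==")
  } else {
    matrix(TRUE, nrow(va), ncol(va))
  }
  n <- nrow(va)
  dist_bins <- abs(outer(seq_len(n), seq_len(n), "-"))
  strata <- sort(unique(dist_bins[dist_bins > 0 & same_chain]))
  strata <- strata[strata <= max_stratum]
  rows <- purrr::map_dfr(strata, function(s) {
    sel <- dist_bins == s & same_chain & upper.tri(va)
    tibble::tibble(
      stratum = s,
      correlation = if (sum(sel) >= 3)
        suppressWarnings(stats::cor(va[sel], vb[sel], method = "spearman"))
        else NA_real_,
      n_pairs = sum(sel)
    )
  })
  sel_all <- upper.tri(va)
  dplyr::bind_rows(rows, tibble::tibble(
    stratum = NA_integer_,
    correlation = suppressWarnings(
      stats::cor(va[sel_all], vb[sel_all], method = "spearman")),
    n_pairs = sum(sel_all)
  ))
}

#' Write a contact map as TSV with a BED sidecar
#'
#' @param map A [contact_map()].
#' @param path Matrix TSV path; the bin table goes to `<path>.bins.bed`.
#' @export
write_contact_map <- function(map, path) {
  utils::write.table(map$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(map$bins$chain,
               format(map$bins$start, scientific = FALSE, trim = TRUE),
               format(map$bins$end, scientific = FALSE, trim = TRUE),
               map$bins$bin),
    paste0(path, ".bins.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}
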