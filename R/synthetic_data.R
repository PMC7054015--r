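#' Mini karyotype with tiled synthetic genes
#'
#' Builds a small karyotype (fast to simulate) with evenly tiled synthetic
#' genes, for exercising the full pipeline without genome-scale inputs.
#'
#' @param n_chroms Number of chromosomes.
#' @param lengths_bp Chromosome lengths (recycled to `n_chroms`).
#' @param centromere_frac Centromere position as a fraction of length.
#' @param gene_every Gene start spacing in bp.
#' @param gene_length Gene length in bp.
#' @param seed Unused at present (generation is deterministic); kept so
#'   callers can thread one seed through the synthetic stack.
#' @return List: `karyotype`, `genes` (tibble `gene_id`, `chrom`, `start`,
#'   `end`).
#' @examples
#' mk <- make_mini_karyotype(4, 1e5)
#' karyotype_summary(mk$karyotype)
#' @export
make_mini_karyotype <- function(n_chroms = 4, lengths_bp = 1e5,
                                centromere_frac = 0.5, gene_every = 4000,
                                gene_length = 1500, seed = 1) {
  lengths_bp <- rep_len(lengths_bp, n_chroms)
  stopifnot(all(lengths_bp > 0))
  nm <- paste0("mc", seq_len(n_chroms))
  specs <- dplyr::bind_rows(purrr::map2(
    nm, lengths_bp,
    ~ chromosome_spec(.x, .y, round(centromere_frac * .y))))
  genes <- purrr::map2_dfr(nm, lengths_bp, function(ch, len) {
    starts <- seq(0, len - gene_length, by = gene_every)
    tibble::tibble(
      gene_id = sprintf("%s_g%03d", ch, seq_along(starts)),
      chrom = ch, start = starts, end = starts + gene_length)
  })
  list(karyotype = karyotype(specs), genes = genes)
}

#' Tile synthetic genes over a karyotype
#'
#' Evenly spaced synthetic genes in source-chromosome coordinates, usable
#' with any karyotype (wild-type or fused) whose source specs are known.
#'
#' @param kar A [karyotype()].
#' @param gene_every Gene start spacing in bp.
#' @param gene_length Gene length in bp.
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`.
#' @export
tile_genes <- function(kar, gene_every = 8000, gene_length = 1500) {
  purrr::map2_dfr(kar$specs$name, kar$specs$length_bp, function(ch, len) {
    starts <- seq(0, len - gene_length, by = gene_every)
    tibble::tibble(
      gene_id = sprintf("%s_g%04d", ch, seq_along(starts)),
      chrom = ch, start = starts, end = starts + gene_length)
  })
}

#' Synthetic expression generator parameters
#'
#' Parameters of the synthetic TPM generator. The headline periphery effect
#' `g` is the fractional expression change per percentage point of decrease
#' in peripheral residency: at the default `g = 0.01`, a gene losing 25 pp
#' of peripheral residency gains a factor 1.25 of expression. The
#' subtelomeric term represses genes near chromosome ends by `delta` log2
#' units at the telomere, decaying with length scale `lambda_kb`.
#'
#' @param n_genes Gene count (used by callers that need one).
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline log2-TPM
#'   distribution.
#' @param periphery_effect Effect g (fraction per pp), >= 0.
#' @param subtel_depth Subtelomeric repression depth delta (log2 units).
#' @param subtel_lambda_kb Repression decay length (kb), > 0.
#' @param noise_sd Replicate noise SD (log2 units), >= 0.
#' @param library_size Optional Poisson counting-noise library size (reads);
#'   NA disables counting noise.
#' @param seed RNG seed.
#' @export
expression_generator_params <- function(n_genes = 2000,
                                        baseline_log2_mean = 5,
                                        baseline_log2_sd = 2,
                                        periphery_effect = 0.01,
                                        subtel_depth = 2,
                                        subtel_lambda_kb = 10,
                                        noise_sd = 0.25,
                                        library_size = NA,
                                        seed = 1) {
  stopifnot(periphery_effect >= 0, subtel_lambda_kb > 0, noise_sd >= 0)
  list(n_genes = n_genes, baseline_log2_mean = baseline_log2_mean,
       baseline_log2_sd = baseline_log2_sd,
       periphery_effect = periphery_effect, subtel_depth = subtel_depth,
       subtel_lambda_kb = subtel_lambda_kb, noise_sd = noise_sd,
       library_size = library_size, seed = seed)
}

#' Simulate an expression table
#'
#' Generates replicate TPM values per gene and strain:
#' `TPM = 2^(mu_g - delta * exp(-d_tel / lambda) +
#' log2(1 + g * (P_WT - P_strain)) + eps)`, with `eps ~ N(0, noise_sd)`.
#' Genes flagged deleted in a strain are omitted for that strain. With
#' `periphery_effect = 0`, `subtel_depth = 0` and `noise_sd = 0` every
#' strain reproduces the baseline exactly.
#'
#' @param gene_positions Tibble with `gene_id`, `strain`, `pct_peripheral`,
#'   `pct_peripheral_wt`, `dist_telomere_kb` and optional `deleted`; one row
#'   per gene x strain (include the WT strain row if WT samples are
#'   wanted).
#' @param params [expression_generator_params()].
#' @param replicates Replicates per strain.
#' @return Long tibble: `gene_id`, `strain`, `replicate`, `tpm`.
#' @export
simulate_expression <- function(gene_positions, params =
                                  expression_generator_params(),
                                replicates = 4) {
  need <- c("gene_id", "strain", "pct_peripheral", "pct_peripheral_wt",
            "dist_telomere_kb")
  stopifnot(all(need %in% names(gene_positions)))
  if (any(gene_positions$pct_peripheral < 0 |
            gene_positions$pct_peripheral > 100, na.rm = TRUE)) {
    stop("pct_peripheral outside [0, 100]")
  }
  gp <- gene_positions
  if (!"deleted" %in% names(gp)) gp$deleted <- FALSE
  gp <- gp[!gp$deleted, ]
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(params$seed)

  genes <- unique(gp$gene_id)
  mu <- stats::setNames(
    stats::rnorm(length(genes), params$baseline_log2_mean,
                 params$baseline_log2_sd), genes)

  out <- gp |>
    dplyr::mutate(
      mu = mu[.data$gene_id],
      subtel = params$subtel_depth *
        exp(-.data$dist_telomere_kb / params$subtel_lambda_kb),
      shift = log2(1 + params$periphery_effect *
                     (.data$pct_peripheral_wt - .data$pct_peripheral))
    )
  out <- tidyr::expand_grid(out, replicate = seq_len(replicates))
  out$tpm <- 2^(out$mu - out$subtel + out$shift +
                  stats::rnorm(nrow(out), 0, params$noise_sd))
  if (!is.na(params$library_size)) {
    lam <- out$tpm / 1e6 * params$library_size
    out$tpm <- stats::rpois(nrow(out), lam) / params$library_size * 1e6
  }
  out[, c("gene_id", "strain", "replicate", "tpm")]
}

#' Stub gene-position profiles
#'
#' Fast stand-in for simulator-derived percentage-peripheral values:
#' wild-type residency decays from the chromosome ends inward
#' (`base + amp * exp(-d_tel / lambda)`), and a `"fused"` profile
#' additionally displaces genes near a deleted telomere toward the interior
#' by up to `drop_pp`. Bounded to \[0, 100\]; reproducible by seed.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param kar Wild-type [karyotype()] providing chromosome lengths.
#' @param profile `"wt"` or `"fused"`.
#' @param fused_chroms Chromosomes whose (left) telomere was deleted in the
#'   fused profile.
#' @param base_pp,amp_pp Interior residency and subtelomeric amplitude (pp).
#' @param lambda_kb Wild-type decay length (kb).
#' @param drop_pp Maximum displacement on fused arms (pp).
#' @param drop_lambda_kb Displacement decay length (kb).
#' @param noise_pp Gaussian jitter (pp).
#' @param seed RNG seed.
#' @return Tibble: `gene_id`, `chrom`, `pct_peripheral`,
#'   `dist_telomere_kb`, `dist_deleted_telomere_kb` (fused profile only).
#' @export
make_position_stub <- function(genes, kar, profile = c("wt", "fused"),
                               fused_chroms = NULL,
                               base_pp = 25, amp_pp = 65, lambda_kb = 40,
                               drop_pp = 30, drop_lambda_kb = 100,
                               noise_pp = 2, seed = 1) {
  profile <- match.arg(profile)
  len <- stats::setNames(kar$specs$length_bp, kar$specs$name)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(seed)
  mid <- (genes$start + genes$end) / 2
  d_tel <- pmin(mid, len[genes$chrom] - mid) / 1000
  pct <- base_pp + amp_pp * exp(-d_tel / lambda_kb) +
    stats::rnorm(nrow(genes), 0, noise_pp)
  d_del <- rep(NA_real_, nrow(genes))
  if (profile == "fused") {
    if (is.null(fused_chroms)) fused_chroms <- unique(genes$chrom)[1]
    on_fused <- genes$chrom %in% fused_chroms
    d_del[on_fused] <- mid[on_fused] / 1000  # left telomere deleted
    pct[on_fused] <- pct[on_fused] -
      drop_pp * exp(-d_del[on_fused] / drop_lambda_kb)
  }
  tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    pct_peripheral = pmin(100, pmax(0, pct)),
    dist_telomere_kb = unname(d_tel),
    dist_deleted_telomere_kb = d_del
  )
}
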