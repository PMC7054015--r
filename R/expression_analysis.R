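#' Baseline expression from position-stable strains
#'
#' For each gene, the strains in which its predicted peripheral residency
#' changes by less than `threshold_pp` percentage points (the wild type
#' always qualifies, at zero change) are eligible; the baseline is the
#' median over eligible strains of the per-strain replicate medians. When no
#' strain is eligible the wild-type replicate median is used as a fallback.
#'
#' @param expr Long expression tibble: `gene_id`, `strain`, `replicate`,
#'   `tpm`.
#' @param gene_positions Tibble with `gene_id`, `strain`,
#'   `delta_pct_peripheral` (pp, strain minus WT); the wild-type strain may
#'   be absent (treated as zero change).
#' @param wt_strain Label of the wild-type strain in `expr`.
#' @param threshold_pp Eligibility threshold in percentage points.
#' @return Tibble: `gene_id`, `baseline`, `n_eligible_strains`.
#' @export
baseline_expression <- function(expr, gene_positions, wt_strain = "WT",
                                threshold_pp = 1) {
  strain_median <- expr |>
    dplyr::group_by(.data$gene_id, .data$strain) |>
    dplyr::summarise(med = stats::median(.data$tpm), .groups = "drop")
  dpp <- gene_positions |>
    dplyr::select("gene_id", "strain", "delta_pct_peripheral")
  eligible <- strain_median |>
    dplyr::left_join(dpp, by = c("gene_id", "strain")) |>
    dplyr::mutate(delta_pct_peripheral = dplyr::if_else(
      .data$strain == wt_strain, 0, .data$delta_pct_peripheral)) |>
    dplyr::filter(!is.na(.data$delta_pct_peripheral),
                  abs(.data$delta_pct_peripheral) < threshold_pp)
  base <- eligible |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(baseline = stats::median(.data$med),
                     n_eligible_strains = dplyr::n(), .groups = "drop")
  # fallback: wild-type median for genes with no eligible strain
  wt_med <- strain_median |>
    dplyr::filter(.data$strain == wt_strain) |>
    dplyr::select("gene_id", wt_baseline = "med")
  all_genes <- expr |> dplyr::distinct(.data$gene_id)
  all_genes |>
    dplyr::left_join(base, by = "gene_id") |>
    dplyr::left_join(wt_med, by = "gene_id") |>
    dplyr::mutate(
      baseline = dplyr::coalesce(.data$baseline, .data$wt_baseline),
      n_eligible_strains = dplyr::coalesce(.data$n_eligible_strains, 0L)
    ) |>
    dplyr::filter(!is.na(.data$baseline)) |>
    dplyr::select("gene_id", "baseline", "n_eligible_strains")
}

#' Log2 fold change against the baseline
#'
#' `log2((strain replicate-median + c) / (baseline + c))` per gene and
#' strain, with pseudocount `c` guarding low-abundance genes.
#'
#' @param expr Long expression tibble (`gene_id`, `strain`, `replicate`,
#'   `tpm`).
#' @param baseline Output of [baseline_expression()].
#' @param pseudocount Pseudocount c in TPM.
#' @param exclude_strains Strains not to report (e.g. the wild type itself).
#' @return Tibble: `gene_id`, `strain`, `expr_median`, `baseline`, `lfc`.
#' @export
log2_fold_change <- function(expr, baseline, pseudocount = 0.1,
                             exclude_strains = character()) {
  expr |>
    dplyr::filter(!.data$strain %in% exclude_strains) |>
    dplyr::group_by(.data$gene_id, .data$strain) |>
    dplyr::summarise(expr_median = stats::median(.data$tpm),
                     .groups = "drop") |>
    dplyr::inner_join(baseline[, c("gene_id", "baseline")], by = "gene_id") |>
    dplyr::mutate(lfc = log2((.data$expr_median + pseudocount) /
                               (.data$baseline + pseudocount)))
}

#' Expression trend against predicted peripheral displacement
#'
#' Robust LOESS fit of log2 fold change against the change in percentage
#' peripheral, with a window of `window_genes` points (span =
#' `window_genes / n`, symmetric family -- the MATLAB `smooth(...,'rloess')`
#' convention), plus a binned-group summary: genes grouped by predicted
#' decrease in peripheral residency, one-way ANOVA across groups, and Tukey
#' honest-significant-difference contrasts of every group against the
#' non-displaced reference group. Each group's mean fold change also yields
#' an implied periphery-effect slope `g = (2^lfc - 1) / drop_pp`.
#'
#' @param data Tibble with `delta_pct_peripheral` (pp, strain minus WT) and
#'   `lfc` columns (one row per gene x strain).
#' @param window_genes LOESS window size in points.
#' @param breaks_pp Group breaks on the *decrease* `-delta_pct_peripheral`
#'   (pp); the first group is the non-displaced reference.
#' @return A `position_trend` object: list with `loess` (tibble
#'   `delta_pct_peripheral`, `fit`, `se`), `groups` (per-group summary with
#'   Tukey adjusted p against the reference), `anova_p`, and `n`.
#' @export
position_trend <- function(data, window_genes = 100,
                           breaks_pp = c(-Inf, 1, 5, 10, 20, Inf)) {
  stopifnot(all(c("delta_pct_peripheral", "lfc") %in% names(data)))
  d <- data |>
    dplyr::filter(is.finite(.data$delta_pct_peripheral),
                  is.finite(.data$lfc)) |>
    dplyr::arrange(.data$delta_pct_peripheral)
  n <- nrow(d)
  if (n < 10) stop("too few points for a trend")
  win <- min(window_genes, n)
  if (win < window_genes) {
    warning("window shrunk to ", win, " points (n = ", n, ")")
  }
  # heavy ties in delta %P (many non-displaced genes) make local quadratic
  # windows rank-deficient; loess falls back to the pseudoinverse and says
  # so per window, which is expected here
  lo <- suppressWarnings(
    stats::loess(lfc ~ delta_pct_peripheral, data = d,
                 span = win / n, degree = 2, family = "symmetric",
                 surface = "direct"))
  grid <- tibble::tibble(
    delta_pct_peripheral = seq(min(d$delta_pct_peripheral),
                               max(d$delta_pct_peripheral), length.out = 200))
  pr <- suppressWarnings(stats::predict(lo, newdata = grid, se = TRUE))
  grid$fit <- as.numeric(pr$fit)
  grid$se <- as.numeric(pr$se.fit)

  d$drop_pp <- -d$delta_pct_peripheral
  d$group <- cut(d$drop_pp, breaks = breaks_pp, right = TRUE)
  ref <- levels(d$group)[1]
  groups <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_drop_pp = mean(.data$drop_pp),
      mean_lfc = mean(.data$lfc),
      implied_g = (2^mean(.data$lfc) - 1) / mean(.data$drop_pp),
      .groups = "drop"
    )
  keep <- table(d$group)[levels(d$group)] >= 2
  av_p <- NA_real_
  tk <- NULL
  if (sum(keep, na.rm = TRUE) >= 2) {
    dd <- d[d$group %in% names(keep)[keep], ]
    dd$group <- droplevels(dd$group)
    fit <- stats::aov(lfc ~ group, data = dd)
    av_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tuk <- stats::TukeyHSD(fit)$group
    cmp <- rownames(tuk)
    vs_ref <- grepl(paste0("-", ref), cmp, fixed = TRUE) |
      grepl(paste0(ref, "-"), cmp, fixed = TRUE)
    tk <- tibble::tibble(contrast = cmp[vs_ref],
                         diff = tuk[vs_ref, "diff"],
                         p_adj = tuk[vs_ref, "p adj"])
  }
  structure(list(loess = grid, groups = groups, tukey = tk,
                 anova_p = av_p, reference_group = ref, n = n,
                 window = win),
            class = "position_trend")
}

#' @export
print.position_trend <- function(x, ...) {
  cat(sprintf("<position_trend> %d gene-strain points, LOESS window %d\n",
              x$n, x$window))
  cat(sprintf("  group ANOVA p = %.3g\n", x$anova_p))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.position_trend <- function(x, ...) {
  out <- x$groups
  if (!is.null(x$tukey)) {
    out$p_adj_vs_reference <- c(NA, x$tukey$p_adj)[
      match(out$group, c(x$reference_group,
                         sub(paste0("-", x$reference_group), "",
                             x$tukey$contrast, fixed = TRUE)))]
  }
  out
}

#' @export
glance.position_trend <- function(x, ...) {
  tibble::tibble(n = x$n, window = x$window, anova_p = x$anova_p)
}

#' Count genes that move and change expression
#'
#' Counts genes predicted to change peripheral residency by more than
#' `min_move_pp` percentage points whose expression differs significantly
#' (two-sample t-test on log2(TPM + c), p < `alpha`) between the strain's
#' replicates and the replicates of that gene's baseline-eligible strains.
#' No multiple-testing correction is applied to the per-gene tests.
#'
#' @param expr Long expression tibble.
#' @param gene_positions Per gene x strain `delta_pct_peripheral` tibble.
#' @param wt_strain Wild-type strain label.
#' @param min_move_pp Minimum |change| in pp for a gene to count as moving.
#' @param alpha Per-gene significance level.
#' @param pseudocount Pseudocount (TPM) inside the log.
#' @param eligible_threshold_pp Baseline-eligibility threshold (pp).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return List: `n_movers`, `n_significant`, and the per-gene `table`.
#' @export
count_significant_movers <- function(expr, gene_positions, wt_strain = "WT",
                                     min_move_pp = 5, alpha = 0.05,
                                     pseudocount = 0.1,
                                     eligible_threshold_pp = 1,
                                     var_equal = FALSE) {
  dpp <- gene_positions |>
    dplyr::select("gene_id", "strain", "delta_pct_peripheral")
  lexpr <- expr |>
    dplyr::mutate(ltpm = log2(.data$tpm + pseudocount)) |>
    dplyr::left_join(dpp, by = c("gene_id", "strain")) |>
    dplyr::mutate(delta_pct_peripheral = dplyr::if_else(
      .data$strain == wt_strain, 0, .data$delta_pct_peripheral))

  movers <- dpp |>
    dplyr::filter(abs(.data$delta_pct_peripheral) > min_move_pp,
                  .data$strain != wt_strain)
  if (nrow(movers) == 0) {
    return(list(n_movers = 0L, n_significant = 0L,
                table = tibble::tibble()))
  }
  by_gene <- split(lexpr, lexpr$gene_id)
  res <- purrr::pmap(movers, function(gene_id, strain, delta_pct_peripheral) {
    gx <- by_gene[[gene_id]]
    a <- gx$ltpm[gx$strain == strain]
    b <- gx$ltpm[!is.na(gx$delta_pct_peripheral) &
                   abs(gx$delta_pct_peripheral) < eligible_threshold_pp]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble::tibble(gene_id = gene_id, strain = strain,
                            delta_pct_peripheral = delta_pct_peripheral,
                            p_value = NA_real_, skipped = TRUE))
    }
    p <- tryCatch(stats::t.test(a, b, var.equal = var_equal)$p.value,
                  error = function(e) NA_real_)
    tibble::tibble(gene_id = gene_id, strain = strain,
                   delta_pct_peripheral = delta_pct_peripheral,
                   p_value = p, skipped = FALSE)
  })
  tab <- dplyr::bind_rows(res)
  n_skip <- sum(tab$skipped)
  if (n_skip > 0) message(n_skip, " mover genes skipped (<2 replicates per side)")
  list(n_movers = sum(!tab$skipped),
       n_significant = sum(!tab$skipped & !is.na(tab$p_value) &
                             tab$p_value < alpha),
       table = tab)
}

#' Sequential (Type I) ANOVA for centromere effects
#'
#' Fits `lfc ~ delta_pct_peripheral + wt_expr + cen_dist + cen_lost +
#' cen_dist:cen_lost` with sequential sums of squares, so each term is
#' tested for what it adds over the terms before it, on the full gene set
#' and on subsets restricted to genes within the given centromere
#' distances.
#'
#' @param data Tibble with `lfc`, `delta_pct_peripheral`, `wt_expr`,
#'   `dist_centromere_kb`, `cen_lost` columns.
#' @param subsets_kb Centromere-distance subsets (kb); `Inf` = all genes.
#' @return Tibble: `subset_kb`, `term`, `df`, `f_statistic`, `p_value`,
#'   `n_genes`.
#' @export
sequential_anova_cen <- function(data,
                                 subsets_kb = c(Inf, 200, 100, 75, 15)) {
  need <- c("lfc", "delta_pct_peripheral", "wt_expr",
            "dist_centromere_kb", "cen_lost")
  stopifnot(all(need %in% names(data)))
  purrr::map_dfr(subsets_kb, function(cut_kb) {
    d <- data |>
      dplyr::filter(is.finite(.data$lfc),
                    .data$dist_centromere_kb <= cut_kb)
    if (nrow(d) < 10 || stats::var(d$lfc) == 0) {
      terms <- c("delta_pct_peripheral", "wt_expr", "cen_dist",
                 "cen_lost", "cen_dist:cen_lost")
      return(tibble::tibble(subset_kb = cut_kb, term = terms,
                            df = NA_integer_, f_statistic = 0,
                            p_value = NA_real_, n_genes = nrow(d)))
    }
    d$cen_lost <- factor(d$cen_lost, levels = c(FALSE, TRUE))
    form <- lfc ~ delta_pct_peripheral + wt_expr + dist_centromere_kb +
      cen_lost + dist_centromere_kb:cen_lost
    if (length(unique(d$cen_lost)) < 2) {
      form <- lfc ~ delta_pct_peripheral + wt_expr + dist_centromere_kb
    }
    fit <- stats::aov(form, data = d)
    sm <- summary(fit)[[1]]
    terms <- trimws(rownames(sm))
    keep <- terms != "Residuals"
    tibble::tibble(
      subset_kb = cut_kb,
      term = sub("dist_centromere_kb", "cen_dist", terms[keep]),
      df = sm$Df[keep],
      f_statistic = sm$`F value`[keep],
      p_value = sm$`Pr(>F)`[keep],
      n_genes = nrow(d)
    )
  })
}

#' Windowed r-squared: peripheral change vs telomere distance
#'
#' For genes on fused chromosome arms, takes moving windows centred every
#' `step_kb` kb of distance-to-the-deleted-telomere (window half-width 10 kb
#' for the 20-kb variant, 25 kb for the 50-kb one), and in each window fits
#' two single-predictor linear models for the fold change: one on the
#' change in percentage peripheral, one on the log distance to the deleted
#' telomere. Reports both r-squared values and
#' `log2(r2_pct_peripheral / r2_distance)`; positive values mean peripheral
#' residency is the better predictor there.
#'
#' @param data Tibble with `lfc`, `delta_pct_peripheral`,
#'   `dist_deleted_telomere_kb`.
#' @param window_kb Full window width (20 or 50 kb).
#' @param step_kb Window centre spacing in kb.
#' @param min_genes Windows with fewer points are skipped.
#' @return Tibble: `center_kb`, `n_genes`, `r2_pct_peripheral`, `r2_dist`,
#'   `log2_ratio`.
#' @export
windowed_r2_comparison <- function(data, window_kb = 20, step_kb = 5,
                                   min_genes = 5) {
  d <- data |>
    dplyr::filter(is.finite(.data$lfc),
                  is.finite(.data$delta_pct_peripheral),
                  is.finite(.data$dist_deleted_telomere_kb))
  if (nrow(d) == 0) return(tibble::tibble())
  half <- window_kb / 2
  centers <- seq(half, max(d$dist_deleted_telomere_kb), by = step_kb)
  purrr::map_dfr(centers, function(ck) {
    w <- d[abs(d$dist_deleted_telomere_kb - ck) <= half, ]
    if (nrow(w) < min_genes) return(NULL)
    r2 <- function(x) {
      if (stats::var(x) == 0 || stats::var(w$lfc) == 0) return(NA_real_)
      summary(stats::lm(w$lfc ~ x))$r.squared
    }
    r2p <- r2(w$delta_pct_peripheral)
    r2d <- r2(log(w$dist_deleted_telomere_kb + 1))
    tibble::tibble(center_kb = ck, n_genes = nrow(w),
                   r2_pct_peripheral = r2p, r2_dist = r2d,
                   log2_ratio = log2(r2p / r2d))
  })
}

#' Resampled correlation of expression with position and telomere distance
#'
#' Draws `n_resamples` random 90% subsets of genes and, in each, computes
#' the absolute Pearson correlation of (log) expression with predicted
#' percentage peripheral and with distance to the telomere (log and linear),
#' overall and stratified by expression quartile. Also returns binned-median
#' curves and the bivariate linear model of expression on both predictors.
#'
#' @param data Tibble with `expr` (TPM), `pct_peripheral`,
#'   `dist_telomere_kb` per gene.
#' @param n_resamples Number of resamples.
#' @param frac Fraction of genes per resample.
#' @param seed RNG seed.
#' @param n_bins Bins for the binned-median curves.
#' @return List: `resamples` (long tibble of |corr| per predictor x
#'   stratum), `binned` (median expression per predictor bin), `bivariate`
#'   (coefficient table of `log expr ~ pct_peripheral + log dist`).
#' @export
resampled_correlation_comparison <- function(data, n_resamples = 1000,
                                             frac = 0.9, seed = 1,
                                             n_bins = 20) {
  stopifnot(all(c("expr", "pct_peripheral", "dist_telomere_kb") %in%
                  names(data)))
  d <- data |>
    dplyr::filter(is.finite(.data$expr), is.finite(.data$pct_peripheral),
                  is.finite(.data$dist_telomere_kb))
  d$lexpr <- log2(d$expr + 0.1)
  d$ldist <- log(d$dist_telomere_kb + 1)
  d$quartile <- dplyr::ntile(d$expr, 4)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(seed)
  k <- max(2, round(frac * nrow(d)))
  res <- purrr::map_dfr(seq_len(n_resamples), function(i) {
    s <- d[sample.int(nrow(d), k), ]
    one <- function(sub, stratum) {
      tibble::tibble(
        resample = i, stratum = stratum,
        predictor = c("pct_peripheral", "log_dist_telomere",
                      "linear_dist_telomere"),
        abs_corr = abs(c(
          stats::cor(sub$lexpr, sub$pct_peripheral),
          stats::cor(sub$lexpr, sub$ldist),
          stats::cor(sub$expr, sub$dist_telomere_kb)))
      )
    }
    dplyr::bind_rows(
      one(s, "all"),
      purrr::map_dfr(1:4, function(q) one(s[s$quartile == q, ],
                                          paste0("Q", q)))
    )
  })
  binned <- dplyr::bind_rows(
    d |>
      dplyr::mutate(bin = dplyr::ntile(.data$dist_telomere_kb, n_bins)) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(predictor = "dist_telomere_kb",
                       bin_center = stats::median(.data$dist_telomere_kb),
                       median_expr = stats::median(.data$expr),
                       .groups = "drop"),
    d |>
      dplyr::mutate(bin = dplyr::ntile(.data$pct_peripheral, n_bins)) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(predictor = "pct_peripheral",
                       bin_center = stats::median(.data$pct_peripheral),
                       median_expr = stats::median(.data$expr),
                       .groups = "drop")
  )
  biv <- stats::lm(lexpr ~ pct_peripheral + ldist, data = d)
  co <- summary(biv)$coefficients
  bivariate <- tibble::tibble(term = rownames(co), estimate = co[, 1],
                              std_error = co[, 2], p_value = co[, 4])
  list(resamples = res, binned = binned, bivariate = bivariate)
}
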