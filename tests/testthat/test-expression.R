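# Brute-force oracles on small synthetic tables, then behavioural checks
# (null calibration, parameter recovery) on generator output.

make_small_table <- function() {
  # 3 genes x 4 strains x 3 replicates with hand-set medians
  genes <- paste0("g", 1:3)
  strains <- c("WT", "S1", "S2", "S3")
  expr <- tidyr::expand_grid(gene_id = genes, strain = strains,
                             replicate = 1:3)
  base_tab <- c(g1 = 10, g2 = 20, g3 = 40)
  mult <- c(WT = 1, S1 = 1, S2 = 2, S3 = 3)
  expr$tpm <- base_tab[expr$gene_id] * mult[expr$strain] +
    (expr$replicate - 2) * 0.5  # replicate spread, median at replicate 2
  pos <- tidyr::expand_grid(gene_id = genes,
                            strain = c("S1", "S2", "S3"))
  # S1 position-stable for all genes; S2 stable for g1 only; S3 never
  pos$delta_pct_peripheral <- ifelse(
    pos$strain == "S1", 0.2,
    ifelse(pos$strain == "S2" & pos$gene_id == "g1", -0.5, -30))
  list(expr = expr, pos = pos)
}

test_that("baseline is the nested median over position-stable strains", {
  st <- make_small_table()
  base <- baseline_expression(st$expr, st$pos)
  # brute force: per-strain replicate medians, then median over eligible
  brute <- function(g) {
    med <- sapply(split(st$expr$tpm[st$expr$gene_id == g],
                        st$expr$strain[st$expr$gene_id == g]), median)
    elig <- c("WT", "S1", if (g == "g1") "S2")
    median(med[elig])
  }
  for (g in paste0("g", 1:3)) {
    expect_equal(base$baseline[base$gene_id == g], brute(g))
  }
  # eligible per-strain medians {10, 20, 30} -> baseline 20
  toy <- tibble::tibble(
    gene_id = "g", strain = rep(c("A", "B", "C"), each = 1),
    replicate = 1L, tpm = c(10, 20, 30))
  toy_pos <- tibble::tibble(gene_id = "g", strain = c("A", "B", "C"),
                            delta_pct_peripheral = 0)
  expect_equal(baseline_expression(toy, toy_pos, wt_strain = "A")$baseline, 20)
  # no eligible strain -> wild-type fallback
  toy_pos2 <- toy_pos; toy_pos2$delta_pct_peripheral <- 10
  expect_equal(baseline_expression(toy, toy_pos2, wt_strain = "A")$baseline, 10)
})

test_that("log2 fold change follows the pseudocount policy", {
  base <- tibble::tibble(gene_id = c("g1", "g2"), baseline = c(10, 10),
                         n_eligible_strains = 1L)
  expr <- tibble::tibble(gene_id = c("g1", "g1", "g2"),
                         strain = c("A", "B", "A"),
                         replicate = 1L, tpm = c(10, 20, 0))
  fc <- log2_fold_change(expr, base, pseudocount = 0.1)
  expect_equal(fc$lfc[fc$gene_id == "g1" & fc$strain == "A"], 0)
  expect_equal(fc$lfc[fc$gene_id == "g1" & fc$strain == "B"],
               log2(20.1 / 10.1))
  expect_equal(fc$lfc[fc$gene_id == "g2"], log2(0.1 / 10.1))
})

test_that("LOESS trend is flat under the null and recovers an injected
           periphery effect", {
  set.seed(21)
  n <- 2000
  # null: no relation between displacement and fold change
  null_d <- tibble::tibble(
    delta_pct_peripheral = runif(n, -40, 5),
    lfc = rnorm(n, 0, 0.4))
  tr0 <- position_trend(null_d)
  cover <- mean(abs(tr0$loess$fit) <= 2 * tr0$loess$se + 1e-9)
  expect_gt(cover, 0.9)
  expect_gt(tr0$anova_p, 0.001)

  # injected effect: lfc = log2(1 + 0.01 * drop) + noise
  inj <- tibble::tibble(
    delta_pct_peripheral = runif(n, -40, 2),
    lfc = log2(1 + 0.01 * pmax(0, -delta_pct_peripheral)) + rnorm(n, 0, 0.25))
  tr1 <- position_trend(inj)
  at25 <- tr1$loess[which.min(abs(tr1$loess$delta_pct_peripheral + 25)), ]
  expect_lt(abs(at25$fit - log2(1.25)), 2 * at25$se + 0.05)
  # group ANOVA strongly significant, Tukey flags the displaced groups
  expect_lt(tr1$anova_p, 1e-6)
  expect_true(any(tr1$tukey$p_adj < 0.01))
  # implied slope from the most-displaced group within 20% of 0.01
  g_hat <- tr1$groups$implied_g[nrow(tr1$groups)]
  expect_lt(abs(g_hat - 0.01) / 0.01, 0.2)
})

test_that("mover counting is calibrated under the null and powered under
           2-SD effects", {
  set.seed(31)
  n_genes <- 1000
  genes <- paste0("g", seq_len(n_genes))
  expr_null <- tidyr::expand_grid(gene_id = genes,
                                  strain = c("WT", "S0", "FC"),
                                  replicate = 1:4)
  expr_null$tpm <- 2^rnorm(nrow(expr_null), 5, 0.25)
  pos <- dplyr::bind_rows(
    tibble::tibble(gene_id = genes, strain = "S0",
                   delta_pct_peripheral = 0),
    tibble::tibble(gene_id = genes, strain = "FC",
                   delta_pct_peripheral = -20))
  res <- count_significant_movers(expr_null, pos)
  expect_equal(res$n_movers, n_genes)
  # ~5% false positives, 4 sigma binomial margin
  expect_lt(abs(res$n_significant / n_genes - 0.05),
            4 * sqrt(0.05 * 0.95 / n_genes))

  # true effects of 2 SD on log scale: power > 0.8 at 4 replicates
  # (classical Student test, the paper's stated choice, via var_equal)
  expr_eff <- expr_null
  up <- expr_eff$strain == "FC"
  expr_eff$tpm[up] <- expr_eff$tpm[up] * 2^(2 * 0.25)
  res2 <- count_significant_movers(expr_eff, pos, var_equal = TRUE)
  expect_gt(res2$n_significant / n_genes, 0.8)

  # empty input
  expect_equal(count_significant_movers(
    expr_null, pos[0, ])$n_movers, 0L)
})

test_that("sequential ANOVA credits delta-percent-peripheral, not CEN terms,
           when it drives the response", {
  set.seed(41)
  n <- 1500
  d <- tibble::tibble(
    delta_pct_peripheral = runif(n, -30, 2),
    wt_expr = rnorm(n, 5, 2),
    dist_centromere_kb = runif(n, 1, 500),
    cen_lost = sample(c(TRUE, FALSE), n, replace = TRUE),
    lfc = log2(1 + 0.01 * pmax(0, -delta_pct_peripheral)) + rnorm(n, 0, 0.2))
  out <- sequential_anova_cen(d, subsets_kb = c(Inf, 100))
  full <- out[out$subset_kb == Inf, ]
  expect_lt(full$p_value[full$term == "delta_pct_peripheral"], 1e-10)
  cen_terms <- full[grepl("cen", full$term), ]
  expect_true(all(cen_terms$p_value > 0.01, na.rm = TRUE))

  # orthogonal covariates: sequential F equals the marginal regression F
  d2 <- tibble::tibble(
    delta_pct_peripheral = rep(c(-1, 1), 400),
    wt_expr = rep(c(-1, 1), each = 400),
    dist_centromere_kb = 100, cen_lost = FALSE)
  set.seed(5)
  d2$lfc <- 0.3 * d2$delta_pct_peripheral + 0.2 * d2$wt_expr + rnorm(800, 0, 1)
  seqF <- sequential_anova_cen(d2, subsets_kb = Inf)
  f_marg <- summary(stats::aov(lfc ~ wt_expr + delta_pct_peripheral,
                               data = d2))[[1]]
  expect_equal(
    seqF$f_statistic[seqF$term == "wt_expr"],
    f_marg$`F value`[trimws(rownames(f_marg)) == "wt_expr"],
    tolerance = 1e-6)

  # zero-variance response: all F zero
  d3 <- d; d3$lfc <- 0
  out3 <- sequential_anova_cen(d3, subsets_kb = Inf)
  expect_true(all(out3$f_statistic == 0))
})

test_that("windowed r2 favours the true driver and matches brute-force
           least squares", {
  set.seed(51)
  n <- 600
  d <- tibble::tibble(
    dist_deleted_telomere_kb = runif(n, 0, 120),
    delta_pct_peripheral = -30 * exp(-dist_deleted_telomere_kb / 40) +
      rnorm(n, 0, 3),
    lfc = log2(1 + 0.01 * pmax(0, -delta_pct_peripheral)) + rnorm(n, 0, 0.1))
  w <- windowed_r2_comparison(d, window_kb = 20, step_kb = 10)
  expect_gt(nrow(w), 3)
  expect_gt(mean(w$log2_ratio > 0, na.rm = TRUE), 0.5)

  # brute-force r2 check on one window
  w1 <- w[1, ]
  sel <- abs(d$dist_deleted_telomere_kb - w1$center_kb) <= 10
  fit <- lm(lfc ~ delta_pct_peripheral, data = d[sel, ])
  expect_equal(w1$r2_pct_peripheral, summary(fit)$r.squared)

  # identical predictors give a zero log ratio
  d2 <- d
  d2$delta_pct_peripheral <- log(d2$dist_deleted_telomere_kb + 1)
  w2 <- windowed_r2_comparison(d2, window_kb = 50, step_kb = 25)
  expect_true(all(abs(w2$log2_ratio) < 1e-9))
})

test_that("resampled correlations separate the true predictor and shrink
           with sample size", {
  set.seed(61)
  n <- 800
  d <- tibble::tibble(
    pct_peripheral = runif(n, 0, 90),
    dist_telomere_kb = runif(n, 1, 400))
  # expression driven by percent peripheral only
  d$expr <- 2^(6 - 0.03 * d$pct_peripheral + rnorm(n, 0, 0.6))
  rc <- resampled_correlation_comparison(d, n_resamples = 200, seed = 9)
  med <- rc$resamples |>
    dplyr::filter(stratum == "all") |>
    dplyr::group_by(predictor) |>
    dplyr::summarise(m = median(abs_corr))
  expect_gt(med$m[med$predictor == "pct_peripheral"],
            med$m[med$predictor == "log_dist_telomere"])
  # perfectly correlated pair: every resample gives |corr| = 1
  d2 <- d; d2$expr <- 2^(1 + 0.1 * d2$pct_peripheral)
  rc2 <- resampled_correlation_comparison(d2, n_resamples = 20, seed = 9)
  pp <- rc2$resamples |>
    dplyr::filter(stratum == "all", predictor == "pct_peripheral")
  expect_true(all(pp$abs_corr > 0.999))
  # resampling spread shrinks with gene count
  dbig <- dplyr::bind_rows(d, d, d, d)
  rc_small <- resampled_correlation_comparison(d, n_resamples = 200, seed = 3)
  rc_big <- resampled_correlation_comparison(dbig, n_resamples = 200, seed = 3)
  spread <- function(rc) rc$resamples |>
    dplyr::filter(stratum == "all", predictor == "pct_peripheral") |>
    dplyr::pull(abs_corr) |> sd()
  expect_lt(spread(rc_big), spread(rc_small))
  # bivariate model reports both predictors
  expect_setequal(rc$bivariate$term,
                  c("(Intercept)", "pct_peripheral", "ldist"))
})
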