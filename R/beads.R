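#' Tile a chromosome into beads
#'
#' Tiles a composite chromosome (or a one-row [chromosome_spec()]) into
#' consecutive beads of `bp_per_bead` base pairs (~3.2 kb per 30-nm bead at
#' the default). The bead count is the ceiling of `length / bp_per_bead`; the
#' final partial bead carries the remainder. Flags:
#' \describe{
#'   \item{is_centromere}{the single bead containing the centromere point;}
#'   \item{is_terminal}{the first and last bead of the chain (the telomeres);}
#'   \item{is_telomeric}{beads overlapping the 20 kb at either free
#'     chromosome end (fused junctions are internal and never flagged);}
#'   \item{is_rdna}{beads overlapping the rDNA array interval.}
#' }
#'
#' @param chrom A one-row tibble from [chromosome_spec()], or an internal
#'   composite entry of a [karyotype()].
#' @param bp_per_bead Bead size in bp (> 0).
#' @param specs Source specs (needed when `chrom` is a composite); supplied
#'   automatically by [build_bead_chains()].
#' @param telomeric_bp Extent of the telomeric region at each free end (bp).
#' @return Tibble with columns `chain`, `bead`, `source`, `src_start`,
#'   `src_end` (source-chromosome half-open bp), `start`, `end` (composite
#'   bp) and the four flags.
#' @export
build_bead_chain <- function(chrom, bp_per_bead = 3200, specs = NULL,
                             telomeric_bp = 20000) {
  stopifnot(bp_per_bead > 0)
  if (is.data.frame(chrom)) {
    specs <- chrom
    chrom <- karyotype(chrom)$chromosomes[[1]]
  }
  len <- .composite_length(chrom)
  if (len <= 0) stop("zero-length chromosome")

  # Fusion joins bead chains; beads always live on the source chromosome's
  # tiling grid so bead counts are conserved across fusions (minus any beads
  # wholly removed with deleted junction sequence).
  seg_beads <- purrr::pmap(chrom$segments, function(source, start, end, strand) {
    first <- floor(start / bp_per_bead)
    last <- ceiling(end / bp_per_bead) - 1
    idx <- seq.int(first, last)
    b <- tibble::tibble(
      source = source,
      src_start = pmax(idx * bp_per_bead, start),
      src_end = pmin((idx + 1) * bp_per_bead, end)
    )
    if (strand == -1L) b <- b[rev(seq_len(nrow(b))), ]
    b$.w <- b$src_end - b$src_start
    b
  })
  beads <- dplyr::bind_rows(seg_beads)
  n <- nrow(beads)
  beads$end <- cumsum(beads$.w)
  beads$start <- beads$end - beads$.w
  beads$.w <- NULL

  cen <- chrom$centromere
  is_cen <- beads$source == cen$source &
    beads$src_start <= cen$bp & cen$bp < beads$src_end

  is_tel <- beads$start < telomeric_bp | beads$end > len - telomeric_bp

  is_rdna <- rep(FALSE, n)
  if (!is.null(specs)) {
    rd <- specs[!is.na(specs$rdna_start), , drop = FALSE]
    for (i in seq_len(nrow(rd))) {
      is_rdna <- is_rdna | (beads$source == rd$name[i] &
                              beads$src_start < rd$rdna_end[i] &
                              beads$src_end > rd$rdna_start[i])
    }
  }

  tibble::tibble(
    chain = chrom$name, bead = seq_len(n),
    source = beads$source, src_start = beads$src_start,
    src_end = beads$src_end, start = beads$start, end = beads$end,
    is_centromere = is_cen,
    is_terminal = seq_len(n) %in% c(1L, n),
    is_telomeric = is_tel,
    is_rdna = is_rdna
  )
}

#' Bead table for a whole karyotype
#'
#' @param kar A [karyotype()].
#' @param bp_per_bead Bead size in bp.
#' @return Tibble of all chains stacked (see [build_bead_chain()]) with an
#'   additional global bead `index` column.
#' @export
build_bead_chains <- function(kar, bp_per_bead = 3200) {
  stopifnot(inherits(kar, "karyotype"))
  beads <- dplyr::bind_rows(purrr::map(
    kar$chromosomes, build_bead_chain,
    bp_per_bead = bp_per_bead, specs = kar$specs))
  beads$index <- seq_len(nrow(beads))
  beads
}

#' Export bead annotations as BED
#'
#' Writes one BED line per bead (chain, start, end, name = flag string).
#'
#' @param beads Bead table from [build_bead_chains()].
#' @param path Output path.
#' @export
write_beads_bed <- function(beads, path) {
  flags <- paste0(
    ifelse(beads$is_centromere, "C", ""), ifelse(beads$is_terminal, "T", ""),
    ifelse(beads$is_telomeric, "t", ""), ifelse(beads$is_rdna, "r", ""))
  flags[flags == ""] <- "."
  utils::write.table(
    data.frame(beads$chain, format(beads$start, scientific = FALSE, trim = TRUE),
               format(beads$end, scientific = FALSE, trim = TRUE), flags),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map source-coordinate genes onto beads of a karyotype
#'
#' Genes are annotated in wild-type (source chromosome) coordinates; this
#' maps each gene through the karyotype's fusion segments onto the beads that
#' overlap it (any-overlap rule). Genes whose sequence was wholly or partly
#' deleted at a fusion junction are flagged `deleted` and carry no beads.
#'
#' @param kar A [karyotype()].
#' @param genes Tibble with columns `gene_id`, `chrom` (source label),
#'   `start`, `end` (0-based half-open bp).
#' @param bp_per_bead Bead size in bp.
#' @return Tibble: `gene_id`, `chain`, `bead`, `index`, `deleted`; one row
#'   per overlapped bead (a single all-NA bead row for deleted genes).
#' @export
map_genes_to_beads <- function(kar, genes, bp_per_bead = 3200) {
  stopifnot(inherits(kar, "karyotype"),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  beads <- build_bead_chains(kar, bp_per_bead)
  rows <- purrr::pmap(genes[, c("gene_id", "chrom", "start", "end")],
                      function(gene_id, chrom, start, end) {
    b <- beads[beads$source == chrom &
                 beads$src_start < end & beads$src_end > start, ]
    kept <- sum(pmin(b$src_end, end) - pmax(b$src_start, start))
    if (nrow(b) == 0 || kept < (end - start)) {
      return(tibble::tibble(gene_id = gene_id, chain = NA_character_,
                            bead = NA_integer_, index = NA_integer_,
                            deleted = TRUE))
    }
    tibble::tibble(gene_id = gene_id, chain = b$chain,
                   bead = b$bead, index = b$index, deleted = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Per-gene genomic distances in wild-type coordinates
#'
#' For each gene (midpoint convention), the distance in kb to the nearest
#' wild-type chromosome end, to its chromosome's centromere, and -- given a
#' fused karyotype -- to the nearest telomere deleted by the fusion plan,
#' plus whether the chromosome's centromere was lost.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param wt Wild-type [karyotype()].
#' @param fused Optional fused karyotype (for deleted-telomere distances and
#'   centromere-lost flags).
#' @return Tibble: `gene_id`, `chrom`, `midpoint_bp`, `dist_telomere_kb`,
#'   `dist_centromere_kb`, `dist_deleted_telomere_kb`, `cen_lost`, `on_fused`.
#' @export
gene_genomic_distances <- function(genes, wt, fused = NULL) {
  specs <- wt$specs
  len <- stats::setNames(specs$length_bp, specs$name)
  cen <- stats::setNames(specs$centromere_bp, specs$name)
  mid <- (genes$start + genes$end) / 2

  deleted_ends <- character(0)  # "chrom:left" / "chrom:right"
  lost_cen <- character(0)
  fused_sources <- character(0)
  if (!is.null(fused)) {
    deleted_ends <- .deleted_source_ends(fused)
    retained <- purrr::map_chr(
      purrr::keep(fused$chromosomes, ~ !is.null(.x$centromere)),
      ~ .x$centromere$source)
    fused_sources <- unique(unlist(purrr::map(
      purrr::keep(fused$chromosomes, ~ nrow(.x$segments) > 1),
      ~ .x$segments$source)))
    lost_cen <- setdiff(fused_sources, retained)
  }

  d_del <- rep(NA_real_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    cands <- c()
    if (paste0(ch, ":left") %in% deleted_ends) cands <- c(cands, mid[i])
    if (paste0(ch, ":right") %in% deleted_ends) cands <- c(cands, len[ch] - mid[i])
    if (length(cands)) d_del[i] <- min(cands) / 1000
  }

  tibble::tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    midpoint_bp = mid,
    dist_telomere_kb = pmin(mid, len[genes$chrom] - mid) / 1000,
    dist_centromere_kb = abs(mid - cen[genes$chrom]) / 1000,
    dist_deleted_telomere_kb = d_del,
    cen_lost = genes$chrom %in% lost_cen,
    on_fused = genes$chrom %in% fused_sources
  )
}

# Replay a fusion plan tracking which natural source-chromosome end sits at
# each composite side, and return the ends consumed at junctions
# (as "SRC:left" / "SRC:right" in source-chromosome orientation).
.deleted_source_ends <- function(kar) {
  comps <- list()
  for (nm in kar$specs$name) {
    comps[[nm]] <- list(members = nm, left = paste0(nm, ":left"),
                        right = paste0(nm, ":right"))
  }
  find <- function(label) {
    for (k in names(comps)) if (label %in% comps[[k]]$members) return(k)
    stop("no composite contains '", label, "'")
  }
  consumed <- character(0)
  for (ev in kar$plan) {
    rk <- find(ev$recipient); dk <- find(ev$donor)
    rec <- comps[[rk]]; don <- comps[[dk]]
    if (ev$recipient_end == "left") {
      rec[c("left", "right")] <- rec[c("right", "left")]
    }
    if (ev$donor_end == "right") {
      don[c("left", "right")] <- don[c("right", "left")]
    }
    consumed <- c(consumed, rec$right, don$left)
    comps[[rk]] <- list(members = c(rec$members, don$members),
                        left = rec$left, right = don$right)
    comps[[dk]] <- NULL
  }
  consumed
}
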