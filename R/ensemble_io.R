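#' Write an ensemble to disk
#'
#' Writes an ensemble as an extended-XYZ trajectory (one frame per retained
#' conformation; the comment line carries replicate, sample and seed), the
#' bead table as TSV, the karyotype as YAML, and a JSON manifest with
#' provenance (schedule, force field, geometry scalars, master seed,
#' failed replicates).
#'
#' @param ensemble A `nuc_ensemble`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "nuc_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xyz <- file.path(dir, "trajectory.xyz")
  con <- file(xyz, "w")
  on.exit(close(con))
  n <- nrow(ensemble$beads)
  for (i in seq_along(ensemble$conformations)) {
    m <- ensemble$conformations[[i]]
    meta <- ensemble$meta[i, ]
    writeLines(as.character(n), con)
    writeLines(sprintf("replicate=%d sample=%d seed=%d", meta$replicate,
                       meta$sample, meta$seed), con)
    writeLines(sprintf("%s %.3f %.3f %.3f", ensemble$beads$chain,
                       m[, 1], m[, 2], m[, 3]), con)
  }
  utils::write.table(ensemble$beads, file.path(dir, "beads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ensemble$karyotype)) {
    write_karyotype_yaml(ensemble$karyotype, file.path(dir, "karyotype.yaml"))
  }
  prov <- ensemble$provenance
  manifest <- list(
    n_conformations = length(ensemble$conformations),
    n_beads = n,
    master_seed = prov$master_seed,
    failed_replicates = prov$failed_replicates,
    schedule = unclass(prov$schedule),
    forcefield = unclass(prov$forcefield),
    geometry = if (!is.null(prov$geometry)) {
      list(r_nuc = prov$geometry$r_nuc, r_spb = prov$geometry$r_spb,
           r_nucl = prov$geometry$r_nucl, indent_k = prov$geometry$indent_k)
    },
    package_version = prov$package_version
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read an ensemble written by [write_ensemble()]
#'
#' @param dir Ensemble directory.
#' @return A `nuc_ensemble`.
#' @export
read_ensemble <- function(dir) {
  beads <- tibble::as_tibble(utils::read.table(
    file.path(dir, "beads.tsv"), header = TRUE, sep = "\t",
    stringsAsFactors = FALSE))
  lines <- readLines(file.path(dir, "trajectory.xyz"))
  n <- nrow(beads)
  frame_len <- n + 2
  n_frames <- length(lines) %/% frame_len
  confs <- vector("list", n_frames)
  meta <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    off <- (f - 1) * frame_len
    hdr <- lines[off + 2]
    kv <- as.numeric(sub(".*=", "", strsplit(hdr, " ")[[1]]))
    at <- lines[(off + 3):(off + 2 + n)]
    parts <- strsplit(at, " ", fixed = TRUE)
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3,
                byrow = TRUE)
    confs[[f]] <- m
    meta[[f]] <- tibble::tibble(replicate = kv[1], sample = kv[2],
                                seed = kv[3])
  }
  kar <- NULL
  if (file.exists(file.path(dir, "karyotype.yaml"))) {
    kar <- read_karyotype_yaml(file.path(dir, "karyotype.yaml"))
  }
  ens <- as_nuc_ensemble(confs, beads, kar, dplyr::bind_rows(meta))
  mp <- file.path(dir, "manifest.json")
  if (file.exists(mp)) ens$provenance <- jsonlite::read_json(mp)
  ens
}

#' Read gene annotations from BED or GFF3
#'
#' Accepts BED (chrom, start, end, optional name) or GFF3 (gene features; ID or
#' Name attribute) and returns the tidy gene tibble the analysis functions
#' consume. Coordinates are returned 0-based half-open.
#'
#' @param path Annotation file.
#' @param feature GFF3 feature type to keep.
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_annotations <- function(path, feature = "gene") {
  first <- readLines(path, n = 1)
  if (grepl("^##gff", first) || grepl("\\.gff3?$", path)) {
    gff <- utils::read.table(path, sep = "\t", comment.char = "#",
                             quote = "", stringsAsFactors = FALSE)
    gff <- gff[gff[[3]] == feature, ]
    ids <- sub(".*(?:ID|Name)=([^;]+).*", "\\1", gff[[9]])
    return(tibble::tibble(gene_id = ids, chrom = as.character(gff[[1]]),
                          start = gff[[4]] - 1, end = gff[[5]]))
  }
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  tibble::tibble(
    gene_id = if (ncol(bed) >= 4) as.character(bed[[4]])
              else paste0("gene", seq_len(nrow(bed))),
    chrom = as.character(bed[[1]]), start = bed[[2]], end = bed[[3]])
}

#' Write / read a wide expression matrix
#'
#' The TSV layout is genes x samples with strain_replicate column labels
#' (e.g. `WT_1`); `read_expression_tsv()` melts it back to the long format
#' used throughout.
#'
#' @param expr Long expression tibble (`gene_id`, `strain`, `replicate`,
#'   `tpm`).
#' @param path TSV path.
#' @export
write_expression_tsv <- function(expr, path) {
  wide <- expr |>
    dplyr::mutate(sample = paste0(.data$strain, "_", .data$replicate)) |>
    dplyr::select("gene_id", "sample", "tpm") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "tpm")
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  wide <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(wide) |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample",
                        values_to = "tpm") |>
    tidyr::separate_wider_regex(
      "sample", c(strain = ".*", "_", replicate = "[0-9]+")) |>
    dplyr::mutate(replicate = as.integer(.data$replicate))
}
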