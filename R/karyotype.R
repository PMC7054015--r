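#' Chromosome specification
#'
#' One source chromosome: its length, point centromere position and, for
#' chromosome XII, the rDNA array interval. Coordinates are 0-based,
#' half-open base pairs; strand is ignored at the bead level.
#'
#' @param name Chromosome label (e.g. `"IV"`).
#' @param length_bp Chromosome length in bp (> 0).
#' @param centromere_bp Point centromere position, 0 < centromere < length.
#' @param rdna_start,rdna_end Optional half-open rDNA interval within
#'   `[0, length_bp)`.
#' @return A one-row tibble.
#' @export
chromosome_spec <- function(name, length_bp, centromere_bp,
                            rdna_start = NA_real_, rdna_end = NA_real_) {
  stopifnot(length_bp > 0, centromere_bp > 0, centromere_bp < length_bp)
  if (!is.na(rdna_start)) {
    stopifnot(!is.na(rdna_end), rdna_start >= 0, rdna_end > rdna_start,
              rdna_end <= length_bp)
  }
  tibble::tibble(name = as.character(name), length_bp = as.numeric(length_bp),
                 centromere_bp = as.numeric(centromere_bp),
                 rdna_start = as.numeric(rdna_start),
                 rdna_end = as.numeric(rdna_end))
}

# sacCer3 (R64-1-1) chromosome lengths and centromere midpoints (bp).
.SC_LENGTHS <- c(
  I = 230218, II = 813184, III = 316620, IV = 1531933, V = 576874,
  VI = 270161, VII = 1090940, VIII = 562643, IX = 439888, X = 745751,
  XI = 666816, XII = 1078177, XIII = 924431, XIV = 784333, XV = 1091291,
  XVI = 948066
)
.SC_CENTROMERES <- c(
  I = 151465, II = 238207, III = 114385, IV = 449711, V = 151987,
  VI = 148510, VII = 496920, VIII = 105586, IX = 355629, X = 436307,
  XI = 440129, XII = 150828, XIII = 268031, XIV = 628758, XV = 326584,
  XVI = 555957
)
# Reference rDNA locus on chr XII (collapsed to ~2 repeats in the assembly);
# it is replaced by a configurable repeat array in the model karyotype.
.SC_RDNA_REF <- c(start = 451575, end = 468931)

#' Wild-type S. cerevisiae model karyotype
#'
#' The 16 chromosomes at their R64-1-1 lengths, with the reference rDNA locus
#' on chromosome XII replaced by an explicit repeat array of
#' `rdna_repeats * rdna_repeat_bp` bp (the assembly collapses the 100-200
#' repeat array). At the defaults (101 repeats of 9.1 kb) the genome tiles
#' into 4062 beads of 3.2 kb.
#'
#' @param rdna_repeats Number of rDNA repeats modelled on chromosome XII.
#' @param rdna_repeat_bp Repeat unit size in bp.
#' @return A `karyotype` object (see [karyotype()]).
#' @examples
#' kar <- yeast_karyotype()
#' karyotype_summary(kar)$n_beads  # 4062
#' @export
yeast_karyotype <- function(rdna_repeats = 101, rdna_repeat_bp = 9100) {
  stopifnot(rdna_repeats >= 0, rdna_repeat_bp > 0)
  specs <- purrr::map(names(.SC_LENGTHS), function(nm) {
    len <- .SC_LENGTHS[[nm]]
    cen <- .SC_CENTROMERES[[nm]]
    if (nm == "XII") {
      array_bp <- rdna_repeats * rdna_repeat_bp
      len <- len - (.SC_RDNA_REF[["end"]] - .SC_RDNA_REF[["start"]]) + array_bp
      chromosome_spec(nm, len, cen,
                      rdna_start = .SC_RDNA_REF[["start"]],
                      rdna_end = .SC_RDNA_REF[["start"]] + array_bp)
    } else {
      chromosome_spec(nm, len, cen)
    }
  })
  karyotype(dplyr::bind_rows(specs))
}

#' Karyotype: a set of (possibly fused) chromosomes
#'
#' A karyotype records the immutable source chromosome specifications plus a
#' list of composite chromosomes, each a sequence of oriented source segments.
#' Wild-type karyotypes have one single-segment composite per source
#' chromosome; [apply_fusion_plan()] concatenates composites.
#'
#' @param specs Tibble of source chromosomes as built by [chromosome_spec()].
#' @return A `karyotype` object.
#' @export
karyotype <- function(specs) {
  stopifnot(is.data.frame(specs))
  if (anyDuplicated(specs$name)) stop("duplicate chromosome names")
  chromosomes <- purrr::pmap(specs, function(name, length_bp, centromere_bp, ...) {
    list(
      name = name,
      segments = tibble::tibble(source = name, start = 0, end = length_bp,
                                strand = 1L),
      centromere = list(source = name, bp = centromere_bp)
    )
  })
  structure(list(specs = tibble::as_tibble(specs),
                 chromosomes = chromosomes,
                 plan = list()),
            class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  s <- karyotype_summary(x)
  cat(sprintf("<karyotype> %d chromosomes, %d telomeres, %d fusion events\n",
              s$n_chromosomes, s$n_telomeres, length(x$plan)))
  for (comp in x$chromosomes) {
    cat(sprintf("  %-14s %9.0f bp  [%s]\n", comp$name,
                .composite_length(comp),
                paste0(ifelse(comp$segments$strand == 1, "", "-"),
                       comp$segments$source, collapse = " + ")))
  }
  invisible(x)
}

.composite_length <- function(comp) sum(comp$segments$end - comp$segments$start)

# Map a source-coordinate point to composite coordinates (NA if deleted).
.map_point <- function(comp, source, pos) {
  off <- 0
  for (i in seq_len(nrow(comp$segments))) {
    seg <- comp$segments[i, ]
    w <- seg$end - seg$start
    if (seg$source == source && pos >= seg$start && pos < seg$end) {
      return(if (seg$strand == 1L) off + (pos - seg$start)
             else off + (seg$end - 1 - pos))
    }
    off <- off + w
  }
  NA_real_
}

# Map a source-coordinate half-open interval; returns a tibble of composite
# half-open intervals (possibly empty).
.map_interval <- function(comp, source, start, end) {
  out <- list()
  off <- 0
  for (i in seq_len(nrow(comp$segments))) {
    seg <- comp$segments[i, ]
    w <- seg$end - seg$start
    a <- max(start, seg$start); b <- min(end, seg$end)
    if (seg$source == source && b > a) {
      piece <- if (seg$strand == 1L) {
        c(off + (a - seg$start), off + (b - seg$start))
      } else {
        c(off + (seg$end - b), off + (seg$end - a))
      }
      out[[length(out) + 1]] <- tibble::tibble(start = piece[1], end = piece[2])
    }
    off <- off + w
  }
  if (length(out) == 0) {
    tibble::tibble(start = numeric(), end = numeric())
  } else {
    dplyr::bind_rows(out)
  }
}

.find_composite <- function(kar, label) {
  hits <- which(purrr::map_lgl(kar$chromosomes,
                               ~ label %in% .x$segments$source))
  if (length(hits) == 0) stop("no chromosome contains source '", label, "'")
  hits[1]
}

#' Fusion event
#'
#' One end-to-end fusion between the chromosome (or composite) containing
#' `recipient` and the one containing `donor`. The stated telomeric ends are
#' consumed: `deleted_bp_*` base pairs are removed at the junction and the
#' junction loses its terminal/telomeric character. The donor orientation is
#' determined by which of its ends joins the junction (`donor_end = "left"`
#' keeps the donor forward; `"right"` reverts it).
#'
#' @param recipient,donor Source chromosome labels.
#' @param recipient_end,donor_end Which telomere of the current composite is
#'   consumed, `"left"` or `"right"`.
#' @param deleted_bp_recipient,deleted_bp_donor Base pairs removed at the
#'   junction from each side (default 0).
#' @param retained_centromere Source chromosome whose centromere survives in
#'   the fused composite (must be present on one side).
#' @return A `fusion_event` list.
#' @export
fusion_event <- function(recipient, donor,
                         recipient_end = c("right", "left"),
                         donor_end = c("left", "right"),
                         deleted_bp_recipient = 0, deleted_bp_donor = 0,
                         retained_centromere = recipient) {
  recipient_end <- match.arg(recipient_end)
  donor_end <- match.arg(donor_end)
  stopifnot(deleted_bp_recipient >= 0, deleted_bp_donor >= 0)
  structure(list(recipient = recipient, donor = donor,
                 recipient_end = recipient_end, donor_end = donor_end,
                 donor_orientation = if (donor_end == "left") "forward" else "reverted",
                 deleted_bp_recipient = deleted_bp_recipient,
                 deleted_bp_donor = deleted_bp_donor,
                 retained_centromere = retained_centromere),
            class = "fusion_event")
}

.flip_composite <- function(comp) {
  segs <- comp$segments[rev(seq_len(nrow(comp$segments))), ]
  segs$strand <- -segs$strand
  comp$segments <- segs
  comp
}

# Trim n bp off the right end of a composite's segment list.
.trim_right <- function(segs, n) {
  while (n > 0 && nrow(segs) > 0) {
    i <- nrow(segs)
    w <- segs$end[i] - segs$start[i]
    take <- min(w, n)
    if (segs$strand[i] == 1L) segs$end[i] <- segs$end[i] - take
    else segs$start[i] <- segs$start[i] + take
    if (segs$end[i] <= segs$start[i]) segs <- segs[-i, ]
    n <- n - take
  }
  segs
}

.trim_left <- function(segs, n) {
  while (n > 0 && nrow(segs) > 0) {
    w <- segs$end[1] - segs$start[1]
    take <- min(w, n)
    if (segs$strand[1] == 1L) segs$start[1] <- segs$start[1] + take
    else segs$end[1] <- segs$end[1] - take
    if (segs$end[1] <= segs$start[1]) segs <- segs[-1, ]
    n <- n - take
  }
  segs
}

#' Apply a fusion plan to a karyotype
#'
#' Applies [fusion_event()]s in order. Each event concatenates two composites
#' end to end, deletes the stated junction base pairs, drops the centromere
#' not retained, and updates chromosome/telomere bookkeeping. The fused
#' junction is internal sequence: its beads carry no terminal or telomeric
#' flags and receive no telomere-wall attraction in the force build.
#'
#' @param kar A [karyotype()].
#' @param plan A single [fusion_event()] or a list of them.
#' @return A new `karyotype`.
#' @examples
#' fc <- apply_fusion_plan(yeast_karyotype(), fc_fusion_plan("FC(IV:XII)CEN4"))
#' karyotype_summary(fc)[, c("n_chromosomes", "n_telomeres")]
#' @export
apply_fusion_plan <- function(kar, plan) {
  stopifnot(inherits(kar, "karyotype"))
  if (inherits(plan, "fusion_event")) plan <- list(plan)
  for (ev in plan) {
    stopifnot(inherits(ev, "fusion_event"))
    ri <- .find_composite(kar, ev$recipient)
    di <- .find_composite(kar, ev$donor)
    if (ri == di) stop("recipient and donor are already on the same chromosome")
    rec <- kar$chromosomes[[ri]]
    don <- kar$chromosomes[[di]]
    # orient so the junction is recipient-right / donor-left
    if (ev$recipient_end == "left") rec <- .flip_composite(rec)
    if (ev$donor_end == "right") don <- .flip_composite(don)
    rec_segs <- .trim_right(rec$segments, ev$deleted_bp_recipient)
    don_segs <- .trim_left(don$segments, ev$deleted_bp_donor)
    cen_sources <- c(if (!is.null(rec$centromere)) rec$centromere$source,
                     if (!is.null(don$centromere)) don$centromere$source)
    if (!ev$retained_centromere %in% cen_sources) {
      stop("retained_centromere '", ev$retained_centromere,
           "' is not present on either side of the fusion")
    }
    cen <- if (!is.null(rec$centromere) &&
               rec$centromere$source == ev$retained_centromere) {
      rec$centromere
    } else {
      don$centromere
    }
    fused <- list(
      name = paste(rec$name, don$name, sep = ":"),
      segments = dplyr::bind_rows(rec_segs, don_segs),
      centromere = cen
    )
    # centromere must survive the junction deletion
    if (is.na(.map_point(fused, cen$source, cen$bp))) {
      stop("retained centromere was deleted at the junction")
    }
    kar$chromosomes[[ri]] <- fused
    kar$chromosomes[[di]] <- NULL
    kar$plan <- c(kar$plan, list(ev))
  }
  kar
}

#' Canonical fusion plans for the ten fusion-chromosome strains
#'
#' Strain names follow the convention `FC(<recipient>:<donors...>)CEN<n>`:
#' donors are fused sequentially onto the recipient and only the stated
#' centromere survives. Junction orientation (recipient right end to donor
#' left end) is the package's canonical convention; chromosome, centromere
#' and telomere counts do not depend on it.
#'
#' @param strain One of the names in [fc_strain_names()].
#' @return A list of [fusion_event()]s.
#' @export
fc_fusion_plan <- function(strain) {
  m <- regmatches(strain, regexec("^FC\\(([^)]+)\\)CEN([0-9]+)$", strain))[[1]]
  if (length(m) != 3) stop("unrecognized strain name: ", strain)
  chroms <- strsplit(m[2], ":")[[1]]
  if (length(chroms) < 2) stop("a fusion strain needs at least two chromosomes")
  roman <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
             "XI", "XII", "XIII", "XIV", "XV", "XVI")
  cen_keep <- roman[as.integer(m[3])]
  if (!cen_keep %in% chroms) stop("retained centromere not in the fusion")
  plan <- list()
  have <- chroms[1]
  for (d in chroms[-1]) {
    sides <- c(have, d)
    retained <- if (cen_keep %in% sides) cen_keep else have[1]
    plan[[length(plan) + 1]] <- fusion_event(
      recipient = chroms[1], donor = d, retained_centromere = retained)
    have <- c(have, d)
  }
  plan
}

#' @rdname fc_fusion_plan
#' @export
fc_strain_names <- function() {
  c("FC(IV:XII)CEN4", "FC(IV:XII)CEN12",
    "FC(IV:XV)CEN4", "FC(IV:XV)CEN15",
    "FC(IV:XV:V)CEN4", "FC(IV:XV:V)CEN5",
    "FC(IV:XV:XVI)CEN4", "FC(IV:XV:XVI)CEN16",
    "FC(IV:V:VII:XV)CEN4", "FC(IV:V:VII:XV)CEN7")
}

#' Build a karyotype for a named strain
#'
#' `"WT"` gives the wild-type karyotype; any [fc_strain_names()] entry gives
#' the corresponding fused karyotype.
#'
#' @param strain Strain name.
#' @param ... Passed to [yeast_karyotype()].
#' @return A `karyotype`.
#' @export
strain_karyotype <- function(strain = "WT", ...) {
  kar <- yeast_karyotype(...)
  if (identical(strain, "WT")) return(kar)
  apply_fusion_plan(kar, fc_fusion_plan(strain))
}

#' Karyotype summary counts
#'
#' @param kar A [karyotype()].
#' @param bp_per_bead Bead size used for the bead count (default 3200 bp).
#' @return One-row tibble: chromosome, centromere, telomere and bead counts,
#'   plus the longest chromosome-arm length in bp.
#' @export
karyotype_summary <- function(kar, bp_per_bead = 3200) {
  stopifnot(inherits(kar, "karyotype"))
  n_chr <- length(kar$chromosomes)
  if (n_chr == 0) {
    return(tibble::tibble(n_chromosomes = 0L, n_centromeres = 0L,
                          n_telomeres = 0L, n_beads = 0L, longest_arm_bp = 0))
  }
  lens <- purrr::map_dbl(kar$chromosomes, .composite_length)
  n_beads <- sum(ceiling(lens / bp_per_bead))
  arms <- purrr::map_dbl(kar$chromosomes, function(comp) {
    cen <- .map_point(comp, comp$centromere$source, comp$centromere$bp)
    max(cen, .composite_length(comp) - cen)
  })
  tibble::tibble(
    n_chromosomes = n_chr,
    n_centromeres = sum(!purrr::map_lgl(kar$chromosomes,
                                        ~ is.null(.x$centromere))),
    n_telomeres = 2L * n_chr,
    n_beads = as.integer(n_beads),
    longest_arm_bp = max(arms)
  )
}

#' Karyotype YAML round-trip
#'
#' Serializes a karyotype (source specs, composite segments, centromeres) to
#' YAML and back; reloading reproduces identical bead annotations.
#'
#' @param kar A `karyotype`.
#' @param path Output file path.
#' @return `read_karyotype_yaml()` returns a `karyotype`.
#' @export
write_karyotype_yaml <- function(kar, path) {
  obj <- list(
    specs = purrr::transpose(as.list(kar$specs)),
    chromosomes = purrr::map(kar$chromosomes, function(comp) {
      list(name = comp$name,
           segments = purrr::transpose(as.list(comp$segments)),
           centromere = comp$centromere)
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_karyotype_yaml
#' @export
read_karyotype_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  specs <- dplyr::bind_rows(purrr::map(obj$specs, tibble::as_tibble))
  specs$rdna_start <- as.numeric(specs$rdna_start)
  specs$rdna_end <- as.numeric(specs$rdna_end)
  kar <- karyotype(specs)
  kar$chromosomes <- purrr::map(obj$chromosomes, function(comp) {
    segs <- dplyr::bind_rows(purrr::map(comp$segments, tibble::as_tibble))
    segs$strand <- as.integer(segs$strand)
    segs$start <- as.numeric(segs$start); segs$end <- as.numeric(segs$end)
    list(name = comp$name, segments = segs,
         centromere = list(source = comp$centromere$source,
                           bp = as.numeric(comp$centromere$bp)))
  })
  kar
}
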