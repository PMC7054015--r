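#' Solenoidal initial conformation for one chain
#'
#' Folds a chain of `n_beads` into a stacked-helix (solenoid) rod of the
#' given radius: compact, unentangled, and overall rod-like. Consecutive
#' beads are `spacing` nm apart (below the 45-nm maximum bond extension) and
#' successive turns are separated by more than a bead diameter, so the rod
#' has no self-overlap.
#'
#' @param n_beads Number of beads (>= 1).
#' @param rod_radius Helix radius in nm.
#' @param spacing Consecutive-bead spacing in nm.
#' @param rise Axial rise per bead in nm.
#' @return `n_beads` x 3 matrix of nm coordinates, centred on the origin
#'   with the rod axis along z. A single bead sits at the origin.
#' @export
build_solenoid <- function(n_beads, rod_radius = 150, spacing = 29,
                           rise = 1.0) {
  stopifnot(n_beads >= 1, rod_radius > 0, spacing > rise, spacing < 45)
  if (n_beads == 1) return(matrix(0, 1, 3))
  chord <- sqrt(spacing^2 - rise^2)
  if (chord >= 2 * rod_radius) stop("spacing too large for the rod radius")
  dtheta <- 2 * asin(chord / (2 * rod_radius))
  pitch <- rise * (2 * pi / dtheta)
  if (pitch < 28) stop("turns too close: increase rise or spacing")
  k <- seq_len(n_beads) - 1
  pos <- cbind(rod_radius * cos(k * dtheta),
               rod_radius * sin(k * dtheta),
               k * rise)
  # centre along the axis only, so every bead stays exactly on the helix
  # radius about the rod axis
  pos[, 3] <- pos[, 3] - mean(pos[, 3])
  pos
}

# Uniform random rotation matrix (from a random axis + angle via quaternions).
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Place chromosome rods inside the nucleus
#'
#' Builds a solenoid rod per chromosome and places them one by one, longest
#' chromosome first, at uniformly random centres and orientations inside the
#' nuclear sphere. A placement is accepted only if every bead is inside the
#' nucleus and no bead comes within one bead diameter (`sigma`) of a
#' previously placed chain; clashing attempts are redrawn. Deterministic
#' under a fixed seed.
#'
#' @param kar A [karyotype()].
#' @param geometry A [nuclear_geometry()].
#' @param seed Integer RNG seed.
#' @param bp_per_bead Bead size in bp.
#' @param sigma Bead diameter in nm (clash criterion).
#' @param rod_radius Solenoid radius in nm.
#' @param max_retries Attempts per chromosome before giving up.
#' @return A `nuc_conformation`: list with `positions` (n x 3 nm matrix),
#'   `beads`, `karyotype`, `seed`.
#' @export
place_chromosomes <- function(kar, geometry = nuclear_geometry(), seed = 1,
                              bp_per_bead = 3200, sigma = 30,
                              rod_radius = 150, max_retries = 5000) {
  stopifnot(inherits(kar, "karyotype"))
  beads <- build_bead_chains(kar, bp_per_bead)
  chains <- beads |>
    dplyr::count(.data$chain, name = "n_beads") |>
    dplyr::arrange(dplyr::desc(.data$n_beads))

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(seed)

  r_margin <- geometry$r_nuc - sigma / 2
  placed <- matrix(numeric(0), 0, 3)
  out <- vector("list", nrow(chains))
  names(out) <- chains$chain

  for (ci in seq_len(nrow(chains))) {
    rod <- build_solenoid(chains$n_beads[ci], rod_radius = rod_radius)
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      # uniform centre inside the nucleus (rejection sampling)
      repeat {
        ctr <- stats::runif(3, -1, 1) * geometry$r_nuc
        if (sum(ctr^2) <= geometry$r_nuc^2) break
      }
      cand <- rod %*% t(.random_rotation())
      cand <- sweep(cand, 2, ctr, "+")
      if (max(rowSums(cand^2)) > r_margin^2) next
      if (nrow(placed) > 0) {
        d2min <- min(.min_cross_dist2(cand, placed))
        if (d2min < sigma^2) next
      }
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("failed to place chromosome '", chains$chain[ci], "' after ",
           max_retries, " attempts (seed ", seed, ")")
    }
    out[[ci]] <- cand
    placed <- rbind(placed, cand)
  }

  # reorder bead-wise to the bead-table order
  pos <- matrix(NA_real_, nrow(beads), 3)
  for (ci in seq_len(nrow(chains))) {
    idx <- beads$index[beads$chain == chains$chain[ci]]
    pos[idx, ] <- out[[ci]]
  }
  structure(list(positions = pos, beads = beads, karyotype = kar,
                 replicate = NA_integer_, sample = NA_integer_, seed = seed),
            class = "nuc_conformation",
            placement_order = chains$chain)
}

# minimum squared distance from each row of a to the rows of b, blockwise
.min_cross_dist2 <- function(a, b) {
  na <- nrow(a)
  res <- numeric(na)
  block <- max(1, floor(2e6 / max(nrow(b), 1)))
  for (s in seq(1, na, by = block)) {
    e <- min(s + block - 1, na)
    d2 <- outer(rowSums(a[s:e, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[s:e, , drop = FALSE] %*% t(b)
    res[s:e] <- apply(d2, 1, min)
  }
  res
}
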