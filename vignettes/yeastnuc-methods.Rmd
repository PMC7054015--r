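---
title: "Modelling the budding-yeast nucleus and its expression consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the budding-yeast nucleus and its expression consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Interphase chromosomes in *Saccharomyces cerevisiae* adopt a stereotypical
Rabl-like arrangement: the sixteen centromeres cluster at the spindle pole
body (SPB), telomeres associate dynamically with the nuclear envelope (NE),
and the rDNA array on chromosome XII organizes the nucleolus opposite the
SPB. `yeastnuc` reproduces this organization with a minimal-restraint
coarse-grained polymer model and then asks what the resulting radial gene
positions imply for expression, in particular for strains in which two to
four chromosomes are fused end to end (losing the donor centromeres and
the junction telomeres).

## Chain representation

Each chromosome is a bead-and-spring chain of 30-nm beads carrying ~3.2 kb
of DNA each, giving 4062 beads for the haploid genome. The model karyotype
uses the R64-1-1 chromosome lengths with the collapsed reference rDNA locus
on chromosome XII replaced by an explicit array of 101 repeats of 9.1 kb;
101 repeats sit inside the experimentally reported 100-200 range and yield
exactly the 4062-bead total, which is why it is the default. Per-chromosome
sizes are configurable if exact published bead tables are available.

Three intramolecular terms act on the chain:

* **Excluded volume** — purely repulsive (WCA) Lennard-Jones spheres,
  diameter $\sigma = 30$ nm, $\varepsilon = 1\,k_BT$.
* **Connectivity** — FENE bonds with maximum extension 45 nm and spring
  constant $30\,\varepsilon/\sigma^2$ (the standard Kremer–Grest value;
  together with excluded volume this prevents chain crossing).
* **Bending** — a Kratky–Porod term $\kappa(1-\cos\theta)$ with
  $\kappa = L_p/b$ in $k_BT$: $L_p = 61.7$ nm for internal chromatin
  ($\kappa \approx 2.06$) and $L_p = 195$ nm ($\kappa = 6.5$) over the
  terminal 20-kb telomeric regions, which are more compact and rigid.
  The `bending_map = "langevin"` option instead inverts the exact
  freely-rotating-chain relation $\langle\cos\theta\rangle =
  \coth\kappa - 1/\kappa = e^{-b/L_p}$; at these stiffnesses the simple
  ratio, combined with the angle-restricting effect of excluded volume,
  reproduces the target persistence length of a free chain within the 15%
  check used in the tests, so the ratio remains the default.

## Nuclear landmarks

All restraints act through the one-sided confinement force
$F(r) = K\,(r-R)^2$ with $K = 10$ (reduced units), applied only while a
bead violates its condition:

* every bead is kept inside the nucleus, a rigid sphere of radius
  $R_{nuc} = 1000$ nm;
* centromere beads are kept inside a 150-nm sphere internally tangent to
  the NE at $(-850, 0, 0)$, mimicking microtubule attachment to the SPB;
* rDNA beads are kept inside — and all other beads outside — the nucleolar
  region: the lens formed by the nucleus and a sphere centred on the NE
  point opposite the SPB whose radius is solved so the lens holds 10% of
  the nuclear volume (640.92 nm for the default geometry);
* terminal (telomere) beads feel a truncated 12-6 attraction to the NE
  acting within 126 nm of it, i.e. exactly over the peripheral shell.

The peripheral shell is the outermost of three concentric shells of equal
volume ($r_1 = (1/3)^{1/3}R_{nuc}$, $r_2 = (2/3)^{1/3}R_{nuc}$; outer
thickness 126 nm). Shell-boundary ties classify inward, a zero-measure
choice fixed for determinism. The degenerate direction of the
keep-outside force at the sphere centre resolves to $+x$.

**Telomere-wall depth.** The attraction depth is the one deliberately
calibrated parameter. It was swept upward from 1 $k_BT$ on reduced
wild-type ensembles until roughly 40% of telomere observations fell
outside the peripheral shell — the observed behaviour the restraint
stands for (telomere anchoring is dynamic, not absolute). The calibrated
default is 4.75 $k_BT$ for this potential's form and range (measured
non-peripheral fractions on reduced ensembles: ~64% at 2.5 $k_BT$, ~50%
at 4, ~48% at 4.5, ~44% at 4.75); shallower wells leave telomeres
under-anchored for this geometry because the chain drag of SPB-tethered
centromeres competes with the wall.

## Protocol

Chromosomes are initialized as solenoidal rods (radius 150 nm, ~29-nm
bead spacing, ~32-nm pitch): compact, unentangled, rod-like. Rods are
placed longest-first at uniform random positions and orientations inside
the nucleus, redrawing on clashes (inter-chain bead distance below
$\sigma$). A 60 $\tau_{LJ}$ preliminary Langevin run with all restraints
active brings centromeres, rDNA and telomeres into compliance; the
production run then samples conformations at fixed intervals.

Integration is BAOAB Langevin at $T = 1\,\varepsilon/k_B$ with
$dt = 0.01\,\tau_{LJ}$ and mass 1. The friction default is
$\gamma = 0.25\,\tau_{LJ}^{-1}$: equilibrium ensemble statistics are
independent of $\gamma$, and the lower friction shortens the compact-rod
to steady-state transient severalfold, which is what makes desk-scale
ensembles practical; $\gamma = 1$ reproduces the same distributions more
slowly. Restraint forces are capped at 6 reduced units so that the
capped drag velocity $F/\gamma$ stays well below one bead diameter per
step while the large post-placement violations relax; during production
the cap is inactive because violations stay small. A far larger global
force cap ($10^3$) guards
against pathological overlap spikes without shaping healthy trajectories.

At full scale the protocol is 1000 replicates x 30,000 $\tau_{LJ}$
production sampled every 3000 $\tau_{LJ}$ — 10,000 conformations per
strain. The packaged tests run reduced ensembles instead (documented
per test): the full wild-type genome with a 600 $\tau_{LJ}$ burn-in and
600 $\tau_{LJ}$ of sampling every 30 $\tau_{LJ}$ across 5 replicates
(100 conformations), and two-chromosome mini karyotypes for
fusion-displacement checks. Radial occupancy statistics plateau after
roughly 600 $\tau_{LJ}$ at $\gamma = 0.25$, which sets the burn-in;
samples 30 $\tau_{LJ}$ apart are correlated, so these ensembles buy
variance, not bias, relative to the full protocol.

# Structural statistics

Per bead, shell occupancy is the fraction of conformations spent in each
equal-volume shell; a gene's "% peripheral" is the unweighted mean over
the beads its interval overlaps, and the fusion effect is the change
relative to wild type (matched bead-for-bead through the fusion segment
map, so wild-type and fused ensembles compare in source coordinates).
NE distances use bead centres ($R_{nuc} - |x|$); 10-kb loci are
non-overlapping triples of consecutive beads with a short trailing locus.
Contact maps use a 120-nm cutoff and 10-bead (32-kb) bins; a bin pair is
in contact in a conformation when at least one of its bead pairs is, so
frequencies are probabilities in $[0,1]$ (a raw-count mode is available).
2D localization densities project beads to $(a, \rho) = (x,
\sqrt{y^2+z^2})$ on a 2x2 µm grid of 10-nm pixels with a 30-nm Gaussian
kernel, normalized to a maximum of 1.

# Expression analyses

The synthetic generator emulates the structure of a TPM table with
per-strain replicates:
$$\mathrm{TPM} = 2^{\mu_g - \delta e^{-d_{tel}/\lambda} +
\log_2(1 + g\,(P_{WT} - P_s)) + \epsilon}$$
with per-gene baselines $\mu_g \sim N(5, 2^2)$ (log2 TPM), subtelomeric
repression depth $\delta = 2$ log2 units decaying over $\lambda = 10$ kb,
replicate noise $\epsilon \sim N(0, 0.25^2)$ (a placeholder magnitude,
flagged as such in the configuration), and the headline periphery effect
$g = 0.01$: a 25-pp loss of peripheral residency multiplies expression by
1.25. Optional Poisson thinning adds counting noise. What the generator
does *not* emulate — bursty transcription, strain-specific trans effects,
correlated replicate batches, compositional TPM constraints — bounds what
passing tests say about real data: they validate the statistical
machinery, not the biology.

The analysis mirrors the study design: baselines are nested medians over
strains whose predicted residency change is below 1 pp (wild type always
qualifies; wild-type medians are the fallback, which the source analysis
found interchangeable); fold changes are $\log_2$ ratios with a 0.1-TPM
pseudocount (the low-count guard; configurable); the displacement trend
is a robust LOESS with a 100-gene window plus binned groups with one-way
ANOVA and Tukey HSD contrasts against the non-displaced group; mover
counts use per-gene t-tests at raw $p < 0.05$ (Welch by default, pooled
via `var_equal`) comparing a strain's replicates against the pooled
replicates of that gene's baseline-eligible strains; the centromere
analysis is a sequential (Type I) ANOVA adding $\Delta\%P$, wild-type
expression, centromere distance, centromere-loss and their interaction in
that order, over nested distance subsets; and the telomere-deletion
analysis compares windowed single-predictor $r^2$ values
($\log_2 r^2_{\%P}/r^2_{dist}$, 20- and 50-kb windows).

# Numerical choices and limitations

Root finding uses bracketed `uniroot` to well below 0.005 nm. All
randomness flows from explicit seeds (placement and replicate seeds
derive from a master seed; the C++ integrator uses a counter-derived
`mt19937_64` stream), so ensembles are bit-reproducible. Degenerate
inputs are rejected early (zero-length chromosomes, residency outside
[0, 100], mismatched contact-map bins) or handled with a warning
(out-of-nucleus beads count as peripheral; LOESS windows shrink below
100 points).

Known limitations: no hydrodynamics, topoisomerase-like strand passage or
cell-cycle forces; a rigid spherical NE of fixed size; fusion-junction
deletions default to 0 bp because the lost ORF coordinates are not part
of the configuration; and the canonical fusion plans fix a junction
orientation convention (recipient right end to donor left end) — the
bookkeeping quantities the package asserts are orientation-independent,
but locus-level coordinates across a junction would not be.
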