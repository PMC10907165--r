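---
title: "Detecting and characterizing beta-strand recruitment of the TonB D-box"
author: "dboxr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing beta-strand recruitment of the TonB D-box}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dboxr)
```

# The system and the questions

Gram-negative bacteria import scarce or bulky nutrients through
TonB-dependent transport: an inner-membrane motor (ExbBD) generates force
from the proton-motive force, and the coupling protein TonB transmits it
across the periplasm to outer-membrane transporters. The handle by which the
motor grips TonB is a short conserved element just downstream of TonB's
membrane anchor -- the *D-box* -- which a homodimer of ExbD periplasmic
domains captures by **beta-strand recruitment**: the peptide joins the edges
of the two ExbD beta sheets through backbone hydrogen bonds, forming a
parallel ladder with one protomer and an antiparallel ladder with the other.

`dboxr` implements the quantitative analyses that support this picture as
reusable, tested functions:

1. **Motif discovery** (`scan_dbox()`): the D-box reads
   \eqn{\Phi\zeta\Phi\zeta\Phi\Phi\zeta} in a two-letter hydropathy alphabet
   (\eqn{\Phi} hydrophobic, \eqn{\zeta} hydrophilic), flanked by prolines,
   with high intrinsic beta-strand propensity.
2. **Binding isotherms** (`fit_itc()`, `fit_anisotropy()`): a single-site
   model with fitted stoichiometry for calorimetry, and the exact
   ligand-depletion quadratic for fluorescence anisotropy.
3. **Structural characterization** (`detect_backbone_hbonds()`,
   `classify_bridges()`, `sheet_topology()`, `fractional_burial()`,
   `complex_ca_rmsd()`, `detect_strand_recruitment()`).
4. **Conservation** (`global_align()`, `column_classes()`,
   `map_conservation()`).
5. **Synthetic data with embedded ground truth** (`gen_*`), so that every
   stage is testable without downloads.

# Motif model

## Hydropathy classes

Each standard residue maps to exactly one of three classes. The hydrophobic
set is fixed at `{A, C, F, I, L, M, V, W, Y}`; everything else except
proline is hydrophilic; proline is its own class because it delimits the
motif rather than participating in it. Glycine and histidine are assigned to
the hydrophilic class -- neither occurs at a hydrophobic position in any
known D-box example, and both are marginal on standard hydropathy scales.
The set is a `phi_set` argument everywhere, so a scale-based alternative can
be substituted.

## Beta-strand propensity

Secondary-structure prediction by a trained neural network is deliberately
out of scope; the motif call only needs a local propensity signal, so
`beta_propensity_profile()` averages the classical Chou-Fasman beta-sheet
propensities over an odd window. Defaults: window 5 (the narrowest window
that smooths single-residue noise but still resolves a 4-residue strand) and
threshold 1.0 (the natural "enriched in strands" boundary of the
Chou-Fasman scale). On the E. coli D-box peptide the Ser-Val-Thr-Met stretch
scores 1.16-1.37, comfortably above threshold:

```{r}
pep <- annotated_sequence("TonB_Ec", "QPISVTMVTPAD", 43)
beta_propensity_profile(pep)[4:7, ]
```

Window ends are handled by shrinking the window and *flagging* the position
(`truncated`), never by silently padding.

## Scanning and scoring

`scan_dbox()` slides a 7-residue window, requires the exact class string
`FzFzFFz`, and looks for prolines within `proline_window` residues of each
core end (default 2; in E. coli the prolines are immediately adjacent, but
ortholog alignments show the prolines can sit one position further out).
Overlapping matches are all reported; the propensity gate only sets a flag so
that filtering is transparent. `score_motif()` combines mean core propensity
with an optional distance penalty from the membrane-anchor end (the
functional copy of the motif sits immediately downstream of the anchor);
the anchor position is user input, never predicted.

Coordinates are reported in author numbering through a per-sequence
`numbering_offset`, because the same peptide is conventionally numbered two
ways (43-54 as a TonB fragment, 55-63 in crystal-structure annotation); the
package does not privilege either scheme.

# Binding models

## The depletion quadratic

Both assays reduce to the equilibrium `P + L <-> PL` solved exactly:

$$[PL] = \frac{(K_d + L_t + P_t) - \sqrt{(K_d + L_t + P_t)^2 - 4 P_t L_t}}{2}$$

`bound_complex()` evaluates the algebraically equivalent form
$2 P_t L_t / (S + \sqrt{S^2 - 4 P_t L_t})$, $S = K_d + L_t + P_t$, which is
stable when the square root nearly cancels $S$ (weak binding, strong
depletion). A property test checks $0 \le [PL] \le \min(P_t, L_t)$ over
$10^5$ random triples.

## Anisotropy: corrected versus as-printed

With a fixed labeled-peptide total $L_t$ and titrated protein $P_t$, the
physically meaningful signal is the bound *fraction of the labeled species*:

$$A = A_0 + (A_{max} - A_0)\,\frac{[PL]}{L_t}.$$

A form sometimes printed in methods sections divides the quadratic's
numerator by $2 P_t$ instead of $2 L_t$. With $P_t$ titrated that expression
does not saturate at $A_{max}$ and vanishes at large $P_t$, which contradicts
the observed saturating titration curves; it is therefore kept only as the
`as_printed` mode of `anisotropy_model()` for comparison, and the `corrected`
mode is the default used in fitting. The default study conditions are
$L_t = 0.1\,\mu M$ and a two-fold dilution series from 500 down to
0.49 $\mu M$ protein.

## ITC

`itc_injection_heats()` implements the standard single-site model with
fitted stoichiometry $n$ (injectant sites per macromolecule monomer; a value
of 0.5 means one peptide bridges two monomers, reported as its reciprocal
"monomers per peptide" where that reads more naturally). Dilution follows
the overflow-cell convention: injecting $dV$ into a cell of volume $V_0$
dilutes existing species by $(1 - dV/V_0)$ and displaces the same fraction
of previously formed complex, so the heat of injection $i$ is
$V_0\,\Delta H\,([PL]_i - [PL]_{i-1}(1 - dV_i/V_0))$ with units
$\mu L \times \mu M \times$ kcal/mol $= \mu$cal. The generator and the
fitter share this bookkeeping exactly, and a test compares it against an
independent oracle that re-solves the mass balance by root-finding after
every injection.

`fit_itc()` excludes the first injection by default (syringe-tip diffusion
during equilibration makes it systematically low) and fits
$(\log K_d, \log n, \Delta H)$ by Levenberg-Marquardt; the log
parameterization enforces positivity, and standard errors come back through
the delta method. Initialization is automatic: $K_d$ from the steepest point
of the heat curve, $\Delta H$ from the first usable heat, $n = 1$.
Degenerate inputs (flat or all-zero heats) return a non-converged fit with
an explanatory diagnostic rather than numbers.

## Uncertainties

Published "±" values rarely state their method, so `bootstrap_ci()` reports
residual-resampling percentile intervals alongside the asymptotic standard
errors. Coverage is checked by simulation (60 synthetic replicates, 80
bootstrap draws, nominal 90%); at these sizes the empirical coverage sits
within ten points of nominal.

## Noise defaults

The synthetic generators use independent Gaussian noise: for ITC 2% of the
first model heat (a typical per-injection integration error), for anisotropy
an SD of 0.002 (typical plate-reader repeatability). Real thermograms also
carry baseline drift and a first-injection artifact; only the latter is
modeled (via the exclusion rule). These defaults, together with the
concentrations above, *are* the study conditions for the acceptance
simulations and are not adjusted per run.

# Structural analyses

## Hydrogen bonds and bridges

`detect_backbone_hbonds()` uses the Kabsch-Sander electrostatic criterion,

$$E = 27.888\left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}} - \frac{1}{r_{OH}} -
\frac{1}{r_{CN}}\right)\ \text{kcal/mol},$$

with a bond when $E < -0.5$ kcal/mol. Amide hydrogens are taken from the
model when present and otherwise placed 1.0 A from N, anti to the preceding
carbonyl; prolines cannot donate; placement is skipped across chain breaks
(C-N distance > 2.5 A). Following DSSP practice, at most the two
lowest-energy acceptors are kept per donor. A geometric criterion
(H..O < 2.5 A, N..O < 3.5 A, N-H..O angle > 120 degrees) is available as a
flag and agrees with the energetic one on clean ladders.

Bridge typing follows the Kabsch-Sander rules in their original convention,
where `Hbond(i, j)` means the *carbonyl of i accepts from the amide of j*
(the same convention in which an alpha-helical 4-turn is `Hbond(i, i+4)`).
Reading the rules with the donor first looks superficially symmetric but is
not: the antiparallel rules are invariant under the swap, while the parallel
rules become geometrically unsatisfiable -- the two bonds of a parallel
bridge would both have to reach one rise *forward* along both strands, which
no rigid placement of two periodic strands can do. Ladders are maximal runs
of same-type consecutive bridges; `sheet_topology()` counts strands as
bridge-residue runs of length >= 2 and helices as 4-turn runs of length
>= 4.

## SASA and burial

`compute_sasa()` is a direct Shrake-Rupley implementation: 960
quasi-uniform (Fibonacci lattice, hence deterministic) points per atom,
probe 1.4 A, united-atom-style radii C 1.70 / N 1.55 / O 1.52 / S 1.80 A.
At 960 points the two-overlapping-spheres analytic solution is reproduced
within 1% (part of the acceptance suite). Waters and hydrogens are excluded
by default; unknown elements are an error with residue context, never a
guessed radius.

`fractional_burial()` defines burial as
$1 - \mathrm{SASA}_{side}(\text{complex}) / \mathrm{SASA}_{side}(\text{target alone})$,
clamped to $[0, 1]$, with the side chain being all non-backbone heavy atoms
(C-beta included). The reference state extracts the target selection *in
place* (no re-posing), so the quantity measures occlusion by the partner
rather than conformational change. Glycine, having no side-chain heavy
atoms, is reported `NA` rather than 0 or 1.

## Superposition

`kabsch_superpose()` is the SVD form of the Kabsch algorithm with the
determinant correction that forbids reflections; a test verifies it against
a brute-force rotation-grid search and that mirrored inputs still return a
proper rotation. `complex_ca_rmsd()` pairs C-alpha atoms by author number
within chains and searches all sequence-compatible chain assignments --
necessary because the two protomers of a homodimer are sequence-identical
and deposited chain labels need not correspond across crystal forms.
Residues present in only one model are excluded and counted, and both
with-peptide and without-peptide comparisons can be made by passing
`chainsA`.

## Recruitment detection

`detect_strand_recruitment()` keys on detected topology, not chain names: it
collects bridge ladders between the peptide chain and every partner,
reports each ladder's type and author-numbered ranges, computes burial for
the peptide's hydrophobic-class residues, and sets the two-sheet flag iff
ladders to at least two distinct partners exist.

# Conservation

Pairwise global alignment (Needleman-Wunsch, affine gaps) is delegated to
`Biostrings::pairwiseAlignment` with BLOSUM62, gap open 10, gap extend 0.5;
a brute-force enumeration oracle confirms optimal scores for sequences up to
8 residues. A star projection of reference-anchored pairwise alignments
replaces a progressive multiple aligner: the quantities needed here
(identity percentages, per-column classes) are defined column-wise on the
reference, and the star view reproduces them without importing an external
aligner. Column classes use the published Clustal strong/weak groups; a gap
anywhere in a column gives "none". Percent identity defaults to the
gapless-column denominator, with full-alignment-length and
shorter-sequence denominators available because reporting conventions vary.
`map_conservation()` joins classes to structure residues by author number
and flags systematic numbering mismatches (> 20% unmatched), which is how an
off-by-12 offset between the two published numbering schemes surfaces
immediately.

# Synthetic data

All generators are deterministic under a fixed seed and isolate their RNG
stream (a generator call never perturbs the caller's stream), and each
titration generator embeds its ground truth in the returned object and in a
JSON sidecar next to any CSV it writes.

The ideal beta-pair fixtures (`gen_ideal_beta_pair()`) are backbone-only
poly-alanine strands built from standard internal coordinates at textbook
dihedrals (antiparallel -139/135, parallel -119/113, trans peptide bonds)
with explicit amide hydrogens. The second strand is placed by a
deterministic rigid-body optimization (Nelder-Mead from a fixed grid of
starting placements -- no randomness) that drives every *designed* hydrogen
bond to H..O = 1.9 A and N..O = 2.9 A while repelling inter-strand clashes.
The designed register is chosen analytically: reciprocal bonds at opposed
pairs for antiparallel ladders, the alternating two-bond motif for parallel
ladders. The expected bond and bridge lists are enumerated from that
register, never by running the detector, so detector tests are genuine
round trips. `gen_recruitment_complex()` exploits the alternating up/down
orientation of strand amides to attach one partner in parallel register to
the odd residues and a second partner in antiparallel register to the even
residues -- the same geometry by which the D-box bridges two ExbD sheets.

The burial fixture is a single idealized valine inside a spherical carbon
cage (radius 5.5 A, 400 atoms); the radius must stay below ~6 A so the
probe-expanded cage spheres actually occlude the side chain's accessible
shell, and a `cage_offset` pulls the cage away to realize the zero-burial
control.

What the synthetic data do *not* emulate: real side-chain packing,
crystallographic disorder and alternate conformations beyond simple cases,
correlated instrument noise, or ortholog sequence divergence beyond point
substitutions. Passing tests on these fixtures therefore demonstrate
correctness of the algorithms and bookkeeping, not performance on noisy
experimental structures; the deposited-model analyses (see
`analysis/03_structure.R`) exercise the latter when the user supplies the
PDB entries 8VGC/8VGD, which this package does not redistribute.

# Problem sizes and numerical choices

The simulation studies use 50 noise realizations per assay, 20-injection
thermograms, 11-point dilution series, fixtures of 3-10 residues per
strand, 960 SASA points per atom, and bootstrap sizes of 80-200. These are
the package's chosen defaults: large enough that medians and coverages are
stable to well inside the tolerances asserted, small enough that the whole
suite runs on a laptop in a few minutes. Ties in alternate-location
occupancy resolve by label order; degenerate superposition inputs
(collinear points) warn; even propensity windows, negative concentrations,
sub-minimum bootstrap sizes and unknown elements are errors, not warnings.

# Known limitations

- The interface is an analysis workflow (functions plus the numbered scripts
  under `analysis/`), not a shell tool; there is deliberately no separate
  command-line binary.
- Binding models are single-site only: no cooperativity, competition, or
  kinetics, and no instrument-file parsing.
- The water-mediated contact network at the peptide interface is out of
  scope (waters are parsed and flagged, but excluded from SASA and H-bond
  analyses).
- Helix/strand assignment implements only the bridge- and 4-turn-based
  counts needed here, not a full DSSP state machine (no 3-10/pi
  distinction, no bulge handling).
- Multiple alignment is a star projection; it is faithful for
  reference-anchored column classes but is not an MSA objective optimizer
  and builds no trees.
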