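---
title: "Quantifying variable domain orientation in antibodies and T-cell receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying variable domain orientation in antibodies and T-cell receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvorient)
```

## The problem

The antigen-binding unit of an antibody (the Fv, domains VH and VL) and of an
alpha-beta T-cell receptor (domains Vbeta and Valpha) are structurally
homologous pairs of immunoglobulin variable domains. Beyond the six CDR
loops, the *relative orientation* of the two domains shapes the geometry of
the binding site: two receptors with identical loops but different
inter-domain poses present those loops differently to antigen. For T-cell
receptors this matters doubly, because the receptor must sit diagonally
across a peptide-MHC groove (the "canonical" docking mode); an inter-domain
pose incompatible with that geometry clashes sterically with the MHC.
`fvorient` implements the quantitative machinery for this analysis under the
VH-Vbeta / VL-Valpha domain equivalence: throughout, the "H side" pools VH
with Vbeta and the "L side" pools VL with Valpha, so antibodies and TCRs are
measured in one common coordinate system.

## Relative measure: the orientation RMSD

`orientation_rmsd(x, y)` quantifies how much two paired structures differ in
inter-domain pose, independent of any reference frame. The two structures
are superposed on the Calpha atoms of their shared L-side framework
positions; the H-side domains are then superposed independently; the RMSD
between the first structure's H-side domain in its native pose and in the
independently superposed pose measures how far the H side has to move once
the L sides agree. The same is done with the domain roles swapped and the
two values averaged, which makes the measure symmetric. Superpositions use
an SVD-based least-squares fit (the Kabsch construction) with reflections
excluded. Framework positions missing from either partner are dropped from
that pairwise comparison (crystal structures routinely lack a few residues;
the intersection rule keeps every comparison well defined, at the cost that
different pairs may use slightly different position sets — the counts are
recorded).

Pairwise orientation RMSDs feed `cluster_orientations()`, complete-linkage
agglomeration via `stats::hclust`, whose merge heights equal the maximum
within-cluster pairwise distance. Equal merge heights are resolved by
`hclust`'s deterministic order given a fixed input order, so reports are
reproducible for identical inputs.

## Absolute measures: five angles and a distance

The relative measure says *how much* two poses differ but not *how*. The
absolute description registers a fixed reference frame onto each domain and
reads off six coordinates:

1. **Coresets** (`derive_coresets()`): the structurally most conserved
   framework positions of each side. Starting from all framework positions
   present in at least 95 percent of the ensemble, the members are
   iteratively superposed on the current coreset and the position with the
   largest positional spread (RMS deviation from the mean) is dropped, until
   every remaining position has spread at most 1.0 Angstrom or a floor of 20
   positions is reached. The 95 percent presence rule, the 1.0 Angstrom
   ceiling and the floor of 20 are package defaults chosen so that a typical
   crystallographic ensemble retains a stable beta-sandwich core; all three
   are arguments. The derived lists are carried in the returned object for
   transparency, since coresets derived from different ensembles differ.
2. **Consensus domains** (`build_consensus_and_frames()`): per-position mean
   Calpha coordinates after iteratively superposing each member onto the
   evolving mean (converged when the largest mean shift is below 1e-4
   Angstrom; non-convergence after 100 iterations is an error).
3. **Frames**: per side, the origin is the centroid of the consensus Calpha
   atoms at the interface positions, and e1/e2 are the first two principal
   axes of those atoms. The default interface set is IMGT 38-50 and 87-104 —
   the beta-sheet faces that form the dimer interface — and is
   user-overridable. Principal axes are sign-ambiguous, so e1 is oriented
   towards the consensus Calpha of IMGT 104 (the conserved interface
   cysteine) and e2 towards IMGT 50; both anchors are salient, invariably
   present positions.
4. **Registration**: for a query structure, each consensus is superposed
   onto the query via the shared coreset positions and the frame is carried
   along. A registration RMSD above 2.5 Angstrom flags the result as
   unreliable rather than failing, since a poor core fit degrades the
   measures gradually.
5. **The six measures** (`compute_measures()`): with C the vector from the
   registered L-side origin to the H-side origin, `dc = |C|` (Angstrom);
   `HL` is the torsion angle of the two e1 vectors about C; `HC1`/`HC2` are
   the angles of C with the H-side e1/e2; `LC1`/`LC2` the angles of -C with
   the L-side e1/e2. All angles are reported in degrees, the convention of
   the packing-angle literature.

Because the pivot axis and frames are constructed from the consensus of the
*supplied* ensemble rather than imported from prior antibody work (whose
data files are not redistributable), absolute values are internally
consistent but offset from previously published packing-angle scales.
Comparisons *within* a run — antibody versus TCR cohorts measured against
one shared frame system — are unaffected, and that comparative use is what
the package targets. This is the main reason the package does not promise
numeric agreement with published per-structure angle tables.

## The docking angle

For a receptor bound to a peptide-MHC, `docking_angle()` reports the angle
between the major axis of the peptide (first principal axis of its Calpha
atoms, oriented from the N to the C terminus) and the vector between the
Calpha atoms of the interface cysteines at IMGT 104, directed from the
VL/Valpha domain to the VH/Vbeta domain. The angle is the plain 3D angle
between the two vectors, reported in [0, 180); no projection onto the groove
plane is applied. The N-to-C and Valpha-to-Vbeta direction conventions make
angles beyond 90 degrees meaningful (reversed-polarity binders) instead of
folding them back into [0, 90]. Angles between 40 and 85 degrees are
classified canonical.

## Orientation grafting and steric quantification

`graft_orientation()` asks whether a given inter-domain pose is *sterically
compatible* with a native receptor-pMHC binding geometry. The decoy's
L-side-equivalent domain is superposed onto the native L-side domain via
shared framework positions; the native H-side domain is then superposed onto
the decoy's H-side domain in that aligned context. The native H-side thus
inherits the decoy's pose while the L side, MHC and peptide stay fixed; both
anchoring choices can be run. Grafting moves whole domains rigidly, so every
chain's internal geometry is preserved exactly.

Steric strain is counted two ways:

* `count_clashes()`: a receptor residue and an MHC/peptide residue clash
  when any heavy-atom pair overlaps the sum of van der Waals radii (C 1.70,
  N 1.55, O 1.52, S 1.80 Angstrom, others 1.70) by at least 0.4 Angstrom —
  the overlap convention of standard all-atom clash scoring — with each
  residue pair counted once. When only Calpha/Cbeta coordinates are present
  the fallback criterion is a Cbeta-Cbeta distance under 3.0 Angstrom.
  Because no side-chain remodelling is performed between graft and count,
  all-atom counts correspond to pre-repacking numbers; callers may run an
  external side-chain remodeller on the written PDB between the two steps.
* `contact_pairs()`: all receptor-to-MHC/peptide residue pairs with
  Cbeta-Cbeta distance under 7 Angstrom (glycine contributes its Calpha),
  sorted by distance.

`run_graft_experiment()` drives both anchorings over two decoy cohorts and
compares total clash counts with a two-sided Mann-Whitney U test
(`stats::wilcox.test`, exact for small untied samples, normal approximation
with tie correction otherwise).

## Sequence analyses

All sequence work is positional on the IMGT 1-128 grid; unobserved positions
are excluded from numerators and denominators alike. A position is
*conserved* when one residue reaches 50 percent of observations; the
domain-equivalence tally uses "at least 50 percent" while the divergent
interface table uses a strict "more than 50 percent", both printed
thresholds being parameters. An exact 50/50 two-way tie is flagged ambiguous
and treated as unconserved. `equivalence_support()` counts, for each
possible VH/VL-to-Vbeta/Valpha pairing, the positions whose conservation
pattern argues for the other pairing. `divergent_interface_positions()`
lists interface positions conserved in both sets but with different
residues, flagging those where the second set's residue already occurs at a
background frequency of at least 2 percent in the first set as plausible
engineering targets. `filter_redundant()` applies a greedy 90 percent
identity filter, ordering candidates by resolution (then identifier) so the
best-resolved representative of each sequence family is retained; identity
is computed position-wise over shared observed positions of the concatenated
two-domain sequence, which differs from word-based clustering tools, so
retained-set sizes need not match counts produced with such tools.

## The synthetic testbed

Every geometric claim in the test suite is validated against structures with
*known* ground truth, generated by `make_fv()`, `make_pose_family()` and
`make_pmhc()`:

* The scaffold is a deterministic pseudo beta-sandwich Calpha/Cbeta trace
  over the IMGT grid (eight 16-position strands in two sheets), with
  framework/CDR annotation, conserved cysteines at 23 and 104, tryptophan at
  41, and domain-type-specific CDR3 occupancy giving the field-typical modal
  loop lengths (VL 9, VH/Vbeta 12, Valpha 13). Geometry is keyed on the IMGT
  position, so all domain types share an identical framework trace.
* `make_fv()` solves the frame construction analytically: the pivot axis is
  laid along +z, the requested bend/twist angles fix the frame vectors up to
  an azimuth, the requested torsion fixes the azimuth, and each scaffold is
  moved rigidly onto its solved frame. Noiseless structures therefore round
  trip through `compute_measures()` at numerical precision; a requested
  angle combination with no orthonormal solution (e.g. HC1 10 with HC2 170
  degrees) is rejected as unreachable. Default pose values (HL -60, HC1 70,
  HC2 115, LC1 120, LC2 82 degrees, dc 16 Angstrom) sit in the
  antibody-typical region of orientation space, with smaller HC2 used for
  TCR-like cohorts; isotropic Gaussian coordinate noise and the seed are
  explicit parts of the pose specification.
* `make_pmhc()` builds a nine-residue peptide along +x, a two-layer MHC slab
  with a groove channel, and places the receptor with its 104-104 cysteine
  vector at exactly the requested docking angle and a requested minimum
  receptor-to-MHC separation (default 5 Angstrom, a realistic binding gap
  for Cbeta-resolution models). `make_twist_decoys()` tips the H-side domain
  toward the groove about a far-side horizontal axis so that grafted clash
  counts grow monotonically with the injected twist.

What the generator does **not** emulate: real side-chain chemistry and
packing, sequence diversity (all scaffolds share one sequence), CDR loop
conformational variation, and the correlated, position-dependent coordinate
error of crystallography (noise is isotropic and independent). Passing tests
therefore demonstrate that the geometry, counting and statistics are
implemented correctly and are internally consistent — they do not certify
numeric agreement with any particular crystallographic cohort, whose
composition depends on database versions and external filtering tools.

## Problem sizes, numerics, defaults

The shipped validation runs use cohorts of 20 structures per family
(spread 2 degrees), six-member ensembles for frame building, a 25-pose
round-trip grid, and twist grids to 40 degrees; these sizes give stable
statistics (the shifted-family KS test saturates at D = 1) while keeping a
full run in tens of seconds. Tolerances follow the data path: coordinates
written to PDB are fixed-width (1e-3 Angstrom), so round-trip assertions use
2e-3; purely in-memory rigid identities are asserted at 1e-6 to 1e-9.
Degenerate inputs error early and by name: fewer than three superposition
points, collinear targets, identical point clouds for principal axes,
coincident or collinear torsion points, missing IMGT 104 anchors, fewer
than 50 mapped framework positions per domain at load time (relaxable for
deliberately truncated fixtures), and peptides shorter than three residues
for the docking angle.

Two deliberate I/O conventions: IMGT renumbering is *consumed*, never
computed — every PDB is accompanied by a tab-separated sidecar mapping
(chain, author number, insertion code) to IMGT positions, since renumbering
is a separate, well-served tool class; and alternate locations keep the
highest-occupancy altloc (ties by identifier order), with MSE read as MET
and other heteroatoms ignored.

## Worked example

```{r example}
# two synthetic cohorts: a TCR-like family (small HC2) and an antibody-like
# family, measured against one shared frame system
tcr_fam <- make_pose_family(pose_spec(HC2 = 105), spread = 2, n = 8,
                            seed = 1, receptor_class = "tcr")
ab_fam <- make_pose_family(pose_spec(HC2 = 120), spread = 2, n = 8,
                           seed = 2, receptor_class = "antibody")
rep <- run_survey(tcr_fam, ab_fam, labels = c("tcr", "antibody"))
rep
summary(rep)
```

```{r graft}
native <- make_pmhc(51.4, groove_gap = 5, seed = 3)
docking_angle(native)
decoys <- make_twist_decoys(native, c(0, 10, 20, 30))
vapply(decoys, function(d) {
  g <- graft_orientation(native, d, anchored = "Valpha")
  g$clashes_moved_domain + g$clashes_anchored_domain
}, 0L)
```

## Known limitations

* Absolute angle values are tied to the frame system built from the supplied
  ensemble; they are not interchangeable with published packing-angle tables
  (see above).
* Clash counts at Cbeta resolution are a coarse proxy; all-atom counts
  without side-chain repacking overestimate strain relative to a repacked
  model.
* The docking angle uses the unprojected 3D angle; conventions that project
  onto the MHC groove plane can differ by a degree or so for tilted
  receptors.
* mmCIF input, automatic chain pairing and automatic IMGT renumbering are
  out of scope by design.
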