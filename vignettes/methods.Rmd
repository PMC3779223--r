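---
title: "Detecting structurally deviant superfamily members: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting structurally deviant superfamily members: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rebelscan)
```

## The problem

A protein domain superfamily groups families of common evolutionary origin
whose members often retain a conserved structural core at sequence
identities far below the twilight zone. Against that conserved backdrop,
individual members can diverge sharply — hinge rotations of whole
subdomains, inserted secondary-structure elements, terminal extensions,
circular permutation, domain swapping — and such structural "rebellion"
frequently accompanies a change of function. Given the members' Cα
coordinates and a structure-based multiple alignment, `rebelscan`
identifies the deviant members, labels family-specific deviations, and
quantifies whether deviants are also functional outsiders in Gene Ontology
terms.

The pipeline deliberately starts *after* alignment construction. A
structure-based alignment already encodes the expert correspondence
decisions (variable gap penalties, conserved-element anchoring); treating
its non-gap columns as equivalences keeps this package small, deterministic
and auditable. The alignment is the sole source of residue correspondence —
PDB residue numbering is carried along only as labels.

## Superposition model

**Pairwise.** Kabsch least-squares superposition: for matched point sets
the optimal proper rotation comes from the SVD of the cross-covariance
matrix, with the smallest singular direction sign-corrected so that
reflections are never produced — a mirror-image fit is physically
meaningless for a polypeptide backbone. Point sets of rank < 2 (collinear
traces) admit no unique rotation; the fit is returned but flagged
degenerate.

**Multiple.** Members are placed in a common frame by iterative consensus
fitting over the *core columns* (columns ungapped in every member):
initialise the consensus from the reference member, then alternate
(i) Kabsch-fit every member's core Cαs onto the consensus and
(ii) recompute the consensus as the coordinate-wise mean of the fitted
members. The procedure is a block-coordinate descent on the summed squared
deviation to the consensus, so each sweep is non-increasing; iteration
stops when no consensus point moves by more than `tol = 0.01` Å (typically
2–3 sweeps) or after `max_iter = 100` sweeps, in which case a `converged =
FALSE` flag is set rather than an error raised. At convergence the
consensus is a fixed point of the mean of the superposed cores, which the
test suite checks directly.

Two deterministic tie-break rules make runs reproducible: the reference
member is the one with the most non-gap alignment positions (lexicographic
member id on ties), and equivalences stay fixed to the alignment columns
throughout — the iteration never reassigns correspondences.

## Deviation statistics

**Pairwise RMSD** for members *a, b* is computed over their *pairwise*
ungapped columns (a superset of the core) from the coordinates in the
common superposed frame. This matches the protocol order — one multiple
superposition, then deviations read off the matched Cαs — and makes the
matrix reflect deviation from the *ensemble's* frame, not the best
achievable pairwise fit. An explicitly non-default `mode = "repair"`
re-superposes each pair optimally; it never exceeds the common-frame value
and is provided for sensitivity analysis only. Pairs sharing fewer than 3
matched columns are excluded from means with a warning.

**MeanRMSD** is each member's arithmetic mean of off-diagonal, non-missing
row entries — the one-against-all statistic whose exceedance signals a
deviant member.

**TM-score** confirms candidates on a fold-level scale that, unlike RMSD,
is length-normalised and saturating:
`TM = max (1/L_N) Σ 1/(1 + (d_i/d0)²)` with
`d0 = 1.24 (L_N − 15)^⅓ − 1.8` Å. Choices:

* `L_N` defaults to the *shorter* member's residue count (the conservative
  symmetric convention); `longer`, `first` and `second` are available.
* `d0` is floored at 0.5 Å because the cube-root formula turns negative
  below L_N ≈ 21.
* Maximisation is seed-and-extend: every seed fragment is Kabsch-fitted,
  then refined by iterating "keep matched pairs with d < d0 + 1 Å (never
  fewer than 4), re-fit" until the score changes by < 1e-6 (≤ 20 rounds);
  the maximum score over all seeds and rounds is returned. For matched
  regions of ≤ 60 residues *every* contiguous fragment of length ≥ 4 is
  used as a seed, which makes the search exhaustive at negligible cost; for
  longer regions seeds are fragments of lengths ≈ {L, L/2, L/4} at stride
  ≈ L/10. Sparse seeding alone proved able to miss the optimum by ~2×10⁻³
  on small hinge instances, which motivated the exhaustive small-L branch;
  the suite verifies agreement with an independent exhaustive-seed oracle
  to 1e-6 on ≤ 40-residue instances.

**Outlier rule.** Member *m* is an outlier iff mean RMSD(m) > 5.5 Å *and*
median TM(m,·) < 0.5, both strict. The conjunction is deliberate: a single
huge outlier inflates *every* member's mean RMSD (each row contains the
outlier's pair), so mean RMSD alone over-calls in small superfamilies; the
TM confirmation removes exactly those collateral candidates. The per-member
TM aggregate is the *median* of its pairwise scores — robust to one
aberrant partner — since a mean would let a single pathological pair drag a
normal member below the cut. An `"or"` rule is available behind a flag for
sensitivity analysis. Members exactly at a threshold are not outliers.
Because the rule is a conjunction, TM-scores are only *needed* for members
whose mean RMSD already exceeds the cut; `tm_scope = "candidates"` exploits
this for large simulation studies, while the pipeline default computes the
full matrix for complete reports.

**Family specificity.** An outlier set is family-specific iff all outliers
share one family label and no non-outlier carries it — the pattern of a
whole family having wandered away from its superfamily.

**Screens.** Two cheap, deliberately humble heuristics annotate *why* a
member may deviate. (i) Gap runs: a maximal column run where a member has
residues but > 50 % of the others are gapped is an insertion (relabelled
N-/C-terminal extension when it touches an alignment end); the converse is
a deletion. Deletion runs keep their label at the termini — a truncated
member is not an "extension". (ii) Circular permutation: cyclic shifts of
one member's residue order (grid of 5 residues, ± 4 refinement) are
re-superposed positionally; a best-shift improvement over the unshifted
register greater than 2 Å is reported as a CP signal. The 2 Å tolerance was
chosen against the null: for unrelated generated traces the unshifted
register is already optimal (improvement ≈ 0), while a true CP pair's
improvement is of the order of the full misregister RMSD (tens of Å). These
are screening hints; topology changes, swaps and duplications need human
eyes and are out of scope.

## GO semantic similarity

Term-level similarity follows the Wang method: each term's *S-value*
mapping assigns 1 to itself and propagates semantic contribution upward,
`S(u) = max over child edges (w_edge · S(child))`, with contribution
factors 0.8 (`is_a`) and 0.6 (`part_of`) — the method's conventional
weights, configurable. Two terms are compared by summing S-values over
shared ancestors relative to their total semantic content. Aggregation is
two-level, exactly as the deviation layer needs it: the **domain-pair
mean** averages all |A|×|B| term cross-pairs, and the **member grand
average** averages a member's pair means against every other annotated
member. Cross-namespace pairs (no shared ancestry) score 0 rather than
being skipped — "all pairs that could be compared" is read literally, and 0
is the natural similarity of unrelated terms; `skip_disjoint = TRUE` gives
the other reading. Annotations are compared as given: no propagation of
annotations to ancestors and no evidence-code filtering, matching the
direct term-comparison convention of the aggregation. A symmetric
best-match average is available behind `aggregate = "best_match"` but is
not the default. Obsolete OBO terms are dropped at parse time; cycles and
dangling parents are hard errors.

## The synthetic generator

The generator emulates the statistical situation the detector faces: a
conserved core seen through per-member noise, with a few members carrying
large, nameable perturbations.

* **Core trace:** a smooth self-avoiding path with exact 3.8 Å Cα spacing,
  alternating idealised helical turns (radius 2.3 Å, rise 1.5 Å/residue,
  100°/residue) with short extended segments, the axis re-orienting by
  8–20° between segments. Candidates with non-consecutive contacts below
  2.2 Å are redrawn deterministically from the same stream.
* **Members:** core + isotropic Gaussian noise (default σ = 0.3 Å, a
  realistic magnitude for coordinate scatter among well-aligned homologous
  cores) in a random rigid frame each.
* **Planted perturbations:** hinge rotations about axes perpendicular to
  the local chain direction; insertions (emitted as alignment columns
  gapped in all non-carriers); deletions (gapped in the carrier); circular
  permutations and segment swaps, emitted with the *permuted* residue order
  under a positionally naive alignment row — what a real alignment pipeline
  produces for a CP pair, and why CP members surface as high-RMSD outliers.
* **Canonical outlier:** the two-hinge plan rotates residues [L/3+1, 2L/3]
  by 120° and [2L/3+1, L] by 150° about orthogonal axes, leaving a largest
  rigid block of L/3 — so no single superposition can align much more than
  a third of the member well, guaranteeing both a high mean RMSD and a low
  TM-score.
* **Toy ontologies:** one root, n disjoint `is_a` chains, occasional
  `part_of` shortcuts to great-grandparents (diamond motifs exercising the
  part_of weight without bridging branches). Branch 1 is reserved for
  planted-outlier families, so their annotations share nothing below the
  root with the rest — the construction under which structural outliers
  must also be semantic outliers.

All draws flow through one seeded stream per call in a documented order, so
every fixture is byte-reproducible. What the generator does **not**
emulate: side chains, Ramachandran statistics, secondary-structure hydrogen
bonding, sequence realism, alignment errors, or correlated (domain-level)
noise. Passing the planted-recovery suites therefore demonstrates that the
statistics behave as designed under their own model — not that curated
real-world alignments are error-free inputs.

## Simulation sizes and numerical conventions

The repeated-simulation studies use 200 seeds of a 10-member, 120-residue
superfamily (noise σ = 0.3 Å) per condition — large enough for stable 95 %
/ 99 % recovery-rate statements while keeping a full suite run in minutes
on one core. Report TSVs print Å and similarity values at 4 decimals;
alignment gaps are `'-'` only (`'.'` is rejected to keep one dialect);
all user-facing failures carry typed condition classes
(`rebelscan_missing_file`, `rebelscan_no_core`, …) so callers can
distinguish error kinds programmatically. Means over members are taken in
sorted member-id order.

## Known limitations

* Correspondences come entirely from the input alignment; a poor alignment
  yields poor deviation statistics (garbage in, garbage out by design).
* The mean-RMSD statistic is frame-dependent: in small superfamilies one
  extreme outlier lifts everyone's mean, and only the TM confirmation
  separates cause from collateral. Interpret mean RMSD jointly with the TM
  column in `members.tsv`.
* The CP and gap-run screens are hints for triage, not classifiers; the
  full reason taxonomy (topology change, swap, duplication) requires
  inspection.
* TM maximisation is exhaustive only for matched regions ≤ 60 residues;
  above that the sparse seed ladder may in principle return a slightly
  sub-optimal (lower) score, which is conservative for outlier
  *confirmation* but worth remembering when scores sit at the 0.5 boundary.
* GO comparisons use annotated terms as given; sparsely or inconsistently
  annotated members make the grand averages noisy, and unannotated members
  are silently excluded from the semantic layer.
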