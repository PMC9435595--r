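---
title: "Methods: the model-building cycle engine and its metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the model-building cycle engine and its metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxbuild)
```

## The procedure and its assumptions

Automated crystallographic model building alternates map interpretation
(building atoms into electron density) with reciprocal-space refinement,
using the cross-validation residual R_free as the arbiter of progress.
`mxbuild` implements the control layer of such a pipeline and the
numerical pieces it owns, while the heavy engines — shift-field and
conventional refinement, density modification, main-chain tracing,
nucleic-acid building, rotamer fitting, residue scoring — are reached
through the `backend_suite()` function contract. The engine assumes each
backend call is a pure function of its arguments; everything the engine
decides (step order, acceptance, stopping, output selection) is then a
deterministic function of the backend outputs.

A cycle runs seven steps in fixed order: pruning, density modification,
dummy-atom addition, protein building, chain pruning, nucleic-acid
building, water addition. Dummy atoms and waters exist purely to improve
phases: the hybrid model is refined and kept only if its R_free is
strictly lower than the preceding refinement's, and both categories are
stripped before any building step, so a rejected step can never leak
atoms into the built model. The nucleic-acid step is skipped (with a log
entry) when no nucleic sequence is supplied; running it would be a no-op
and would spend a backend call.

Stopping combines a hard cap of 25 cycles with an early stop after 4
consecutive cycles whose end-of-cycle R_free fails to improve on the
best value seen; "end of cycle" means the last accepted refinement of
that cycle, so an accepted water refinement counts. The returned model
comes from the cycle with the lowest R_free (earliest on ties), followed
by an optional side-chain rebuild gated at d_min < 2.5 Å and R_work
< 0.30 and itself accepted only on an R_free improvement.

## Tunable parameters

All knobs live in `pipeline_config()` with these defaults (units in
parentheses): 25 max cycles; 4-cycle no-improvement stop; 3 then 2
building-engine cycles (first vs later iterations); 3 nucleic-building
cycles; 10 refinement cycles after building/dummies/waters and 5 after
pruning or the final rebuild; 12 shift-field cycles with the resolution
schedule linear from 6 to 3 (Å); building-map cap 2.0 (Å); experimental
phases dropped once R_work ≤ 0.35 (latching: once off, off for good,
which is the conservative reading of a switch that "stops using"
phases); waters attempted once R_work < 0.40; rebuild gates 2.5 (Å) and
0.30; residue/side-chain pruning skipped when d_min > 2.3 (Å); pruning
factors 0.2 (chains) and 0.5 (residues/side chains) of the structure
median with a 20% per-stage cap; rebuild selection factors 0.25/0.25;
peak thresholds 2 (σ); dummy-atom distance band 1.9–10 (Å) with 1.4 (Å)
pair separation; water rules < 15 (Å³), > 2.4 (Å), ≤ 3.2 (Å), 3 passes.
The free-flag convention is CCP4's: flag value 0 marks the free set, a
flag set is valid when 0 < fraction(zero) ≤ 0.5, and regenerated flags
default to a 5% free fraction (the regeneration fraction is a
configuration choice, not a claim about any external program).

## Metrics

**Completeness** is the percentage of reference protein residues whose
N, Cα and C atoms all lie within 1 Å of the corresponding atoms of some
built residue, after each built chain is independently moved onto the
reference by the space-group operation and allowed origin shift that
maximize its matched count; each reference residue is matched at most
once, greedily in reference order with nearest-Cα tie-breaking. Allowed
origin shifts are the translations that conjugate the group onto itself;
they are enumerated on a 1/4-step lattice per discrete axis, while polar
axes admit any shift. Continuous components are seeded from wrapped
Cα-pair differences between the rotated built chain and the reference
and then polished by shifting with the mean matched residual — a
deterministic scheme that also resolves the three simultaneous polar
axes of P1, where a 1-D scan seeded at zero would not suffice. All
residue distances are lattice-minimum-image, so a model placed in a
neighbouring cell matches its parent.

**F-map correlation** between two models is
Σ F₁F₂ cos(φ₁−φ₂) / √(Σ F₁² · Σ F₂²) over one Friedel hemisphere to
d_min with F(000) excluded — by Parseval's identity this equals the
real-space Pearson correlation of the two zero-mean, band-limited maps,
which is the reading the test suite verifies against an FFT oracle.
**R factors** use the least-squares scale k = ΣF_oF_c/ΣF_c² fitted on
the working set. The **quality gate** fails a case when R_free >
0.06·d_min + 0.17, data completeness < 90%, or F-map correlation < 0.2,
and reports every failed clause. **Superposed similarity** truncates a
predicted model to the residues of a reference chain (matched by residue
number), superposes common Cα atoms by Kabsch's SVD solution with a
determinant correction against reflections, and counts chain Cα atoms
within 1 Å of any predicted Cα; the "best chain" is the one maximizing
the percentage, ties broken by chain id.

## Density operations and numerical choices

A peak is a voxel strictly greater than all 26 periodic neighbours with
height ≥ 2σ above the map mean, where σ is the population (not sample)
standard deviation over all voxels, the map-grid convention. Positions
are refined per axis by quadratic interpolation (offset clamped to half
a voxel; a vanishing curvature denominator falls back to the voxel
centre). The peak "volume" is the 6-connected voxel region above the
picking threshold times the voxel volume — the external program this
emulates does not define its volume, and the connected-region reading is
the simplest testable one. Dummy-atom flooding accepts peaks greedily in
descending height (ties by grid index order) subject to the pairwise
rule, which makes the outcome deterministic. Water picking runs exactly
three passes; the hydrogen-bond partner test uses the model as of the
start of the pass (waters accepted in earlier passes count as O atoms),
while the 2.4 Å exclusion also sees waters accepted earlier in the same
pass — this is what makes a second-shell water appear in pass 2 rather
than pass 1 while still guaranteeing that no two accepted waters violate
the exclusion distance. Distance rules are symmetry-expanded by default
(crystal contacts are real contacts); a flag disables the expansion for
P1 toy fixtures.

Structure factors are computed by direct summation over
symmetry-expanded atoms with single-Gaussian form factors — one (a, b)
pair per element with a near the electron count. The quantities in
scope (correlations, R-factor ratios) are insensitive to form-factor
fidelity, so a 4-Gaussian table would add cost without changing any
decision; this is a documented limitation for anyone wanting absolute
amplitudes. The synthetic map generator samples exactly the Fourier
transform of those form factors (a Gaussian of width b + B per atom),
which is what lets an FFT of the sampled map serve as an independent
cross-check of the direct summation at the 10⁻³ level.

Degenerate inputs are handled explicitly: a constant map is flagged
(σ = 0) and peak search on it errors; filtering that removes every
reflection warns and returns an empty set; a pLDDT cutoff that removes
every residue warns; an empty model is rejected by the distance and
structure-factor routines.

## Scoring-rule conventions

The medians in the pruning rules are taken over residues of the whole
structure, not per chain. The 20% cap applies to residue and side-chain
pruning (each class independently, eligible population = all scored
residues, respectively all residues with side chains), not to chain
pruning; victims are removed lowest-score-first with ties broken by
(chain, residue) order. The LLK outlier filter uses the sample (n−1)
standard deviation, the small-sample default. Every-third seed selection
starts at the first survivor — the offset is otherwise unspecified, and
starting at the first keeps the selection a pure function of the
survivor list. Acceptance comparisons are strict (<) throughout: "better"
does not include ties, which is the conservative choice.

## What the synthetic module emulates — and what it does not

`make_helix_model()` builds an ideal poly-alanine α-helix (rise 1.5 Å,
100°/residue, Cα radius 2.3 Å, N/C/O/Cβ at canonical cylindrical
offsets) centred in the cell; `perturb_model()` rescales Gaussian
displacements to an exact target RMSD; `delete_residues()` removes a
seeded random subset; `make_scores()` draws correct residues from a
high correctness band (0.7–0.95, LLK ≈ +5) and incorrect ones from a
low band (0.01–0.2, LLK ≈ −5); `scripted_backends()` replays a
per-cycle R_free trajectory (with optional offsets for refinements of
models carrying dummies or waters, so acceptance branches can be
driven), and `toy_backends()` computes real R factors from the model by
direct summation. Toy cells default to ~24 Å P1 boxes for density
work and P2₁ for symmetry work — the smallest cases that exercise each
code path; the exhaustive symmetry checks run on 10-residue fixtures
over P1, P2₁, C2, P2₁2₁2₁ and P4₃2₁2.

These generators reproduce the *logic-relevant* features of real data:
seeded determinism, symmetry relations, controlled error and
completeness levels, scripted convergence behaviour. They do not
reproduce experimental noise statistics, solvent contribution, bulk
disorder, realistic B-factor distributions, or the failure modes of real
building engines; a green test suite therefore certifies the control
logic, the rule arithmetic and the metric definitions, not performance
on deposited data.

## Known limitations

Space-group support covers 15 common Sohncke groups via a bundled
operator table, not all 230 groups; anisotropic B factors, alternate
conformers, TLS and MTZ binary parsing are out of scope (mmCIF is the
canonical coordinate format, PDB writing is best-effort for
single-character chain ids). The completeness matcher assigns built to
reference residues one-to-one; in heavily NCS-overlapped cases a
different assignment convention could count differently. Improper
(inverted) matches are not considered, as macromolecular space groups
lack inversion.
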