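---
title: "Rotation refinement for multiple circular sequence alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation refinement for multiple circular sequence alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circMSA)
```

## The problem

Mitochondrial genomes, viroid and viral genomes, plasmids and naturally
circular proteins have no biologically meaningful first position: the
linearisation deposited in a database starts wherever sequencing or
convention happened to cut the circle. Conventional multiple sequence
aligners assume the left and right ends of their inputs correspond, so a set
of closely related circular molecules linearised at different points aligns
badly — inflated length, spurious indels, a higher average pairwise
distance. `circMSA` computes, for a set of `d` circular sequences, a
rotation array `R` such that the rotated sequences `rotateSeq(s[i], R[i])`
linearise the set consistently; the rotated output is then given to any
conventional MSA program. The package never removes information — it only
rotates.

## The three-stage heuristic

**Stage 1 — pairwise cyclic comparison.** For every ordered pair `(i, j)`
the method searches for the rotation `r` of `s_i` minimising its distance to
`s_j`. Scanning all `m` rotations under the edit distance would be
quadratic per rotation; instead the scan uses the beta-blockwise q-gram
distance: both strings are cut into `beta` blocks (as evenly as possible;
`beta = max(1, floor(min(m, n) / blockLength))`), and corresponding blocks
are compared by the L1 distance of their q-gram occurrence counts. The
partition enforces locality — shared material only counts when it sits in
corresponding parts of both strings — which is what makes the distance
sensitive to rotation at all: with a single block the q-gram bag of a
circular string is almost rotation-invariant. The scan is incremental (one
q-gram enters and one leaves each block per unit rotation), so a full
rotation scan costs `O(m * beta)` operations.

The q-gram optimum is then polished on a *refined pair*: a prefix of
`w = round(P * m / beta)` letters, a spacer run of `w` sentinel letters
`'$'` (not in the residue alphabet), and a suffix of `w` letters, taken from
`x^r` and from `y`. Every rotation of the first refined string whose cut
falls in the copied ends (cuts inside the spacer correspond to no rotation
of `x` and are skipped) is scored against the second with Gotoh global
alignment under the substitution matrix, and the best-scoring offset updates
`r` by at most `w`. The spacer scores 0 against itself and `-2 * |gapOpen|`
against anything else, which keeps the two spacer runs aligned so that only
the copied sequence ends drive the score. Finally the cell `(i, j)` of the
pair matrix `M` stores that rotation `r` together with `e`, the edit
distance between the final refined pair — bit-parallel (Myers) under unit
costs, plain dynamic programming under weighted costs.

**Stage 2 — guide tree.** Neighbour joining on the symmetrised `e` values
`(e[i,j] + e[j,i]) / 2` (the refined-pair distance depends on which sequence
was rotated, so `M` is not exactly symmetric). The construction is
deterministic: Q-criterion ties break towards the lexicographically smallest
pair of cluster creation indices, the final join is the root, and children
are stored in creation order. Determinism here is not cosmetic — the
traversal order of Stage 3 follows it.

**Stage 3 — rotation-aware progressive alignment.** Profiles (alignments
viewed column-wise over the gapped alphabet) are merged bottom-up along the
guide tree. The profile with more rows is always profile A; profile B is the
one whose rows get rotated. Column pairs are scored through the frequency
matrices of both profiles, `p[i, j] = t(F_A) %*% sim %*% F_B`, with a
linear gap cost per gapped column by default (an affine Gotoh mode is
available via `msaAffine`). The pairwise rotation between the two profiles'
*anchor* rows (the rows left unrotated when their profiles were built) is
transferred to the whole of B by the propagation rule `r + g`, where `g`
counts the gap characters inserted in B's anchor row before the residue at
original position `r` — gaps accumulated during earlier merges shift every
later column. The propagated column rotation is then refined on
*end-profiles* (the profile analogue of the refined pair: `w` leading
columns, `w` spacer columns, `w` trailing columns), applied by cyclically
shifting B's rows, and the profiles are merged. Each row's cumulative
rotation is maintained in original, ungapped coordinates — shifting a row
by `k` columns advances its rotation by the number of residues among those
`k` columns — so the final `R` is read directly off the root profile, whose
anchor row stays at rotation 0.

The worked five-sequence example from the published description of this
method runs in a few milliseconds and reproduces its printed numbers: the
pairwise rotation of `AAGTAAGCT` against `AAGCCTTTAGT` is 4, three gaps
precede that residue in the profile anchor row `A---AGTAAG-C--T`, and the
profile rotates by `4 + 3 = 7` columns into `AAG-C--TA---AGT`.

## Parameters

* `q` (default 5): q-gram length of the rotation search. Must not exceed
  the shortest block. For sequences of a few kilobases, 4–6 works well; the
  toy examples in the tests use `q = 3` with 3-letter blocks.
* `blockLength` (default 50, residues): target block size from which the
  per-pair `beta` is derived (`floor`, per pair — the shorter sequence gets
  blocks of about this many residues). Smaller blocks mean stronger
  locality and a sharper rotation signal, at the cost of sensitivity to
  indel drift.
* `refineExtent` `P` (default 1.0, in blocks): half-width of the refinement
  windows, `w = round(P * m / beta)` residues. Larger values refine more
  aggressively but cost quadratically in `w`. The constraint `P <= beta/3`
  (windows cannot exceed a third of the sequence) is enforced per pair by
  *clamping* the effective value to `min(P, beta/3)` rather than failing:
  short sequences with `beta = 1` would otherwise reject the default
  `P = 1.0`, and the largest admissible window is the natural intent.
* `costModel` (default `"unit"`): the distance stored in `M.e`. Unit costs
  use the bit-parallel algorithm; `"weighted"` uses dynamic programming
  with `subCost`/`indelCost`.
* Gap penalties: `gapOpen`/`gapExtend` (defaults -10/-1) score the pairwise
  refinement; `msaGapOpen`/`msaGapExtend` (defaults -10/-1) the profile
  stage. The default profile mode is the literal linear recurrence (a gap
  column costs `msaGapOpen` regardless of run length); `msaAffine = TRUE`
  switches to Gotoh-style costs.
* Substitution scores: +5/−4 for DNA, BLOSUM62 for protein, or any matrix
  in NCBI text format via `readSubstitutionMatrix()`. Letters outside the
  matrix (e.g. `N`) match only themselves under unit costs and score as
  mismatches under weighted scoring; input fidelity is preserved rather
  than expanding ambiguity codes.

## The simulator, and what passing tests do and do not show

`simulateFamily()` emulates the synthetic evaluation protocol of the
method's published assessment: families of ~2,500 bp DNA sequences at 5, 20
or 35% substitution divergence under the Jukes–Cantor model, with insertion
and deletion rates 0.04 and 0.06 relative to a substitution rate of 1,
every leaf randomly rotated and the true rotation recorded. Choices the
protocol leaves open were fixed once: indel lengths follow
1 + Geometric(0.5) capped at 20; substitutions are applied before indels on
each branch; and evolution proceeds along a random bifurcating guide tree
(uniform topology, equal branch lengths scaled so the mean root-to-leaf
substitution probability equals the divergence setting). The guide tree
matters: with independent leaves (a star, available as
`topology = "star"`), all leaves are equidistant in expectation, distance
trees built on the family are arbitrary resolutions of noise, and
tree-stability comparisons are meaningless. The simulator does not emulate
rate heterogeneity across sites, compositional bias, inversions or
duplications — so passing tests demonstrate correct rotation recovery under
idealised sequence evolution, not performance on any particular real
genome family.

Two checks summarise what the pipeline achieves on simulated data. At
divergence 0 (pure rotations of one string) the recovered rotations must
invert the true ones exactly, up to one common shift of the whole family —
tested with maximal refinement (`P = beta/3`). At 5% divergence,
12 × 2,500 bp, the neighbour-joining tree built from full cyclic edit
distances of the refined output equals the tree built from the original,
never-rotated family (relative Robinson–Foulds distance 0 on every seed
tested), and the internal MSA of the refined sequences never has a worse
average pairwise distance than a rotation-unaware progressive alignment of
the same rotated inputs. For the tree comparison the pair matrices are
computed with `refinedE = FALSE`: the refined-pair `e` used inside the
pipeline samples only `3w ≈ 150` characters per pair, which is ample for a
guide tree but too noisy to fix a 12-taxon topology on its own, whereas the
full-length cyclic edit distance — the quantity `M` is defined to
approximate — is cheap under unit costs and topologically stable.

## Numerical choices and degenerate inputs

* Ties break deterministically everywhere: smallest rotation index in the
  rotation searches (profile refinement prefers the propagated rotation
  first), smallest creation-index pair in neighbour joining, and
  diagonal-over-up-over-left in alignment tracebacks.
* `round(x)` in window sizes is "half away from zero" (`floor(x + 0.5)`),
  independent of R's banker's rounding; windows are floored at one
  column/residue so degenerate profiles still refine.
* Offsets of a refined string are mapped back as `r0 + k` for cuts in the
  prefix (`k <= w`) and `r0 - (3w - k)` for cuts in the suffix
  (`k >= 2w`); spacer cuts are skipped.
* A single input sequence passes through with rotation 0 and a warning.
  Sequences shorter than a q-gram, or parameter combinations whose blocks
  undercut `q`, fail with an error naming the offending pair.
* Output files are written to a temporary name and renamed, so a failing
  run never leaves partial output.

## Problem sizes used in the checks

The bundled tests run the worked five-sequence example exactly; oracle
equivalences on 500 random instances each (rotation scan up to length 48,
edit distance up to length 300 against `utils::adist`, alignment scores
against `Biostrings::pairwiseAlignment`); and the simulation studies at
12 × 2,500 bp across five seeds for tree stability plus two seeds each for
rotation recovery and AVPD, sizes chosen so the whole suite completes in a
few minutes on one CPU. The published evaluation used the same per-dataset
scale (12–50 sequences × 2,500 bp) but external MSA programs and
maximum-likelihood trees for the final comparisons; those absolute table
values depend on the external tools' versions and are out of scope here.

## Known limitations

* The rotation search is a heuristic: blockwise q-gram locality can lock
  onto the wrong optimum when `beta = 1` (no locality) or when repeats
  dominate the sequence ends that the refinement samples.
* Refinement never moves a rotation further than `w` from the blockwise
  optimum, by construction; a grossly wrong Stage-1 rotation is not
  recoverable in Stage 3.
* The literal linear-gap profile scoring weights column similarity by raw
  frequency products while gap columns cost a constant, so gap placement
  in large profiles is driven mainly by the frequency term; the affine
  mode moderates but does not remove this.
* Branch lengths of the guide tree are neighbour-joining estimates on
  refined-pair distances; they order the merges and are exported for
  inspection, but are not calibrated phylogenetic estimates.
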