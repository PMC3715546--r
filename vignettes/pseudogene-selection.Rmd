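---
title: "Detecting gene loss and relaxed selection in coding sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene loss and relaxed selection in coding sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonLoss)
```

## The problem

When a gene stops contributing to fitness -- as visual-perception genes
appear to do in bats whose sophisticated laryngeal echolocation reduces
their reliance on vision -- purifying selection on its protein sequence
relaxes, and the gene decays into a pseudogene: frameshifting and in-frame
insertions and deletions accumulate, and premature stop codons truncate
the reading frame. Three questions follow for a gene sequenced across a
clade:

1. **Which sequences are broken?** Each sequence is compared against a
   functional reference that defines the codon reading frame, and every
   ORF-disrupting event is catalogued.
2. **How many times was the gene lost?** A disruption shared by several
   species at the same position, with the same length, is evidence of a
   single loss in their common ancestor; disjoint disruption sets point to
   independent losses.
3. **Is the molecular signature consistent with relaxed selection?**
   Branch models of codon evolution compare the nonsynonymous/synonymous
   rate ratio omega (dN/dS) on the lineages carrying the broken gene
   against the rest of the tree.

`codonLoss` implements all three stages plus a simulator that generates
codon alignments with known branch-specific omega and planted loss events,
so that every stage can be validated against ground truth.

## Disruption scanning

`buildFrameMap()` anchors every alignment column to a 1-based coordinate
on the reference coding sequence; all reported positions use this
coordinate system (alignment columns are never exposed). `scanIndels()`
reports each maximal run of query gaps opposite reference bases as one
deletion and each maximal run of reference gaps opposite query bases as
one insertion, flagged frameshifting when the length is not a multiple of
three.

Two conventions deserve explanation:

* **Indel positions.** A deletion is reported at the first deleted
  reference base, an insertion at the last mapped reference coordinate
  preceding the inserted block. This makes a statement like "a 17-bp
  deletion at position 979" reproducible: the event spans reference
  coordinates 979-995.
* **Terminal truncations are not disruptions.** Sequenced fragments of a
  gene routinely miss their ends for reasons of PCR design, not gene
  death, so leading and trailing gap runs are excluded.

`scanPrematureStops()` defaults to the query's *running* reading frame:
translation starts in phase with the reference at the first aligned
position and thereafter follows the query's own residues, so a
frameshifting indel shifts the frame exactly as a ribosome would
experience it. This is the biologically meaningful reading for a
pseudogene and matches how annotated pseudogene alignments highlight stop
codons. A `frame = "reference"` mode instead reads only query codons
aligned to complete reference codons; it is insensitive to frameshifts and
is the mode under which planted simulation truth is recovered exactly (a
frameshifted sequence genuinely contains chance stop codons downstream of
the shift -- the running-frame scanner is right to report them, but they
are not planted records, so exact-recovery checks use the reference
frame). Codons containing `N` are never called: a disruption is not
evidence if it rests on ambiguity. The stop set is the universal nuclear
one, `TAA/TAG/TGA`.

`classifyFunctional()` calls a sequence nonfunctional if and only if it
carries at least one disruption. `stripDisruptions()` then produces the
alignment used for model fitting: reference-gap columns are removed,
codon columns containing any gap are dropped whole (a conservative,
reproducible alternative to manual realignment, whose exact behaviour the
original manual protocols leave unstated), the reference's terminal stop
codon is removed, and any residual stop codon is replaced by `NNN`
(missing data). The result is in frame and stop-free, as the codon model
requires. `maskRegion()` removes a reference-coordinate interval before
analysis -- used for hypervariable regions that would otherwise distort
omega estimates; the interval is a configuration input because published
region boundaries are typically given graphically, not numerically.

## Loss events on the species tree

`collectShared()` groups records by the exact key (kind, reference
position, length). Exact equality is deliberate: treating nearby but
unequal indels as homologous would manufacture shared ancestry. A
position tolerance exists (`tol`) but defaults to 0. Premature stops
participate in sharing exactly like indels -- both are heritable markers
of the same dead gene.

`inferLossEvents()` applies a Dollo reading: a gene, once lost, is not
regained. Each shared key proposes a loss on the stem branch of the most
recent common ancestor of its carriers. The proposal is accepted only
when every tip of that clade is nonfunctional and all of them share at
least one key; a key whose carrier clade contains functional tips is
reported as a *conflict* (it cannot be a single ancestral loss). Each
nonfunctional tip is then assigned to the most ancestral accepted clade
containing it, and uncovered tips become terminal-branch events. Because
accepted clades form a nested family, this assignment yields the minimum
number of independent events consistent with the evidence; the test suite
verifies minimality against an exhaustive search on trees of up to 12
tips.

## Branch models of codon evolution

The substitution model is the standard Goldman-Yang codon model on the 61
sense codons: the instantaneous rate from codon *i* to *j* is zero unless
they differ at exactly one position, and otherwise proportional to the
target codon frequency, multiplied by kappa for transitions and by omega
for nonsynonymous changes. The matrix is scaled so one unit of branch
length is one expected substitution per codon at stationarity.
`buildRateMatrix()` exposes this construction; the fitting kernel (C++,
via symmetric eigendecomposition of the reversible generator) is verified
against an independent matrix exponential and against brute-force
enumeration of the likelihood on small trees.

Three models are fitted by `fitBranchModel()` / `runBattery()`:

| model | free omega parameters | role |
|---|---|---|
| A `one_ratio` | one shared omega | null: no shift on the foreground |
| B `two_ratio_free` | background + foreground omega | alternative |
| C `two_ratio_fixed1` | background omega, foreground fixed at 1 | pure relaxation |

Every model also estimates kappa (one per dataset) and all branch lengths
of the rooted topology (2n-2 for n tips), so the free-parameter counts
are 2n, 2n+1 and 2n for A, B, C -- `npBranchModel()`. Codon frequencies
are empirical and not counted, following standard practice; the default
scheme is F3x4 (position-specific nucleotide frequencies), with F1x4 and
equal frequencies available. Gaps and N in the cleaned alignment are
per-sequence missing data, not reasons to delete a site.

Comparisons use chi-square likelihood-ratio tests with df = 1
(`lrTest()`). No boundary correction is applied for the omega = 1
constraint in C-vs-B, and no multiple-testing adjustment is made by
default, matching the conventional branch-model protocol this package
reproduces; a statistic that comes out negative by less than 1e-6 is
clipped to zero, anything worse raises a convergence warning. Displayed
p-values are rounded to three decimals with a `<0.001` floor
(`formatP()`); the underlying numbers are kept in full precision.

**Pruning.** Before testing a foreground lineage, every *other*
nonfunctional species is removed (`pruneDataset()`): a second dead
lineage left in the background would drag the background omega upward and
blunt the contrast the test is about. Pruning below four species is
refused.

**Optimization.** Likelihood is maximized by bounded quasi-Newton
(L-BFGS-B) on log-transformed parameters, with multiple omega starting
values (default 0.05, 0.5, 1.5) because the omega surface can be
multimodal near 0 and 1, and a convergence tolerance of about 1e-8 on the
log-likelihood (`factr = 1e7`). Branch lengths start from the input tree
when present, otherwise at 0.1 substitutions/codon. Interpretation of the
battery: "relaxed selection" when B-vs-A is significant but C-vs-B is not
(the foreground omega is elevated and statistically indistinguishable
from 1); "purifying" when C-vs-B is significant with a foreground
estimate below 1.

## The simulator and what it does (and does not) emulate

`simulateAlignment()` draws root codons from the equilibrium frequencies
and evolves them branch by branch by sampling from the exact transition
matrix exp(Qt) per site -- there is no approximation in the substitution
process, and a Gillespie event-by-event mode exists purely to validate
the matrix sampler. Substitution never produces a stop codon (the state
space is the 61 sense codons). A functional reference row is simulated as
a short sister branch from the root under the background omega, standing
in for the out-of-clade functional reference a real analysis would use.

`plantPseudogenization()` then overlays gene death on designated loss
branches: indels with geometric lengths (default parameter 0.15, mean
about 6.7 bp, roughly a quarter of events 10 bp or longer -- long enough
to exercise the scanner on 17-bp-scale deletions), a configurable
frameshift fraction (default 2/3, the neutral expectation), deletions
favoured 7:3 over insertions, and per-codon premature-stop conversions
(default 0.02). Every loss branch receives at least one disruption, and
each branch's events are drawn once and copied to all descendant tips, so
planted keys are shared by descent by exactly the tips below the branch.
Events are kept non-overlapping, separated by at least two reference
bases and away from the sequence ends, which is what makes exact
scanner recovery provable rather than merely likely.

Defaults for the evolutionary regime are background omega 0.2 (mammalian
nuclear genes under purifying selection typically estimate 0.1-0.3),
foreground omega 1 (full relaxation), kappa 2. The validation suite uses
background 0.16 / foreground 0.73 and 500 codons for parameter-recovery
checks -- the regime estimated for the rhinolophid visual-gene dataset --
and 6-12 tip trees with 120-200 codons elsewhere; these sizes give
stable answers at desk scale while keeping the full suite to a few
minutes.

What the simulator does *not* emulate: realistic indel evolution (no
TKF-style birth-death of residues; planted indels are decay events, not
background turnover), alignment error (sequences are generated aligned,
so scanner tests carry no realignment noise -- real data will), sequencing
artifacts, rate variation among sites, and paralogy. Passing the
round-trip tests therefore demonstrates the correctness of the
bookkeeping and inference logic, not robustness to alignment error or
model misspecification in real data.

## Validation summary

The test suite checks, among others: detailed balance of the rate matrix
over random parameter draws; agreement of the pruning likelihood with
brute-force enumeration over all internal-node codon assignments on 2-4
tip trees (1e-8); likelihood invariance under rerooting; recovery of
planted disruptions with 100% precision and recall in reference-frame
scanning; exact recovery of planted loss branches across 50 random
simulate-plant-scan-infer round trips; median-unbiased recovery of the
foreground omega (20 replicates of 500 codons); approximate uniformity of
the B-vs-A p-value under the null (200 replicates, Kolmogorov-Smirnov at
1%); and reproduction of the published worked examples (LRT p-values from
printed log-likelihoods, parameter counts, pruned dataset sizes) shipped
as reference tables in `extdata`. `scripts/acceptance.R` recomputes the
headline numbers from scratch.

## Known limitations

* The scanner trusts the input alignment; a misaligned indel moves the
  reported coordinate. The original analyses this package systematizes
  involved manual alignment curation, which is out of scope here.
* Column-wise codon dropping in `stripDisruptions()` discards some
  information relative to per-sequence removal followed by realignment;
  it is used because it is deterministic and reproducible.
* The Dollo loss mapper is a parsimony argument, not a probabilistic
  reconstruction: it reports the minimum number of events consistent with
  exact key sharing and flags conflicts, nothing stronger.
* Site-heterogeneous models (gamma rate variation, branch-site positive
  selection) are out of scope; the engine covers the three branch models
  above.
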