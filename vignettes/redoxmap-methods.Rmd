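---
title: "Methods: conserved-cysteine mapping, redox classification and engagement scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved-cysteine mapping, redox classification and engagement scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxmap)
```

`redoxmap` chains four analyses: cross-species mapping of cysteines,
classification of their in-vivo oxidation dynamics, functional annotation,
and covalent-ligand engagement scoring. This vignette is the package's
account of the underlying models, the tunable parameters, the numerical
choices, and what the synthetic-data tests do and do not establish.

## Conservation mapping

The unit of mapping is a mouse/human ortholog pair sharing a record
identifier. Pairs are aligned with a deterministic Needleman–Wunsch /
Gotoh dynamic program under an affine gap model in which a gap of length
$k$ costs $g_{open} + k\,g_{ext}$ (defaults: BLOSUM62, $g_{open} = 11$,
$g_{ext} = 1$ — the standard BLOSUM62 pairing). Pairwise alignment is used
rather than multiple alignment because the mapping unit is a pair; an
import path for externally produced aligned FASTA (`as_alignment()`)
allows parity runs against another engine.

Numerical choices worth stating:

* **Optimality.** The score is the exact affine-gap optimum; the test
  suite verifies it against exhaustive enumeration of all global
  alignments on short sequences and against an independent implementation
  (`Biostrings::pairwiseAlignment`) on longer random pairs.
* **Tie-breaking.** Many alignments can share the optimal score. The
  traceback prefers, at every cell, a diagonal step over a gap in the
  second sequence over a gap in the first, so the emitted alignment is a
  deterministic function of the inputs. The score is unique regardless.
* **Terminal gaps** are penalised like internal gaps by default — the
  simplest contract for full-length ortholog pairs of similar length. A
  `free_end_gaps` flag provides the semi-global variant for fragmentary
  inputs.
* **Coordinates** are 1-based residue indices throughout (UniProt
  convention, as in "Cys102"), and `project_position()` maps indices
  across the alignment, returning `NA` at gap columns. Projection is an
  involution on non-gap positions, which the tests check by round-trip.

A *conserved cysteine* is an alignment column carrying Cys in both
species. A Cys aligned to a gap or to any other residue yields no record
— conservative by construction: we only map sites whose homology is
positionally supported.

## Redox dynamics

The oxidation input is a long table of per-replicate percent oxidation
(site × condition × replicate), conditions being opaque tissue-by-age
labels. For each site:

$$\Delta = \max_c \bar{x}_c - \min_c \bar{x}_c,$$

where $\bar{x}_c$ is the replicate mean in condition $c$. Because the
comparison is between means, the maximum pairwise difference between any
two conditions equals this max-minus-min closed form; the tests assert the
equivalence against a brute-force pairwise oracle.

Classification: **dynamic** iff $\Delta >$ threshold (default 10
percentage points) *strictly* — a site never exceeding a 10-point
difference is stable, so $\Delta = 10.0$ exactly is stable. Sites observed
in fewer than two conditions are **unclassified**, not stable: absence of
a second condition is absence of evidence. The threshold is a parameter
everywhere (`threshold`), with the limits behaving as expected (0 ⇒
everything with any spread is dynamic; 100 ⇒ nothing is).

Two open design points were settled as follows. Tissue-by-age composites
are kept as separate conditions by default (up to 20 conditions for 10
tissues × 2 ages); `collapse_ages = TRUE` averages ages within a tissue
first, for sensitivity analyses. "Top" dynamic sites are ranked by delta
descending — the natural one-number ordering — with ties broken
lexicographically by (protein, position) so rankings are reproducible.

## Annotation

Domain intervals are 1-based inclusive on the human sequence (Pfam
convention); containment is `start ≤ position ≤ end`. Protein-class
membership is a named list of identifier sets; a protein may carry several
tags. The compendium is an **inner** join of conserved cysteines with
redox profiles on the mouse site — sites without oxidation data are
excluded, mirroring the restriction of the analysis to mapped cysteines —
with an audit mode listing the dropped sites. Headline counts
(conserved ≥ dynamic ≥ dynamic-on-domain) are attached to every build.
Structure identifiers are opaque strings; no structure parsing is done.

## Engagement scoring

For a cysteine site in a competition screen, the engagement ratio is
$R = \mathrm{S/N}_{vehicle} / \mathrm{S/N}_{treated}$, computed per
replicate with vehicle and treated channels paired by replicate index
(same multiplex). Percent engagement is derived as

$$E = 100\,(1 - 1/R), \qquad \text{clipped to } [0, 100].$$

The rationale: a ligand occupying fraction $f$ of a site blocks the
labeling tag on that fraction, leaving treated signal $(1-f)$ of vehicle,
so $R = 1/(1-f)$ and $f = 1 - 1/R$. This competition-ratio stoichiometry
conversion is the package's convention; clipping at 0 absorbs apparent
negative engagement from replicate noise.

Practical rules: S/N values below a floor (default 1) are raised to it
before ratioing to prevent division blow-ups, and a site whose *vehicle*
signal sits at the floor is marked unquantified and excluded from hit
calling. A site is *reproducible* at a dose when $E \ge$ cutoff (default
50%) in at least $\lceil 2n/3 \rceil$ of $n$ replicates, and a *hit* when
reproducible at any tested dose; the per-dose table is always emitted so a
stricter caller can re-filter. Hit calling is threshold-based, not a
p-value procedure; instead of multiple-testing correction the null
false-hit rate is estimated by simulation on a target-free screen and
reported per run. Dose dependence is summarised by Spearman concordance
between dose and median engagement, with "monotone" meaning no backward
step larger than 5 percentage points (tolerance parameter).

## The synthetic-data generator

The generator produces every input with planted truth, under the
conditions the analyses assume:

* **Ortholog pairs**: a mouse sequence with planted conserved cysteines
  (protected from mutation and indels), a human sequence derived by
  substituting an exact count of mutable positions — so realised core
  identity is deterministic — plus species-specific cysteines and
  insertions/deletions at a per-site rate. Defaults used by the standard
  configuration: length 120, identity 0.85, 4 conserved + 1
  species-specific Cys, indel rate 0.02.
* **Oxidation tables**: stable sites have identical true means in every
  condition; dynamic sites draw a delta uniformly from (15, 40) percent
  with the two extremes pinned so the planted delta is exact. Observations
  add Gaussian noise (default s.d. 2 percentage points, 5 replicates, 20
  conditions) and clip to [0, 100]. The delta range must clear the
  classification threshold, otherwise the generator refuses: a planted
  signal below threshold would be undetectable by construction.
* **Screens**: per-site lognormal S/N baselines (median 100); vehicle and
  treated channels multiply the baseline by lognormal noise with unit mean
  and coefficient of variation `cv` (default 0.1, 3 replicates); the
  single planted target's treated channel is additionally scaled by
  $1 - f_d$ at each dose $d$, with $f$ non-decreasing in dose (default
  20/35/50/65% at 5/10/20/40 µM). Engagement of 100% is rejected since
  treated signal would vanish.

Noise magnitudes for the real resources are not published, so the
defaults above are the package's calibration choices, exposed in the
configuration. Seeding is per-table: substreams derive deterministically
from one master seed by stream name, so adding a generator call does not
perturb earlier tables, and same-seed runs are byte-identical (output
headers deliberately carry no timestamp).

What passing the synthetic tests shows — and does not. The generator
emulates the *statistical shape* the methods assume: homologous cores
with point substitutions and sparse indels, condition-mean structure with
i.i.d. Gaussian replicate noise, multiplicative TMT noise with one engaged
site. It does not emulate alignment-ambiguous repeats or paralogy,
tissue-correlated or heteroscedastic oxidation noise, missing values,
peptide-to-site rollup artefacts, or reporter-ion interference. Perfect
recovery here therefore validates the pipeline's logic and its
implementation, not its performance on any real resource; headline counts
from the published full-scale resources depend on version-pinned external
databases and are out of scope.

## Problem sizes and determinism

The standard configuration (30 pairs × 120 residues, 120 sites × 20
conditions × 5 replicates, 2,000-site screens × 3 replicates; recovery
summaries over 10–20 seeds) was chosen so a complete run takes seconds
and the whole verification suite minutes on a single core, while keeping
every estimate's sampling error far from the decision boundaries. All
entry points take explicit seeds; `run_pipeline()` echoes its full
configuration and a config hash into the run directory so any table can
be traced to the exact parameters that produced it.

## Known limitations

* Pairwise-only alignment: no multiple-sequence alignment, isoform
  disambiguation or paralog assignment; inputs arrive pre-paired by
  identifier.
* Conservation calls inherit alignment ambiguity: where an indel sits next
  to a cysteine-rich stretch, a shifted mapping can score as well as or
  better than the homologous one, and the (deterministic) optimum then
  mis-pairs a cysteine. At 80% identity and 2% indel rate this affects
  well under 1% of synthetic pairs; it is a property of score-optimal
  alignment, not of the implementation.
* The stable/dynamic call is a fixed-threshold rule on condition means,
  not a statistical test; no imputation of missing conditions.
* The engagement-to-stoichiometry conversion assumes pure competition at
  a single site; allosteric changes in labeling efficiency would bias it.
* Real-data mode expects tables in the documented TSV schemas; upstream
  mass-spectrometry processing is entirely out of scope.
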