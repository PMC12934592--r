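# redoxmap

Tools for discovering functionally relevant, redox-regulated cysteines on
proteins, and for scoring covalent-ligand engagement of those cysteines in
competition chemoproteomics screens.

Protein cysteines carry reversible oxidative modifications whose level
(*oxidation stoichiometry*, 0–100%) varies across tissues and
physiological states. A cysteine whose oxidation swings widely in vivo is
a candidate regulatory — and druggable — site. `redoxmap` implements the
desk-scale analysis chain for finding such sites:

1. **Cross-species conservation.** Mouse/human ortholog pairs are globally
   aligned (Needleman–Wunsch with affine gaps, BLOSUM62, gap open 11 /
   extend 1, deterministic traceback) and mouse cysteine positions are
   projected onto the human sequence; a *conserved cysteine* is a Cys/Cys
   alignment column.
2. **Redox dynamics.** For each site, per-condition mean oxidation is
   computed over replicates and the **delta** statistic is
   `max(condition means) − min(condition means)`. A site is **dynamic**
   when delta strictly exceeds 10 percentage points (i.e. it shows more
   than 10% difference between some two tissue conditions), **stable**
   otherwise, and *unclassified* with fewer than two conditions.
3. **Annotation.** Dynamic and stable conserved cysteines are joined to
   domain intervals (Pfam-style, 1-based inclusive), protein-class
   membership lists (kinase, phosphatase, transcription factor, metabolic
   enzyme) and structure identifiers, yielding a compendium table with
   headline counts (conserved / dynamic / dynamic-on-domain).
4. **Engagement scoring.** From TMT signal-to-noise tables of a covalent
   ligand competition screen, the per-replicate competition ratio is

   `R = S/N(vehicle) / S/N(treated)`,   percent engagement = `100·(1 − 1/R)`

   (clipped to [0, 100]; S/N floored at 1). A site is a **hit** when its
   engagement reaches the 50% cutoff in at least ⌈2n/3⌉ replicates at some
   dose; selectivity ranks the target against the rest of the cysteine
   proteome, and dose–response monotonicity is checked by rank
   concordance.

A synthetic-data module generates every input with planted ground truth
(conserved positions, dynamic sites, engaged site and stoichiometry), so
each stage is verifiable without external downloads.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
standard synthetic configuration (30 ortholog pairs, 20 tissue-by-age
conditions × 5 replicates, a 2,000-site screen with SHP1 Cys102 planted at
20/35/50/65% stoichiometry over 5–40 µM):

```sh
Rscript analysis/01_simulate.R       # inputs + truth -> results/sim/
Rscript analysis/02_align_map.R      # conserved cysteines
Rscript analysis/03_classify_redox.R # delta + stable/dynamic classes
Rscript analysis/04_annotate.R       # compendium + headline counts
Rscript analysis/05_engagement.R     # screen scoring + selectivity
```

Output actually printed by these runs:

```
called 120 conserved cysteines across 30 pairs
recovery vs planted truth (Jaccard): 1.0000 (120 planted)
profiled 120 sites over 20 conditions: 12 dynamic, 108 stable
dynamic-site sensitivity 1.000, specificity 1.000 vs truth
compendium: 120 conserved cysteines, 12 dynamic (10.0%), 4 dynamic on a domain
screen: 2000 sites scored, 1 reproducible hit(s) at the 50% cutoff
SHP1 Cys102: rank 1, peak engagement 65.1%, 0 off-target(s)
dose response: concentration-dependent (Spearman concordance 1.00):
  5 uM -> 16.9%, 10 uM -> 43.0%, 20 uM -> 51.2%, 40 uM -> 65.1%
null screen: 0 false hit(s) in 2000 sites
```

Read: every planted conserved cysteine was re-identified from sequence
alone; classification recovered the planted dynamic sites perfectly at
this noise level (2 percentage points s.d., 5 replicates); the planted
target is the screen's unique reproducible hit, its estimated engagement
tracks the planted stoichiometry with dose, and a matched screen with no
planted target produces no hits.

The same run is available as a single call:

```r
library(redoxmap)
res <- run_pipeline(default_config(seed = 1407), "my_run")
res$recovery
```

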