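---
title: "Methods: motif-architecture mapping of a protease degradome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-architecture mapping of a protease degradome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degradome)
```

## The model

A protease family's catalytic machinery is usually visible as a short
ordered set of linear motifs: the aspartic-protease psi-loops `DTG` and
`D(T/S)G`, the subtilisin dyad-bearing pair `D(D/T)G` and
`GXSXX(T/S/G)`, the zincin zinc site `HEXXH`, and so on. This package
models a family as an **architecture rule**: an ordered list of motif
components, each with a role (`catalytic`, `metal-binding`, `turn`,
`accessory`), bound to a MEROPS-style subfamily, clan, catalytic class,
EC sub-subfamily bucket and (for metallopeptidases) a tribe. A protein is
classified by finding the rule whose catalytic components it realizes
best; its **activity** follows from which catalytic components are
present.

### Motif notation

`parse_motif()` accepts the compact notation used in the protease
literature:

| token          | meaning                                                 |
|----------------|---------------------------------------------------------|
| `H`            | fixed residue                                           |
| `X`            | wildcard (any of the 20 standard residues)              |
| `(T/S/G)`      | alternation at one position                             |
| `NEXXT/A`      | trailing alternation binding to the previous position   |
| `X_6`          | spacer of exactly 6 residues                            |
| `X_3-8_`       | spacer of 3 to 8 residues                               |
| `X_n_`         | open spacer, bounded by `xn_max` (default 100)          |

Parsing round-trips: `render_motif()` produces a canonical form whose
re-parse is element-wise identical. Sequences are normalized to upper
case; `*` and `-` are stripped with a warning; the non-standard codes
B, J, O, U, Z, X in a *sequence* satisfy wildcard positions only.

### Scanning semantics

`scan_motif()` reports matches at every feasible start position, 1-based
and inclusive. For gapped patterns each start yields at most one match:
the one whose gap-length vector is lexicographically minimal (earlier
gaps shortened first), i.e. the leftmost-shortest match. This is
implemented by compiling the pattern to a lazily-quantified regular
expression anchored at each candidate start, and is verified in the test
suite against an independent brute-force enumerator over all windows and
gap assignments (1,000 random cases with total gap span up to 12 and
sequences up to 300 residues). Two useful consequences: scanning is
deterministic, and widening a gap's upper bound never removes a reported
match start.

`match_architecture()` assigns an ordered list of components greedily:
each component is matched at its earliest feasible position after the end
of the previously *matched* component. Components that cannot be placed
are recorded as absent; later components continue from the last matched
position, so partial architectures are reported faithfully, and matches
never overlap or reorder.

### Classification and ties

`classify_sequence()` evaluates every motif-bearing rule and ranks
candidates by (1) number of catalytic-role components matched,
(2) **specificity** — the total number of non-wildcard residue positions
across matched components — and (3) catalogue order, with classes
ordered aspartic, glutamic, threonine, cysteine, serine, metallo. The
literature gives no explicit ambiguity-resolution rule, so the tie-break
is deterministic and documented; a cross-class tie at equal catalytic
count and specificity is additionally flagged `ambiguous`.

Activity calls follow the presence/absence rule:

* **active** — all catalytic components of the best rule matched
  (accessory and turn motifs are listed but not required; set
  `require_accessory = TRUE` to demand them);
* **putatively-inactive** — at least one but not all catalytic
  components matched;
* **non-peptidase-homologue** — homology evidence asserts a family whose
  catalytic *and* metal-binding components are all demonstrably absent;
* **unclassified** — no motif and no homology evidence, or the sequence
  is shorter than `min_length` (20 residues, configurable).

For *motif-free* families (e.g. the glutamic G1 family or the
proteasome β-subunits T1A, whose catalytic threonine is the processed
N-terminus and has no consensus linear context), absence of a motif
cannot demonstrate anything, so homology evidence assigns the family
directly rather than producing a non-peptidase call.

### Metallopeptidase tribes

`assign_tribe()` re-derives the tribe of each metallopeptidase family
from its compiled architecture, in this order: AAA fold context (M41,
whose generic `HEXXH` would otherwise read as a gluzincin); extended
three-His zincin motifs (`H(Q/E)XXHXXGXXH/D`, `HEXXHXX(H/F)XXH`) →
metzincin; short `HEXXH`/`HEXXXH` zincin *with a downstream glutamate
ligand in another component* → gluzincin; inverted `HXXEH` → inverzincin;
the four-residue `HXXE` funnel motif → funnelin; the co-catalytic
`(S/G/A)HXDXV…` arrangement → αβα-exopeptidase (aminoacylase-1 branch);
adjacent `EE` ligands → αβα-exopeptidase (EEM2 branch); otherwise
unassigned (e.g. M76's bare `HEXXH` with no glutamate ligand). The test
suite checks that this routing reproduces the stored tribe label of all
35 metallopeptidase rules.

## The packaged catalogue

The package ships a 71-rule catalogue (`inst/extdata/aniger_rules.yaml`,
versioned structured text documented in its header) and a 232-record
inventory (`inst/extdata/aniger_inventory.tsv`) for the two sequenced
*A. niger* strains. `validate_inventory()` recomputes every expected
marginal — gene models, clans, subfamilies, unassigned, inactive,
secreted and characterized counts per class — and reports cell-by-cell
agreement. Two rows of the manifest (new members and new active sites)
compare against an earlier genome annotation that is not part of the
records, so they are carried as data and marked non-recomputable.

Two bookkeeping conventions for clans are computed side by side:
the headline count (26) counts annotated clans plus one *non-classified*
clan for a class hosting a family without clan assignment; the pooled
variant additionally counts an unassigned pseudo-clan for every class
with records of unknown family. Subfamily counts (71) exclude unassigned
records (14 across all classes).

```{r validate}
cat1 <- load_catalogue()
validate_inventory(cat1$records, cat1$manifest)
```

## Secretome vote and EC buckets

`consensus_vote()` implements a strict majority: secreted iff
secreted-calls / non-missing-calls > threshold (default 0.5, so a 3–3
split among six predictors is conservatively non-secreted;
`other-compartment` counts as non-secreted). Fewer than four non-missing
calls yield `undetermined`. The vote is symmetric under predictor
relabeling and row order, and raising the threshold can only remove
secreted calls, never add them.

EC sub-subfamily buckets split into exopeptidase sides (3.4.11, .13,
.14, .16, .17, .19), endopeptidase sides (3.4.21, .22, .23, .24, .25,
.99), and unknown. Records carry a per-locus bucket (which resolves
families hosting both exo- and endopeptidases); classification results
fall back to the family-level default.

## Numerical conventions

Percentages are rounded **half-up** (`percentage(1, 16, 1)` is 6.3, where
banker's rounding would give 6.2), at 1 decimal for composition shares
and 2 decimals for genome-coverage fractions, matching printed precision.
The genome size defaults to 14,165 protein-coding gene models and is
configurable.

## Synthetic data: design and limits

`generate_degradome()` plants exactly one family architecture per
protein: every component of the rule is instantiated (one residue per
wildcard/alternation, one length per spacer), components are joined in
order by 2–15-residue random linkers, and 30–80-residue flanks are drawn
from the background composition (uniform by default, configurable).
Knockouts replace one catalytic-role residue with a residue *outside*
that position's residue set.

A literal rejection of "any accidental full match of another rule" does
not terminate: several catalogue motifs are so short (`EE`,
`QXXXXXC`) that almost every random flank completes them. The generator
therefore rejects a candidate when **classification would not recover the
planted family and expected activity** — the property the ground truth
actually requires — with a cap of 100 retries per record, and raises an
error beyond that (an over-permissive rule). This makes the generated
truth identifiable by construction, which is what the recovery
experiments measure.

The default family mix (A1A, S8A, S53, A22B, S54) deliberately uses
families with **at least two catalytic components**: a single-residue
knockout then leaves residual catalytic evidence, so the record remains
attributable to its family and is called putatively-inactive — the
behaviour the knockout experiments assert. Families whose rule has a
single catalytic component lose all catalytic evidence under knockout
and cannot support that inference; motif-free families cannot be planted
at all and are rejected at configuration time.

Predictor calls flip from the true localization independently with the
configured error rate. At error rate $p$ and strict majority over six
predictors, the consensus accuracy has the closed binomial form
implemented in `majority_vote_accuracy()`:
$q\,P(\mathrm{Bin}(6, 1-p) \ge 4) + (1-q)\,P(\mathrm{Bin}(6, p) \le 3)$
with secretion prior $q$. The acceptance checks require the empirical
accuracy at $n = 1000$ to fall within three standard errors of this
value for $p \in \{0.1, 0.3, 0.5\}$.

Everything is a deterministic function of the configuration (including
its mandatory seed): regenerating with the same configuration writes
byte-identical FASTA and call tables. The generator makes no attempt to
mimic real *A. niger* residue composition, paralogy or gene structure —
it provides ground truth for the classifier's assumptions, not a
sequence-evolution model.

```{r recovery}
rec <- recovery_experiment(simulation_config(25, seed = 42), cat1)
c(family = rec$family_accuracy, activity = rec$activity_accuracy,
  secretion = rec$secretion_accuracy)
```

## Problem sizes and runtime

All computations are desk-scale: the packaged inventory has 232 records
and 71 rules; classification of a few hundred synthetic proteins takes
seconds; the full acceptance script (1,000 scanner oracle cases, a
100-record noiseless recovery, a 40-record knockout run, and three
1,000-record vote experiments) runs in a few minutes on one CPU with no
network access.

## Limitations

* Classification is purely motif-based: no sequence similarity,
  E-values, domain databases or phylogenetics. Families without linear
  consensus motifs are reachable only through supplied homology
  evidence.
* The catalogue encodes one archetypal architecture per subfamily;
  genuine within-family architectural variation collapses onto the
  closest rule.
* The greedy leftmost architecture matcher can miss contrived
  arrangements where a later placement of an early component would allow
  more components to fit; for the catalogue's well-separated motifs this
  does not arise in practice.
* The localization consensus consumes predictor calls as data; it does
  not model the predictors themselves.
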