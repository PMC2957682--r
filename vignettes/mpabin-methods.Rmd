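---
title: "Binning metagenomic reads by most probable ancestors: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binning metagenomic reads by most probable ancestors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpabin)
```

## The problem

A metagenomic sample yields reads from many organisms, most of which are
not in any reference database. Similarity-based binning compares each
read against a protein database and infers a source taxon from the hits.
The classical conservative answer — the lowest common ancestor (LCA) of
all significant hits — is safe but unspecific: a single spurious hit in a
distant clade drags the assignment to the phylum or higher. Conversely,
trusting the best hit alone is precise but frequently wrong when the true
source organism is absent from the database, because the best hit then
comes from whichever relative happens to be sequenced.

`mpabin` navigates this trade-off with three mechanisms, applied per
read: a quality-dependent ceiling on assignment depth, a scored choice
among the LCAs of hit prefixes, and a population-based reclassification
of sparse bins.

## Taxonomic-level restriction

The best valid hit's identity fraction and (when the input provides it)
positives fraction, both computed against the full alignment length
including gap columns, determine the *taxonomic level* (TL): the deepest
canonical rank at which the read may be assigned. All hit taxa are then
substituted by their ancestors at the TL before anything else happens, so
every later step operates at or above the TL by construction.

The rule table maps quality to rank, first match wins:

```{r}
default_tl_config()
```

These thresholds are calibration constants shipped with the package; the
two-phase binners this design follows do not publish their exact
cut-offs, so ours are chosen to be monotone (better alignments never give
a shallower rank — a property the test suite checks over randomized
inputs) and are fully overridable via `tl_config()` or the CLI's
`--tl-config`. With plain 12-column tabular input there is no positives
count and the identity thresholds decide alone. A lineage that lacks the
TL rank (common around non-canonical nodes) substitutes the nearest
canonical ancestor shallower than the TL, which preserves the "at TL or
above" contract.

## Candidate ancestors and the ratio score

For a read with three or more valid hits, the hits are ordered by
descending bit score (ties: ascending subject taxid, then input order —
a total order that makes runs reproducible regardless of file row
order). The running LCA of the top two, top three, ... substituted taxa
produces the *candidate ancestors*: a chain in which each new element is
a strict ancestor of the previous one, beginning at the LCA of the top
two taxa and ending at the LCA of all of them.

Each candidate $c$ is scored by

$$ S(c) = \sum_{h} \frac{\mathrm{bits}(h)}{d(c, t_h) + 1} $$

where $t_h$ is hit $h$'s substituted taxon and $d$ counts edges on the
tree path between the two nodes (node levels are raw edge counts from
the root, so non-canonical nodes such as "cellular organisms" or species
groups lengthen paths exactly as they do in the reference taxonomy). The
rationale: bit score falls with evolutionary distance between query and
subject, so bits-per-edge is largest for candidates close to the strong
hits. The read is assigned to the argmax (the *most probable ancestor*);
exact ties go to the deeper candidate, since specificity is the point of
the scoring.

Two numerical choices deserve note:

* **The +1 offset.** The raw ratio is undefined when a hit taxon equals
  the candidate, which happens routinely (the first candidate often *is*
  the substituted best-hit taxon). Offsetting every denominator by one
  edge keeps the score finite while preserving the ordering intent —
  closer still means strictly larger. Because the offset is uniform, it
  never changes which of two hits contributes more to a given candidate.
* **No per-taxon collapsing.** Multiple hits to the same subject taxon
  all contribute; a well-represented organism should pull the assignment
  towards itself.

Reads with exactly one valid hit take its substituted taxon; with two,
the LCA of the pair. Reads whose hits all substitute to one taxon
short-circuit to it (the chain would have length one anyway). A read
with BLAST rows but no valid hit — bit score below 35 or alignment length
of 25 or less, thresholds configurable — is `Unassigned`; a read with no
rows at all is `NoHits`. The two categories are kept distinct throughout
because they answer different questions about the reference database.

## Isolated-taxon reclassification

Misclassified reads concentrate in sparsely populated bins. Rather than
discarding assignments to small bins (the minimum-bin-size strategy,
which inflates the unassigned fraction), taxa whose *direct* read count
falls below the isolated-taxon size — `min(300, ceiling(1% of total
reads))`, floored at one — have their reads promoted along the lineage:
from the immediate parent (non-canonical nodes included) upward, the
first ancestor whose *cumulative* (subtree) count exceeds the threshold
receives them. The walk never passes the superkingdom; assignment *at*
the superkingdom is allowed, and if even it fails the test the reads
become `Unassigned`. The 300 cap exists so that organisms with small
genomes at low coverage — 300 reads of 1000/400/250/100 bp cover a
0.6 Mb genome at 0.5X/0.2X/0.13X/0.05X (`fold_coverage()`) — are not
dissolved into their ancestors in large data sets.

The wording "number of reads assigned" (isolation) versus "cumulative
number of reads" (acceptance) is read literally: isolation uses direct
counts, acceptance uses cumulative counts. Both comparisons are strict
(`<` and `>`). Cumulative counts are computed once on the input table and
frozen for the pass, which makes the result independent of the order in
which isolated taxa are processed; whether counts should update as reads
move is genuinely open, so an `iterate` argument optionally repeats
frozen passes to a fixed point (bounded by the tree depth). The default
is the single deterministic pass. One consequence worth knowing: a pass
can move reads *into* a bin that is itself below threshold, and iterated
passes will then walk those reads further up — the single-pass default
deliberately leaves them at the first populated ancestor.

## Evaluation

Against a truth table, an assignment is **Correct** when the assigned
node lies on the path from the root to the source taxon, **Wrong**
otherwise; `Unassigned`/`NoHits` pass through, and all four percentages
are reported over all reads. Correct assignments are depth-classed:
**Higher** (root, nodes above the superkingdom, superkingdom),
**Intermediate** (phylum, class, order), **Specific** (family and
deeper). Nodes of non-canonical rank take the class of their nearest
canonically ranked ancestor — a species group classes as Specific, a
node above the superkingdom as Higher — because the classes are defined
over canonical ranks while real assignments frequently land between
them.

## The synthetic generator

`scenario_spec()` + `make_taxonomy()` + `make_hit_tables()` generate the
test bed: a balanced taxonomy with all seven canonical ranks (genera
paired into families, families into orders, and so on; every species
leaf at level 7) and, for each simulated read, hits whose expected bit
score decays linearly with the tree distance between the read's source
species and the reference species, plus Gaussian noise, truncated at the
validity threshold. Identity and positives counts are derived from the
score so that stronger hits also look better aligned. The defaults —
300 bits at distance zero, 25 bits per edge, noise sd 10, alignment
length 90 — were fixed once as plausible desk-scale conditions: they
keep cross-family hits (6 edges, ~150 bits) well above the validity
floor while separating hit tiers by several noise standard deviations.

Two aspects are deliberate:

* **Self-hits.** When the source species is present in the reference it
  contributes `self_hits = 2` hits, because a sequenced genome offers
  multiple homologous subjects. This matters structurally: the candidate
  chain starts at the LCA of the top two hits, so with a single self-hit
  no read could ever be assigned back to its exact source species even
  with perfect noiseless alignments. With two, the noiseless known-
  organism scenario recovers the source leaf for 100% of reads — the
  property the acceptance checks exercise.
* **Clade deletion.** The unknown-organism modes drop all reference
  species inside the read's source species, genus or family, emulating
  queries from taxa absent from the database. Best-hit distances then
  shift upward mode by mode (a Monte-Carlo test over >1000 reads per
  mode asserts the ordering), and assignments retreat to shallower —
  but still correct — ranks, which is exactly the behaviour the TL
  restriction is meant to produce.

What the generator does *not* emulate: sequence-level read simulation
(no error models, no length distributions), database composition biases,
horizontal gene transfer, or hit-score heterogeneity along a genome.
Passing tests therefore demonstrate the algorithmic contracts — chain
structure, score arithmetic, conservation, recovery under clade
deletion — not field accuracy on real samples, which depends on the
reference database and aligner.

In the balanced toy taxonomy the plain-LCA baseline is rarely *wrong*
(remaining hits always include on-lineage relatives), so the baseline
comparison there shows the wrong-rate never exceeding the baseline's
rather than a dramatic gap; the specificity advantage of the ratio
scoring is shown directly on the worked example (`example_taxonomy()`),
where engineered off-lineage hits pull the LCA to the phylum while the
MPA stays at the genus.

## Problem sizes and runtime choices

The shipped checks use sizes chosen to finish comfortably on one CPU:
the distance oracle runs on 20 random trees of 20–200 nodes (all node
pairs against breadth-first-search distances from igraph); the chain and
ceiling contracts run on a 10,000-read scenario (10 genera × 4 species ×
250 reads, ~13,000 candidate evaluations); the recovery and baseline
comparisons use 600–750 reads per scenario across five seeds. LCA is
computed by longest-common-prefix over precomputed root paths — at
taxonomy depths below ~40 nothing faster is warranted.

## Known limitations

* Merged or deleted taxids (`merged.dmp`) are not resolved; hits with
  unknown taxids are skipped with a warning.
* The TL defaults are calibration constants, not published values;
  cross-tool parity at the TL stage is not claimed.
* The reclassification threshold treats all taxa alike; rank-dependent
  thresholds are not implemented.
* No attempt is made to parse XML or pairwise BLAST reports, or to run
  the alignment itself.
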