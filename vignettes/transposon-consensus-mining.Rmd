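---
title: "Mining transposon copies and refining a majority-rule consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining transposon copies and refining a majority-rule consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temine)
```

## The problem and the model

Tc1/*mariner* DNA transposons are 1300–2400 bp cut-and-paste elements: a
transposase coding sequence flanked by two inverted terminal repeats
(ITRs) that carry the transposase binding sites. Sleeping Beauty (SB) is a
synthetic element of this family, resurrected as a consensus of fish
sequences; its 1638-nt layout — 227-nt ITRs flanking a 1022-nt transposase
CDS — is the geometry this package models.

A genome that harbours many copies of such an element is an evolutionary
record of the ancestral, presumably functional, sequence. Under a neutral
star-phylogeny model — every genomic copy diverging independently from one
ancestor by random substitution — the per-column majority of an alignment
of all copies estimates the ancestral base. `temine` implements that
estimator end to end: find all copies, align them, call an inclusive 60%
majority consensus, and annotate how the consensus differs from the
reference element, separating changes inside transposase binding regions
(which could alter recognition) from changes outside, and synonymous from
nonsynonymous coding changes.

The majority threshold behaves as follows at a column with base
frequencies $f_A, f_C, f_G, f_T$ and gap frequency $f_-$ (the five symbols
share one denominator, the number of counted rows):

* emit the top base $b$ if $f_b \ge 0.60$ (the threshold is inclusive:
  exactly 60% is a call);
* else emit nothing if $f_- \ge 0.60$ (a deletion column);
* else emit `N` and record the full frequency vector — variable positions
  are first-class results, not noise.

## Pipeline stages and their parameters

1. **Homology search** (`find_hits`). A permissive seed-and-extend search:
   `word_size = 11` seeds sampled every `step = 5` nt of the query, one
   seed mismatch tolerated (`allow_one_mismatch`, implemented as exact
   matching of each seed's full one-mismatch neighborhood). Seeds are
   chained within a diagonal band of ±10% of the query length
   (`xdrop = 0.10`); a chain needs `min_seeds = 4` seed matches before it
   is extended, which suppresses isolated random 11-mer matches while a
   true ≥90%-identity copy of a 1638-nt query still carries hundreds of
   matching seeds. Chains are extended by local alignment with +1/−1
   match/mismatch and a linear −2 gap penalty. Overlapping hits (more than
   half the shorter span, either strand) resolve to the higher score, then
   the leftmost start; the cross-strand rule matters because an element
   with true inverted ITRs always produces a weak mirror-orientation hit
   over every genuine copy. Precomputed hits from an external search tool
   can be substituted as PSL (`psl_in`).
2. **Length filter** (`filter_by_length`). A hit is discarded only when
   its span deviates from the query length by *more than* 10% — the bound
   itself is kept (1475 nt survives a 1638-nt query; 1474 does not). This
   single rule removes CDS-only and other fragmentary matches from the
   full-element search.
3. **Trim search** (`trim_search`). The two-step strategy: search with the
   CDS, then extend every hit 500 nt on each side and keep it only if the
   left ITR is detectable in the query-upstream flank and the right ITR in
   the query-downstream flank. Flank assignment is strand-aware, so
   retention is strand-invariant. Detection thresholds inside flanks are
   not dictated by the procedure's description, so they are explicit
   parameters: `itr_min_identity = 0.75` and `itr_min_coverage = 0.80` —
   loose enough for 90%-identity family members, strict enough that a
   random 227-nt match in a 500-nt flank is essentially impossible. Hits
   whose flank is fully clipped at a chromosome end are dropped: the
   repeat cannot be verified there.
4. **Duplicate removal** (`dedupe_hits`). Among hits whose extracted,
   query-oriented sequences are identical strings, one representative (the
   lowest chromosome/start/strand) is kept.
5. **Alignment** (`align_sequences`). The built-in engine is a
   deterministic center-star progressive aligner anchored on the reference
   (pairwise global alignments with affine gaps, penalties
   `gap_open = 4`, `gap_extend = 1`, a gap of length $k$ costing
   $4 + k$; merged on one gap scaffold). An external MAFFT adapter is
   provided for parity with practice; a missing binary is a loud error,
   never a silent fallback. MAFFT's common guidance pairs the accurate
   L-INS-i mode with *small* sets, and the adapter's default heuristic
   follows that (L-INS-i below 200 sequences, FFT-NS-2 at or above), but
   the mode is always overridable via `mafft_mode` because descriptions of
   the size rule in the literature are ambiguous about which mode goes
   with which side of the 200-sequence line.
6. **Curation** (`curate_alignment`). Manual removal of indel-heavy rows
   is replaced by a reproducible rule: any non-reference row whose gap
   fraction exceeds `max_gap_fraction = 0.10` is dropped and all-gap
   columns are deleted. "A high number of insertions or deletions" needs
   an operational definition for runs to be repeatable; this is it.
7. **Consensus** (`column_frequencies`, `call_consensus`,
   `map_to_reference`). The reference (query) row is excluded from the
   counts by default — the consensus should reflect the genomic copies,
   not the probe — with `include_reference = TRUE` available; with
   hundreds of rows the difference is negligible, but the choice is
   explicit. Gaps count in the denominator as a fifth symbol, making
   "conserved in at least 60% of the sequences" literal. Frequencies are
   reported to 0.1% precision. Consensus columns where the reference has a
   gap become insertion records anchored to the preceding reference
   position; reference positions in deletion columns become deletions.
8. **Annotation** (`diff_consensus`). Every difference is reported with
   its 1-based position *within its feature* (left ITR, CDS, right ITR) —
   the convention used when describing such elements — plus the
   binding-region flag and, in the CDS, the codon effect. Synonymy is
   evaluated one substitution at a time against the reference codon;
   compound same-codon changes are flagged (`ambiguous`) rather than
   combined. Indels in the CDS are frameshifts unless their length is a
   codon multiple. A model without configured binding-region spans yields
   an explicit "unevaluable" (`NA`) flag, never a silent `FALSE`.
9. **Phylogeny** (`pairwise_distances`, `neighbor_joining`,
   `bootstrap_support`). Distances use the Kimura two-parameter correction
   (the equal-frequency simplification of HKY85) with pairwise deletion of
   gap sites, which preserves partially truncated copies; saturated pairs
   raise errors naming the pair. Tree inference is neighbor joining with
   deterministic tie-breaking (lowest index pair) and negative branch
   lengths clamped to zero with the deficit moved to the sister branch
   (path lengths preserved; NJ is exact on additive matrices). Support
   values come from column-resampling bootstrap under a fixed seed.
   Maximum-likelihood inference and aLRT-style supports are deliberately
   out of scope: the tree is interpretive here (is there subfamily
   structure or not), not a quantitative deliverable.

## The synthetic-data generator

`generate_genome()` emulates exactly the situation the pipeline is built
for: an i.i.d. background genome at a chosen GC content into which
`n_copies` descendants of a known ancestor are spliced at uniform,
non-overlapping breakpoints, each reverse-complemented with probability
`strand_prob = 0.5`. Divergence is per-site substitution with probability
`p_sub`, transitions weighted `kappa = 2` against each transversion,
optional geometric indels, optional truncation, and optional ITR-less CDS
decoys — the "homologous transposase gene" confounder that motivates the
trim search. Defaults (2-Mb genome, 50 copies, `p_sub = 0.03`, 10 decoys)
are the package's reference study conditions: 3% divergence sits in the
90–97% identity band typical of a young, still-recognisable transposon
family, 50 copies is enough for a stable 60% majority at every site with
near certainty, and 2 Mb keeps a desk-scale run under a couple of minutes
while leaving the copies vastly outnumbered by background sequence.

Everything is deterministic under the mandatory seed (per-copy RNG
substreams are derived from it), every copy carries a mutation log that
replays exactly, and the truth table records every planted interval, so
search sensitivity, trim specificity, consensus recovery and subfamily
structure (an optional two-sub-ancestor mode) can all be checked against
ground truth rather than against expectations.

What the simulator does *not* emulate — and hence what passing tests do
not show about real genomes: isochore structure and repeat families other
than the planted one, nested or recombined elements, target-site
duplications, sequencing or assembly artefacts, and selection (the model
is strictly neutral). Results on the simulator validate the machinery,
not the biology of any particular assembly.

The packaged demonstration model (`sb_like_model()`) is a randomly
generated 1638-nt element with SB-like geometry — 227-nt true inverted
repeats, a 1022-nt CDS at offset 300, two editable binding-region boxes
per ITR — and is deliberately *not* the real SB sequence; users analysing
the real element supply their own FASTA and YAML config. Binding-region
coordinates are shipped as editable config values because they are part of
the model's interpretation, not something the package should hard-code;
every binding-region-dependent output carries the spans used.

## Numerical and design choices

* **Coordinates.** All coordinates are 1-based closed intervals, the
  R/Bioconductor convention; PSL files are converted from their native
  0-based half-open layout at the file boundary only. User-facing reports
  use 1-based positions within the named feature.
* **CDS frame.** 1022 nt is not a codon multiple, so the reading-frame
  offset is an explicit model field (`cds_frame`), never assumed zero.
  Positions before the frame offset or in the trailing partial codon have
  no codon effect. The annotator reports frame consequences (e.g. a
  conserved 1-nt insertion in the CDS is a frameshift against the
  reference frame) and never "fixes" frames silently.
* **Hit extension.** Extension is implemented as local alignment over the
  chained seed window rather than a literal greedy x-drop walk; it is
  deterministic and serves the same contract (permissive recovery of
  ≥90%-identity copies), with the window margin playing the role of the
  termination band.
* **Ties.** Base ties at a consensus column resolve alphabetically;
  NJ agglomeration ties resolve to the lowest index pair; overlapping-hit
  ties resolve to the leftmost start. All paths are deterministic:
  identical inputs give byte-identical artifacts, which the test suite
  asserts literally on the written files.
* **Degenerate inputs.** Empty genomes give empty hit lists; fewer than
  two element sequences abort the pipeline with the stage named; a pair
  with no comparable alignment columns, or a saturated K2P pair, is an
  error naming the pair; curation never drops the reference row.
* **Run artifacts.** Every stage writes its intermediate (PSL + TSV hits,
  element FASTA, alignment FASTA, frequency TSV, consensus FASTA,
  difference TSV, newick, run log), so a genome-scale run can be resumed
  or re-entered at any stage (e.g. via `psl_in`). The run log contains
  stage counts and parameters but no timings — timings go to the console —
  so reruns with the same configuration are byte-identical. The
  configuration hash appears in the header of every TSV artifact and in
  the manifest; FASTA and newick files cannot carry comments without
  breaking standard parsers, so their hash lives in the manifest.

## Problem sizes used in the tests

Unit tests run on a 200-nt miniature model (30-nt ITRs, 120-nt CDS) in
20–30-kb genomes so each stage is exercised in milliseconds; the
acceptance suite runs the full study conditions (2-Mb genome, 50 copies of
the 1638-nt model, 3% divergence, 10 decoys) through both the full-element
and trim strategies, plus oracle cross-checks: per-column frequencies
against brute-force tallies, the built-in search against a sliding-window
alignment oracle on a 50-kb genome, NJ against generated additive
matrices up to 8 taxa, K2P against its closed form, and codon
classification against whole-protein translation over every substitution
of a 999-nt coding sequence.

## A worked example

```{r example, eval = FALSE}
library(temine)

model <- sb_like_model()
params <- sim_params(genome_length = 2e6, n_copies = 50, p_sub = 0.03,
                     n_decoys = 10, seed = 1)
sim <- generate_genome(model, params)

res <- run_pipeline(run_config(sim$genome, model, strategy = "trim",
                               out_dir = "run_trim"))
projected_consensus(res$consensus) == model$sequence
res$differences
```

## Known limitations

* The built-in search is permissive but not BLAT: bit-identical hit lists
  with external tools are obtained by importing their PSL output, not by
  emulation.
* The center-star aligner is exact enough for closely related,
  mostly-colinear copies (the use case); highly rearranged or deeply
  diverged sets should use the MAFFT engine.
* Consensus calling is frequency-based, not probabilistic; there is no
  profile-HMM weighting, no quality weighting.
* Codon-level summaries at variable (`N`) positions report the frequency
  vector and leave amino-acid-level interpretation to the reader, since a
  single column's `N` does not identify a unique codon.
* Target-site-duplication detection and nested-element resolution are out
  of scope.
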