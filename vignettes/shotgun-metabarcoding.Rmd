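---
title: "Shotgun metabarcoding of multi-ingredient herbal products: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shotgun metabarcoding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the procedure

A powdered herbal patent medicine is a mixture of several botanical
ingredients, possibly substituted, adulterated or contaminated. Shotgun
metabarcoding identifies its biological composition by sequencing the total
DNA without any PCR enrichment, and then recovering the classical DNA
barcode regions computationally: the nuclear ribosomal ITS2 and the plastid
psbA-trnH, matK and rbcL. `herbshotgun` implements the full recovery chain
at desk scale:

trim → k-mer enrichment → per-marker assembly (two parameter settings,
merged and de-duplicated at 100% identity) → barcode annotation (ITS2 by
conserved flank motifs, plastid markers by primer sites) → de novo chimera
screening → OTU clustering → read-back mapping with depth/coverage QC →
multi-marker taxonomic assignment → prescription-aware classification.

The package also owns a synthetic-data generator
(`generate_species_panel()`, `simulate_shotgun_reads()`) that emulates such
a product and emits a per-read truth table, so every stage is testable
against ground truth without external downloads.

The underlying assumptions are those of the field method: barcode loci are
present at usable copy number in the powder; reads are short (100–150 bp)
relative to loci (200–900 bp); substitution errors dominate (no indel error
model); and species resolution is bounded by the marker — ITS2 is the most
discriminating, while matK/rbcL cannot separate closely related Apiaceae.

# Tunable parameters

| Stage | Parameter | Default | Rationale |
|---|---|---|---|
| trim | `min_quality` (Phred) | 20 | conventional 3' cut-off |
| trim | `min_length` (bp) | 50 | shorter mates carry < 30 usable 21-mers |
| enrich | `k` (bp) | 21 | specific at barcode scale; robust to 1 error per ~100 bp |
| enrich | `min_shared_kmers` | 3 | a 150-bp read at 1% error retains ≥ 3 intact shared 21-mers with high probability |
| assemble | `min_overlap` (bp) | 30 and 50 | two settings emulate two assemblers; union merged then de-duplicated |
| assemble | `max_mismatch_rate` | 0.02 | tolerates sequencing error; deliberately *above* the ~1.5% divergence of confamilial plastid barcodes, so their collapse is reproduced |
| assemble | `at_repeat_abort` (bp) | 20 | AT-dinucleotide tandem runs of this length abort extension |
| annotate | primer `max_mismatch` | 2 | short-primer practice; substitutions only |
| annotate | motif threshold | 80% of max log-odds score | accepts ~2 substitutions in a 20-bp flank |
| chimera | `min_parent_identity` | 0.99 | segments must nearly match their parents |
| chimera | `min_gain` (columns) | 4 | the two-parent model must explain ≥ 4 more matching columns than any single parent |
| cluster | `identity` | 1.00 | final choice for same-family loci; 0.99 exposed to reproduce the merge of a 4-difference rbcL pair |
| map | `max_mismatch` | 3 | ≈ 2% of a 150-bp read |
| map | `multimap_mode` | `random` | seeded and reproducible; `all` is first-class because random multi-mapping is the documented false-positive mechanism |
| QC | depth / coverage | ≤ 3 / ≤ 95% removed | inclusive bounds, exactly as printed in the QC rule this implements |
| QC | evenness window / ratio | 30 bp / 50 | flags conserved-flank pileups (hundreds-fold end spikes) without tripping on ordinary unevenness |
| assign | `min_identity`, `tie_margin` | 0.97, 0.002 | BLAST-style species floor; ties within ~1 base in 500 drop the rank |
| assign | `min_query_coverage` | 0.8 | a segmental (partial or chimeric) match must not be assignable |

# The synthetic-data generator

`divergence_spec()` describes the taxa and their target pairwise
identities per marker. Taxa explicitly related above the baseline form
groups; within a group sequences are generated on a star topology by
mutating a group ancestor at *disjoint* position sets, so realized
within-group identities hit their targets up to rounding (±0.005); an
identity matrix that violates star additivity is rejected. Groups descend
from a common root so cross-group identities land near the baseline (0.70
by default) — these deep divergences are approximate, which is irrelevant
downstream. AT-rich loci are rebuilt at their target composition with a
30-bp AT-dinucleotide tandem repeat. ITS2 interiors are embedded between
conserved 5.8S-end / 28S-start motifs plus conserved lead/tail context
shared by *all* taxa (that conservation is what makes 28S reads
multi-map); plastid interiors sit between their primer binding sites with
50 bp of random per-taxon genomic context beyond them, so locus ends are
not coverage cliffs. Every taxon also carries a random genomic-background
pseudo-locus so enrichment specificity is measurable.

`simulate_shotgun_reads()` draws each pair taxon-first by formulation
fraction, then locus by copy weight (plastid loci 10× a single-copy
nuclear locus, multi-copy rDNA ITS2 likewise 10×, background 1×; weights
are relative copy numbers, not genome-length weighted, which keeps barcode
yield high at desk scale — real libraries are overwhelmingly genomic
background). Fragment lengths are normal (mean 180, sd 60) truncated below
at the read length; per-taxon `degraded` overrides model severely
processed ingredients with a tight short-fragment distribution
(sd = mean/4, floor 30 bp) subject to library size selection at 100 bp, so
severe degradation depletes the taxon — the mechanism by which a processed
rhizome disappears from a commercial sample. A configurable fraction of
fragments (default 1%) is built as two-parent chimeras: two *distinct*
same-marker templates joined at a uniform breakpoint, flagged in the truth
table.

What the generator does **not** emulate: indel sequencing errors,
quality-correlated errors (qualities are a constant or position-decay
profile), PCR bias (the protocol is PCR-free), within-species haplotype
variation, and realistic genome-scale background. Green tests therefore
show that the pipeline's logic is correct under these idealizations, not
that real libraries of any given product will behave identically.

# Numerical and algorithmic choices

**Assembly.** Greedy overlap–layout–consensus instead of a de Bruijn
metagenome assembler: loci are 200–900 bp and per-marker read sets are
thousands, so OLC is exact enough and auditable. Reads are seeded in
lexicographic id order (no hash-order nondeterminism); extension always
takes the longest acceptable prefix overlap, anchored on exact 15-mers;
after each extension pass the supporting reads are re-recruited and the
contig replaced by its per-column majority consensus, which repairs
single-coverage errors at the growing tip and lets extension continue.
Consensus ties resolve to the earliest supporting read — never an IUPAC
code. Columns where ≥ 30% of ≥ 4 reads disagree are variant columns; two
or more of them raise a collapse warning (near-identical haplotypes merged
into one consensus, the documented failure mode for confamilial
matK/rbcL). The AT-repeat abort is enforced twice: reads containing an
approximate repeat window (≤ 2 defects in 20 bp) are withheld, and any
consensus that still contains a ≥ 20 bp alternating-AT run — possible when
a rare multi-error read bridges the repeat and the pileup then repairs it
— is split at the run. The split pieces carry only one primer each and are
discarded as `partial` at annotation, reproducing the AT-rich psbA-trnH
dropout deterministically.

**Annotation.** Position-weight-matrix flank motifs replace a profile
HMM: they are deterministic, trainable from the panel's flanks, and
sufficient to express the retained-28S failure and its fix. A sub-threshold
but recognizable 28S hit (≥ 50% of threshold) is still used as a trimming
anchor and sets `conserved_tail_trimmed`; with no usable hit the barcode is
`partial`. Partial barcodes are dropped by default because an unanchored
end means the diagnostic interior is not delimited.

**Chimera screen.** The UCHIME-style vote system is deliberately
simplified to an auditable two-segment identity rule with an abundance
constraint (parents at least as abundant as the candidate) and a top-20
most-abundant parent search. Segment profiles come from a banded global
alignment (match +1, mismatch −1, linear gap −2) — adequate because
candidates and parents are same-locus sequences of similar length. On the
tie plateau of equally good breakpoints the middle one is reported.
Single-fragment chimeric islands whose reads carry sequencing errors can
evade the 0.99 segment threshold; they are nevertheless eliminated by the
depth-≤ 3 QC rule, so they do not reach the species calls.

**Identity definitions.** Clustering uses global-alignment identity
(matching columns / alignment columns, end gaps penalized) because the
definition changes membership at the 99–100% boundary for same-locus
barcodes. Assignment and the Sanger comparator use end-gap-free (overlap)
alignment with match +1 / mismatch −1 / gap open 2 / extend 0.5;
differences count every differing column of the mutually covered region,
gap columns included (substitution-only counts are reported alongside,
since published base-difference tallies depend on this convention).
Because overlap alignment clips ends for free, assignment additionally
requires ≥ 80% query coverage — otherwise a chimeric or half-assembled
representative would inherit the identity of whichever half matches.

**QC semantics.** "Sequencing depth" is the mean per-base depth over the
representative; removal bounds are inclusive (`≤ 3`, `≤ 95%`) following
the printed rule; both depth and coverage are logged per OTU for audit.
The evenness diagnostic compares the maximum 30-bp window mean against the
median window (floored at 1) and reports whether the high-depth window
abuts a sequence end — the conserved-flank signature.

**Classification** is configuration-driven: the prescription config lists
official species per ingredient, sanctioned substitutions, known
adulterants and the positive control, because these categories encode
pharmacopoeial knowledge, not sequence similarity. Genus-level calls whose
genus matches an official species are counted as supporting that
ingredient (the species-level detection matrix is unaffected); family- and
genus-level calls otherwise fall through to the contaminant rules.
Fungal calls aggregate to genus with fractions of total fungal reads.

**Determinism.** Every stage seed derives from the single pipeline seed;
random multi-mapping uses R's seeded generator; assembly and clustering
have fixed tie-breaks. Running the same configuration twice yields
byte-identical report JSON.

# Design decisions that were genuinely open

* **Chimera parents are distinct templates.** Joining two windows of the
  *same* locus would mostly create biologically meaningless
  self-rearrangements whose only effect at desk scale is to bridge
  assembly gaps artificially (including across AT repeats); requiring
  distinct parents matches the usual two-template crossover concept.
* **The clustering-threshold contrast (1 vs 2 OTUs for a 4-difference
  pair) lives at the clustering module.** The OLC assembler merges such
  near-identical haplotypes upstream (its mismatch tolerance must exceed
  the sequencing error rate), so a full pipeline run cannot isolate the
  clustering threshold's effect; `cluster_otus()` exposes it directly.
* **Table-style recipe percentages are normalized, not rejected.** A
  prescription totalling 99.8% is a recipe, not a probability vector; the
  raw total is retained so results can be reported back on the recipe's
  percent scale.
* **Reference databases are local and explicit.** No remote queries; the
  panel written by the generator doubles as the assignment reference, which
  makes the provenance of every assignment auditable per run.
* **Stage-level CLI subcommands are served by `run_pipeline()` artifacts**
  (every stage writes its outputs under the run directory) plus the
  exported stage functions; the shipped CLI wraps the four entry points a
  shell user actually needs (`simulate`, `run`, `evaluate`,
  `compare-sanger`).

# Problem sizes used by the test suite

Unit tests run on loci of 100–900 bp with tens to hundreds of read pairs.
The enrichment accuracy property uses a 5,000-pair simulation; pipeline
tests use 6,000-pair simulations; the full mock-detection check uses a
simulation sized to yield ≥ 50,000 enriched pairs; and the
fraction-recovery check uses 100,000 pairs. These sizes were chosen so the
binomial sampling error of every asserted fraction is far below its
tolerance.

# Known limitations

* The assembler is exact-anchor greedy OLC: it requires error-free 15-mers
  for overlap detection and is not meant for genome-scale input.
* No indel handling in read mapping or primer matching; indel-rich data
  would need gapped alignment.
* Collapse of > 98%-identical haplotypes is reproduced, not solved; the
  package reports collapse warnings and family-rank assignments rather
  than attempting haplotype phasing.
* The chimera screen models a single breakpoint and two parents only.
* Mixture fractions are reported as read counts; no copy-number or
  biomass calibration is attempted.
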