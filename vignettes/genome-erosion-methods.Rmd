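---
title: "Measuring endosymbiont genome erosion: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring endosymbiont genome erosion: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Obligate intracellular endosymbionts such as *Buchnera aphidicola* live
under relaxed selection and strong drift: their genomes shed genes,
drift toward A+T, and accumulate substitutions that erode the identity
of the surviving proteins to their free-living homologs. `generosion`
packages the quantitative machinery for studying that erosion across a
set of annotated genomes: composition statistics, reciprocal-best-hit
homology against a free-living reference proteome, a synteny-ordered
gene array with its pan/core genome and rearrangement reports, the
%GC-versus-identity quadrant framework with its regression model,
allele-frequency analytics for detecting co-resident strains, and
expression summaries. A genome-reduction simulator with a complete
ground-truth ledger backs every stage, so each analysis can be checked
against a known answer before being pointed at real data.

This vignette records the models, the tunable parameters, and the
design decisions a maintainer would want explained.

## The gene model

All coordinates are 0-based half-open internally; GenBank I/O converts
at the boundary (1-based inclusive on disk). This makes every length a
plain difference, and every intergenic gap `start[i+1] - end[i]`,
without per-call off-by-one bookkeeping. Circular replicons are
linearized at position 0 of the record; a feature whose `join()`
location spans the origin is kept as a single gene with
`end > genome length` and is extracted with wrap-around. Pseudogenes
are parsed and flagged but excluded from all protein-coding-gene (PCG)
statistics by default, matching how annotation summaries in this field
are conventionally drawn.

GenBank parsing is implemented in the package because no installed
package reads local flat files; FASTA, translation (bacterial code,
transl_table 11) and reverse-complementation go through Biostrings.
A CDS that translates with an internal stop is truncated there and
reported as a split-gene candidate — exactly the signature by which
fragmented genes betray themselves.

## Composition statistics

`gc_percent()` is the standard G+C fraction with `N` excluded from both
numerator and denominator. Sliding-window profiles default to a 1 kb
window and 200 bp step — fine enough to show the GC-rich genic islands
against the AT-rich intergenic background in a ~640 kb genome without
producing an unwieldy table; both are parameters. Standard deviations
are sample SDs (n−1), the spreadsheet convention the published summary
statistics in this area most plausibly used. Overlapping genes produce
negative intergenic gaps which are retained in the mean: clipping at
zero would bias the average upward, and no published rule says to clip.

The homopolymer census counts a gene once if its annotated span on the
forward strand contains a run of any base in the chosen set (default
`{A, T}`) of at least `min_run` (default 10). Because an A-run on one
strand is a T-run on the other, the `{A, T}` census is strand
symmetric, which is the right invariance for asking which transcripts
could self-prime in a poly-dT library.

## Homology

Protein pairs are aligned with global (Needleman–Wunsch/Gotoh) affine
alignment, BLOSUM62, gap open 11, gap extend 1 — the classic protein
search defaults. The aligner lives in `src/` (a few dozen lines of
C++), with two properties the analysis depends on: the gap model is
`open + L·extend` for a gap of length `L`, and the traceback is
deterministic with tie preference match/mismatch over gap-in-second
over gap-in-first, so reruns are byte-identical. The test suite checks
the scores against exhaustive enumeration of all alignments on short
peptides and against an independent aligner on longer ones.

Percent identity divides identical columns by the alignment length
after trimming terminal-gap columns; internal gaps stay in the
denominator. The published pooled identity value this framework echoes
never states its denominator, so the choice is exposed
(`denominator = "alignment" | "shorter" | "longer"`) and the pooled
mean should be treated as approximately reproducible only.

Reciprocal best hits exploit the symmetry of the global score: one
query×reference score matrix serves both search directions. Ties are
broken by percent identity, then lexicographic gene id. Queries whose
best score falls below `min_score` (default 40) stay unassigned, the
fate of severely deteriorated genes.

## The gene array

The array is the package's central object: one row per positional
homolog, one column per genome, rows in synteny order. The builder:

1. anchors rows on genes sharing a gene name or a reciprocal reference
   assignment;
2. rotates each circular gene order to start at the gene matching the
   earliest existing row (a cheap deterministic proxy for minimizing
   order disagreement — exact for genomes that actually preserved
   order, which is the regime this analysis targets);
3. places unanchored genes between their flanking anchors, merging
   into an existing row only when protein identity to a row member
   reaches 30% (the twilight-zone floor; configurable), else founding
   a new row;
4. gives a second same-genome gene that hits an occupied row (a
   duplicate or split fragment) its own adjacent row carrying the same
   identity, which is how a manually curated array lays out fragments
   next to their parent.

Reading any genome's cells top-to-bottom returns its genes in genomic
order — except inside inversions, where anchored placement necessarily
reverses the local order; `check_array_order()` verifies the invariant
on inversion-free builds.

Pan/core compaction merges rows sharing a reference identity (so
fragment and duplicate rows collapse onto their parent); rows without
a reference stand alone. A unit is core when its member rows jointly
cover every genome. Split detection requires two or more genes of one
genome, adjacent in that genome's order (one intervening gene
allowed), best-hitting the same reference gene, with summed amino-acid
length within ±15% of the reference — full-length tandem paralogs sum
to ~200% and are thereby classified as duplications, not splits. The
adjacency is deliberately defined in the genome's own order rather
than in array rows: unrelated genomes' fragment rows can interleave in
the array without separating a genuine fragment pair.

Strand deviations split into isolated direction changes and
inversions: an inversion is a maximal run of two or more genes,
consecutive in their genome, strand-flipped against the row majority
*and* occupying descending rows. Syntenic blocks scan assigned rows in
array order, extending while reference indices advance by exactly +1
(or −1 for a reversed block); repeats of an index (fragment/duplicate
rows) do not break a block, and unassigned rows are skipped by default
so that deteriorated genes do not shatter the block structure.

## Quadrants and the regression

Genes are classified against two thresholds — mean PCG %GC and mean
homolog identity — into Q1 (GC above, identity below), Q2 (both
below), Q3 (both above), Q4 (GC below, identity above). Exact ties go
to the "above" side; boundary points are vanishingly rare in real data
but the rule must be fixed for reproducibility. Thresholds are
recomputed from the input set by default because published means are
dataset-specific; they can be pinned. A caveat worth surfacing: the
figure-caption definition of Q1/Q2 adopted here (Q1 = high-GC,
low-identity) is the canonical one, but prose discussions of
"quadrant 1" sometimes describe what the caption calls Q2; when
comparing against external numbers, check which convention they used.

The regression is ordinary least squares of identity on gene %GC and
relative length (percent of the reference protein length — the length
measure the conservation question is actually about, not raw bp).
Standardized coefficients are raw coefficients times
SD(predictor)/SD(response). Rank-deficient designs error out naming
the collinear columns rather than silently dropping one.

## Strain variation

Variant calling consumes per-site allele-count tables (pileup-style
TSV, or VCF with AD/DP through the alternative reader) rather than
BAMs, keeping the package mapping-tool-agnostic. The three filters —
minimum depth 100, minimum mean base quality Q20, minimum alternate
frequency 20% — are all inclusive (the upstream tool semantics are
unstated, so inclusivity is declared and configurable). Multi-allelic
sites emit one record per passing alternate allele. Sites with
alternate frequency in [0.20, 0.80] (inclusive) are flagged variable:
a fixed difference between hosts sits near 0 or 1, while a genuine
strain mixture holds intermediate frequencies across hundreds of
generations. Coding effects re-translate the affected codon
strand-awarely; indels shift frame unless their length change is a
codon multiple (in-frame indels are reported as missense, since they
alter the protein without shifting frame).

## Expression

logCPM is `log2((count + prior) / (lib + 2·prior) · 1e6)` with prior
0.5 — the damped-log convention of count-based expression analysis;
prior 0 recovers plain log2-CPM, and the columns then re-exponentiate
to exactly one million. Tiers split at logCPM 9 and 11 with boundaries
mapping to "mid". Ex90 is the smallest number of genes whose summed
expression reaches 90% of the total — scale- and order-invariant, and
insensitive to zero-expression genes. Library sizes may be supplied
externally precisely because endosymbiont reads are a small fraction
of a whole-body library; logCPM is then computed against the full
library, as it is in practice.

## The simulator

The generator is the package's ground truth, not a fixture. Its
defaults describe the study conditions used throughout the tests and
the acceptance script: ten descendants of a 150-gene ancestor
(mean gene 900 bp, codon-rounded, matching the ~970 bp average of real
reduced-genome PCGs; 120 bp ancestral spacers), ancestor %GC 50 like a
free-living relative, AT bias 0.8 (four of five substitutions write A
or T), per-gene substitution rates Gamma(shape 2) with mean 0.08
substitutions per site — mild erosion, the regime in which pan/core
recovery can be demanded exactly. Loss probability is logistic in the
eroded gene's %GC around a 26% midpoint — the "tipping point" reading
of the compositional threshold — scaled by `loss_max` 0.25 and a
protected-category weight (40% of genes at weight 0.1, standing in for
translation machinery and other indispensable functions). Splits plant
an internal stop and re-annotate two fragments sharing the parent's
name; duplications insert a tandem copy; inversions (expected 0.1 per
descendant, 2–6 genes) reverse a run and flip its strands; isolated
strand flips occur at 0.002 per gene; spacers shrink by 30%.

Two structural choices matter for what the tests mean. First, %GC
erosion and identity decay are coupled through one latent per-gene
intensity (the gamma rate), because that shared-intensity structure is
precisely the correlation the quadrant framework interprets; it is the
correct null for recovery tests. Second, substitutions that would
create an in-frame stop in a retained gene are rejected (the original
codon is restored), so descendants remain valid ORFs and every
internal stop in the data is a deliberately planted split. Start and
stop codons are likewise held fixed. The per-gene identity recorded in
the ledger is nucleotide identity to the ancestor after this
correction.

What the simulator does *not* emulate — and hence what green tests do
not show about real data: descendants are independent draws from the
ancestor (no phylogenetic branch structure; gene-content clades for
clustering tests are constructed directly in the tests), there is no
selection on codon usage or amino-acid composition, no horizontal
transfer, no annotation error, and real assemblies' mapping artifacts
are absent from the pileup model (sites are independent multinomials
at Poisson depth with a uniform error component). Expression counts
are negative-binomial around tier means calibrated on the logCPM
scale; with the default tier levels the simulated endosymbiont
occupies a somewhat larger share of the library than a whole-body
RNA-seq extraction would show, which is immaterial to the tier and
Ex90 statistics the module computes.

The regression-recovery check uses a dedicated generator
(`simulate_identity_table()`) that plants an explicitly linear
GC–identity coupling: the full erosion process is only approximately
linear, so coverage of a *known* slope is the well-posed test.
Synteny-break planting (`plant_synteny_breaks()`) rearranges the
reference order in segments of at least three genes, so a collinear
array scanned against the rearranged order contains exactly k
discontinuities by construction.

## Problem sizes and reproducibility

Every stochastic function takes an explicit seed, and the pipeline
threads one seed through all stages; reruns are byte-identical. The
validation suite runs the default ten-descendant scenario once and
shares it across checks; the regression-coverage check uses 100
replicates of 150 genes; the alignment oracle panel uses 200 random
pairs of up to six residues (the exhaustive enumerator is exponential);
Ex90 is checked against its cumulative-sum oracle on 1,000 random
vectors. These sizes are the package's choices for a thorough but
convenient default validation; all are parameters in the code.

Analyses of the real study accessions (`analysis/00_fetch_real.R`, and
the first three checks in the acceptance test file) read GenBank
records from a local cache (`~/.cache/generosion`, or option
`generosion.genome_dir`) populated once with `fetch_genome()` on a
networked machine; nothing else in the package touches the network.

## Interface

The package's functions are the interface; the numbered scripts under
`analysis/` are thin narrative drivers over them, and `run_pipeline()`
executes the whole chain from one seeded configuration, echoing the
configuration (with MD5 hash and package version) into the output
bundle for provenance. There is no shell wrapper: this is an analysis
workflow, not a command-line tool.

## Known limitations

The array builder's rotation heuristic assumes at least one anchored
gene early in each genome's order; genomes sharing no anchors with the
first genome are rejected explicitly. Inversion detection requires the
flipped segment to be strand-discordant *and* order-reversed, so an
inversion of a single gene is indistinguishable from a direction
change (as it is in principle). Split fragments separated by an
overlapping inversion can evade the adjacency rule — the one planted
split the default scenario does not recover is exactly of this kind.
The identity denominator question above means pooled identity levels
from different alignment conventions can differ by a few points;
comparisons should pin the convention first.
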