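---
title: "Cas9-targeted nanopore enrichment and per-read methylation analysis with ncatsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cas9-targeted nanopore enrichment and per-read methylation analysis with ncatsr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncatsr)
```

## The analysis problem

Cas9-targeted nanopore sequencing (nCATS) enriches a handful of genomic
loci without PCR: genomic DNA is dephosphorylated, Cas9/sgRNA complexes cut
the target boundaries, and sequencing adapters ligate preferentially to the
fresh cut ends. Because no amplification occurs, the reads retain native
cytosine modifications, so one experiment yields both sequence and per-read
methylation for the target genes. In very large genomes (for example a
24 Gb hexaploid cereal genome) a multi-kilobase target is a ~1/5,000,000
fraction of the genome, so even strong fold-enrichment leaves absolute
target depth low (5--17x in the regime this package addresses), and the
analysis must be honest about what such depths can support.

`ncatsr` implements the downstream computational stages of such an
experiment as testable units:

* **panel** — guide geometry: locate exact protospacer+PAM occurrences on
  both strands, predict blunt cuts, and enumerate the excised fragments a
  guide pair releases.
* **ontarget** — read QC (mean-quality filter, N50) and the enrichment
  accounting: on-target classification, per-locus depth, genome-wide
  coverage, enrichment rate.
* **methtag** — conversion of per-read, reference-anchored methylation
  calls (DeepSignal-plant-style tables) into standard SAM `MM`/`ML`
  base-modification tags, with a decoder used for round-trip validation.
* **methprofile** — read x site methylation matrices, per-site
  frequencies, cytosine sequence context, promoter-vs-gene-body contrast,
  haplotype-split profiles.
* **seqcomp** — CpG-island detection and exact k-mer self-similarity
  (dot-plot) repeat delineation.
* **synth** — a deterministic generator of synthetic references, reads,
  and calls with ground truth, used to validate the whole pipeline.

## Models and conventions

### Coordinates

All internal coordinates are 0-based half-open. Human-facing strings use
the 1-based inclusive `ref:start..end` dialect familiar from GenBank-style
locus tables; `parse_region()` and `format_region()` convert between the
two. BED output is 0-based half-open as usual.

### Cut geometry

SpCas9 cuts bluntly 3 bp 5' of the PAM, between protospacer positions 17
and 18. The spacer must match exactly (20 nt, A/C/G/T); the PAM is an
IUPAC pattern (default `NGG`) in which `N` and the other ambiguity codes
match their usual base sets. Exact matching keeps the search oracle-simple
and suits the panel-verification use case; mismatch-tolerant off-target
scoring is deliberately out of scope, and `offtarget_exact_count()` is
only an exact-occurrence census outside declared targets.

### Read quality

A read's quality is the Phred transform of its **mean error probability**,
`Q = -10 log10( mean(10^(-q_i/10)) )`, not the mean of per-base Phred
scores. This matches how basecallers summarise read accuracy; the filter
retains reads with `Q > min_q` (strictly), with `min_q = 8` as the
conventional cut for "high-quality" nanopore reads.

### Enrichment rate

The package defines

> enrichment = mean on-target depth / genome-wide coverage,

with genome-wide coverage = total retained read bases / genome size. Total
bases include unaligned reads: the denominator models what a whole-genome
run of the same yield would have delivered per position. This is the only
definition under which the published per-locus enrichment figures
(~200x to ~645x at 0.02x coverage) reproduce the printed depths (5x and
~15x) by multiplication, so it is adopted as the formula. Depth counts
primary alignments only (one molecule, one count); deleted reference bases
do not cover, insertions do not add. On-target classification requires at
least `min_overlap_bp = 200` bp of primary-alignment overlap with the
locus, which excludes adapter-scale spurious touches at nanopore read
lengths; the value is configurable.

### MM/ML tags

Methylation calls arrive as caller tables (tab-separated; the
`deepsignal_plant` dialect has columns chrom, position, strand,
position-in-strand, read name, read strand, P(unmethylated),
P(methylated), label, k-mer). `tag_alignments()` maps each call's
reference coordinate through the alignment CIGAR to a read coordinate in
the read's **original orientation** (for reverse-strand alignments,
`read_pos = read_length - 1 - position_in_SEQ`), keeps only positions
whose original-orientation base is `C`, and encodes them as

```
MM:Z:C+m?,d1,d2,...;   ML:B:C,v1,v2,...
```

where `d_i` counts skipped `C` bases between consecutive listed sites and
`v_i = floor(256 * p)` capped at 255. Three choices deserve comment:

* **Skip mode `?`** (unlisted cytosines carry *no* call) rather than the
  implicit-unmodified mode: nCATS calls are sparse per read, and implicit
  mode would silently assert "unmodified" for every unlisted cytosine.
* **`ML` alongside `MM`**: probabilities are available and the tag pair is
  the modern standard; `emit_ml = FALSE` reproduces MM-only output.
* **Wrong-strand calls are dropped, with counters**: a minus-strand
  cytosine (the G of a CpG in forward letters) exists as a `C` only on
  reads whose original orientation presents it; `MM` is defined on the
  read's own letters, so anything else would corrupt the tag.

Calls falling in deletions are dropped and counted. One modification code
(`m`, 5mC) covers all contexts; context is preserved in the per-site
outputs instead. Re-tagging an already tagged file first strips old
`MM`/`ML`, so the operation is idempotent. `decode_mm()` inverts the
encoder up to the 1/256 quantisation and is used pervasively in the test
suite as the round-trip oracle.

### Methylation profiling

Per-read probabilities are binarised at a single threshold (default 0.5,
ties methylated — the caller's argmax label). Sites are (position, strand)
pairs; site frequency is methylated / covered with missing entries
excluded. Cytosine context follows the plant trinucleotide rules (CpG,
CHG, CHH with H = A/C/T), evaluated 5'-3' on the strand carrying the
cytosine.

The promoter-vs-body contrast reports interval means of per-site
frequencies and, optionally, a permutation p-value obtained by reshuffling
site-to-interval labels (two-sided on |difference|, with the standard
+1 correction). The permutation test is an *extension*: it provides a
quantitative backing for what is otherwise a visual comparison of
promoter and gene-body methylation. Promoter and body intervals are user
inputs; the package does not infer them. Unassigned-haplotype reads are
excluded from per-allele profiles but included in pooled ones, so the
pooled frequency is exactly the coverage-weighted mean of the HP1, HP2
and unassigned profiles — an identity the tests assert.

### CpG islands

Islands follow the classical criteria: length >= 200 bp, GC fraction
> 0.5, observed/expected CpG > 0.6 with expected = count(C) x count(G) /
length. The published analysis reports "one CpG island with >200 bp
length" without naming its criteria; the >200 bp phrasing matches the
classical definition, which is therefore adopted with all three thresholds
configurable.

The detector is **exact**: for every start it finds the longest qualifying
interval (up to `max_length`), groups overlapping qualifying intervals,
and reports the longest member of each group (leftmost on ties). An
earlier windowed design — mark qualifying 200-bp windows, merge, trim —
was rejected because it provably misses qualifying intervals none of whose
200-bp windows qualify; the exact enumeration is what the brute-force
oracle in the test suite computes, and the two agree interval-for-interval
on randomized sequences. The `max_length = 2000` cap bounds the quadratic
scan and is far above gene-scale islands; `N` bases never count as C/G and
are excluded from the GC denominator. A known property of the classical
criteria (not a bug): the longest qualifying interval can extend past a
compact CpG-dense core into surrounding sequence that barely keeps the
averages above threshold.

### Dot-plot repeats

`dotplot_matches()` tabulates every exact k-mer self-match off the main
diagonal on both strands (default k = 15), then reports repeat segments as
maximal runs of bases covered by at least `min_density` matching k-mers,
merged across gaps of up to `max_offset_merge` bp; segments shorter than
`2k` are discarded to suppress isolated chance matches. Exact matching
replaces scored local alignment deliberately: it is deterministic,
brute-force-checkable, and sufficient to delineate the low-complexity
tract of a storage-protein gene so that analyses can focus on the unique
coding region upstream of it (`unique_region()`).

## The synthetic-data generator

`sim_config()` fixes the study conditions; `simulate_ncats()` produces a
reference (FASTA + architecture BED), aligned reads (SAM + FASTQ), a
caller-style call table, haplotype labels, and machine-readable ground
truth. One integer seed governs everything; stage `i` of the generator
seeds with `seed + i`, so reference, reads and calls are individually
reproducible and byte-identical across runs.

What the defaults emulate, and why:

* **Target depth 15x** — inside the 5--17x band characteristic of nCATS
  on a multi-gigabase genome; each on-target read spans cut site to cut
  site with <= 50 bp inward end jitter, matching the observation that most
  enriched reads cover the full released fragment.
* **Lognormal background read lengths, mean 3 kb** — heavy-tailed like
  nanopore length distributions, N50 in the ~3--5 kb range.
* **Genome-wide coverage 0.02x** — the background yield is set so total
  bases / nominal genome size equals 0.02. The nominal genome size is
  scaled down 1000-fold (24 Gb to 24 Mb) to keep background read counts
  tractable on a desk machine; depth, coverage and enrichment arithmetic
  are invariant to this scaling. The on-target read *fraction* is not —
  it scales inversely with genome size, so the simulated fraction is
  ~1000x larger than a real 24 Gb run's ~0.03%. Conclusions about the
  fraction therefore do not transfer from simulation to real data; those
  about depth/coverage/enrichment do.
* **Background placement outside the locus** — in a 24 Gb genome the
  chance that a diffuse off-target read lands on a 6 kb target is
  negligible, so the simulator excludes the locus from background
  placement rather than modelling that vanishing tail.
* **Locus architecture** — a 6 kb locus at a known offset: 1.5 kb
  promoter, then gene body containing a designed 300 bp CpG island
  (CpG-enriched, GC-rich synthesis) and a 1.8 kb tandem low-complexity
  tract (30 copies of a 60-mer), flanked by two published glutenin-panel
  spacer sequences planted so the predicted cuts fall exactly on the locus
  boundaries. `make_reference()` self-audits: the island must be
  re-detected by `find_cpg_islands()`, the tract by `dotplot_matches()`,
  and each guide must cut exactly once at the intended position.
* **Methylation truth** — promoter CpG/CHG/CHH = 0.1/0.05/0.02, body =
  0.8/0.1/0.05. The 0.1-vs-0.8 CpG contrast is the canonical gene-body
  methylation profile (hypomethylated promoter, CpG-hypermethylated body);
  non-CpG body methylation is kept low because gene-body methylation is
  definitionally CpG-dominant.
* **Emission model** — per (site, read), the true state is Bernoulli in
  the site's regional probability; the caller probability is then drawn
  from a clipped normal centred at 0.9 (methylated) or 0.1 (unmethylated)
  with sd 0.05. At these settings binarisation at 0.5 recovers the state
  essentially always, so recovery error is purely binomial sampling.
* **Errors** — substitutions at 2% by default; indels off by default so
  coordinate-mapping tests stay interpretable, but an indel mode (1--3 bp
  events, proper CIGARs) is available and tested.
* **Call emission covers both strands of every covered cytosine**, so
  per-site call depth equals read depth (15x). Real single-strand
  nanopore chemistry halves per-strand-site depth; this simplification is
  declared so that "recovery at depth 15" means what it says at the site
  level. The MM-tagging path is unaffected — wrong-strand calls are
  dropped there by the `C`-check, exactly as with real data.

### What passing tests do and do not show

The generator's reads have idealised placement (uniform background,
cut-anchored targets), a single error process, and no coverage biases,
chimeras, or adapter artefacts. Passing recovery tests therefore
demonstrates the *computations* are correct at realistic depths and noise
levels — not that a real experiment will achieve these numbers. The
binomial desk math used in the tolerances: at per-site depth 15 and truth
p = 0.8, a site's frequency lies within +-0.15 of truth with probability
0.904; at p = 0.1, 0.944; at p = 0.05, 0.994. Averaged over the default
site mixture the expected within-rate is ~96%, which is why the 95%-of-
sites criterion is attainable at depth 15 but would not be at, say, a
uniform p = 0.5 mixture. At depth 50 the same +-0.15 band holds for
>99.8% of sites and the region mean estimates truth to well under +-0.05;
a per-site +-0.05 band at depth 50 would be unattainable for intermediate
p (only ~59% of p = 0.8 sites fall within +-0.05 under Bin(50, 0.8)), so
tight tolerances are only applied to region means.

## Numerical and degenerate-input choices

* Probability-to-ML quantisation is `floor(256p)` capped at 255; decoding
  returns bin midpoints, so round trips agree within 1/256.
* Tolerance comparisons at *inclusive* bounds add 1e-9 to absorb
  floating-point ulp noise (e.g. `3/15 - 0.05` differs from `0.15` in the
  last bit).
* Empty inputs: an empty FASTQ yields zero stats (not an error); an empty
  region overlap yields an empty matrix; N50 of an empty set and fragment
  pairs with no cuts are errors; all-unordered cut pairs yield an empty
  fragment list with a warning.
* Sites with zero non-missing calls report frequency `NA` and are skipped
  in bedGraph output.
* Ties: binarisation ties go to methylated; island length ties go to the
  leftmost interval.
* Problem sizes in the shipped tests and acceptance script (a 60 kb
  simulated reference, 6 kb locus, ~150 reads, ~40k calls; 1000-trial
  round-trip suites; 100-sequence oracle-equivalence suites) were chosen
  to exercise every code path at meaningful scale while keeping a full
  run in the tens of seconds.

## Known limitations

* Exact spacer matching only; no mismatch-tolerant off-target search.
* The enrichment definition, while the only one consistent with the
  published figures, is a declared reconstruction — the source never
  states its formula.
* CpG-island criteria are the classical defaults; the published island
  count for the real accession may depend on unstated criteria, and the
  maximal-interval property of the classical definition can stretch island
  bounds beyond a compact core.
* The haplotype pipeline consumes phased labels (HP tags or tables); SNP
  calling and phasing themselves are upstream tools' business.
* The simulator does not model raw signal, basecalling error structure,
  pore dynamics, or strand-specific call sparsity (see the emission-model
  note above).

## A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
dir <- tempfile()
res <- simulate_ncats(cfg, dir)

locus <- target_locus("locus", list(reference_id = "refA",
                                    start = cfg$locus_start,
                                    end = cfg$locus_start + cfg$locus_length))

## enrichment accounting
fq <- filter_reads_by_qscore(file.path(dir, "reads.fastq"), min_q = 8)
enrichment_report(file.path(dir, "reads.sam"), locus,
                  total_bases = fq$stats$total_bases,
                  genome_size = cfg$genome_size)

## methylation profile and promoter/body contrast
calls <- parse_meth_calls(file.path(dir, "calls.tsv"))
prof <- site_frequency(build_matrix(calls, locus))
gbm_contrast(prof,
             c(cfg$locus_start, cfg$locus_start + cfg$promoter_length),
             c(cfg$locus_start + cfg$promoter_length,
               cfg$locus_start + cfg$locus_length),
             n_permutations = 999)

## MM/ML tagging for genome-browser display
tag_alignments(file.path(dir, "reads.sam"), calls,
               file.path(dir, "tagged.sam"))
```
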