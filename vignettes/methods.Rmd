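---
title: "Models and methods behind mthet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mthet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mthet)
```

# Scope

`mthet` re-implements, as a tested and reusable pipeline, the analysis
used to characterize mitochondrial DNA (mtDNA) heteroplasmy in
mutation-accumulation (MA) experiments on *Caenorhabditis briggsae*-like
systems: low-frequency variant calling on a small circular mitochondrial
genome, detection of a direct-repeat-mediated large deletion from split
reads, per-site per-generation mutation-rate estimation for base
substitutions and homopolymer slippage indels, and nuclear-normalized
mtDNA copy-number comparisons. Because the original sequencing libraries
are large external downloads, the package ships a synthetic-data generator
whose defaults reproduce the study conditions, so every stage is testable
end to end from code alone.

# The biological setting

MA lines are propagated through single-individual bottlenecks for up to 50
generations, so genetic drift rather than selection dominates the fate of
new mutations. Within each animal, the mtDNA population itself passes
through a germline bottleneck each generation; a heteroplasmic variant at
frequency $p$ therefore drifts, and after enough generations either fixes,
is lost, or remains heteroplasmic. Certain mtDNA deletions behave as
*selfish* elements: despite being functionally detrimental they are
over-transmitted under drift conditions. The emulated system carries a
pseudogene that shares a 36 bp near-exact direct repeat (one internal
mismatch at offset 6, splitting it into 5 bp and 30 bp exact copies) with
a downstream NADH-dehydrogenase gene; illegitimate recombination between
the repeat copies deletes the intervening 870 bp. Because the deletion
breakpoints fall inside the repeat, their exact position is inherently
ambiguous within the exact-repeat extent.

# Heteroplasmy dynamics

`simulate_ma_lineage()` models one bottleneck per generation over
`n_eff` effective mtDNA copies. A variant at frequency $p$ with
transmission bias $b$ is resampled as

$$p' \sim \mathrm{Binomial}\!\left(N_\mathrm{eff},\;
\frac{pb}{pb + (1-p)}\right) / N_\mathrm{eff},$$

so $b = 1$ is neutral Wright–Fisher drift, for which the replicate
variance after $t$ generations has the closed form
$p_0(1-p_0)\bigl(1-(1-1/N_\mathrm{eff})^t\bigr)$ — the oracle used by the
test suite. The real germline bottleneck size is not known; `n_eff`
defaults to 100 and is a free parameter of the plan. Transmission bias is
a simple frequency-dependent resampling weight because only qualitative
bias is documented for the emulated deletion.

De novo variants arise as Poisson events. Rates are specified per site
per generation and are multiplied by the number of eligible sites *and*
by `n_eff`, because a new mutation can arise on any transmitted mtDNA
copy; each enters at frequency $1/N_\mathrm{eff}$. Under this convention
the frequency-difference estimator below is unbiased for the per-site
rate by the drift martingale property ($E[p_\mathrm{final}] = p_0$).

# Read simulation

`simulate_reads()` draws fragments uniformly from the circular genome
(and from three linear single-copy nuclear loci standing in for *ama-1*,
*efl-2* and *ego-1*). Defaults are 250 bp paired-end reads, fragment
lengths $\mathcal{N}(320, 40)$ truncated to $[260, 470]$ so that every
clean pair merges, 300× mtDNA and 5.5× nuclear coverage (inside the
200–360× and ~5–8× ranges of the emulated libraries), i.i.d. substitution
errors at 0.002 per base, and a 10% exact-duplicate fraction emulating PCR
duplicates. Each fragment carries each variant independently with
probability equal to its truth frequency; large deletions are separate
haplotype molecules. Molecular linkage between point variants, indel
sequencing errors, quality-score variation and GC bias are deliberately
not modeled — passing tests therefore validate the statistical machinery,
not robustness to those real-data artifacts. Fragments are sequenced in
either orientation with probability one half, so merged reads carry both
strands and strand-bias statistics are meaningful.

# Preprocessing

The preprocessing contract is trim → merge → dedupe. Adapter trimming
removes the longest read suffix matching an adapter prefix with at most
one mismatch per ten bases (suffixes shorter than 5 bases are ignored so
random sequence is never clipped). Merging reverse-complements the second
mate and scans overlaps from longest to shortest, requiring at least 20
bases of overlap at a mismatch rate of at most 0.1, resolving
disagreements toward the higher-quality base; pairs that fail to merge
are discarded by default. Deduplication removes exact sequence
duplicates only (containment is not collapsed), keeping the first
occurrence, so each surviving read can be treated as an independent
source molecule.

# Mapping

`map_read()` is a seed-and-extend mapper for small circular references.
Exact k-mers (default $k = 8$) vote for placement diagonals; candidate
diagonals are scored by direct comparison at +1 per match and −1 per
mismatch. A single biological indel is modeled as two collinear segments
on diagonals $d_1, d_2$ with the split point chosen to maximize matches
(computed in one pass from cumulative match counts); the reference gap may
reach `maxindel` (default 2000 bp) for deletions and 50 bp for
insertions, and costs a flat penalty of 4 match units regardless of
length, reflecting a single event. Reads whose best single placement is
already near-perfect (identity ≥ 0.99) skip the split search; otherwise
diagonals one step off every candidate are added as partners, because a
±1 bp slippage indel near a read end leaves its short segment without any
seed. Placements tying for the best score are discarded as ambiguous;
best identity below `minratio` (default 0.8) is unmapped. Breakpoints
inside a direct repeat are ambiguous by construction; deletions are
left-aligned to the smallest reference start for reporting, and
`realign_indels()` rescores reads overlapping a candidate deletion
against the deletion haplotype in both pairings (the read's diagonal as
either the left or right segment), converting reads that score strictly
better.

`extend_reference()` reproduces the iterative consensus-extension
procedure for truncated references: reads are mapped with a unique-anchor
requirement (at least 30 overlapping bases at ≤ 5% mismatches, and at most
one acceptable placement — low-complexity reads anchoring in several
places are ignored), overhanging bases vote into a majority consensus
(accepted at coverage ≥ 2 with ≥ 70% agreement), and the reference grows
over up to 10 iterations. Extended positions with final coverage below
mean − 2 SD of the whole-reference coverage are trimmed back.

# Variant calling

`build_pileup()` tallies per-position, per-strand base counts; insertion
and deletion events from split alignments are left-aligned before
aggregation so that every placement of a homopolymer slippage event
collapses onto one canonical record (reported as `(A)10 -> (A)11` style
changes, with the containing run length attached). The progenitor's
majority base at every position becomes the working reference for all
lines; zero-coverage positions and exact ties fall back to the FASTA base
and are flagged.

A candidate variant is reported when it clears, jointly: coverage ≥ 100,
raw support ≥ 4, an upper-tail exact binomial p-value below $10^{-6}$
against the sequencing-error null, and a strand-bias screen. The
strand-bias screen activates only when one strand carries more than 65% of
the support; it then requires a two-sided exact binomial test of the
support's strand split against the site's strand coverage proportions to
have $p > 10^{-5}$. A permissive mode drops the coverage/support/p gates
to screen progenitor libraries for variants segregating at any frequency;
a variant in an MA line is flagged de novo only when that screen shows
zero supporting progenitor reads. The binomial error null is an explicit,
documented replacement for the undocumented "approximated p" of the
emulated commercial caller; `error_rate` defaults to the library's
per-base error (0.002 for the default simulations) and should be set near
$10^{-4}$ when working with merged-consensus libraries of that quality
(at which setting the printed p-values of the emulated study are
reproduced to order of magnitude). Published per-site p-values are
otherwise not an exactness target. No multiple-testing correction is
applied; the thresholds are per-site, as in the emulated design.

Large deletions are called from split reads clustered by canonical
(left-aligned) start and length, requiring the same minimum support.
Because molecules whose junction overhang stays inside the flanking exact
repeat are content-identical to reference molecules, the frequency
denominator counts only *informative* spanning reads: a read must extend
10 bases beyond the breakpoint on both sides, and at the left breakpoint
beyond the whole ambiguity zone. The frequency is reported as a range
over the two breakpoints — the per-breakpoint denominator used in the
emulated study's printed ranges is not stated, so this convention is the
package's own documented choice. The flanking repeat pair is attached via
`find_direct_repeats()`.

# Mutation rates

For each variant class the per-site per-generation rate is
$\mu = m/(LnT)$ with standard error $\sqrt{\mu/(LnT)}$, where $L$ is the
number of MA lines, $T$ the mean generations per line, $n$ the scanned
sites, and $m$ the summed mutation measure: over MA lines and the union
of variant sites, the sum of $|f_\mathrm{MA} - f_\mathrm{progenitor}|$
with absent treated as zero. Loss of a progenitor heteroplasmy
contributes $|0 - f_\mathrm{prog}|$ and fixation contributes
$|1 - f_\mathrm{prog}|$. For base substitutions $n$ is the genome length
minus the AT-rich region; for homopolymer indels $n$ is the A/T census of
runs of ≥ 8 bp outside the AT-rich region (slippage in shorter runs is
reported by the caller but excluded from rate estimation, matching the
slippage threshold established for nematode mtDNA). Runs partially
overlapping the AT-rich boundary contribute only their outside bases —
the boundary treatment is not fully specified in the emulated design, so
this is the package's resolution.

# Copy number

Per-position mtDNA coverage (AT-rich region excluded) is divided by the
mean of the three nuclear loci's average coverages. Per-position values
are treated as exchangeable observations in a Kruskal–Wallis test across
groups followed by Dunn's post hoc z tests of each MA line against the
progenitor, Bonferroni-adjusted over those contrasts (the emulated
analysis names only "Dunn's multiple comparisons test"; the conventional
family default is assumed). Positional autocorrelation of coverage is
ignored by design, which makes the reported p-values anti-conservative
for real data — a documented limitation. Distribution shapes are
compared with the two-sample Kolmogorov–Smirnov test, and normality is
assessed with a D'Agostino–Pearson $K^2$ omnibus test (implemented in the
package and cross-validated against an independent implementation,
since none of the standard R packages provides it). Significance is
declared at $p < 0.05$.

# The synthetic genome

`genome_spec()` defaults describe a 14,420 bp circular genome at 75% AT
(95% inside a 270 bp AT-rich control region), seven protein-coding genes
written as random sense codons under the invertebrate mitochondrial code
(table 5) ending in TAA, two tRNAs and an rRNA, a pseudogene carrying the
left copy of the 36 bp direct repeat whose right copy lies 870 bp
downstream inside the nd5-like gene, a planted serine codon so that a
C→T at its second position is a S→L substitution, and eight A/T
homopolymer runs of 5–13 bp placed in the feature contexts of the
emulated study (after a stop codon, inside coding sequence, intergenic).
Accidental A/T runs reaching the 8 bp census threshold outside the
AT-rich region are broken, and the repeat copies' flanks are forced to
disagree, so the planted truth is exactly recoverable. Genes are
annotated on the forward strand; effect annotation for reverse-strand
genes is not implemented (none of the planted architecture needs it).

# Numerical and design choices

* Coordinates are 1-based inclusive everywhere user-visible; circularity
  is handled internally on a doubled sequence with wrapped hits
  deduplicated, and origin-spanning features carry an explicit wrap flag.
* Ties: the progenitor reference falls back to the FASTA base on exact
  ties (flagged); mapper score ties are discarded as ambiguous; indel
  placements tie-break to the leftmost equivalent position.
* In-frame indels inside genes (length divisible by three) are reported
  with no protein effect rather than guessing at residue-level
  consequences; indels whose length is not divisible by three are
  frameshifts; large deletions removing a gene's start are annotated
  alternative-start plus truncation.
* Problem sizes in the test-suite: unit tests run on 2–4 kb genomes at
  30–150× where the property under test does not depend on scale; the
  acceptance checks run at the full study conditions (14.4 kb, 300×, 50
  sites, 20 null replicates, 50 rate-recovery experiments), which the
  package's pure-R mapper handles in a few minutes.

# Worked example

```{r example, eval = FALSE}
genome <- build_synthetic_genome(genome_spec(), seed = 42)
nuclear <- synthetic_nuclear_refs(seed = 42)
manifest <- data.frame(
  isolate = "SYN",
  line = c("P0", "MA1", "MA2"),
  role = c("progenitor", "MA", "MA"),
  generations = c(0L, 50L, 46L))
config <- list(
  read_params = read_sim_params(mt_coverage = 300),
  plan = list(initial = data.frame(type = "insertion", position = 3565,
                                   ref = "A", alt = "A", length = 1,
                                   frequency = 0.3)))
res <- run_pipeline(manifest, genome, nuclear, config,
                    out_dir = "mthet_run", seed = 1)
res$rates
res$copy_number$contrasts
```

# Known limitations

The simulator's error model is substitution-only and unlinked; the mapper
has no base-quality awareness and handles at most one indel per read; the
copy-number tests treat positions as independent; reverse-strand genes
are not effect-annotated; and published per-site p-values and mutation
rates are matched in structure and order of magnitude, not digit for
digit, because the upstream tools' null models and $m$ bookkeeping are
not fully documented.
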