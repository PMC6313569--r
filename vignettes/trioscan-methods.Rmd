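---
title: "trioscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trioscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`trioscan` prioritizes variants in a father–mother–proband whole-genome
trio: de novo SNV/indel candidates, recessive-model candidates (compound
heterozygotes and homozygous-recessive genotypes), and copy-number losses
from depth of coverage. It also carries a small, exact toxic-equivalency
(TEQ) calculator for dioxin congener panels, because the motivating use
case is trios with documented dioxin exposure. This vignette explains the
models, the tunable parameters, and the design decisions taken where the
underlying procedure was open.

## De novo detection

Detection is deterministic set logic over called genotypes, not a
likelihood model. The proband is compared with each parent separately; a
site is a candidate iff the proband carries an alt allele absent from the
mother's genotype **and** absent from the father's genotype. This is
equivalent to intersecting the two single-parent comparisons, and the suite
checks that identity on simulations.

Quality control is per sample and per site: a genotype is *evaluable* when
it is called (no `./.`) and passes `min_dp` (default 10 reads) and `min_gq`
(default 20). The defaults are ordinary short-read trio thresholds; the
procedure we emulate states none. A site failing QC in any member is
**unevaluable** — excluded, never counted as de novo — so the candidate
count is conservative. Missing DP/GQ metadata does not fail QC (absence of
evidence is not low quality).

Parents are not required to be homozygous reference: the dual-comparison
rule only requires that neither parent carries the proband's alt allele,
and that is what is implemented.

### Edge-of-read indel filter

Short indels supported only near read ends are a recognizable alignment
artifact. Each indel carries read-support metadata (`RL` read length, `RO`
pipe-separated 0-based offsets of the indel start within supporting reads)
in custom FORMAT tags, so the filter needs no BAM access. An indel is kept
iff at least one read places it **more than** `edge_margin` bases (default
10, boundary inclusive: offsets 0–10 count as edge in a 101-bp read, as do
the mirrored offsets at the other end) from both read ends. Indels without
metadata are kept with a warning — the filter only ever removes positive
evidence of an artifact.

### Mutation spectrum

For an annotated candidate set the package reports transitions (A↔G, C↔T)
vs transversions, the CpG-context proportion among SNVs (a variant is in
CpG context when the reference dinucleotide at (pos, pos+1) or (pos−1, pos)
is CG — strand-symmetric by construction), and the per-generation rate

$$\mu = \frac{n_{\text{dnm}}}{2L},$$

with $L$ the haploid genome length: each generation transmits two haploid
genomes. $L$ defaults to the hg19 assembly total (3,137,161,264 bp) but
real analyses should pass their callable length; published per-nucleotide
rates are sensitive to that denominator, and the procedure we emulate does
not state its value. With zero SNVs the Ts/Tv ratio is undefined and
reported as absent, not zero.

## Recessive model

Variants enter the recessive analysis only with effects in {missense,
nonsense, frameshift, in-frame indel, splice site} — non-synonymous SNVs,
coding indels and splice variants — and with population allele frequency at
most `max_af` (default 0.01; a conventional "rare" cutoff, since the
emulated analysis reasons about "low frequency" without a stated number).
A variant absent from the frequency table counts as frequency 0. An
optional healthy-cohort panel excludes its members outright, at any
frequency, mirroring a local-population check.

**Compound heterozygosity** requires the trans configuration: one
paternal-only and one maternal-only heterozygote in the same gene. Origin
is assigned by transmission (the only parent carrying the allele); alleles
present in both parents are ambiguous and never pair. Cis pairs are
rejected because they leave one intact gene copy; the emulated analysis
shows segregation consistent with trans but never states the exclusion — we
state it. The caller is checked against an exhaustive pair-enumeration
oracle on 50 genes × up to 20 variants.

**Homozygous recessive**: proband `1/1` with both parents `0/1`. A `1/1`
child with a `0/0` parent is a Mendelian inconsistency and belongs to the
de novo logic, not here.

## CNV segmentation

Depth is binned (1 kb default), normalized per sample by its median bin
depth (so normal diploid ≈ 1, one-copy loss ≈ 0.5), and segmented by an
in-house circular binary segmentation:

* circularize the bin sequence; every arc $(i, j]$ splits it into arc and
  complement;
* the split statistic is the pooled two-sample $t$ between the groups;
* the best split is accepted when its permutation p-value (1000 shuffles,
  add-one estimator) is below `alpha` (0.01), then recursion continues in
  the three resulting pieces;
* every resulting segment must span at least `min_width` (3) bins.

Defaults resolve the smallest event of interest here (10 kb = 10 bins) and
are all configurable; the emulated analysis states neither bin size nor
significance level. Segmentation runs on **linear** normalized depth, not
log-ratio: homozygous deletions have depth 0 where the log is undefined.

Numerical details worth knowing:

* With prefix sums $S$, $Q$, the within-group sum of squares is
  $ssw = Q_n - s_a^2/k - (S_n - s_a)^2/(n-k)$ — a function of the arc sum
  alone — so for each arc length only the extreme window sums need a $t$
  evaluation, and permutation exceedance reduces to a precomputed per-length
  threshold (shuffles preserve $S_n$ and $Q_n$). This is an exact
  reformulation, verified against an exhaustive split search in the tests.
* A zero-variance split with differing means has $t = \infty$ (the noiseless
  step case); equal means give $t = 0$ and constant input yields no split.
* Permutations stop early once the exceedance count makes $p \ge \alpha$
  certain; accepted splits always complete their 1000 shuffles. The shuffle
  draws from R's RNG, so runs are reproducible under `set.seed()`.
* The statistic is location- and scale-invariant, so segmentation commutes
  with shifting and scaling of the input (tested).

Trio consensus segments come from the union of per-sample changepoints —
the three samples share a bin grid and, for the deletions of interest, the
boundaries — rather than a joint segmentation. Copy states per segment and
sample follow the mean normalized depth: `hom_del` < 0.25 ≤ `hemi` < 0.75 ≤
`normal` < 1.25 ≤ `gain`; these midpoints between the expected ratios
(0, 0.5, 1, ≥1.5) are forgiving of moderate noise. Adjacent segments with
identical trio state vectors are merged. Inheritance is an explicit rule
replacing manual review: child `hom_del` with both parents `hemi` ⇒
`inherited_recessive`; child loss with both parents `normal` ⇒ `de_novo`;
anything else ⇒ `other`.

## TEQ arithmetic

$\mathrm{TEQ} = \sum_c \mathrm{conc}_c \times \mathrm{TEF}_c$ over the
measured congeners, by family. Both the WHO-1998 and WHO-2005 TEF tables
ship with the package; **WHO-1998 is the default** because panels measured
under late-1990s protocols (like the shipped example serum panel) were
reported against it — WHO-2005 post-dates them. Non-detects default to half
the detection limit (standard practice); `zero` and `full` are available,
and totals are provably monotone across the three policies. PCB rows are
TEF-weighted and reported, but the default grand total covers PCDD/PCDF
only, matching the "TEQ based on PCDD/F" convention of such reports. The
shipped panel reproduces a 115 ppt total with its two dominant congeners
(TCDD at 87 ppt, PeCDD at 12 ppt) contributing 86%.

## The synthetic trio generator

There are no public data for the emulated study, so the generator is a
first-class module: it emits a complete, Mendelian-consistent trio world
(reference FASTA, transcript models, trio VCF, catalogs, AF table, depth
bins) plus a truth table, and every pipeline stage is tested by recovery
against that truth.

What the default `paper_trio` world states (chosen once, not tuned):

* a 2-Mb two-contig genome with ~60 transcripts (80% coding, 2–4 exons);
* 12,000 inherited sites with allele frequencies from Beta(0.5, 0.5) — a
  U-shaped folded site-frequency spectrum giving the novelty filter both
  common and rare sites; parental alleles are redrawn until each site
  segregates in the parents, so every emitted row is a genuine variant
  site; the child inherits one random allele from each parent (Mendelian by
  construction); 10% of inherited sites are 1–3 bp deletions;
* 93 planted de novo events — 92 heterozygous SNVs and one 5-bp non-coding
  deletion — 3 of them in coding exons, 18 SNVs in CpG context (planted as
  C→T at explicitly written CG dinucleotides), transition fraction 62/94.
  Those counts restate the event mix of the emulated study, including its
  internal 93-vs-94 accounting discrepancy, which is reproduced as stated
  rather than resolved;
* one artifact indel with edge-only read support (offsets within 10 bp of a
  read end), present in the VCF but not the truth table, so the edge filter
  is load-bearing in recovery tests;
* two compound-heterozygous genes, each with a paternal-only and a
  maternal-only missense heterozygote, carrying the literature-style allele
  frequencies (8.32×10⁻⁶/absent and 1.5×10⁻³/5.8×10⁻⁵);
* catalogs: inherited sites with AF ≥ 0.01 are dbSNP-like, AF ≥ 0.003
  1000G-like; planted events are never cataloged;
* depth: 30× mean at copy 2 (the emulated trio was sequenced at ≥30×),
  Gaussian noise SD 3 truncated at 0, with SD scaled by `sqrt(copy/2)` so a
  homozygous deletion has exactly zero depth — read sampling is counting
  noise, and a true homozygous loss attracts no (correctly mapped) reads.

The `paper_cnv` preset puts a 150-kb and a 10-kb deletion — child
homozygous, parents hemizygous — on a 5-Mb contig of 1-kb bins. The printed
event sizes (150/10 kb) are used rather than the 155-kb span implied by the
source's HGVS coordinates, which disagree with its own stated length; the
coordinates are scaled into the 5-Mb contig.

Randomness is one master seed with per-stage derived sub-streams
(reference, genes, positions, alleles, genotypes, depth, read support), so
adding events in one stage does not shuffle another stage's draws, and the
same config + seed is byte-identical on disk (tested).

**What a green recovery test does and does not establish.** The generator
has no sequencing errors, no mapping bias, no coverage waviness or GC
effect, uniform base composition outside planted CpG sites, complete and
correct genotype calls, and only one artifact class (edge-supported
indels). Recovery being exact therefore validates the *logic* of the
filters — Mendelian set algebra, annotation arithmetic, segmentation — not
their robustness to caller noise. The QC path is exercised by dedicated
tests with degraded genotypes, not by the preset.

## Other design decisions

* Coordinates are 1-based inclusive for variants (VCF) and 0-based
  half-open for intervals (BED); conversion happens only at I/O boundaries.
* Multi-allelic VCF sites decompose into one record per alt; an allele that
  is some *other* alt of the same site becomes missing in the decomposed
  record (it is neither ref nor this record's alt).
* Region precedence across overlapping transcripts: splicing > exonic >
  5'UTR > 3'UTR > ncRNA_exonic > intronic > ncRNA_intronic > intergenic —
  the rarest, most diagnostic categories win. Splice region = 2 intronic
  bases flanking an exon boundary, coding transcripts only. Among
  transcripts tied at `exonic`, the most severe coding effect wins, with
  transcript name as the deterministic tie-break. Indels are classified at
  their first altered base (VCF anchor convention). Variants in no
  transcript are reported as `intergenic` rather than silently dropped.
* The run configuration file is JSON (`run_config(file=)`): the environment
  provides a mature JSON parser and no TOML parser, and the config is
  machine-written anyway.
* Intergenic has no row in the classic per-region accounting of such
  studies; the report keeps it as its own category so the partition
  identity (categories sum to totals) holds exactly.

## Known limitations

* No statistical phasing or read-backed phasing: compound-het origin
  assignment needs each allele to be carried by exactly one parent.
* X-linked recessive logic is out of scope (autosomal model only).
* No GC correction or mappability masking in the depth model or the
  segmentation; no split-read/discordant-pair SV detection.
* The coding-effect caller handles SNVs and fully-contained coding indels;
  it does not annotate splice-disrupting indels beyond the region category,
  and multi-nucleotide substitutions are passed through unclassified.
* Pathogenicity scores (PolyPhen-2/SIFT/Provean-style) are accepted as
  pass-through annotations only; no scoring engine is reimplemented.
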