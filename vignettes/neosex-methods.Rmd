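---
title: "Detecting early neo-Y degeneration and B-chromosome candidates from sex-separated reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting early neo-Y degeneration and B-chromosome candidates from sex-separated reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neosex)
```

## The comparative design

A very young neo-sex chromosome system arises when an autosome fuses to the
ancestral sex chromosomes. The neo-Y is then male-limited and stops
recombining, so deleterious mutations start to accumulate on it immediately:
extra substitutions in coding sequence, premature stop codons and
frameshifts (putative pseudogenes), and an excess of tandem duplications
that recombination can no longer purge. None of this is directly observable
from a single assembly; it is detected *comparatively*, by mapping male and
female read sets separately against a female-derived reference:

* female reads carry two neo-X copies, so female variant calls measure
  segregating neo-X variation only;
* male reads carry one neo-X and one neo-Y, so male calls additionally
  contain every fixed neo-X/neo-Y difference — necessarily at a roughly
  1:1 allele ratio in the male pool.

The male-only, heterozygous-like fraction of calls is therefore the neo-Y
divergence signal. `neosex` implements this design end to end, together with
a synthetic-data generator that lets every stage be validated against a
known truth table without any external data.

## The synthetic genome

`genome_plan()` defaults to a 2 Mb, four-chromosome karyotype: an ancestral
X (400 kb, 25 genes), the fused neo element (800 kb, 50 genes — about 40% of
the genome, as in the species that motivated the design), a large autosome
(600 kb, 40 genes) and a dot chromosome (200 kb, 8 genes), at GC 0.42.
Genes are single-exon ORFs (mean CDS 900 bp) with a 200 bp non-coding genic
flank on each side. Single-exon models are sufficient because every
downstream statistic — disruption scanning, Ka/Ks, codon bias, the
exonic/intronic density split — operates on coding sequence, not splice
structure; the flank provides a non-empty "intronic" partition.

`derive_haplotypes()` builds the two samples:

* **female** = reference + a second haplotype with residual heterozygosity
  (default 3 × 10⁻⁴/bp — an inbred line; the true residual value for such a
  line is not knowable in advance, so it is an explicit free parameter);
* **male** = one X-bearing haplotype equal to the reference and one
  Y-bearing haplotype whose neo copy carries the planted divergence:
  substitutions at 2 × 10⁻³/bp, 1–6 bp indels at 2 × 10⁻⁴/bp (outside CDS),
  coding disruptions in a fraction (default 0.2) of neo genes — a single
  premature-stop substitution or a 1/2/4/5 bp frameshift indel — and ten
  tandem duplications of 500–2000 bp. Autosomal copies of the Y-bearing
  haplotype carry 10⁻³/bp heterozygosity (the male line is less inbred).
* **ancestral pseudogenes** (default 10% of genes per chromosome) are
  disrupted on *every* haplotype of both sexes but not in the reference, so
  they surface as female-called disruptions — exactly the signal the
  ancestral-pseudogene exclusion step must remove.
* a **B scaffold** mosaics a 5 kb subcentromeric slice of the ancestral X
  and a 5 kb slice from the neo end with 50 kb of B-private sequence and
  ~25 diagnostic SNPs. The mostly-private composition reflects that
  assembly subtraction can only isolate sequence that is absent from the
  female assembly; the mosaic part models the observed homology of B-linked
  sequence to subcentromeric X/neo-X regions and drives the
  centromeric-read-fraction contrast.

Two details keep the truth table exact. Neutral substitutions planted inside
a CDS are redrawn if they would create or destroy a stop codon (so the
disruption truth is exactly the planted set), and neutral indels are planted
outside CDS. Both choices trade a little realism for an unambiguous
truth table; disruption planting itself covers the in-CDS events of
interest. Planted indels are left-aligned at generation time so they are
directly comparable with the caller's normalized coordinates.

Male pooled samples in such designs are usually many outbred individuals,
so segregating male variation occurs at many frequencies, not only 1:2.
The generator emulates this at read level: polymorphic sites (5 × 10⁻⁴/bp)
are injected into a Bernoulli-chosen subset of overlapping reads at a
per-site frequency drawn from U(0.05, 0.5). This is a read-level, not
genomic, device; it reproduces the frequency spectrum the allele-ratio
analysis needs while keeping a two-haplotype genome.

`simulate_reads()` draws inward-facing pairs with Normal(500, 50) insert
lengths (truncated at twice the 100 bp read length), uniform fragment
positions and a 0.2% uniform substitution error rate, at 30× (female) and
40× (male) total coverage split over the two haplotypes. Read names encode
the origin haplotype and coordinates for truth-based evaluation.

## Mapping contract

The seed-and-extend aligner (`index_reference()`, `align_pairs()`,
`realign_unmapped()`) enforces the mapping rules the analysis assumes:

* at most 2 mismatches per mate, ungapped, paired mode first;
* orientation and span are *recorded but never used to reject* — anomalous
  pairs are the structural-variant evidence, so a mapper that discarded
  them would destroy the signal;
* mates of pairs that fail paired placement are re-aligned in single-end
  mode: first ungapped (a mate is often mappable even when its partner is
  not, and discarding it would systematically depress depth near dense
  variant clusters), then with exactly one 1–6 bp gap (plus ≤2 mismatches),
  the gap left-aligned (canonical indel normalization);
* ties are broken to the left-most placement (chromosome name order, then
  position) for determinism, and tied-score pairs are reported
  unmapped-ambiguous and excluded from all evidence. Exclusion of
  multi-mappers is a policy choice: it biases against repetitive regions
  but never fabricates support.

The default seed length k = 13 guarantees an exact seed for any 36–100 bp
read carrying ≤2 mismatches (pigeonhole over ⌊L/k⌋ ≥ 3 seeds). Inner loops
are compiled (Rcpp) — alignment of ~10⁶ reads in pure R would make the
validation simulations impractical.

## Variant calling and the sex partition

`call_snps()` is a count-threshold caller: a site is called in a sex when
depth ≥ 8, alternative count ≥ 3 and alternative fraction ≥ 0.2 (all
configurable). Synthetic qualities are constant, so a quality-aware
Bayesian caller would add no information; what the downstream statistics
need are counts and the contract (recall of planted neo-Y differences
≥ 95%, caller-error floor ≤ 5 false calls/Mb), which the acceptance tests
enforce. Partitions: `shared`, `male_only` (female alternative count below
threshold), `female_segregating`. Indels (`call_indels()`) come from the
gapped rescue alignments and are retained only with at least one supporting
read from each strand, length 1–6 bp.

Two numerical choices worth noting:

* **Density denominators are callable bp** (depth ≥ min_depth in that sex)
  of the region class, not raw chromosome length. Raw length would confound
  the male/female ratio with the coverage difference between sexes (and the
  male hemizygous X at half depth).
* the "around 1:1" allele-ratio bin is alt-ratio ∈ [0.4, 0.6]
  (configurable): wide enough that binomial sampling at 20× keeps ≥90% of
  true fixed differences in-bin, narrow enough that the injected
  low-frequency polymorphisms (< 0.3) rarely enter.

One behaviour of real pipelines reproduces itself here and is worth knowing
when interpreting the false-call floor: reads overlapping a planted indel or
SV junction by a base or two still place ungapped within the two-mismatch
budget, so mismatches pile up at breakpoints and produce male-only calls
that are *signal at the wrong resolution*, not caller error. The caller
error floor is therefore measured away from planted breakpoints; breakpoint
artifacts are instead swept up by the SV scanner.

## Structural variants

`classify_pairs()` applies, in precedence order: different chromosomes →
interlocus (dispersed-duplication evidence); reverse-forward orientation →
tandem-duplication signature; same-strand mates → inversion evidence
(counted as "other", never emitted as typed calls — no principled typing is
possible from orientation alone at this insert size); span beyond the
insert mean ± 3 SD → deletion/insertion evidence. `cluster_anomalies()`
merges same-type anomalies whose breakpoints lie within one cluster window
(default mean + 3 SD = 650 bp — supporting pairs of a single event cannot
spread farther) and keeps calls with ≥ 3 supporting pairs. Dispersed
duplications additionally require the partner ends to co-locate; same-
chromosome spans beyond 10× the insert mean are treated as dispersed rather
than deletion evidence — a declared approximation, since no method for
dispersed-duplication detection is standard at this evidence level.

## Neo-Y coding degeneration

`reconstruct_alleles()` builds, per gene, the neo-X allele (reference CDS +
female-derived alleles) and the neo-Y allele (neo-X + male-only alleles
with alt-ratio in [0.25, 0.75], i.e. candidate fixed differences;
homozygous-like male-only calls are more likely reference error or
mismapping). Variants are applied position-descending; overlapping indels
make a gene unresolvable and it is excluded with a log record.
`scan_disruptions()` flags internal stops strictly before the annotated
terminal codon, length changes ≢ 0 (mod 3), and start-codon loss.
`filter_ancestral()` removes genes already disrupted in the female-derived
allele, on every chromosome. `pseudogene_enrichment()` is a two-sided
Fisher exact test of each chromosome against the neo set, uncorrected
(a deliberate mirror of the published analysis style).

Ka/Ks uses Nei–Gojobori (1986) pathway-averaged counting with Jukes–Cantor
correction rather than a maximum-likelihood method: it is closed-form,
hand-verifiable by per-codon enumeration (which the test suite does), and
the quantity the package validates is synthetic parameter recovery, not a
reproduction of published Ka values that would require the original reads.
Stop-producing single-base changes are excluded from the synonymous-site
numerator (the common NG86 convention); codons containing N or an in-frame
stop in either allele are skipped, and frameshifted genes are excluded
entirely. Codon-bias indices: Wright's ENC (missing degeneracy classes fall
back to the mean observed homozygosity), CAI with relative-adaptiveness
weights from the top-expression decile of the simulated genes (the
generator emits an expression label; zero-count codons get weight 0.5/max
so CAI stays positive), FOP as optimal/synonymously-variable codons, and
Bennetzen–Hall CBI with a uniform-usage expectation.

## Synteny-guided super-scaffolding

The merging logic assumes protein-anchor hits are supplied as a table (from
any aligner); re-implementing a protein aligner is out of scope and the
contribution here is the merge policy. `resolve_overlapping_hits()` keeps,
among scaffolds overlapping on one protein, only the top-scoring hit;
`merge_by_gene()` concatenates scaffolds covering successive parts of one
protein; `merge_by_synteny()` chains scaffolds anchored (hit spanning > 50%
of the protein) to conserved-adjacent proteins, joining with exactly 500 Ns
and orienting each scaffold by its anchor orientation relative to the map.
Every ambiguity — a scaffold claimed by two merge groups, anchors at
non-adjacent map positions, overlapping position claims — leaves the
scaffolds unmerged with a logged reason: for a reference assembly a missed
join is recoverable, a wrong join is not. Interleaving three or more
scaffolds along one protein is allowed (ordered by protein coordinate).
N50 is computed as the largest member length L whose ≥L scaffolds hold at
least half the total.

## B-chromosome candidates

`subtract_assemblies()` measures, for each male scaffold, the fraction of
its length covered by k-mers shared with the female assembly (both strands,
k = 21) and applies the published-style decision rule: candidate iff < 20%
aligned length. The k-mer coverage replaces an E-value-based aligner
criterion; at k = 21 chance matches against a megabase assembly are
negligible (4 × 10⁶ genome k-mers against a 4²¹ ≈ 4.4 × 10¹² space), while
true homology at a few percent divergence still covers most of a scaffold —
at k = 13 spurious coverage would exceed 50% and the rule would be
meaningless. `filter_known()` then removes candidates carrying annotated
proteins with known-sequence homology, `probe_bait()` ranks scaffolds by
local alignment to a hybridization probe (match +1, mismatch −1, gap −2;
13-mer prefilter), and `centromeric_read_fraction()` compares per-sex
fractions of reads placing (≤2 mismatches) on a centromeric sequence set.

## Validation scope and problem sizes

The package validates itself on simulations whose defaults are the study
conditions described above: a 2 Mb genome at 30×/40× over three seeds for
parameter recovery (disruption recall ≥ 90% with zero ancestral
contaminants, tandem-duplication recovery ≥ 80%, the planted B scaffold as
sole surviving candidate, neo-Y SNP recall ≥ 95%), smaller genomes
(~200–350 kb) for module-level oracle tests, and a ~250 kb configuration
for byte-identical determinism of repeated runs. Every random quantity
derives from a single master seed; reruns with one config are
byte-identical.

What passing these tests shows — and does not show. The generator has
uniform coverage, uniform substitution error, no repeats or transposable
elements, no inversions, no quality-score structure, single-exon genes and
clean diploid samples plus a read-level polymorphism device. Passing
therefore validates the *logic* of every stage (thresholds, partitions,
clustering, exclusion rules, coordinate handling) and its statistical
behaviour under the stated model, not robustness to repeat-rich real
genomes, mapping bias, or library artifacts. On real data the mapper can be
bypassed entirely (`read_sam()` accepts external alignments) and every
threshold above is exposed as a parameter.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg, outdir = "neosex_demo")
res$pseudo_counts       # per-chromosome pseudogene counts with Fisher p
res$sv_report$counts    # male/female SV counts and ratios per chromosome
res$bchrom$candidates   # B-candidate table
res$table2              # the per-chromosome comparison table
```

(The default configuration takes a few minutes; shrink the `genome_plan()`
lengths for a quick look.)
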