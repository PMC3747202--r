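---
title: "Prioritizing haplotype-specific regulatory variants with haplopin"
author: "haplopin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing haplotype-specific regulatory variants with haplopin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopin)
library(dplyr)
```

## The analysis problem

Many disease-associated loci, most prominently within the MHC, carry their
risk on a small number of deeply diverged haplotypes. When the classical
allele tagging the risk haplotype (for psoriasis, *HLA-C\*06:02* at the
PSORS1 locus) has no demonstrated functional defect, the causal variant may
instead be regulatory: a change riding on the risk haplotype that alters the
expression of the gene. Finding such variants requires combining several
lines of evidence, each individually weak:

1. **Locus refinement.** Linkage disequilibrium (LD) conservation in a large
   control panel delimits the interval within which the causal variant must
   lie.
2. **Haplotype comparison.** Aligned full-length haplotype sequences reveal
   the variants unique to risk chromosomes.
3. **Population exclusion.** Variants carried by many individuals who do not
   carry the risk allele cannot be risk-specific and are removed.
4. **Regulatory context.** Only variants inside active enhancers (H3K4me1
   and H3K27ac co-occurrence, open chromatin, unmethylated CpG islands) are
   plausible expression modifiers.
5. **Motif consequence.** A variant that creates or destroys a strong
   transcription-factor binding motif has a mechanistic hypothesis attached.

haplopin implements this funnel as composable, pipe-friendly functions plus
a single orchestrator, `run_pipeline()`. Because the real inputs of such
studies are access-controlled, the package ships a seeded synthetic-data
generator whose ground truth makes every stage verifiable offline.

## Stage models and parameters

### LD refinement

Unphased control genotypes are reduced to markers with minor allele
frequency above `maf_min` (default 0.1, strict inequality) and thinned to a
fixed random subset (default 147 markers) so that pairwise statistics are
not dominated by redundant, tightly packed markers. For each marker pair,
two-locus haplotype frequencies are estimated by an EM algorithm under
Hardy-Weinberg equilibrium: only double heterozygotes are phase-ambiguous,
and the E step splits them between coupling and repulsion in proportion to
the current likelihood. The normalized disequilibrium is
$|D'| = |f_{AB} - p q| / D_{\max}$ with the usual sign-dependent
$D_{\max}$; it is undefined at monomorphic loci and the package refuses to
compute it there.

Two numerical choices deserve note:

* **Initialization.** Linkage-equilibrium initialization is an exact saddle
  point of the EM map for perfectly symmetric double-heterozygote tables
  (the E step returns the starting point unchanged). The estimator
  therefore runs three deterministic starts — near-coupling,
  near-repulsion, and linkage equilibrium — and returns the
  highest-likelihood fixed point. When coupling and repulsion achieve
  exactly equal likelihood (which happens whenever the data consist only of
  double heterozygotes), the reported solution is the coupling-phase one;
  this tie-break is part of the function's contract and mirrored by the
  test oracles. Per-iteration log-likelihoods are exposed via the `loglik`
  attribute and asserted non-decreasing in the tests.
* **Missing data.** Marker pairs use pairwise-complete individuals. This is
  the simplest defensible choice; with the ~1% missingness the generator
  defaults to, the effect on $|D'|$ is negligible.

The conserved block around an anchor interval (the candidate gene) is found
by greedy outward growth: starting from the markers inside the anchor, the
window is extended one marker at a time while the fraction of within-window
pairs with $|D'| \ge$ `dprime_threshold` (default 0.8) stays at or above
`min_fraction` (default 0.9). The published analyses of this kind read
block boundaries off a heatmap by eye; an explicit, parameterized rule is
used here so the boundary is reproducible from the marker table alone. The
block is reported as the span from its first to its last member marker, not
as gap midpoints, for the same reason.

### Haplotype variant extraction

The panel is an alignment of haplotype sequences against a reference row.
Column walking emits SNPs, merges runs of adjacent gap columns into single
indel events, anchors indels on the preceding reference base, and
left-normalizes them (trim shared trailing bases, extending left through
reference context when an allele empties; then trim shared leading bases
beyond the anchor). Normalization is idempotent and asserted so in the
tests. Adjacent substitution columns that co-segregate identically across
every member are merged into an MNP; otherwise each column is its own SNP,
matching per-position variant accounting. Undetermined bases (`N`) in a
member produce a `no_coverage` flag at overlapping variants: such members
count as neither present nor absent.

The risk-specificity rule keeps variants present on at least
`min_risk_present` (default 3) risk haplotypes and on at most
`max_nonrisk_present` (default 0) non-risk haplotypes. The defaults
tolerate one missing or discordant risk haplotype out of four — the
situation that arises when one risk sequence has a coverage gap — while
requiring strict absence from non-risk chromosomes.

Variants inside homopolymer runs longer than 4 nt or dinucleotide tandem
repeats are removed before the specificity call: such positions are
dominated by replication slippage and alignment ambiguity rather than
inheritance. The dinucleotide minimum is set at 3 unit copies (6 bp), the
smallest span conventionally called a microsatellite; it is exposed as
`min_dinuc_units`. A masked insertion is judged by its anchor base and the
following base, since that is the reference span its placement can slide
over.

### Population exclusion

Carrier classes are assigned by exact lookup of the joint genotype at two
tag SNPs in a user-supplied rule table; the table must cover all nine
joint genotypes exactly once, and individuals with missing tag genotypes
become `UNKNOWN` and never enter carrier counts. The exclusion then drops
any candidate carried by strictly more than `max_negative_carriers`
(default 10) `NEGATIVE`-class individuals. Counting is per individual
(dosage $\ge 1$) by default because that is the operationally precise
phrasing of the protocols this stage models; a `count_chromosomes` switch
sums dosages instead, and the two can differ by up to a factor of two.
Candidates absent from the population's site list are retained with an
unobserved count: a filter that cannot be evaluated must not drop
candidates. The tag-to-class mapping itself is study-specific knowledge
and deliberately not hard-coded; the generator emits a matching table.

### Enhancer calling

An active enhancer is an H3K4me1 peak overlapping at least one H3K27ac
peak by `min_overlap` (default 1 bp); its interval is the union of the
H3K4me1 peak with all overlapping H3K27ac peaks. The union is used because
peak callers fragment broad regions differently between marks, and the
biological element extends across both signals. H3K4me1 peaks without
H3K27ac support are reported as inactive elements. CpG-island overlap and
methylation status are annotated when a CGI track is provided;
`require_unmethylated_cgi = TRUE` makes unmethylated CGI support a
requirement for activity, the stricter definition. DNase peaks are
filtered by three strict thresholds (−log10 p > 50, signal > 30,
score > 120), with a rescue pass keeping near-miss peaks lying strictly
less than 1 kb (edge to edge) from a passing peak; DHS is treated as
supporting evidence, never as a gate on the enhancer call. All interval
I/O is BED-convention 0-based half-open; variants are 1-based (VCF
convention), and containment converts explicitly — a SNP at 1-based
position $p$ lies in $[s, e)$ iff $s \le p - 1 < e$.

### Motif gain/loss scanning

Variants are scored against a PWM library as log-odds in bits,
$\sum_i \log_2 m_i(b_i) / \pi(b_i)$, over every placement overlapping the
variant on both strands, for the reference and alternate alleles
separately. A *gain* means the alternate allele's best score passes the
score threshold while the reference's does not; a *loss* is the converse.
The default threshold per PWM is the empirical score whose null exceedance
probability is $10^{-4}$ under i.i.d. background sequence, the
conventional motif-scan operating point; it is computed by seeded sampling
of $10^5$ background windows.

Significance is assessed empirically: the window around the variant on the
gaining allele is dinucleotide-shuffled (Altschul–Erickson, preserving
exact dinucleotide counts and endpoints) `n_null` times and re-scanned;
$p = (1 + \#\{\text{null best} \ge \text{observed best}\}) / (1 + n_\text{null})$,
followed by Benjamini–Hochberg correction across all (variant, PWM) pairs.
The shuffled window extends `null_flank` (default 30) bases on each side
of the variant rather than just the motif length: shuffling only the
motif-sized context of a genuine site leaves the null dominated by the
site's own dinucleotide chain, which can reassemble high-scoring windows
and makes the null spuriously hot. The wider window dilutes the motif
content while leaving the null exchangeable for truly null variants, so
false-positive control is unaffected (and is verified by simulation in the
test suite).

## The synthetic study generator

`simulate_locus_study()` draws every pipeline input from one seed, with the
defaults set to the study design the package models:

* a 179,000 bp locus sequenced on 4 risk and 11 non-risk haplotypes;
* 20 planted risk-specific variants (each on ≥ 3 risk and 0 non-risk
  haplotypes; ~70% SNPs, the rest 1–10 bp indels planted left-aligned), 30
  shared variants, and 10 decoys placed inside homopolymer (6–8 nt) or
  dinucleotide-repeat (3–5 units) tracts written into the reference with
  pattern-breaking flanks so the repeats are maximal;
* of the specific variants, 5 are additionally carried by 12 (> 10)
  negative-class population individuals and 3 lie inside true enhancers —
  so the expected funnel is 20 → 15 → 3;
* 9 H3K4me1 peaks of which exactly 3 co-occur with H3K27ac at the truth
  enhancer intervals (the peak pair is constructed so its union equals the
  truth interval); DNase peaks straddle the score thresholds, including a
  rescueable near-miss and a far near-miss that must be dropped; each
  enhancer overlaps an unmethylated CGI, and methylated/partially
  methylated CGIs sit elsewhere;
* a population panel of 7 risk-positive, 4 confounder-positive and 46
  negative individuals with a consistent tag-rule table;
* a genotype panel of 4,803 individuals at 373 markers over a 357,744 bp
  region containing a central 179,000 bp conserved block, so the LD stage
  recovers a block span close to 179 kb by construction;
* 5 PWMs of length 12 with column dominance 0.90–0.98 plus one invariant
  core column (0.999), as in strong transcription-factor motifs.

Within each genotype-panel LD block, derived alleles are assigned to clades
of a random founder genealogy (laminar subsets, as under infinite sites),
which guarantees the four-gamete condition holds and hence within-block
$|D'| = 1$ before recombination; the within-block D′ target below 1 is
approached by founder-switch recombinants at rate $2(1 - \text{target})$.
Across blocks, haplotypes are drawn independently, so between-block D′ is
near zero. Target MAFs are drawn uniformly from `maf_range` and realized
as the closest clade frequency (allele labels may be flipped; $|D'|$ is
invariant under relabeling).

The planted motif gain embeds a degraded consensus inside an enhancer: the
variant column carries a mismatch at the motif's most informative position
(restored by the alternate allele), and further permanent mismatches are
chosen by subset search so the reference allele scores below the motif
threshold with the alternate allele as strong as possible. The generator
verifies that no low-complexity tract covers the planted position, since
the mask stage would otherwise remove it. Planted indels are
rejection-sampled to be already left-aligned, checked with the same
normalization rule the extractor uses, so truth positions are canonical by
construction.

**What the generator does not emulate.** Real MHC polymorphism density
(one variant every ~30 bp on diverged haplotypes, versus isolated planted
events here), recombination maps and coalescent genealogies, alignment
errors from the upstream aligner, soft-clipped or low-quality sequence,
and imputation uncertainty in the population genotypes. Passing the
planted-recovery tests therefore demonstrates the correctness of the
pipeline's logic — coordinates, normalization, set algebra, counting rules,
statistics — not robustness to the noise sources of real data.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(locus_length = 30000, n_individuals = 100, n_markers = 60,
                  genotype_region_length = 30000, seed = 42)
study <- simulate_locus_study(cfg)
fit <- run_pipeline(study$panel, study$labels,
                    population = study$population,
                    tracks = study$tracks, pwms = study$pwms,
                    params = pipeline_params(n_null = 1000), seed = 9)
fit
glance(fit)
tidy(fit) |> filter(n_enhancers > 0)
autoplot(fit)
```

The funnel for this configuration is 60 extracted → 50 after masking
(10 decoys removed) → 20 risk-specific → 15 after population exclusion →
3 enhancer-resident, and the planted motif gain is recovered at q < 0.05.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run entirely on synthetic data at
desk scale, chosen as the smallest sizes at which each property is
meaningfully exercised: the specificity rule is checked against brute force
over all $2^{15}$ presence patterns of a 4 + 11 panel; the EM estimator
against a phase-enumeration/profile-likelihood oracle over every 3×3
genotype table with up to 8 individuals; planted-variant recovery over 20
seeded 179 kb studies; LD-block recovery on 45-marker, 250-individual
panels over 20 seeds; and the motif FDR on 50 seeded pure-null simulations
with 5,000 shuffles per event. The acceptance script additionally runs the
LD stage at full study scale (4,803 × 373).

## Known limitations

* Multi-allelic markers are not supported in the LD stage; $r^2$ and other
  LD statistics are out of scope.
* The variant extractor consumes an existing alignment; it does not align.
* MNP merging requires exact co-segregation across all members; partially
  shared multi-base substitutions stay split into SNPs, which can make
  per-variant counts differ from analyses that merge more aggressively.
* The empirical FDR machinery assumes contexts long enough to shuffle
  (more than two bases) and treats ambiguous bases as unscorable rather
  than marginalizing over them.
* The block-growth rule is greedy and symmetric; a block whose conserved
  fraction dips just below `min_fraction` at one flank stops growing in
  that direction even if a larger window further out would qualify again.
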