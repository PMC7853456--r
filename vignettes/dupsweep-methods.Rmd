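---
title: "Methods: copy-number-aware association and selection scans at duplicated resistance loci"
author: "dupsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number-aware association and selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupsweep)
```

# The problem

Target-site insecticide resistance in *Anopheles* mosquitoes is often not
a simple SNP. At the *Ace1* locus, a resistance substitution in the
acetylcholinesterase gene segregates inside a large tandem duplication,
so a single chromosome can carry several gene copies — some wild-type,
some mutant. Diploid genotype calls (0/0, 0/1, 1/1) cannot express "two
mutant copies out of five", phasing breaks down inside the duplication,
and naive allele-frequency statistics mis-state both the association with
the phenotype and the selective history of the locus.

`dupsweep` implements the full analysis chain for this situation:
estimating per-sample mutant dosage from read counts, modelling the
phenotype as a function of dosage, scanning for selection and
introgression around the locus, characterising haplotype structure
through diploid-region proxies, and running a reference-free k-mer
association as a cross-check that is blind to alignment artefacts.

# Dosage estimation from read fractions

For a sample with locus copy number $C$ (an input, e.g. from an upstream
CNV caller or qPCR) and $a$ of $a+r$ reads supporting the resistance
allele at the focal SNP, the number of resistant copies is

$$\hat S = \arg\min_{S \in \{0,\dots,C\}} \left| \frac{a}{a+r} - \frac{S}{C} \right|.$$

Ties are broken toward smaller $S$, i.e. conservatively toward wild type;
the data cannot distinguish the tied values and the smaller call never
overstates resistance. A sample with zero depth is an explicit error
("no depth"), never a silent $S = 0$: absence of evidence about dosage
must not become evidence of wild type. The same estimator accepts an
allelic ratio from any source (e.g. a FAM/HEX fluorescence ratio), since
only the fraction enters.

At 30× depth the binomial noise of the read fraction is the limiting
factor: neighbouring dosage hypotheses $S/C$ are separated by $1/C$, so
accuracy falls as $C$ grows. The test suite pins the regime the method is
meant for: at mean depth 30 and $C \le 4$, at least 90% of simulated
samples get their true $S$ back (the observed rate on the fixed-seed
cohort of 500 is 0.925).

The configuration labels follow the biology: `WT_SINGLE` (no duplication,
no resistant allele), `SNP_ONLY` (resistant allele without duplication —
a case the duplication-centred label set would otherwise leave
unnamed), `HET_DUP` (duplication carrying both alleles), `HOM_DUP_ALT` /
`HOM_DUP_WT` (duplication with only one allele type). The classification
rule `resistant iff S > 0 and S >= C − S` encodes the observation that
survival requires at least parity of mutant with wild-type copies.

# Association statistics

2×2 tables (carrier vs wild type × alive vs dead) are tested with
Fisher's exact test (`stats::fisher.test`; two-sided by the
probability-at-most-observed rule) and summarised with the Woolf odds
ratio. The Haldane–Anscombe correction adds 0.5 to *every* cell whenever
requested, not only when a zero is present — the correction is a
smoothing of the estimator, not a patch for degenerate tables, and
applying it uniformly keeps the reported value a deterministic function
of the table.

Dose–response models are binomial GLMs with logit link via `stats::glm`
(IRLS, deviance tolerance 1e-10, up to 100 iterations). The wrapper adds
what field reports need: odds ratios with Wald 95% CIs, the model BIC,
a likelihood-ratio $\chi^2$ p-value against the intercept-only null, and
two flags. `degenerate` marks a constant response; `separation` marks any
non-intercept |coefficient| above 15 on the logit scale, where the
unpenalised MLE is effectively infinite. Separated fits are *reported*
(their odds ratios print as astronomically large numbers, faithful to
the likelihood) rather than clipped or refused, because in small resistant
cohorts complete separation is a real and informative outcome.

Model reduction is backward elimination under BIC: refit with each
remaining term removed, drop the removal that lowers BIC most, stop when
none does. Ties break by column order and perfectly collinear (aliased)
columns are dropped first, so the procedure is deterministic — a property
worth having when the minimal model itself is a reported result.

# Windowed scans

All windows count *consecutive variants* (not base pairs), the natural
unit when variant density varies along the genome; trailing partial
windows are dropped. Internally windows are 0-based half-open index
ranges; all input/output coordinates are 1-based inclusive.

**Hudson's F<sub>ST</sub>** uses the unbiased per-site estimator
(numerator $(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)$,
denominator $p_1(1-p_2)+p_2(1-p_1)$) and ratio-of-sums aggregation within
windows, which is stable where per-site denominators are small. A
consequence the tests document: comparing a population with itself gives
a slightly *negative* estimate at finite $n$, so identities that hold for
the parameter (e.g. PBS of identical populations being zero) hold only
approximately for the estimator.

**PBS.** Pairwise window F<sub>ST</sub> values are transformed to branch
lengths $T = -\log(1 - F_{ST})$ (clamped at $1 - 10^{-12}$ before the
log) and combined as $\mathrm{PBS}_A = (T_{AB} + T_{AC} - T_{BC})/2$.
Values are standardised to unit variance over the scanned region, given
two-sided normal p-values, and FDR-corrected; a window is called under
selection in the focal population when its standardised PBS is positive
and its FDR is below the threshold (default 0.001). The default window
is 1,000 variants.

**FDR.** Benjamini–Hochberg is the default. A two-component
empirical-null local FDR (null proportion from the central interquartile
mass, mixture density by Gaussian kernel) is available as
`method = "local"` for users who prefer local error rates; the choice and
threshold are exposed because local-FDR estimators carry tuning that a
scan's conclusions should not silently depend on.

**Block jackknife.** Genome-wide averages of ratio statistics
(F<sub>ST</sub>, D) violate independence across sites through linkage, so
standard errors come from a delete-one block jackknife over consecutive
blocks (default 100 variants for D):
$SE^2 = \frac{B-1}{B}\sum_i (\hat\theta_{(-i)} - \bar\theta)^2$.

**LD pruning and PCA.** Rogers–Huff $r$ (Pearson correlation of 0/1/2
dosages over complete pairs) drives pruning in 500 bp windows advanced by
200 bp at $|r| > 0.1$, repeated for 10 passes. PCA centres each variant
dosage and scales by $\sqrt{p(1-p)}$ (Patterson scaling) before SVD;
monomorphic variants are excluded with a warning and missing dosages are
mean-imputed for the decomposition only.

# Haplotype structure through tagging variants

Phased haplotypes are unavailable inside a duplication, but short diploid
segments (internal deletions, diverged paralogs) survive. The package
therefore looks for *tagging variants*: phased-set variants within the
scan region whose Rogers–Huff $|r|$ with the focal SNP exceeds 0.95 and
whose surrounding window is effectively diploid — per-window
haplotype-score and normalised-coverage tracks both within a tolerance
(default 0.25) of 2. These tracks are plain TSV inputs; the package does
not recompute them from alignments.

Around a tagging variant (default ±300 bp), identical haplotypes are
collapsed into clusters, cluster consensus sequences get pairwise Hamming
distances, a minimum spanning tree is built, and tree edges of distance
> 1 are removed, so the displayed network connects clusters separated by
exactly one substitution. The MST uses Kruskal's algorithm with edges
sorted by (weight, node index, node index): equal-weight ties always
resolve identically, making networks reproducible run to run.

Sweep profiles compute, in windows of 500 variants with 20% overlap
(step = window × 0.8; the alternative reading, step = 20% of window, is a
parameter), Garud's $H_1 = \sum p_i^2$,
$H_{12} = (p_1+p_2)^2 + \sum_{i\ge3} p_i^2$, $H_2 = H_1 - p_1^2$ and
$H_2/H_1$, plus unbiased haplotype diversity
$(1-\sum p_i^2)\,n/(n-1)$, where $p_i$ are whole-window haplotype-cluster
frequencies computed over the analysis subset (e.g. tagging-allele
carriers only). EHH from a core variant is the probability two random
haplotypes are identical over the span from the core:
$\sum_c \binom{n_c}{2} / \binom{n}{2}$; it starts at 1 and never
increases outward. Flank averages (e.g. over ±5 kb of the duplication
breakpoints) carry leave-one-haplotype-out jackknife errors.

# Introgression

Patterson's D is computed from population allele frequencies (not single
genomes), since cohort frequencies are what the upstream data provide:
per site, $\mathrm{ABBA} = (1-p_A)p_Bp_C(1-p_O)$ and
$\mathrm{BABA} = p_A(1-p_B)p_C(1-p_O)$; a window's D is
$\sum(\mathrm{ABBA}-\mathrm{BABA}) / \sum(\mathrm{ABBA}+\mathrm{BABA})$
(5,000-variant windows at 20% step by default). Outgroup-polymorphic
sites are retained with $p_O$ as given — they simply down-weight
themselves. Note the orientation: gene flow from C into A inflates BABA
and drives D *negative*; swapping A and B flips the sign exactly.

Region averages are ratio-of-sums over all sites in the region, not means
of window values — matching the jackknife construction and avoiding
small-window instability — with block-jackknife SE, $Z = D/SE$ and
two-sided normal p.

To orient the *direction* of introgression of a duplication, pairwise
branch lengths among three groups (duplication carriers, wild-type
population A, wild-type population B) are decomposed as
$L_X = (T_{XY} + T_{XZ} - T_{YZ})/2$ in non-overlapping 100-variant
windows: the wild-type group whose branch to the duplicated haplotypes is
*shorter* is the likely donor, and the identity $L_X + L_Y = T_{XY}$
holds per window by construction.

# k-mer association

Counting is canonical: each 31-mer (k configurable, odd, ≤ 31) is
identified with the lexicographic minimum of itself and its reverse
complement, erasing strand. Codes are the 2-bit packing (A=0, C=1, G=2,
T=3, first base most significant), carried exactly as a hi/lo pair of
sub-2^32 integers and exposed as decimal strings, since a 62-bit code
exceeds R's exact-integer range; numeric order on codes equals
lexicographic order on sequences. k-mers spanning a non-ACGT character
are skipped and reads shorter than k are tallied, not fatal.

The variance filter retains a k-mer iff it is present (count > 0) in at
least 3 samples *and* absent in at least 3 — presence needs no minimum
count. Normalised frequencies divide each count by the per-sample total
of *retained* k-mer counts (the post-filter reading of "variant k-mers
per sample"; the pre-filter denominator is available as an option since
either reading is defensible). Association is Spearman's rank correlation
with midranks against the 0/1 phenotype, with an exact permutation p over
the $\binom{n}{n_1}$ distinct phenotype assignments when $n \le 10$ and
the t-approximation otherwise, followed by FDR control (threshold 0.001).
Constant-frequency k-mers have no defined rank correlation and are
excluded with a tally.

Significant k-mers are assembled greedily: the pair with the longest
perfect suffix/prefix overlap ≥ 10 bp (either orientation; containments
absorbed first; ties by lexicographic order) is merged until no pair
overlaps. Every member k-mer remains a substring of its contig, and
member counts are conserved, so the assembly is auditable. Contigs are
placed on a reference by exact substring search on both strands —
appropriate for the error-free reads the generator emits; inexact
alignment is deliberately out of scope.

Because both k-mer frequency and locus copy number correlate with the
phenotype, an unlinked but phenotype-associated contig would correlate
with copy number spuriously. The diagnostic residualises contig frequency
(mean normalised frequency of member k-mers) and copy number about their
group means *within each phenotype class*, pools the residuals, and
reports Pearson's r with its t-based p: only physical linkage survives
the adjustment.

# The synthetic generators

The generators produce data with exactly the structure the estimators
assume — no more. All draws come from one seeded stream per call
(the caller's RNG state is saved and restored), identical config + seed
gives identical output, and every latent value is emitted in a truth
table so parameter-recovery tests never peek at internals.

* **Cohort** (`simulateCohort`): copy number $C$ from a configurable
  distribution over {2..5} (default masses 0.35/0.30/0.25/0.10 — the
  within-cohort distribution of $C$ is not something the motivating data
  pin down, so it is config-exposed); resistant dosage
  $S \mid C \sim \mathrm{Bin}(C, 0.44)$ (the focal allele's cohort
  frequency); focal-site depth Poisson with mean 30 truncated at 1;
  alternate reads $\sim \mathrm{Bin}(\mathrm{depth}, S/C)$; survival
  $\sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(-2.5 + 1.2\,S))$, i.e.
  ~8% survival at $S=0$ rising to ~88% at $S=4$, a realistic dose-response
  for a strong resistance allele. Read fractions are simulated at the
  single focal SNP only, because that is the only quantity the dosage
  estimator consumes.
* **Sweep** (`simulateSweep`): a copying model, not a coalescent. Swept
  haplotypes copy one core haplotype, switching permanently to an
  independent background draw with per-site probability `recombScale`
  walking away from the focal variant (identity decays geometrically with
  distance) plus per-site mutation; background haplotypes are independent
  draws from Beta(0.8, 0.8) site frequencies. The statistics under test
  (H12, EHH, diversity) depend only on haplotype-identity structure,
  which this model controls directly. Setting the swept frequency to 1 or
  the recombination scale to 0 produces the degenerate fixtures the
  boundary tests need.
* **Three populations** (`simulateThreePop`): Balding–Nichols frequencies
  about a shared ancestral Beta draw, with per-population drift F
  (defaults A = B = 0.05, C = 0.25, O = 0.5: two close ingroups, a
  diverged donor, a distant outgroup). Inside an optional tract,
  population A's frequency becomes $(1-m)p_A + m\,p_C$. Note this
  *introgression* tract is distinct from a *differentiation* tract:
  mixing A toward C lowers PBS of A; selection-scan spike tests instead
  redraw A with extra drift about its own latent frequencies.
* **Reads** (`emitReads`): error-free reads tiled at uniform random
  offsets to a target depth; duplication carriers draw from both the
  reference locus and a junction-containing allele, so junction-spanning
  k-mers occur only in carriers.

What the generators do **not** emulate: sequencing error, indels,
mapping bias, linked selection beyond the single swept core, demographic
history, and within-duplication read mis-assignment. Passing tests
therefore certify the statistical machinery under its own assumptions —
they do not certify robustness to the alignment and calling artefacts of
real data, which enter this pipeline only through its inputs.

# Numerical conventions and problem sizes

* Missing genotypes are excluded from allele counts (denominators
  shrink); nothing is imputed, matching the segregating-site filters the
  statistics assume.
* Variants without read depths cannot feed dosage estimation; callers get
  an explicit "no depth" error.
* Multiallelic VCF records are rejected under strict mode (default),
  since every statistic in scope is defined for biallelic sites.
* $F_{ST} \ge 1 - 10^{-12}$ is clamped before $-\log(1-F_{ST})$; windows
  with an undefined statistic (zero denominator, under-called population)
  are `NA`-flagged, never silently dropped.
* Scan standardisation requires ≥ 20 windows and errors on zero variance.
* The test and acceptance runs use deliberately modest problem sizes —
  cohorts of a few hundred samples, scans of 50,000 sites, haplotype sets
  of ~100, k-mer cohorts of 20 samples over ~1.5 kb loci, and 20–100
  seeded replicates per power/calibration claim. These sizes were chosen
  so the full suite exercises every claim in minutes while keeping Monte
  Carlo margins (e.g. ≥ 95% recovery thresholds) comfortably away from
  their observed rates.

# Known limitations

* Copy numbers are inputs; the package does not call CNVs from coverage.
* Exact-match placement cannot place contigs across variants absent from
  the reference; such contigs are reported unplaced rather than
  soft-aligned.
* The local-FDR estimator is intentionally simple (Gaussian kernel,
  central-mass null proportion); for publication-grade local FDR on real
  scans a dedicated estimator should be substituted via the exposed
  method switch.
* Frequency-based D assumes within-population Hardy–Weinberg sampling of
  alleles; heavily inbred cohorts would need genotype-aware weighting.
* The dosage estimator treats the read fraction as binomial; strong
  reference bias at the focal SNP would shift $\hat S$ systematically and
  should be corrected upstream.
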