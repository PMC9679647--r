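---
title: "Methods: tumor-only TMB with an optimized SGZ workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-only TMB with an optimized SGZ workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Tumor mutational burden (TMB) — the number of nonsynonymous somatic
mutations and indels per megabase of examined genome — predicts response
to immune checkpoint inhibitors. Computing it normally requires a
matched normal sample to subtract germline variants. When only tumor
tissue is available, germline variants must be removed computationally.
`tmbforge` implements a tumor-only TMB workflow in four stages:

1. **False-positive filters** — four hard-coded exclusion predicates
   over caller INFO/FORMAT tags (oversized alleles and non-somatic
   status; lenient thresholds for hotspot variants; false-positive- and
   germline-database tags; a stringent fifteen-clause artifact screen
   for everything else).
2. **Somatic–germline–zygosity (SGZ) classification** — a purity/ploidy
   copy-number model assigns each variant to the somatic or germline
   allele-fraction family.
3. **Background-library filter** — a panel of normals from the target
   population removes recurrent germline variants that survive
   classification. This step is what distinguishes the *optimized*
   workflow: population-specific germline variation (here, an
   East-Asian-style background) is poorly covered by classifiers tuned
   on other populations.
4. **TMB** — count surviving nonsynonymous SNVs and coding indels
   inside the panel BED and divide by the footprint in Mb.

A paired mode (`tmb_paired()`) runs the same filters on matched
tumor/normal calls and serves as the reference arm; `select_cutoff()`
and friends determine the clinically optimal TMB threshold from
response and survival data.

# The SGZ model

A specimen with tumor purity $P$ and tumor ploidy $\Psi$, in which a
locus has integer copy number $C$ in tumor cells (and 2 in admixed
normal cells), has expected coverage log-ratio

$$\mathrm{lr}(C) \;=\; \log_2\!\frac{P\,C + 2(1-P)}{P\,\Psi + 2(1-P)}.$$

An allele carried by $m$ of the $C$ tumor copies and $g \in \{0,1,2\}$
of the normal copies has expected allele fraction
$\big(P\,m + g(1-P)\big)\,/\,\big(P\,C + 2(1-P)\big)$: germline het
$g=1$ with $m \in \{M,\,C-M\}$ ($M$ = minor allele count), germline hom
$g=2$ with $m=C$, somatic $g=0$ with multiplicity $m=k$.

## Segmentation

Binned coverage log-ratios are segmented by exact least-squares
changepoint partitioning (an $O(n^2)$ optimal-partitioning dynamic
program with a BIC-type penalty, noise scaled by a robust
successive-difference estimate). We use the exact program rather than
greedy binary splitting because greedy splitting provably misses
changepoints in alternating gain/loss profiles — the candidate first
split can fail the acceptance test even though the full segmentation is
far better.

Coverage alone cannot separate regions with equal total copy number but
different allelic composition (balanced diploid vs copy-neutral LOH),
so a second pass (`refine_segments_af()`) splits each coverage segment
at changepoints of the folded heterozygous-SNP allele fraction. Without
this pass, merged mixed-$M$ segments poison both the fit and the
per-variant germline expectations.

## Purity/ploidy fit

`fit_purity_ploidy()` grid-searches $P \in \{0.05,\dots,1.00\}$ (step
0.01) × $\Psi \in \{1.0,\dots,6.0\}$ (step 0.05). For each candidate,
every segment is assigned the integer $(C, M)$ state minimizing the
squared log-ratio error plus the squared error of the *unfolded* het-SNP
allele fractions against the nearer of the two allele-configuration
expectations. Folding (mirroring) allele fractions is deliberately
avoided in the objective: the folded mean of a balanced segment is
biased below 0.5 by roughly $\sigma\sqrt{2/\pi}$, which systematically
favors spurious slightly-unbalanced states.

Three regularizers address genuine degeneracies of this model family —
each is small enough that a real signal overrides it, and each is
configurable:

* **Near-diploid ploidy prior**, $0.002\,(\Psi-2)^2$. The
  whole-genome-doubled solution $(2C, 2M, 2\Psi)$ at a compensating
  purity reproduces segment log-ratios and het allele fractions almost
  exactly; the data cannot resolve it, and the prior breaks the tie
  toward the lower-ploidy solution, as allele-specific copy-number
  tools conventionally do.
* **Aberrant-state prior**, $0.003\,(C-2)^2$ per segment. At low
  candidate purity the integer copy levels lie arbitrarily close in
  log-ratio space, so a low-purity solution can absorb log-ratio noise
  by assigning far-from-diploid states.
* **Homozygous-deletion penalty**, $0.05$ per $C=0$ segment. At low
  purity a fully deleted segment is indistinguishable from diploid
  (only normal DNA is observed: AF 0.5, modest log-ratio drop), opening
  a spurious solution with most of the genome deleted; biologically,
  homozygous deletions are rare and focal.

Ties in the $(C, M)$ assignment break toward lower $C$ (parsimony);
grid ties break toward lower $P$, then lower $\Psi$. After the scan,
$\Psi$ is refined once to the bin-weighted mean of the assigned $C$, so
the reported ploidy is consistent with the reported states. A flat
profile (all segments diploid-balanced-like) is flagged
`identifiable = FALSE` and returned at the configured default purity
(0.5) rather than an arbitrary arg-min; in the pipeline such samples
fall back on an allele-fraction estimate of purity (below).

## Classification

For each filtered variant, the *error log-ratio* is the absolute
difference between the variant-level log-ratio and its segment's
log-ratio. The variant-level log-ratio normalizes the variant's local
tumor depth the same way as the coverage bins: $\log_2(d/D_0)$ with
$D_0$ chosen so the sample-median variant log-ratio matches the median
bin log-ratio.

`classify_variants()` labels each variant by the nearest
expected-allele-fraction family, subject to (defaults in parentheses):

* observed AF > `af_germline` (0.9) → **germline** (homozygous
  signature);
* error log-ratio > `tau_lr` (0.5) → **ambiguous** (the copy-number
  model does not describe this locus);
* distance to the nearest family > `tau_af` (0.1) → **ambiguous**;
* nearest somatic and germline expectations closer than `tau_sep`
  (0.04) → the observation cannot arbitrate; the call falls back on
  population evidence: key present in the background library →
  **germline**, absent → **somatic**, no library supplied →
  **germline** (conservative);
* otherwise the nearer family wins, ties to germline.

Somatic multiplicities considered are $k = 1,\dots,C-1$ (and $k=1$ for
$C=1$). A clonal mutation on *all* $C$ copies is observationally
identical to the homozygous-germline direction; allowing it lets
germline hets at AF 0.5 leak into the somatic family whenever
$P \approx 1/k$, so it is conservatively ceded to germline.

`tau_sep` reflects the binomial noise of allele fractions at
$\sim$1000× depth (s.d. ≈ 0.016 at AF 0.5): families closer than
≈ 2.5 s.d. cannot be distinguished by a single observation. The
degenerate zone is real and purity-dependent — e.g. a clonal somatic
variant vs a het on the deleted allele of an LOH segment coincide at
purity 0.5, and somatic-$k$ vs germline-$m{=}k$ states converge as
purity approaches 1.

## Flat genomes

When the copy-number profile carries no purity signal (all segments
balanced diploid), clonal somatic variants on the diploid background
sit at AF $P/2$, so `estimate_purity_af()` recovers purity as twice the
median AF of the sub-heterozygous cluster of variants *absent from the
background library*. The fallback engages only for unidentifiable fits
with at least 5 cluster members.

# Background library

`build_library()` counts, per normalized variant key
(`chrom:pos:ref:alt` after shared-suffix/prefix trimming), the number of
normal samples carrying the variant (deduplicated within sample).
`background_filter()` default policy removes a call iff its key occurs
**more than 5** times in the library **and** its observed allele
fraction is ≤ 0.9 — high-AF variants are retained. The retention clause
is ambiguous in isolation (retained as what?); we read "frequency" as
the observed tumor allele fraction and retain literally, because
high-AF germline homozygotes are already caught by the classifier's
AF > 0.9 rule. The alternative reading — high AF implies homozygous
germline, so drop — is available as `policy = "high_vaf_germline"`. The
threshold 5 is an absolute count, not a fraction of library size, and
is configurable.

Since alleles are keyed reference-free, normalization trims shared
allele suffixes then prefixes (keeping one anchor base). Full left
alignment would require the reference sequence; representations that
differ by bases *outside* both alleles cannot be unified, which is
acceptable here because library and tumor calls come from the same
caller conventions.

# TMB

`compute_tmb()` counts records that are nonsynonymous — missense,
nonsense or splice SNVs, plus frameshift/inframe coding indels
(configurable class lists) — and fall inside the merged BED footprint,
divided by the footprint in Mb. Hotspot variants are counted by default
(`count_hotspots = FALSE` reproduces assays that exclude known
drivers). The footprint is always taken from the supplied BED, never
hard-coded.

# Cutoff determination

Durable clinical benefit (DCB) is CR/PR or SD lasting ≥ 24 weeks; NDB
is SD < 24 weeks or PD. `select_cutoff()` sweeps candidate cutoffs
(default integers 1–20 mut/Mb), computes Youden $J$ of the rule
`TMB >= cutoff` against DCB, and picks the maximizer (ties toward the
smaller cutoff); the log-rank statistic at each evaluable candidate is
reported as corroboration, mirroring the ROC-then-log-rank presentation
convention. A log-rank-maximizing criterion is available but flagged
for multiplicity. AUC is the Mann–Whitney probability (ties ½);
Kaplan–Meier, log-rank and Cox (Efron ties) delegate to the survival
package; group contrasts use Welch's t and Fisher's exact test. No
multiplicity correction is applied anywhere, matching common practice
in this setting; significance is conventionally 0.05.

# The simulator

`simulate_cohort()` produces the test bed: paired and tumor-only call
sets with known truth. Defaults describe the study conditions the
package is tested under:

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 62 | tumor/normal pairs |
| `footprint_mb` | 1.4 | contiguous panel, 10 equal CN segments |
| `n_background_normals` | 100 | panel-of-normals cohort |
| `germline_spectrum` | AF 0.5/0.25/0.1/0.05/0.01 at 600/700/1500/2500/11000 sites | ~1500 carrier sites per sample |
| `n_private_germline` | 20 | rare variants absent from the catalogue |
| `somatic_rate_range` | 1–30 mut/Mb | per-sample uniform draw, private clonal (k = 1) mutations |
| `purity_range` | 0.4–0.9 | uniform |
| `cn_states` | (2,1) 60%, (2,0) 8%, (1,0) 10%, (3,1) 14%, (4,2) 5%, (4,1) 3% | per-segment states |
| `depth_tumor` / `depth_normal` | 1027 / 455 | Poisson means |
| `lr_noise_sd` | 0.1 | per-bin log-ratio noise |
| `indel_frac`, `hotspot_frac` | 0.1, 0.03 | somatic composition |

Depths are Poisson around the mean scaled by local copy mass; alt reads
are Binomial(depth, expected AF) with the expected AF taken from the
SGZ formulas given the true $(P, C, M)$ — so the generator and the
classifier share the forward model by construction, and classification
accuracy measures the *inverse* problem (segmentation, fit,
thresholds), not model mismatch. Variants with fewer than 3 supporting
reads are not "called". Filter tags are populated with passing values;
`inject_artifacts()` adds records that each trip exactly one filter
clause for engine tests.

The clinical layer draws DCB from a logistic model in true TMB
(center 7 mut/Mb, slope 1.0 per mut/Mb — an odds ratio of ~2.7 per
mut/Mb near the threshold, a deliberately informative but not
deterministic signal), OS/PFS from exponentials with hazard ratio 2.5
between TMB groups (median 10/25 months OS), and independent
exponential censoring (~30%). These values are fixed design choices;
none is derived from patient data.

**What the simulator does not emulate:** sequencing-error substitution
spectra, FFPE artifacts, mappability and GC coverage waviness,
subclonal somatic populations, segmentation-scale CN complexity of real
genomes, linkage between germline sites, or panel gene content.
Passing the simulation suite therefore shows the pipeline solves the
stated inverse problem under its own noise model at realistic depths —
it does not certify performance on real tumors.

# Problem sizes and runtime

The test suite and acceptance analysis use: a 62-sample cohort on a
1.4 Mb panel (~1500 variants/sample, 140 coverage bins) with a
100-normal library; 50 simulated genomes for purity/ploidy recovery;
10⁴ random records for the filter-engine oracle; 4000 permutations for
the log-rank reference; 5 replicate cohorts of 66 patients for cutoff
recovery. The full cohort analysis runs in about a minute on one CPU;
the grid fit is the dominant cost (~1 s/sample).

# Known limitations

* Purity near 0.5 with copy-neutral LOH, and purity above ~0.9 on
  aneuploid segments, are genuinely degenerate for single-observation
  classification; calls there lean on the background library and a
  residual error remains.
* The ploidy prior will bias genuinely high-ploidy (≥ 3.5) genomes
  toward half-ploidy solutions when allele fractions are uninformative.
* Reference-free key normalization cannot unify all representations of
  the same indel (see above).
* The filter engine hard-codes the four printed predicates; clauses can
  be disabled but not re-expressed (an expression-language engine is a
  non-goal).
* The BIAS strand-code comparison reads the first two numeric codes of
  the tumor BIAS string; the exact encoding convention of that tag is
  not standardized, and the chosen interpretation is documented rather
  than asserted.
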