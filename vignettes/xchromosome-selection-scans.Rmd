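---
title: "Selection-signature scanning on the X chromosome with xselscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-signature scanning on the X chromosome with xselscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xselscan)
```

## The problem

Local adaptation leaves footprints on the genome: a favourable allele rising
in frequency drags its haplotype background with it, depressing variation
around the selected site. On the X chromosome this signal is both
under-studied and structurally special. Outside the small pseudo-autosomal
region (PAR), males are hemizygous — their genotype *is* their haplotype, with
no phasing uncertainty — while females are diploid and can carry runs of
homozygosity (ROH). `xselscan` exploits this asymmetry: it runs three
established within-population scans and one richness-based scan that uses
only male haplotypes, on SNP-array data for a focal population (e.g. a sheep
metapopulation) plus a small outgroup (e.g. mouflon) that polarizes alleles
into ancestral and derived states.

The four scans are:

* **eROHi** — extreme ROH islands. ROH are called in diploid females; SNPs
  covered by ROH in an unusually large fraction of females mark candidate
  sweeps.
* **iHS** — the integrated haplotype score: the log-ratio of integrated
  extended haplotype homozygosity (EHH) between ancestral and derived alleles
  at each SNP, standardized within derived-allele-frequency bins.
* **nSL** — the same contrast with haplotype length measured in number of
  segregating sites instead of base pairs, which removes the dependence on a
  recombination map.
* **HRiD** — haplotype richness drop. The effective number of haplotypes
  n_h = 1 / sum(p_k^2) is computed in sliding windows of hemizygous male
  haplotypes; a window whose richness collapses relative to its two
  neighbours scores high.

## The HRiD statistic

For window $w_i$ with effective haplotype number $n_h(w_i)$,

$$\mathrm{HRiD}(w_i) = \frac{n_h(w_{i-1}) + n_h(w_{i+1})}{2\,n_h(w_i)},$$

with edge variants that reuse the single available neighbour twice
($2 n_h(w_2) / 2 n_h(w_1)$ for the first window and its mirror image for the
last), so sweeps at the chromosome ends remain detectable. Under neutrality
the flanking and focal richness are exchangeable and HRiD fluctuates around
1; a hard sweep that collapses one window's richness inflates the ratio.
Windows are defined in SNP counts (default 70 SNPs, step 35) rather than base
pairs because n_h values are only comparable when computed over the same
number of SNPs; a trailing remainder shorter than one window is left
unscanned. For an array with ~7 kb SNP spacing the default window is roughly
500 kb with a 250 kb slide, matching the bp windows used by the other scans.

HRiD values are z-standardized across windows and mapped to
$-\log_{10}$ of the one-sided upper-tail normal probability — only richness
*drops* constitute evidence of positive selection. The default significance
level of 3.3 corresponds to $z \approx 3.29$. This normal reading of
"normalized and converted" is a design choice; the HRiD distribution is
right-skewed, so the extreme tail is somewhat anti-conservative and
occasional single-window false positives on neutral data are expected (see
"What the tests do and do not show").

## Sex-aware QC and PAR detection

Males are diploid inside the PAR and hemizygous beyond it, so their observed
heterozygosity (H_O) collapses at the PAR boundary. `detect_par()` scans the
male per-SNP H_O with a forward window of 50 SNPs: the boundary is placed
before the first window position from which the windowed mean stays below
`het_floor = 0.01` for the remainder of the chromosome. Within the transition
window the boundary then snaps to the last individually diploid-looking SNP
(`het_diploid = 0.1`): male H_O in a truly diploid region sits near 0.3,
whereas isolated genotyping artifacts stay far below 0.1, so the refinement
pins the boundary to the exact last PAR SNP without being dragged by
artifacts. Hemizygous-region SNPs at which any male is heterozygous are
reported as mis-genotyped and dropped by `clean_hemizygous()`, and any
residual male heterozygous call outside the PAR is set missing.

QC follows array practice: SNPs fail on GenTrain < 0.4 or GenCall <= 0.8
(when array metadata are present — their absence is logged, not an error),
call rate < 90%, or a Hardy–Weinberg mid-p exact test at p < 1e-7 computed on
diploid calls only (females outside the PAR, everyone inside); hemizygous
males cannot be in HWE, so including them would be a category error.
Individuals fail below 95% call rate. Exclusions are strict inequalities, so
a SNP sitting exactly at a threshold is retained.

Ancestral states come from the outgroup: the majority allele among outgroup
allele copies (two per diploid call, one per hemizygous male call) is taken
as ancestral; ties and all-missing SNPs stay unknown and are excluded from
iHS/nSL scoring but retained for haplotype construction.

## eROHi parameters

ROH are called per female with at least 15 consecutive SNPs, inter-SNP gaps
at most 250 kb, at least one SNP per 20 kb, and minimum length 0.25 Mb — a
deliberately short minimum that, at ~35 SNPs per 0.25 Mb on this array
density, tracks selection over roughly the last 200 generations. Six length
classes (0.25–1, 1–2, 2–4, 4–8, 8–16, >16 Mb) are scanned independently so
that genotyping error (~0.25% on HD chips) does not fragment long runs: the
shortest class allows no heterozygous or missing calls, and the allowances
grow with length (het 0,0,0,1,2,4; missing 0,1,2,4,8,16). The per-class
allowances above 1 Mb are configurable assumptions chosen to match common
HD-chip practice; only the strictest class is pinned by principle. Per-SNP
ROH frequency (each female counted once per SNP) is z-standardized and
mapped to the one-sided upper-tail $-\log_{10}p$; runs of at least two
consecutive outlier SNPs at or above the threshold form signals ranked by
their peak. The threshold can be fixed (3.3) or derived as
$-\log_{10}(0.05/m_\mathrm{eff})$ with $m_\mathrm{eff}$ from `simple_m()`,
the eigenvalue-based effective number of independent tests (smallest number
of principal components of the SNP–SNP correlation matrix explaining 99.5%
of the variance — the method's published default).

## iHS / nSL choices

EHH around a core allele is the probability that two random carriers are
identical from the core outward; it is integrated over physical distance by
the trapezoidal rule, truncated where the curve falls below 0.05 (the first
sub-cutoff point is retained so the decay is represented), with no gap
penalty. nSL replaces the bp integral with the mean number of consecutive
identical SNPs per carrier pair (counting the core) and needs no map. Raw
scores ln(iHH_A/iHH_D) are standardized within derived-frequency bins of
0.025; bins with fewer than 10 scored SNPs are merged with their nearest
neighbour, which prevents zero-variance artifacts in sparse bins. Because
both tails are informative (derived *and* ancestral sweeps), p-values are
two-sided. SNPs with minor allele frequency below 5% are NA by construction
— the ratio becomes unstable near fixation — but remain in the haplotypes
and in the other scans. Window aggregation tiles 500 kb windows every
100 kb, computes the fraction of scored SNPs with $-\log_{10}p > 2$, and
reports windows above 10% greedily by descending proportion with overlap
suppression. The proportion's denominator is the scored (non-NA) SNP count;
the total SNP count is also emitted for reporting. Phased input is required
for diploid samples — the package does no statistical phasing; hemizygous
male haplotypes are exact and need none.

## The synthetic-data generator

`simulate_neutral()` is a founder-mosaic model, not a coalescent: an
all-ancestral root haplotype, K = 30 founders mutated from it independently
per SNP at rate 0.3, founder frequencies drawn once from a flat Dirichlet,
and each focal haplotype copying one founder with a switch probability of
0.02 per SNP boundary (a recombination stand-in). Outgroup haplotypes are
drawn from the founders nearest the root, so outgroup-majority alleles
really are ancestral-enriched. Defaults mirror the target study design:
~2,000 X SNPs with a 150-SNP PAR, 100 hemizygous males, 101 females, and a
10-animal outgroup (five of each sex; networks use the males). Females get
two haplotypes, males one outside the PAR and two inside. Missingness
(0.002) and symmetric genotyping error (0.0025, the HD-chip rate) are
applied last; error flips one allele of a diploid call or the single allele
of a hemizygous one. `inject_sweep()` replaces each focal haplotype within a
span by a designated swept haplotype with probability f_s — the founder
nearest the root for an ancestral sweep, or a novel haplotype at least five
mutations from every founder for a derived one — and re-applies the noise
stream from the same seed so untouched cells are unchanged.

What the generator does **not** emulate: linkage-disequilibrium decay from a
realistic recombination map, demographic history (bottlenecks, migration,
breed structure), allele-frequency spectra of real arrays, or soft sweeps.
Its neutral haplotype diversity is considerably higher than the real X
data's (window n_h around 60–80 of 100 males, versus single digits to low
tens in the target study), which makes the synthetic setting *harder* for
HRiD alignment effects and easier for richness contrasts. Passing tests
therefore demonstrate algorithmic correctness and calibration under the
stated model, not field performance.

## Median-joining networks

For each HRiD signal, the unique male haplotypes (focal plus outgroup males)
over the signal's windows are collapsed into nodes and connected by a
median-joining construction: a minimum spanning network (all ties kept) is
iteratively augmented with consensus (median) vectors of linked triplets
whenever the median strictly reduces the triplet's spanning cost (within an
`epsilon` tolerance, default 0); inferred medians that end up as
pass-through or dangling nodes are pruned. When no feasible median exists
the result is exactly the minimum spanning network. The favourable group is
the most frequent focal haplotype plus all observed haplotypes within three
mutations; distance is measured along network paths by default (median nodes
may lie on the path) with raw Hamming distance as an option — the two
coincide on all fixtures we construct, and the path reading matches how
"three mutations away" is judged visually on a network. If the most common
outgroup haplotype falls inside the group the swept haplotype is classified
ancestral; outside, derived; ties spanning both sides are ambiguous, and
tied most-common focal haplotypes all seed the group rather than being
broken arbitrarily.

## Numerical and degenerate-input conventions

* Coordinates are 1-based closed in all TSVs (matching "13.04–13.62 Mb"
  reporting style); BED exports are 0-based half-open. NA is written as
  literal `NA`.
* A SNP with every call missing has undefined H_O (NA), never 0.
* Zero variance in a statistic to be z-standardized (all-equal HRiD, all-equal
  ROH frequencies) is an error, not a silent zero.
* An unusable window (all males missing) propagates NA into both of its
  neighbours' HRiD scores; the surviving neighbour is never substituted.
* Exact ties in the outgroup majority yield `unknown` ancestral state.
* `qc_filter` applies SNP filters first, then individual call rate over
  retained SNPs; this is idempotent in practice because removing low-call
  individuals cannot push a passing SNP below the call-rate threshold.

## Problem sizes used in the test-suite and acceptance runs

Calibration and power checks run 50 seeded replicates at the study scale
(2,000 SNPs, 100 males): the neutral mean HRiD per run stays in
[0.95, 1.05], and the top-HRiD window localizes a 70-SNP sweep at f_s = 0.9
in at least 90% of replicates, with power decreasing through f_s = 0.7 and
0.5. Oracle-equivalence checks (effective haplotype numbers against the
direct reciprocal sum, ROH calling against an exhaustive segment scanner,
iHS/nSL against pairwise-tract enumeration) use 1,000 random multisets, 100
toy chromosomes of 40–80 SNPs, and 6–10-haplotype fixtures, where brute
force is exact and fast. Unit fixtures are generated in code; nothing is
downloaded.

## Known limitations

* iHS/nSL power drops near fixation by construction (MAF < 5% ⇒ NA); in
  simulations iHS localization peaks at intermediate sweep frequencies
  (perfect at f_s = 0.7, ~75% at f_s = 0.8 under the generator's high
  background diversity).
* The normal-tail transforms (HRiD, eROHi) are anti-conservative in the
  extreme right tail because the underlying distributions are right-skewed;
  occasional single-window neutral false positives at the 3.3 level are
  expected (~1 in 6 neutral runs of ~50 windows).
* HRiD windows are SNP-count based; a sweep span that straddles two windows
  without filling either dilutes the drop. Half-overlapping windows (step =
  size/2) bound the misalignment at a quarter window.
* The PAR boundary refinement assumes clearly diploid male H_O (~0.3); a PAR
  whose terminal SNPs are nearly monomorphic will place the boundary at the
  last polymorphic diploid SNP.
* The median-joining construction accepts medians only when they strictly
  reduce a linked triplet's spanning cost; this recovers textbook star and
  chain topologies and the MSN limit, but is not guaranteed to enumerate
  every median vector of the full Bandelt procedure on large degenerate
  inputs.

## A minimal run

```{r example, eval = FALSE}
ds <- simulate_sweep(seed = 1, f_s = 0.9)          # data with one hard sweep
res <- run_scan(ds$gm, run_config(seed = 1),
                out_prefix = "scan")               # QC -> PAR -> scans
res$hrid$signals                                   # signal table
res$networks[[1]]$origin                           # ancestral vs derived
```
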