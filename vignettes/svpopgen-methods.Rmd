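---
title: "SVPopGen: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SVPopGen: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(SVPopGen)
```

SVPopGen compares the population genomics of SNPs and structural variants
(SVs) in a multi-population, invasion-style study design. This vignette is
the package's account of the science it implements: the statistical models,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical conventions behind every operation. Nothing
here asserts an empirical result that the test suite does not itself
compute.

# The data model

All downstream statistics run on a `GenotypeMatrix`, a
`RangedSummarizedExperiment` holding a sites × samples dosage assay
(0/1/2 alternate-allele counts, `NA` for missing), variant loci as
`GRanges` (with `type` and `svlen`), and per-sample population and batch
labels. SVs are deliberately coerced into the same biallelic ref/alt
representation as SNPs — an SV allele is "the rearrangement is present" —
so heterozygosity, π, F_ST, PCA and the SFS apply to both variant classes
without modification. TRA records (translocations) are represented by a
single break-end coordinate: they have no defined length, occupy a 1-bp
interval for all overlap arithmetic, and are exempt from length filters.

Coordinates follow VCF (1-based, closed) in all user-facing objects;
conversion to 0-based half-open happens only inside the BED writer.

# Consensus SV merging

Short-read SV callers disagree on exact break-end coordinates and carry
caller-specific false positives. The per-sample consensus rule retains a
call only when at least `minSupport = 2` of the three callers report an
event of the same type and strand orientation whose break ends lie within
`maxDist = 1000` bp, with a minimum SV length of 30 bp — and, as the
genotype-aware refinement, only when the supporting callers also agree on
the sample's genotype. Agreement is enforced by partitioning calls into
the three genotype classes before clustering, then concatenating the
retained clusters. Calls with missing genotypes cannot enter any
partition and are dropped. The cross-sample stage re-clusters the
per-sample consensus calls under the same distance/type/strand rule at
1-caller (here: 1-sample) support, without genotype agreement, producing
one genotype per sample per cohort SV; samples contributing no call are
typed homozygous reference (`0/0`) rather than missing, because site-level
missingness and MAF are subsequently computed on the merged set (a
`./.` convention is available via `absentGenotype`).

Numerical conventions:

* **Distance** between two calls is `max(|Δstart|, |Δend|)` when both
  calls have a second break end (DEL/DUP/INV), else `|Δstart|`.
* **Cluster validity** requires *every pair* of member calls to satisfy
  the distance bound (a clique), and members to come from distinct
  callers (or samples, cross-sample).
* **Representative coordinates** are the per-coordinate medians of the
  members, ties broken toward the smaller value (the lower middle order
  statistic).
* **Cluster selection is exact, not greedy.** A seeded single-linkage
  heuristic was considered and rejected: it provably fails to maximize
  the number of retained calls (a seed can absorb a call whose
  alternative placement would rescue another cluster), which would break
  both the package's brute-force-oracle equivalence and the monotonicity
  of retained calls in `maxDist`. Instead, calls are partitioned by
  chromosome/type/strand(/genotype), split into components at position
  gaps > `maxDist`, and each component is solved by exhaustive
  branch-and-bound: maximize retained calls, break ties by the
  lexicographically smallest block assignment over position-sorted calls
  (which also makes the result independent of input order). Components
  beyond 12 calls — which do not arise with three callers and < 1 kb
  jitter — fall back to a deterministic greedy earliest-block assignment
  with a warning. At `minSupport = 1` every call is retained under any
  valid partition, so the earliest-block assignment *is* the
  lexicographic optimum and is used directly.
* **Two genotype partitions, one locus.** With jitter and false
  positives, one locus can survive in two genotype partitions (e.g. two
  callers at 0/1 and one caller plus a false positive at 1/1). The
  resolution — keep the cluster with more supporting callers, then the
  one with the smaller coordinate — is a package convention; the
  underlying study procedure (concatenating per-genotype merge outputs)
  does not define one.

`bruteForceMergeOracle()` enumerates every set partition of ≤ 10 calls
and applies the same objective; it is implemented independently of the
fast path and defines correctness on small instances.

# Dataset filters

The filter chain mirrors a standard vcftools-style pipeline, with each
rule's removal count logged (`filterLog()`):

* missingness: drop sites with missing fraction > 0.5 (strictly greater);
* MAF: drop sites with minor allele frequency < 0.03 — retention is
  inclusive at the threshold, the `--maf` convention; MAF is computed on
  non-missing alleles;
* linkage pruning: scanning sites in position order, remove the later
  site of any pair within 1000 bp whose squared Pearson correlation of
  dosages exceeds 0.6 (first-retained-wins). The window is interpreted as
  pairwise distance between site positions; r² is the composite genotype
  correlation over samples non-missing at both sites (no phase is
  available), and a zero-variance site yields r² = 0 rather than NA;
* thinning: greedy per-chromosome scan keeping sites strictly more than
  5000 bp after the last kept site;
* kinship: the KING-robust estimator
  φ = (N_het,het − 2·N_opp,hom)/(N_het,i + N_het,j), with pairs at
  φ ≥ 0.25 flagged (the full-sibling screen); a zero denominator reports
  NA. Note the parent–offspring expectation sits exactly at 0.25, so
  flags at that boundary are sampling-noise coin flips by construction.

All filters are idempotent. Read-depth filters from sequencing practice
(min/max mean depth) are out of scope: the synthetic VCFs carry no depth.

# Density landscape

SNP and SV counts are tallied in fixed 1-Mb bins (last bin truncated at
the chromosome end). SVs use coverage semantics — an SV is counted in
every bin its interval overlaps — matching interval-coverage tooling; a
start-position-only mode exists. The SV count is regressed on the SNP
count with `glm(family = quasipoisson)` (log link; point estimates equal
Poisson's, standard errors scale with the Pearson dispersion), and
deviance residuals (the default; Pearson available) are retained as the
SNP-adjusted SV density. Subtelomeric enrichment compares mean residuals
between bins overlapping the chromosome-end windows and interior bins
with a Wilcoxon rank-sum test; with fewer than two bins in either class
the summary is omitted. Break-end repeat classification intersects the
first 30 bp from each SV's first break end with the repeat annotation,
assigning the class of the largest-overlap interval — an
annotation-overlap stand-in for a homology search, which is exactly what
makes it testable against the generator's ground-truth repeat track.

# Diversity, SFS and PCA

Per population and site with n non-missing alleles and j alternate
copies: H_O is the heterozygote fraction among non-missing genotypes,
H_E = 2p(1−p) from sample frequencies, and π = 2j(n−j)/(n(n−1)), the
unbiased mean pairwise difference; the identity π = H_E·n/(n−1) is an
internal consistency check enforced in the tests. Population values are
means over retained (variant) sites — a variant-only averaging
convention, appropriate because only relative cross-population contrasts
are interpreted, not absolute per-bp diversity. Private alleles count
(site, allele) pairs observed in exactly one of the compared populations;
no rarefaction is applied, so unequal sample sizes bias private-allele
counts toward larger samples (a documented caveat of the mirrored
procedure). Invader-specific variants are those with > 0 alternate
copies in the invasive populations and exactly 0 elsewhere, after
excluding designated samples (the extreme-drift range edge, whose
admixture history would confound the contrast); "common" variants then
require MAF strictly > 0.15. The folded SFS uses minor-allele
frequencies in 0.05-wide bins over (0, 0.5] (0.5 falls in the top bin;
monomorphic variants carry no frequency information and are excluded),
split by gene-overlap class: an SV that fully contains a gene is
`complete_overlap`; one with a break end inside a gene (but no contained
gene) is `breakend_overlap`; else `no_overlap`.

PCA standardizes each site's dosages by 2p̂ and √(2p̂(1−p̂)), drops
zero-variance sites, mean-imputes missing entries (zeros after
centering), eigendecomposes the sample covariance, and fixes each
component's sign so its largest-magnitude coordinate is positive —
making coordinates reproducible across BLAS implementations.

# Selection scans

**Differentiation.** The per-locus statistic is the two-population
Weir–Cockerham θ from genotype counts (variance components a, b, c with
the heterozygote corrections); monomorphic loci are undefined and
excluded, and negative estimates are kept raw but floored at zero for
thresholding. Because the Bayesian machinery that usually produces such
scans is an external tool, the package keeps the study's *calibration*
procedure and swaps in the WC statistic: the genome-wide F̂ is the
multi-locus ratio Σa/Σ(a+b+c); 5,000 pseudo-observed neutral loci are
simulated by resampling ancestral frequencies from the observed MAF
distribution, drawing group frequencies from the Balding–Nichols
distribution Beta(p(1−F̂)/F̂, (1−p)(1−F̂)/F̂), and drawing genotypes
binomial(2, p) at the observed group sizes (monomorphic draws redrawn);
the empirical 1% threshold is the POD order statistic at rank
⌈(n_POD+1)·0.99⌉ — the (r+1)/(n+1) empirical-p-value convention, chosen
over an interpolated sample quantile because interpolated extreme
quantiles of 5,000 draws are biased low (anti-conservative). One caveat
is inherited from the procedure itself: the threshold is estimated from
5,000 draws and therefore carries Monte-Carlo noise of its own, so the
realized flagged fraction on neutral data scatters around 1% slightly
more than binomial sampling alone would predict. Contrasts between the
native population and each invasive subgroup are run separately and
their flag sets unioned.

**Balancing selection.** For a core SNP with folded frequency f_c = k/n
(core MAF ≥ 0.15 — low-frequency cores are drift-dominated and
false-positive-prone), all other polymorphic sites within ±1000 bp
contribute the similarity kernel g(f) = (1 − |f − f_c|/M_c)^p with p = 2
and M_c the largest folded distance attainable from f_c. Then
θ_β = Σᵢ g(fᵢ)/b_n(f_c) with the normalizer
b_n(f_c) = Σ_k g(k/n)·c_{n,k}, c_{n,k} = (1/k + 1/(n−k))/(1 + [k = n−k]),
and θ_W = S/a_n (Watterson). Because Σ_k c_{n,k} = a_n, a window whose
folded site counts follow the neutral expectation gives E[θ_β] = θ_W
exactly — β(1) = θ_β − θ_W is unbiased at zero under neutrality by
construction, which the acceptance suite verifies by simulation. An
empty window reports β = 0 with S = 0; fewer than 4 alleles is refused.
The kernel and normalizer are this package's fully specified statistic
in the spirit of the published folded-β approach; numerical equivalence
to external implementations is not claimed.

**Pseudo-β for SVs.** SVs cannot be scanned directly (the statistic
needs dense SNPs), so each SV inherits the SNP β(1) scores in the
half-open 1000-bp window on the lower-coordinate side of its first break
end — positions in [breakend − 1000, breakend), strand ignored; 1000 bp
matches the consensus-merge distance, the scale at which linkage to the
break end is expected. Scores are summarized per SV by a trimmed mean
discarding ⌊0.05k⌋ values at each tail (the "middle 90%" rule — hence no
trimming below k = 20), or pooled raw in the alternative mode. SVs with
no upstream score are excluded and counted.

**Seven groups.** β scores are compared across outlier SNPs, non-outlier
SNPs, outlier SVs (not split by type), and non-outlier DEL/DUP/TRA/INV
with a tie-corrected Kruskal–Wallis test (df = groups − 1) and Dunn's
pairwise z tests on the pooled ranks. INS records are excluded from the
design; any group left with < 2 members is dropped with a warning. The
Dunn adjustment is Benjamini–Hochberg by default ("adjusted p" without a
named method leaves this open; Holm and Bonferroni are available). When
every observation is tied, H = 0 by convention.

# The synthetic world

The generator's defaults state the emulated study design: 49 samples in
five populations — a native source (UK, n = 8, F = 0.03), a second
invasive range (NA_R, n = 8, F = 0.08), two structured invasive
subgroups (AU_EAST/AU_SOUTH, n = 15 each, F = 0.12) and a small
extreme-drift range-edge deme (MGL, n = 3, F = 0.35) — on a
3-chromosome, 12-Mb genome (large enough that the 1-Mb density landscape
has a well-constrained regression) with 5,000 SNPs and 400 SVs. The F values are
the package's own drift calibration (chosen once to give a clear
source/bottleneck ordering and a strongly drifted range edge, the
qualitative structure of the emulated study); the sample sizes and the
population roles are the study design's. Allele frequencies follow the
Balding–Nichols model: ancestral p ~ Uniform(0.05, 0.95) (avoiding
monomorphic draws), population frequencies
Beta(p(1−F)/F, (1−p)(1−F)/F) (degenerate at p for F = 0), genotypes
binomial(2, p_pop) per sample. Planted structure: divergent SNPs with an
allele-frequency gap ≥ 0.6 between the designated pair; balanced
clusters — a core at folded frequency 0.4 in every population with 12
companions within ±1 kb whose folded frequencies lie within 0.05 of the
core, the operationalization of "an excess of SNPs at similar
frequencies"; optionally the cores sit in the 1-kb window upstream of
deletion break ends (`balancedUpstreamOfSv`); and a fixed floor-fraction
of SVs private to the invasive range. Two ascertainment conditions make
end-to-end truth recovery well-posed: every SV carries at least one
alternate allele in the cohort (an SV "exists" because it was
discovered), and distinct same-type/strand SVs are kept > 1 kb apart at
both break ends, since closer pairs are indistinguishable under the 1-kb
consensus rule.

The three default caller profiles are loose caricatures of read-pair/
split-read callers: detection probabilities 0.5–0.9 by SV type, jitter
100–200 bp (well under the 1-kb merge radius), genotype error 2–5%,
false positives 1.5–3 per Mb, PASS rates 0.90–0.97. Jitter shifts both
break ends by one shared offset, preserving SVLEN; false positives are
uniform with random types and genotypes. Optional batch-conditioned SV
dropout removes a (sample, SV) pair from *all* callers with fixed
probability, emulating a batch effect that depresses SV heterozygosity.
All randomness forks named substreams from one seed, so enabling false
positives does not perturb the genotype draws, and identical
(config, seed) reproduce identical outputs byte for byte.

What the generator does **not** emulate — and hence what a green test
does not establish: no reads, base-calling error, mapping bias or depth
variation (so depth-based filters are untestable here); no recombination
or coalescent linkage — LD exists only where planted, so the LD-pruning
rule is exercised by constructed fixtures, not by realistic haplotype
structure; repeat classification tests the 30-bp overlap rule, not
homology detection; and caller errors are independent across callers,
whereas real callers share failure modes on the same evidence.

# Known limitations

* The exact merge search is exponential in component size; the
  gap-splitting bound and the 3-caller setting keep components tiny, but
  adversarial inputs with many units in one 1-kb window fall back to the
  greedy assignment.
* POD calibration inherits the threshold's own Monte-Carlo noise (see
  above); a single neutral dataset's flagged fraction is only
  approximately binomial around 1%.
* Private-allele counts are not rarefied; β(1) windows use a fixed
  ±1 kb irrespective of local SNP density; and the pseudo-β upstream
  window ignores strand, as the mirrored procedure leaves it undefined.
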