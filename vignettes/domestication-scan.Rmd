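---
title: "Detecting domestication signatures in two-population SNP panels"
author: "domscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting domestication signatures in two-population SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domscan)
```

# Overview

`domscan` implements the analytical chain used to characterise crop
domestication from dense biallelic SNP genotypes on a panel that contains
both a wild progenitor population and a derived cultivated population:

1. **Windowed polymorphism statistics** — per-site allele frequencies and
   MAF; nucleotide diversity $\pi$, Tajima's $D$ and Weir–Cockerham
   $F_{ST}$ in non-overlapping genomic windows (100 kb for genome-wide
   summaries).
2. **Composite selective-sweep scan** — 10-kb windows scored by the
   reduction of diversity $ROD = 1 - \pi_{cul}/\pi_{wild}$ and by
   $F_{ST}$; a window is called as a domestication-selection window iff it
   lies in the upper 5% tail of *both* empirical distributions; adjacent
   called windows are merged into sweep regions and annotated with
   overlapping genes.
3. **Linkage disequilibrium** — composite (dosage-correlation) $r^2$
   between nearby SNPs, a binned decay curve, and the half-decay distance
   (the distance at which mean $r^2$ falls to half its short-range
   maximum).
4. **Population structure** — identity-by-state distances, principal
   components, and a neighbor-joining tree with Newick output.
5. **Array design** — a re-usable form of a tag-SNP genotyping-array
   pipeline: MAF/missingness filtering, 33-mer flank-uniqueness screening,
   greedy tag-SNP selection at $r^2 \ge 0.8$, even-coverage window filling
   with genic preference, and VIP supplementation, plus the coverage
   summary metrics (mean spacing, genic and pericentromeric fractions).
6. **Association** — multi-environment BLUP breeding values, VanRaden
   kinship, an exact mixed-linear-model scan with principal-component
   covariates, the $1/n$ significance threshold, and candidate regions
   sized by the population's LD half-decay distance.
7. **Simulation** — a forward Wright–Fisher two-population simulator with
   a domestication bottleneck, planted selective sweeps and
   multi-environment additive phenotypes, so that the whole chain can be
   developed and tested without access to any real panel.

This vignette documents the model choices, the tunable parameters, what
the simulator does and does not emulate, and the numerical conventions.

# Statistical definitions

## Per-site and windowed diversity

All dosages count the alternate allele (0/1/2, `NA` missing). At a site
with $c$ called alleles and alternate frequency $p$, the unbiased per-site
diversity is $\hat\pi = 2p(1-p)\,c/(c-1)$, identical to the mean pairwise
difference over all $\binom{c}{2}$ called-allele pairs. Window $\pi$ sums
$\hat\pi$ over the window's usable sites and divides by the window length
in bp; this per-bp normalisation makes windows with different SNP density
comparable. Windows with no usable site report 0; sites with $c<2$ are
skipped.

## Tajima's D

Computed per window from the number of segregating sites $S$ and the sum
of per-site mean pairwise differences $\hat k$, using the standard
constants $a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$. Missingness makes the
called-allele count vary per site, while the constants require a single
$n$; we use the median called-allele count over the window's segregating
sites, rounded (ties down) — a robust single summary. Windows with $S=0$
or a non-positive variance term report `NA`, never 0 (an absent statistic
is not a neutral one).

## Weir–Cockerham F~ST~

Per-site variance components $a$ (between populations), $b$ (between
individuals within populations) and $c$ (within individuals) follow the
1984 estimator for two populations, using observed heterozygote
frequencies. Windows combine sites by **ratio of sums**
$\sum a / \sum (a+b+c)$, which is the standard weighting and is stable in
low-diversity windows where per-site ratios explode. Sites with a zero
denominator, or with either population uncalled, are skipped. Small
negative window values are legitimate (no differentiation).

## ROD and the composite sweep call

$ROD = 1 - \pi_{cul}/\pi_{wild}$ per window, undefined (`NA`) when
$\pi_{wild} = 0$: with no wild diversity there is no reduction to
measure, so such windows are excluded from the empirical pools and can
never be called. The empirical threshold is the nearest-rank upper-tail
quantile: with $n$ defined windows and quantile $q$, the threshold is the
$k$-th largest value where $k = n - \lfloor qn \rfloor$, and a window is
called iff its value is $\ge$ that threshold in **both** statistics. Ties
at the threshold are included. With $q = 0.95$ and 100 untied windows
this calls exactly the joint top-5 set; with $q = 0$ every defined window
is called. Because the call is an intersection of two $\approx 5\%$
tails, the called fraction can never exceed $5\%$ of defined windows
(plus ties), which also bounds the false-positive rate on panels without
selection.

Adjacent (book-ended) called windows merge into regions; merging is exact
(gap tolerance 0), so the total merged extent always equals the window
size times the number of called windows. A gene is attached to a region
if its span overlaps it by at least 1 bp.

## LD decay

$r^2$ is the squared Pearson correlation of dosage vectors over samples
called at both sites (the composite estimator appropriate for unphased
genotypes). Pairs never span chromosomes; pairs with a monomorphic member
or fewer than 3 shared calls are skipped. The decay curve averages $r^2$
in contiguous distance bins (default 1 kb) pooled over chromosomes, and
the half-decay distance is the first distance at which the binned mean
falls to half of the **first populated bin's** mean, linearly
interpolated between straddling bin centers. Using the first bin as the
maximum (rather than the global maximum) avoids noise-driven maxima at
long range, where bins hold fewer pairs.

`ld_decay()` applies a MAF $\ge 0.05$ filter by default. Rare variants
carry almost no LD information (their $r^2$ with anything is bounded by
allele-frequency ratios), and their abundance is systematically higher in
a recently re-expanded cultivated population, which would otherwise bias
its curve downward relative to the wild panel's. `pairwise_r2()` itself
defaults to all polymorphic sites.

## Structure and trees

The IBS distance between two samples is the mean over co-called sites of
$|d_i - d_j|/2$, equivalently 1 minus the average allele-sharing score
(1 for identical genotypes, 0.5 for one shared allele, 0 for opposite
homozygotes). PCA operates on the centered ($d - 2p$) and scaled
($\sqrt{2p(1-p)}$) genotype matrix with per-SNP mean imputation of
missing dosages. Neighbor joining uses the Saitou–Nei algorithm (via
`ape`); negative branch lengths, which NJ can produce on non-additive
matrices, are clamped to zero with the deficit transferred to the sibling
edge so path lengths are preserved where possible. On additive matrices
the generating tree is recovered exactly.

## Association

Breeding values come from the two-way mixed model
`weight ~ environment (fixed) + sample (random)` fitted by REML with
`lme4` (the standard tool for exactly this model); the per-sample random
effect (BLUP) is the phenotype passed to the scan. Year/location/trial
are treated as a single crossed "environment" factor — the finer
fixed/random partition of those effects is under-determined in a generic
package, and the single-factor model reproduces the balanced-design
closed-form shrinkage exactly.

Kinship is VanRaden's $K = ZZ^\top / (2\sum_k p_k(1-p_k))$ with
$Z = d - 2p$ and per-SNP mean imputation. The scan is the **exact** mixed
linear model $y = X\beta + g b + u + e$, $u \sim (0, K\sigma^2_g)$: the
variance ratio $\lambda = \sigma^2_e/\sigma^2_g$ is estimated once on the
null model by profiled REML over the spectral decomposition of $K$ and
reused for every marker (the standard P3D/EMMAX scheme), each marker is
tested by a Wald $t$-test after rotating into the eigenbasis, and the
significance threshold is $1/n$ with $n$ the number of tested markers
(MAF $\ge 0.05$, call rate $\ge 0.9$). We deliberately implement the exact
MLM rather than a compressed (group-kinship) approximation: compression
is an efficiency device for biobank-scale panels, not a statistical
claim, and at desk scale exactness is the reference behavior. With
$K = I$ and $\lambda \to \infty$ the scan reduces to ordinary least
squares to numerical precision, which the tests assert. Markers exactly
collinear with the covariates report effect 0 and $p = 1$ (absorbed).
Candidate regions are $\pm$ one LD half-decay distance around each
significant SNP, merged when overlapping, with the most significant SNP
as the lead and overlapping genes attached.

## Array design

Candidates must have MAF $\ge 0.10$ and missingness $\le 0.2$. (The
customary description of this filter is self-contradictory if read
literally — it would discard every informative SNP — so the package
implements the only reading under which an array can be built:
*retain* common, well-called SNPs.) Flank uniqueness requires the 33-mer
centered on the SNP to occur exactly once in the reference counting both
strands (an exact-match stand-in for short-flank BLAST screening); SNPs
within 16 bp of a contig end are non-evaluable and dropped. Tag SNPs are
chosen by greedy set cover: a candidate tags all candidates with
$r^2 \ge 0.8$ within a 500-kb window (LD software operates on regional
LD; 500 kb comfortably exceeds any realistic half-decay), ties broken by
leftmost position. Greedy set cover is within a logarithmic factor of the
minimum and the tests verify the tag property exhaustively plus a
2$\times$-of-optimal bound on small instances. The 1,680-bp "even
distribution" step is implemented as non-overlapping tiles: a tile with
at least one candidate and no selected SNP receives one candidate,
preferring genic over intergenic and, within a class, the candidate
nearest the tile center. VIP SNPs are supplemented last (they bypass the
filters by construction — supplementation is the pipeline's final union
step) and duplicates are collapsed.

The coverage summary defines mean spacing as total chromosome length
divided by the number of chromosome-mapped SNPs — the convention under
which 291,962 SNPs on a 975-Mb genome give $\approx 3.3$ kb — plus the
fraction of consecutive-SNP gaps under a threshold (9 kb default),
context-class counts (precedence CDS > UTR5 > UTR3 > intron >
genic-other), pericentromeric versus arm counts from user-supplied
intervals (no inference is attempted), and the number of genes containing
at least one selected SNP.

# The simulator: a stated world

`simulate_two_pop()` is a discrete-generation forward Wright–Fisher
simulator: fitness-weighted multinomial resampling of diploid parents,
Poisson crossovers placed uniformly, infinite-sites mutation. An
ancestral population of $N_{anc}$ diploids is burnt in for
$10\,N_{anc}$ generations (the standard equilibrium heuristic;
configurable), splits into a wild lineage of constant size and a
cultivated lineage that passes through a bottleneck and recovers, and
each planted sweep allele enters the cultivated lineage at the split as a
single new copy and is selected with multiplicative fitness $(1+s)$ per
copy. A lost allele is re-introduced into a random haplotype (bounded
count), and the whole post-split phase is resampled (up to 25 attempts)
until every sweep allele reaches frequency $\ge 0.99$ by sampling time:
the simulator's contract is *planted sweeps at known loci*, so downstream
power estimates measure the scan, not the establishment lottery. Output
is bit-identical given the seed.

## Default parameters and why

No demographic parameters are published for the real domestication
history at the panel's scale, so the defaults are a desk-scale world
chosen once, on theory, to reproduce the qualitative structure of a
domesticated crop panel; they are placeholders for absolute values but
deliberate in their dimensionless ratios.

| parameter | default | rationale |
|---|---|---|
| genome | 5 Mb on 5 chromosomes | large enough for 500 scan windows; one sweep per chromosome avoids selective interference between simultaneously selected loci |
| $N_{anc}=N_{wild}=N_{cul}$ | 500 diploids | desk scale; burn-in $10N = 5000$ generations |
| samples | 105 wild / 262 cultivated | the panel sizes of the motivating study design |
| $\mu$ | $2\times10^{-7}$ /bp/gen | $\theta_{bp} = 4N\mu = 4\times10^{-4}$, giving tens of segregating sites per 10-kb window so window $\pi$ ratios are not dominated by site-sampling noise |
| $\rho$ | $5\times10^{-7}$ /bp/gen | sets a hard-sweep footprint of $\sim s/(\rho\ln 2Ns) \approx 40$ kb (several scan windows, a small genome fraction) and enough recombination per window to average genealogical noise |
| $T_{split}$ | 120 generations | keeps post-fixation recovery $t_{post}/2N \lesssim 0.03$, matching the real system's ratio; longer splits let mutation refill swept windows and erase the signal |
| bottleneck | 10% of $N$ for 30 generations at the split | inbreeding intensity $T_b/2N_b \approx 0.3$: enough to depress cultivated diversity, raise LD and tilt Tajima's $D$, without making background drift noise indistinguishable from sweeps at 10-kb scale |
| sweeps | $s = 0.1$ at the midpoint of a 10-kb window on chr1/3/5 | strong artificial selection; mid-window placement avoids splitting the footprint across a window boundary |

The phenotype generator adds, per sample, a QTL sum
$\sum_k a_k d_{ik}$ rescaled so the genetic fraction of the
within-environment variance equals $h^2$, an environment main effect,
genotype-by-environment noise (30% of the non-genetic variance by
default) and replicate-level residuals (four technical replicates,
mirroring multi-environment seed-weight trials; nine environments by
default). Weights are clipped at 0.01 g to respect positivity — with the
default mean (15 g) and SD (3 g) clipping is a $5\sigma$ event.

## What the simulator does *not* emulate

Green tests on simulated panels establish that the statistics, the
composite caller, the LD machinery and the MLM behave correctly on data
with a known truth. They do **not** establish field performance on a real
crop: the simulator has a uniform recombination map (no pericentromeric
suppression), free mixing within populations (no eco-geographic
substructure or admixture), no genotyping error or ascertainment bias
(array SNPs are discovered in small panels, inflating common-allele
representation), simplistic gene models tiled at fixed spacing, and
desk-scale absolute diversity. Headline empirical numbers from real
panels (80 kb vs 130 kb half-decay, 1,614 selection windows, specific
seed-weight loci) depend on the real genotypes and are reproduced here
only as worked-example arithmetic, not as simulation outcomes.

# Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; conversion
  happens once at the VCF/GFF3/BED boundary. BED output is 0-based,
  VCF/GFF3 1-based.
* Missing dosage is `NA`, never 0 (0 is a valid homozygous-reference
  call). Heterozygotes of either phase count 1.
* Undefined windows (ROD with $\pi_{wild}=0$, $F_{ST}$ with an uncalled
  population, Tajima's $D$ with $S=0$) are `NA` and are excluded from
  empirical pools rather than imputed.
* Quantile thresholds are nearest-rank with ties included — reproducible
  without interpolation conventions.
* The greedy tag selection breaks gain ties by leftmost genomic position,
  making the tag set order-independent.
* `mlm_scan()` optimises the REML criterion for $\log\lambda$ on
  $[-14, 14]$ (beyond which the model is numerically OLS or pure kinship)
  and clamps negative kinship eigenvalues at 0.
* NJ negative branch lengths: clamp to 0, transfer the deficit to the
  first sibling edge, iterate boundedly; residual negatives (pathological
  non-metric inputs) are clamped outright.
* `simulate_two_pop()` errors if a sweep cannot complete within the retry
  budget rather than silently emitting a partial sweep.

# Open design points resolved in this package

* **"Upper 95%"** of an empirical distribution is read as the top 5% tail
  ($\ge$ 95th percentile), the convention of the rice and common-bean
  scans this approach descends from.
* **Inter-SNP spacing** statistics use distances between consecutive SNPs
  on the same chromosome only; chromosome-end gaps are not spacings.
* **100-kb windows** are non-overlapping tiles for all three windowed
  statistics (diversity, MAF, Tajima's $D$).
* **LD pooling**: pairs are computed within chromosomes and pooled
  genome-wide into one decay curve per population.
* **PC covariates** for the scan are computed on the MAF-filtered marker
  set (the set actually tested).
* **VIP SNPs** do not pass back through the flank-uniqueness filter; they
  are supplemented after filtering, matching their role as must-have
  content.

# Known limitations

* The exact MLM refits nothing per marker beyond the GLS projection
  (P3D); per-marker variance re-estimation would be slightly more
  powerful at small $n$ but is not the reference behavior of the tools
  this package mirrors.
* The WF engine is diploid, panmictic, single-locus-fitness
  multiplicative; no selfing rate is modelled even though real soybean is
  highly selfing — at desk scale this mainly affects heterozygosity, not
  the relative signatures the tests assert.
* `flank_unique()` is exact-match uniqueness; it does not emulate
  near-match BLAST hits (mismatched paralogs).
* Bootstrap support for NJ trees is not computed by default; the
  resampling unit would be SNP columns.

# A minimal end-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(out_dir = "domscan_run", seed = 1,
                       sim = sim_params(seed = 1))
res <- run_pipeline(cfg)
res$metrics
```

The run writes the simulated VCF and metadata, the 100-kb window table,
the 10-kb sweep windows and merged regions (BED), the Newick tree, PCA
coordinates, the GWAS score table and a `metrics.json` that is
bit-identical across runs with the same seed.
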