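---
title: "Methods and design choices in herdstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in herdstruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdstruct)
```

# What the package does

`herdstruct` analyzes dense diploid biallelic SNP genotypes sampled from many
breeds (or, generally, populations): a quality-control cascade, diversity and
Weir–Cockerham F-statistics, linkage disequilibrium (LD), allele-sharing and
Reynolds distance trees with bootstrap supports, principal component analysis
(PCA) and between-breed PCA, spatial PCA (sPCA) on a Gabriel neighbor graph
with Moran's *I*, and maximum-likelihood admixture inference by
expectation–maximization (EM). The design target is livestock SNP-chip panels
of the BovineSNP50 type — tens of thousands of markers, dozens of breeds with
one or two dozen animals each, a deep hierarchical structure (continental
groups, breeds within groups, hybrid breeds between groups) and an
ascertainment bias toward the populations in which the chip's SNPs were
discovered.

The central container is `GenotypePanel`, a `SummarizedExperiment` with SNPs
as rows, individuals as columns, an integer dosage assay counting copies of
the panel-wide minor allele (`NA` = missing), the SNP map in `rowData` and the
breed code in `colData`. Dosage orientation is the panel-wide minor allele
(ties broken toward the lexicographically larger allele character) and is
stored per SNP; every downstream statistic used here is invariant to allele
relabeling, so orientation only matters for reproducibility of frequency
tables.

# The synthetic-data generator

Chip data of this kind are rarely redistributable, so the package ships a
generator (`simulatePanel`) whose defaults (`defaultWorldlikeConfig`)
emulate the study design the pipeline targets:

* **Two-level Balding–Nichols drift.** A global ancestral frequency
  $p \sim U(0.05, 0.95)$ per SNP; each group draws its frequency from
  $\mathrm{Beta}\!\big(p\tfrac{1-F}{F},\, (1-p)\tfrac{1-F}{F}\big)$ with the
  group's drift $F$, and each breed drifts likewise from its group ancestor.
  This matches the F~ST~-level structure the downstream estimators measure
  while staying fast at desk scale; it is not a coalescent and makes no
  claim about haplotype structure.
* **Hybrid breeds** take the $\alpha$-mixture of two parents' frequencies —
  the deterministic, interpretable analogue of admixed breed origins.
* **Genotypes** are $\mathrm{Binomial}(2, p_{\text{breed}})$ per individual:
  Hardy–Weinberg within breeds, so the HWE filter operates at its nominal
  false-positive rate on simulated data.
* **Ascertainment** is post-hoc: SNPs with realized MAF below a threshold in
  a designated discovery group are discarded. This is the simplest mechanism
  that reproduces the bias direction seen with real chips (diversity measured
  in the discovery group exceeds that of distant groups).
* **Clines**: a configurable fraction of SNPs has breed frequencies
  overwritten by a logistic function of the breed coordinate along one axis
  (random per-SNP midpoint and sign). Overwriting rather than mixing keeps
  the spatial signal interpretable when validating sPCA.
* **Missingness** is MCAR at a configurable rate.

The default configuration uses 3 groups, 10 pure breeds plus 2 hybrids,
20–30 individuals per breed, 5,000 SNPs on one synthetic chromosome at 50-kb
spacing (chip-like density), 2% missingness, ascertainment at MAF ≥ 0.05 in
the EUT-like group, and a latitudinal cline on 10% of SNPs. Group drift
(0.10–0.12) and breed drift (0.06–0.10) were chosen once so that the global
F~ST~ lands in the 0.15–0.20 range typical of cattle breed panels.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: linkage disequilibrium (sites are
exchangeable, so the LD module is validated on constructed two-locus tables
and the decay curve of simulated data is flat by construction), structured
missingness (MCAR at 2% essentially never pushes a breed below a 75% call
rate, so the call-rate filter is exercised by dedicated fixtures rather than
by the simulator), relatedness within breeds, and real per-breed sample-size
patterns (emulated in range, not matched breed-by-breed).

# Quality control

`runCascade` applies three filters in a fixed order; the order is part of
the contract (a SNP can fail several criteria but is attributed to the first
stage that rejects it, and a SNP monomorphic everywhere must never reach the
HWE stage):

1. **Call rate** (`filterCallrate`, default 0.75): drop a SNP if its call
   rate falls below the threshold in *at least one* breed; the boundary is
   inclusive (exactly 75% called is kept).
2. **Monomorphism** (`filterMonomorphic`): drop a SNP only when all
   non-missing dosages across the panel share one homozygous value. A SNP
   fixed for opposite alleles in two breeds carries between-breed
   information and is retained; any heterozygote anywhere retains the SNP.
3. **Hardy–Weinberg** (`filterHwe`, default q < 0.05): the exact
   conditional test is computed within each breed separately (cells with
   fewer than two called genotypes, or monomorphic in that breed, contribute
   p = 1), p-values are converted to Storey q-values across SNPs *within
   each breed*, and a SNP is dropped when any breed shows q below the
   threshold.

The exact HWE test enumerates the conditional distribution of the
heterozygote count given the allele counts,
$P(h) \propto 2^h / (n_{AA}!\, h!\, n_{aa}!)$, and sums all outcomes no more
probable than the observed one (ties included up to a $10^{-12}$ relative
tolerance). For the q-values, $\pi_0$ is estimated by the natural cubic
spline of $\hat\pi_0(\lambda)$ over $\lambda = 0.05, \dots, 0.95$ evaluated
at $\lambda = 0.95$, clamped to $[1/m, 1]$; with fewer than 100 p-values the
estimate falls back to $\pi_0 = 1$, where the procedure reduces exactly to
Benjamini–Hochberg. Whether p-values should be pooled across breeds for
q-value estimation is genuinely open; per-breed estimation is the default
because the per-breed p-value populations have different null mixtures
(different sample sizes and allele-frequency spectra), and `pool = TRUE` is
exposed. Breeds with fewer than 5 samples trigger a warning — the exact test
has essentially no power there — but their cells are still computed.

`ancestralSubset` selects markers segregating in every group (MAF > 0.01 in
at least two breeds of each group by default), the standard device for
damping ascertainment bias in between-group comparisons.

# F-statistics and diversity

`wcFstats` implements the Weir–Cockerham (1984) variance components per
locus — $a$ (among breeds), $b$ (among individuals within breeds), $c$
(within individuals) — and reports multi-locus estimates as ratios of sums:
$\hat\theta = \sum a / \sum (a+b+c)$ (F~ST~), $F = 1 - \sum c / \sum(a+b+c)$
(F~IT~), $f = 1 - \sum c / \sum(b+c)$ (F~IS~). Monomorphic loci contribute
nothing (skipped, never 0/0). Under these definitions the identity
$(1-F) = (1-\theta)(1-f)$ holds to machine precision and is asserted in the
tests. Note that the estimator is not unbiased at small $n$ for degenerate
designs: two breeds that are literal sample-for-sample copies give
$\hat\theta \approx -1/(2(n-1))$, not 0, which is why the null-divergence
test uses a decent sample size.

Per-breed expected heterozygosity uses the unbiased small-sample form
$2\hat p(1-\hat p)\, n'/(n'-1)$ with $n'$ the allele count, averaged over
SNPs with $n' \ge 2$. F~IS~ per breed is defined as one minus the ratio of
the SNP-averaged observed to the SNP-averaged unbiased expected
heterozygosity; the alternative (averaging per-SNP ratios) is exposed via
`perSnpRatio = TRUE` since the two differ and field descriptions are often
ambiguous about which is meant. Reliability is a standard deviation over
resampled SNP subsets; desk-scale defaults are 100 resamples of 1,000 SNPs
(production analyses of the 10,000 × 5,000 kind are available by argument).

# Linkage disequilibrium

`ldR2` computes Hill's $r^2 = D^2 / (p_A p_a p_B p_b)$ within one breed for
all same-chromosome pairs up to a distance cap. Haplotype frequencies come
from the standard EM over unphased genotypes (only the double-heterozygote
class is phase-ambiguous). The EM starts from linkage-equilibrium product
frequencies, which also deterministically resolves likelihood ties, and
stops when the log-likelihood moves by less than $10^{-8}$ (configurable;
the ML fixed point is reproduced to $10^{-6}$ in $r^2$ when run tighter).
Non-converging pairs are excluded and counted. `ldDecay` bins pairs into
half-open distance bins $[kw, (k+1)w)$ and reports empty bins explicitly.

# Distances and trees

The allele-sharing distance between individuals is
$1 - \bar s$ with per-SNP sharing $s \in \{0, \tfrac12, 1\}$ (identical
dosages share both alleles, dosages one apart share one), averaged over SNPs
called in both individuals; a pair with no overlap is an error, never a
guess. The Reynolds distance between breeds is the coancestry ratio
$\sum_l 2(p_{1l}-p_{2l})^2 \big/ \sum_l 2(p_{1l}+p_{2l}-2p_{1l}p_{2l})$,
computed from frequencies alone, skipping loci where either breed's
frequency is undefined. The plain (uncorrected) coancestry ratio is what
PHYLIP-style workflows consume and is the only variant implemented: with
chip-scale marker counts and 14–31 animals per breed, the small-sample
correction moves distances far less than bootstrap noise does.
$-\ln(1-\theta)$ is available via `transform = "minuslog"`.

Neighbor-joining (`njTree`) is the Saitou–Nei agglomeration; the
implementation is `ape::nj` behind a validating wrapper (symmetry, zero
diagonal, no NaN; optional clamping of negative branch lengths). Bootstrap
supports (`bootstrapSupport`) resample **SNP columns** with replacement —
SNPs are the only exchangeable unit here, and both ASD and Reynolds trees
are functions of per-SNP summaries — rebuild the tree per replicate, and
attach to each internal edge of the point-estimate tree the percentage of
replicates containing the same bipartition (matched by bipartition identity
via `ape::prop.clades`, hence robust to node rotation). Outgroup rooting is
`ape::root` on the outgroup's pendant edge.

# Ordination

`pcaGenotypes` centers each SNP column at twice its mean allele frequency
after imputing missing dosages at the column mean — the simplest policy that
uses all available information without dropping individuals — and takes the
SVD; eigenvalues are squared singular values over $n-1$. Columns are
unscaled by default: the choice is orientation-invariant, matches common
genotype-PCA practice, and unit-variance and Patterson
($\sqrt{p(1-p)}$) scalings are exposed for comparison. Axis signs are
canonicalized (largest-magnitude loading positive) so results are invariant
to individual ordering.

`betweenBreedPca` is the PCA of breed-mean rows of the same centered matrix,
each breed weighted by its sample size. With the shared $n-1$ divisor the
Huygens decomposition (between + within = total) is exact, so the reported
`variancePartition` — the between-breed share of the total individual
variance — is an exact decomposition, not an approximation. Individuals are
projected onto the between-breed axes, and `compareAxes` reports unsigned
correlations between loading vectors of the two analyses.

`ldResidualCorrection` reproduces the SMARTPCA-style LD correction: each
centered SNP column is replaced by its residual from a no-intercept
regression on up to two preceding SNPs on the map, each within 200 kb;
original columns serve as predictors, the first SNP of a chromosome is left
unchanged, and rank-deficient predictor sets fall back to the usable
subspace via pivoted QR.

`dispersionEllipse` summarizes a 2-D score cloud by the bivariate-normal
ellipse with nominal coverage $c$: semi-axes
$\sqrt{\chi^2_2(c)\,\lambda_i}$ along the covariance eigenvectors. Its
empirical coverage on large normal samples matches the nominal level to
±0.01, which the acceptance checks verify.

# Spatial PCA

`gabrielGraph` connects two breeds when no third lies strictly inside the
open disk having their segment as diameter. The open-disk rule matters on
degenerate lattices (a point exactly on the disk boundary does not block an
edge — the unit square keeps both diagonals); squared distances are computed
directly, without a square-root round trip, to keep such boundary cases
exact. Longitude/latitude are projected by a local equirectangular
projection about the centroid (adequate for the few-hundred-km spans this
analysis targets; planar coordinates can be supplied directly). The weight
matrix `L` is the row-normalized adjacency; binary weights would change
Moran's *I* values, so the convention is fixed and recorded.

`spca` decomposes $H = X'(L+L')X / (2n)$ with $X$ the column-centered
breeds × SNPs frequency matrix. The $1/(2n)$ scaling is chosen so that the
method's defining identity
$$\lambda_k = \mathrm{var}(s_k) \times I(s_k)$$
holds **exactly** per axis (variance with divisor $n$; Moran's *I* of the
axis score) — this identity is the testable anchor of the implementation and
is asserted to $10^{-8}$ on random fixtures. Positive eigenvalues are global
structures (neighbors alike: clines, patches), negative ones local
(neighbor contrasts); axes are ordered by decreasing eigenvalue. The
decomposition is done in the row space of $X$ (rank ≤ number of breeds), so
the SNP × SNP matrix is never materialized. With identity weights the
analysis collapses to a PCA of $X$ (divisor $n$), which the tests use as an
oracle. Disconnected graphs are analyzed jointly with a warning; isolated
nodes break the $\sum W = n$ normalization behind the identity, so they are
worth heeding. `colorplotScores` min–max scales up to three leading score
vectors into RGB channels (constant or absent channels sit at 128) for map
rendering by external tools.

# Admixture

`fitAdmixture` fits the binomial admixture model — dosage
$g_{il} \sim \mathrm{Binomial}(2, \sum_k q_{ik} p_{kl})$ — by plain EM with
closed-form updates, as in the frappe lineage of programs; no quasi-Newton
acceleration (an acceleration flag would change iteration counts, not fixed
points, and plain EM keeps the per-iteration likelihood-ascent property that
the tests assert). Missing genotypes are simply omitted from the likelihood.
$P$ is clamped to $[10^{-9}, 1-10^{-9}]$ after each M-step to avoid
degenerate likelihoods while leaving the ascent property intact to machine
precision. Multiple random starts (Q rows Dirichlet(1,…,1), P uniform on
(0.05, 0.95)) are derived from the master seed by fixed offsets and the best
final likelihood wins. The desk-scale default cap is 2,000 iterations with
a $10^{-6}$ log-likelihood tolerance; production-style runs of 10,000
iterations are one argument away. Convergence is recorded (`converged`), as
the criterion is empirical in this model family. `matchClusters` resolves
label switching by a minimal-cost column assignment (exhaustive for K ≤ 8,
greedy above), and `admixtureScan` fits a K range and tabulates final
log-likelihoods, which must be non-decreasing in K up to EM tolerance.

# Pipeline, determinism, and problem sizes

`runPipeline` executes the stages in the study's order, writes plain-text
artifacts (TSV, Newick, JSON) plus a JSON report with per-stage counts,
headline statistics, wall times and an md5 manifest, and aborts on a stage
error with the stage name and the partial manifest. One master seed fans out
to per-stage seeds by fixed offsets so any stage can be rerun in isolation;
a rerun with the same configuration and seed reproduces every artifact
md5-identically. The package exposes all functionality as R functions (this
is an analysis library, not a shell tool); the pipeline configuration object
plays the role a command line would.

Test and example problem sizes are deliberately desk-scale: the worldlike
panel is ~4,000 retained SNPs × 287 individuals; parameter-recovery checks
use 2,000–20,000 SNPs and 40–100 individuals; the heaviest check (drift
recovery of Weir–Cockerham $\theta$ against a Monte-Carlo oracle) uses ten
20,000-SNP replicates plus one 200,000-locus oracle panel. These sizes make
the full suite run in about a minute while keeping Monte-Carlo error well
inside the asserted tolerances.

# Known limitations

* The generator's exchangeable sites mean LD-related behavior is validated
  on constructed tables, not on realistic haplotype structure.
* The equirectangular projection is inappropriate for continental-scale
  graphs near the poles; supply planar coordinates for such cases.
* The HWE exact test and q-value machinery assume biallelic SNPs
  throughout; multi-allelic markers are out of scope.
* Admixture EM finds local maxima; the multi-start default is modest, and
  strongly admixed panels may need more starts and iterations.
* Negative branch lengths from NJ are reported as computed unless clamped;
  bipartition supports are attached to the point tree only (no consensus
  tree is built).
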