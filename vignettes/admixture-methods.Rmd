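---
title: "Detecting and quantifying admixture with admixkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying admixture with admixkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

European domestic pig breeds carry substantial Chinese ancestry: breeders
during the Industrial Revolution crossed Asian pigs into Northern European
stock, and gene flow between domestic pigs and wild boars has continued
since. `admixkit` implements the statistical machinery used to detect and
quantify such admixture from SNP-chip genotypes: the three-population
(f3) test, the F4-ratio estimator of mixture proportions, ADMIXTURE-model
ancestry fractions, drift-based population trees, and a coalescent
simulator of a multi-population demography so that every claim the package
makes can be checked on data with a known truth.

This vignette explains the models, the defaults, and the design choices;
the test suite asserts every quantitative statement made here.

# f-statistics and the block jackknife

For per-SNP alternate-allele frequencies $a, b, c, d, x$ and allele-copy
counts $n_x$:

* $f_2(A,B)$ averages $(a-b)^2 - \frac{a(1-a)}{n_a-1} - \frac{b(1-b)}{n_b-1}$,
  an unbiased estimate of the squared frequency drift between two
  populations;
* $f_3(X;A,B)$ averages $(x-a)(x-b) - \frac{x(1-x)}{n_x-1}$. Under any
  tree-like history the expectation is positive (shared drift on X's
  branch); it can only be negative when X is a mixture of sources related
  to A and B. The subtracted term removes the upward-noise bias of $x$
  appearing in both factors; SNPs where the target has fewer than 2 allele
  copies are dropped. A 100,000-draw binomial Monte Carlo in the test
  suite confirms the corrected term is unbiased at $n = 10$ diploids while
  the uncorrected product is visibly biased.
* $f_4(A,B;C,D)$ averages $(a-b)(c-d)$; no correction is needed because no
  population repeats.

Aggregation is the unweighted mean over complete-case SNPs, matching the
convention of the *threepop* implementation family. Standard errors come
from a weighted delete-one-block jackknife over contiguous blocks of
SNPs in (chromosome, position) order; the final short block is kept and
handled by Busing-style weights. `Z = estimate / SE`, and `Z < -2` is the
conventional admixture call for f3. A statistic constant across blocks has
SE exactly 0, and on data simulated as independent blocks the jackknife SE
tracks the empirical replicate SD within 20%.

Block-size defaults: 200 SNPs for chip-density real data (the window is
chosen to span far beyond typical linkage disequilibrium), 5,000 for dense
simulated data; both are exposed as `block_size` everywhere. For our own
simulated fixtures with roughly 200–300 SNPs per independent locus we use
1,000-SNP blocks for f3 power runs and 500-SNP blocks for F4-ratio runs so
that each block spans several independent loci while at least 20 blocks
remain — chosen from the design (block ≳ 2–4 loci), not tuned to outcomes.

## The F4-ratio

With an outgroup `Sum`, a wild reference `EUW`, an unadmixed European
breed `IB`, and a Chinese donor representative `BMX`, the proportion of
IB-like ancestry in an admixed breed `EUD` is

$$\alpha = \frac{f_4(\mathrm{EUW}, \mathrm{Sum}; \mathrm{EUD}, \mathrm{BMX})}
                {f_4(\mathrm{EUW}, \mathrm{Sum}; \mathrm{IB}, \mathrm{BMX})},$$

and the Chinese fraction is $1-\alpha$. The jackknife is applied to the
ratio itself — numerator and denominator are recomputed on every
delete-one-block replicate — because the two f4 statistics share SNPs and
are strongly correlated; propagating their separate SEs would be wrong.
When the denominator sits within 10 SE of zero the estimate is flagged
unstable (the references no longer separate the two ancestries).

# Quality control

`filter_samples()` (call rate, default 0.95) and `filter_markers()` (MAF,
default 0.05) apply the thresholds exactly as counted on non-missing
genotypes. `ld_prune()` mirrors PLINK's `--indep-pairwise 50 5 0.5`:
within each 50-marker window (step 5, per chromosome), while any retained
pair exceeds $r^2 = 0.5$ on dosages, the member with lower MAF is removed
(ties remove the later marker); a brute-force greedy oracle in the tests
reproduces the retained set. $r^2$ is computed on unphased dosages with
pairwise-complete observations, appropriate for chip data.

`estimate_ibd()` is the method-of-moments relatedness estimator: observed
identity-by-state counts per pair are compared with their expectations
given allele frequencies to solve for P(IBD = 0, 1, 2), bounded into
[0, 1] and renormalised; `pihat = P(IBD=2) + P(IBD=1)/2`. When
frequencies are estimated from the data the expectations use unbiased
allele-count moments (products of distinct draws without replacement),
which removes the finite-sample inflation of plug-in frequencies. Because
the probabilities are bounded at zero, pi-hat for truly unrelated pairs is
half-normal rather than centred noise: with ~8,000 near-independent
markers its mean sits near 0.02–0.03 and most values fall below 0.05,
which is what the tests assert. Duplicate pairs give pi-hat 1 and
parent–offspring pairs 0.5 within a few percent.

`drop_related()` removes, within each population group separately (as one
does when breeds are analysed separately), the sample participating in the
most pairs with pi-hat above the threshold (default 0.3), iterating until
no such pair remains. Which member of a related pair to drop is not
dictated by the method, so we fixed a deterministic rule: highest degree,
then lower call rate, then the lexicographically later id. The greedy rule
is verified against an independently coded oracle on random 5-sample
graphs.

# Drift-normalised PCA

Markers are centred by twice their sample allele frequency and scaled by
$\sqrt{\hat p (1-\hat p)}$ with the shrunken frequency
$\hat p = (\mathrm{count}+1)/(2n+2)$, the normalisation under which each
marker contributes variance proportional to drift. Missing entries are
mean-imputed (zero after centring), which keeps the estimator
deterministic. Coordinates are SVD scores ($UD$); variance fractions are
eigenvalue shares; component signs are fixed by making the
largest-magnitude loading positive so output is reproducible. Zero-variance
markers (including all-heterozygote columns) are excluded as
non-informative.

# ADMIXTURE-model ancestry by EM

The binomial admixture likelihood
$\sum_{ij} [\, g_{ij}\log(QP)_{ij} + (2-g_{ij})\log(1-(QP)_{ij})\,]$ is
maximised by FRAPPE-style EM updates, which are monotone in the
log-likelihood — simpler and more robust than quasi-Newton block
relaxation, at the price of slower convergence, which is acceptable at the
scales this package targets. Missing genotypes contribute nothing. $P$ is
clipped to $[10^{-6}, 1-10^{-6}]$ each iteration to avoid $\log 0$; $Q$
rows start from a symmetric Dirichlet(1) draw and $P$ from
Uniform(0.05, 0.95), both seeded; by default 5 seeded restarts are run and
the best likelihood kept, mitigating local optima. At $K=1$ the update
reaches the closed form ($P$ = sample frequencies) after one iteration.

`cv_error()` follows the cross-validation logic used to choose $K$:
non-missing genotype entries are split into folds (in canonical
sample/marker-id order, so masking is invariant to dataset permutation),
the model is refitted with each fold masked, and the mean squared
prediction error $\overline{(g - 2QP)^2}$ on held-out entries is averaged
across folds. On data simulated from three deeply diverged populations the
error is minimised at $K = 3$.

# Drift trees

`f2_matrix()` assembles pairwise f2 distances with jackknife SEs (negative
point estimates, possible under sampling noise, are clamped to zero).
`build_tree()` applies neighbour joining, floors negative branch lengths
at zero, and roots on the chosen outgroup, splitting its pendant edge at
the midpoint; labels are sorted internally so the topology is independent
of input order. Full maximum-likelihood tree search with migration edges
is out of scope; NJ on f2 reproduces the topology-level conclusions the
simulation study targets. `variance_explained()` refits branch lengths by
non-negative least squares on the path-incidence system and reports
$1 - SS_{res}/SS_{tot}$ about the mean pairwise distance, with the
residual matrix attached; on an additive metric it returns exactly 1.

## Classifying the wild/domestic placement

The simulation study's qualitative claim concerns where the wild-boar
clade attaches: with domestic-to-wild gene flow the wild groups and the
domestic breeds remain separate groups, while wild-to-domestic gene flow
at 4–6% per generation buries the wild clade inside the domestic
radiation. `classify_group_placement()` operationalises this: walking
rootward from the wild clade's common ancestor, every successive sister
that is a single domestic tip is one "interleaved" breed — a breed
individually closer to the wild clade than to the rest of its own group,
the signature of received wild ancestry. Two or more interleaved breeds
(or a non-monophyletic wild group) classify as "nested"; otherwise
"separate". The threshold of two reflects that a single adjacent breed can
arise from estimation noise or from unrelated confounds (for instance,
Asian-admixed breeds being displaced toward the root), whereas several
breeds independently interleaving between the wild clade and the remaining
domestics cannot.

# The coalescent simulator

`simulate_genotypes()` draws each region as one non-recombining genealogy
under a structured coalescent: within every population, lineage pairs
coalesce at rate $k(k-1)/(4N_e)$ per generation; at split times all
lineages of the derived population move to the ancestral one; and during a
migration pulse window each lineage of the recipient moves to the donor
with the per-generation rate, applied at discrete generations. Mutations
are infinite-sites, Poisson with mean $\mu L \times$ branch length.
Consecutive chromosomes within a population are paired into diploids, and
loci are concatenated with each region as its own "chromosome", so
jackknife blocks spanning several regions are independent. Everything is
driven by one seed.

Calibration checks in the suite: a single population at $N_e = 10{,}000$
reproduces $\pi = 4 N_e \mu$ per site within 5% (the acceptance run uses
4,000 regions, chosen so the Monte Carlo standard error, about 0.3% of the
expectation, is well inside the 5% band); segregating sites match
Watterson's expectation; and lineage-tracked migrant ancestry after a
10-generation pulse at rate $m$ matches $1-(1-m)^{10}$ within sampling
error for $m \in \{1\%, 2\%, 4\%, 6\%\}$.

A pulse "starting at generation $T$ before present and continuing $d$
generations" acts, forward in time, from $T$ toward the present, i.e. at
backward generations $T-d+1, \dots, T$. The source paper does not state
this convention; we fixed it so that recipients that came into existence
exactly at $T$ (the earliest breed isolations) can receive the flow.

## The pig-history demography

`build_pig_model()` encodes the published simulation model: effective
sizes $N_{anc} = N_{Sum} = 10{,}000$, $N_{EU} = 175{,}000$,
$N_{AS} = 170{,}000$, $N_{EUD} = 20{,}000$, $N_{EUW} = 8{,}000$,
$N_{ASD} = 26{,}000$, $N_{ASW} = 36{,}000$; $\mu = r = 10^{-8}$ per bp per
generation; five years per generation; 8 European breeds, 3 Asian breeds,
7 European wild groups and 1 Asian wild group isolated at $N_e = 2{,}000$
between 40 and 60 generations BP; Asian-to-European pulses into six breeds
starting 40 generations BP for 10 generations at per-breed rates
alternating 1% and 2%; wild/domestic pulses between five breed/group pairs
starting 30 generations BP for 10 generations at 2, 4 or 6% per
generation, directed according to the scenario (I: domestic→wild, II:
wild→domestic, III: I plus Asian flow, IV: II plus Asian flow).

Choices the published description leaves open, fixed here as package
defaults:

* isolation times are evenly spaced over [40, 60] generations BP
  (deterministic, for reproducibility), a single isolate sits at 50;
* the six Asian-flow recipients and five wild/domestic pairs are the first
  breeds/groups by label; per-breed Asian rates alternate 1%, 2%;
* split times the model needs but the description omits: wild/domestic
  splits at 2,000 generations BP (about 10,000 years at 5
  years/generation, the age of domestication), the Europe–Asia split at
  200,000 and the Sumatran outgroup at 300,000 generations BP — of the
  order of the ~1 Myr divergence of European and Asian *Sus scrofa*.
  These three are defaults of this package, not published values.

Intra-locus recombination is not modelled (each region is one genealogy);
`subloci` splits a region into several independent genealogies as a coarse
approximation. Per-block statistics only require independence *between*
blocks, which concatenated independent regions provide. No SNP-chip
ascertainment bias is emulated: simulated site-frequency spectra are
neutral-coalescent, not chip-like, so absolute diversity-dependent
quantities (for instance raw f2 magnitudes) are not comparable to
Porcine-60K values even though the admixture contrasts are.

# What the simulations do and do not establish

Passing tests on these fixtures show that the estimators recover the
quantities they target under the stated demography with clean, complete,
unascertained genotypes. They do not establish robustness to chip
ascertainment, genotyping error, strand misassignment across platforms, or
unmodelled substructure in real data — which is why the QC stage (marker
intersection on merge, call-rate, MAF, LD pruning, relatedness removal)
exists as a separate, tested layer.

# Problem sizes used in the checks

The simulation conditions mirror the study design (1,000 regions of 50 kb
and 40 chromosomes per population) where the check needs them, and are
scaled down where a smaller design already gives the Monte Carlo precision
the assertion requires: f3 power runs use 110 regions x 120 chromosomes
(>= 20,000 SNPs) with 40 replicates; F4-ratio recovery 50 regions x 200
chromosomes with 20 replicates per mixing fraction; tree-placement runs
300 regions and 20 chromosomes per population per scenario-rate
combination; neutral-diversity calibration 4,000 two-chromosome regions;
relatedness calibration ~8,000 near-independent markers. Each choice is a
precision decision stated here once and reused by the tests and the
acceptance script.

# Known limitations

* The relatedness estimator assumes near-linkage-equilibrium markers;
  applying it without pruning inflates its variance substantially.
* NJ on f2 distances is a method-of-moments substitute for Gaussian ML
  tree search; with strong confounding admixture the set of breeds that
  fall outside their own radiation can differ from an ML tree, which is
  why the placement classifier counts interleaved breeds instead of
  asserting strict monophyly of the domestic group.
* EM convergence slows near the optimum; for publication-grade Q estimates
  raise `max_iter` and lower `tol` beyond the test defaults.
* The merge step keeps strand-ambiguous (A/T, C/G) markers in the first
  dataset's orientation and never strand-flips; merging across genotyping
  platforms with inconsistent strand conventions requires external
  harmonisation first.
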