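---
title: "Methods: trait architecture and the accuracy of genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait architecture and the accuracy of genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitarch)
```

This vignette documents the statistical models, estimators and design
decisions behind `traitarch`. The package studies a single scientific
question on synthetic data: how does the *architecture* of a complex trait —
the distribution of variance across loci — shape what genome-wide marker
data can deliver, both for locus discovery and for genomic prediction? The
three trait archetypes are modelled on contrasting dairy-cattle traits: a
spotting-type coat-colour trait with three moderate loci, a milk-fat
percentage trait with one major gene, and a near-infinitesimal conformation
trait.

All problem sizes used here and in the examples are deliberate desk-scale
choices: a few hundred to ~1,100 individuals and a few hundred to 2,000
SNPs, so that every experiment in the test suite runs on a single core in
minutes. The statistical machinery is identical at any scale.

## 1. The synthetic population

`sim_population()` runs a forward-in-time Wright–Fisher simulation of
`2 Ne` haplotypes for `n_generations` (default `4 Ne`, enough for the
drift–recombination–mutation balance of LD to establish). Each generation
every haplotype is a recombinant gamete of two randomly drawn parents;
crossovers are Poisson on the genetic map (Haldane model, no interference)
and recurrent mutation at rate `mu` per locus per meiosis keeps the panel
polymorphic. The final generation is expanded into `n_sires` paternal
half-sib families: each offspring receives one recombinant gamete from its
sire and one from a random dam.

The default map — 2,000 SNPs evenly spaced on 5 chromosomes of 0.6 Morgans,
`Ne = 100`, `mu = 2.5e-4` — was calibrated so that the mean adjacent-SNP
r² on the QC-passed panel is ≈ 0.23–0.25, the low-LD regime typical of a
livestock population of effective size ~100 genotyped on a dense array
(r² between adjacent SNPs ≈ 0.27). Two practical notes from that
calibration: at `mu = 1e-3` mutation breaks LD at a rate comparable to
recombination between adjacent SNPs, capping attainable r² near 0.14; and
r² is best measured on the post-QC panel, because rare variants depress the
raw average. The simulator makes no attempt to emulate ascertainment bias
of commercial arrays, varying recombination intensity, or selection; LD
level and family structure are the two properties the analyses depend on.

`qc_filter()` applies three per-SNP rules — call rate ≥ 0.90, minor allele
frequency strictly greater than 0.02, Hardy–Weinberg chi-square (1 df)
P ≥ 1e-5 — then mean-imputes surviving missing calls.

## 2. Trait archetypes

`trait_architecture()` places the moderate loci and the polygenic tail;
`sim_trait()` draws effects and phenotypes:

* `black_like` — three moderate loci on distinct chromosomes explaining
  9.4%, 6.0% and 8.8% of the *phenotypic* variance, plus a t-distributed
  tail (4.012 df).
* `fat_like` — one locus explaining 30% of the phenotypic variance plus a
  t-distributed tail.
* `type_like` — no moderate loci; a normally distributed tail in which, by
  definition, no single locus may exceed 0.5% of the genetic variance
  (enforced by iterative capping and rescaling).

Moderate-locus fractions are stated on the phenotypic scale because that is
how such loci are reported from field data; `sim_trait()` converts them to
genetic-variance fractions as `frac / h2` and sizes each effect against the
empirical dosage variance of its locus. Tail effects are rescaled so that
the tail carries exactly the remaining genetic variance, and environmental
noise is added so the heritability of a record equals `h2`; with `h2 = 1`
the phenotype *is* the true breeding value. Tail loci are drawn excluding a
±25-SNP window around each moderate locus so the nominal fractions are not
inflated by linkage.

The discovery/validation split is family-disjoint by default: whole sire
families are assigned to validation, so no validation animal has a paternal
half-sib among the reference records. This emulates forward validation on a
later cohort. With a random split instead, validation animals have many
close relatives in the reference and realised accuracies are dominated by
family covariance rather than marker effects — we observed 0.84–0.94 for
every archetype under random splitting, wiping out the method contrast the
experiment is designed to expose.

## 3. Kinship and mixed models

`build_w()` centres dosages by twice the allele frequency,
`build_grm()` forms **G** = **WW**′/Σ2pⱼ(1−pⱼ). Frequencies should be
estimated on the reference animals and reused for validation so no
validation information leaks into the predictor. `grm_pair()` builds the
segment GRM **G₁** and rest-of-genome GRM **G₂** from disjoint SNP sets.

`greml()` maximises the restricted likelihood of
y = **X**b + Σₖ gₖ + e, gₖ ~ N(0, **G**ₖ σ²ₖ), by EM-REML,

σ²ₖ′ = σ²ₖ + σ²ₖ² (y′**P** **G**ₖ **P**y − tr(**P G**ₖ))/n,

which is monotone in the restricted likelihood and keeps estimates in the
parameter space — a component driven to the boundary is reported as exactly
zero, a property the segment-variance analysis relies on (about half of all
null estimates are expected at zero). Every fourth iteration a safeguarded
Aitken extrapolation is attempted and kept only if the likelihood does not
decrease. With one kernel the model is rotated to the eigenbasis of **G**
so an iteration costs O(n); with several kernels dense algebra is used.

`gblup()` solves the animal-model equations: the mean by GLS, then
ĝ = σ²_g **G**[·, train] **V**⁻¹(y − µ̂), which predicts unphenotyped
animals through their genomic relationships. `snp_blup()` is the
marker-effect formulation (ridge regression with λ = σ²_e/σ²_u,
σ²_u = σ²_g/Σ2pⱼ(1−pⱼ)); the two are algebraically the same predictor, and
the test suite checks their GEBV agree to 1e-6. Realised accuracy is
r(GEBV, y_val)/h with h = √h².

## 4. GWAS with a random sire effect

`snp_scan()` fits, for each SNP, y = µ + x b + **Z**s + e with sire effects
s ~ N(0, **I**σ²_S). The variance ratio σ²_S/σ²_e is estimated once under
the no-SNP null model (REML via `lme4`) and held fixed across SNPs; the
residual scale is re-estimated per SNP from the generalised residual sum of
squares, so that with a zero sire ratio the statistic reduces *exactly* to
the ordinary least-squares F — an equivalence tested to 1e-8. Block
inversion of the family-structured **V** makes the scan a single vectorised
pass. `validate_hits()` refits discovery hits (P < 1e-4) on the disjoint
validation set and confirms at P < 0.001 by default, reporting the variance
explained as 2p(1−p)b²/var(y).

## 5. BayesA

`bayesa()` samples y = µ + Σⱼ xⱼuⱼ (+ **Z**v) + e with uⱼ ~ N(0, σ²_uⱼ)
and σ²_uⱼ ~ scaled-inv-χ²(ν, S), ν = 4.012, whose marginalisation gives the
moderately leptokurtotic t prior on effects. Single-site Gibbs updates with
residual updating run in C++; the prior scale defaults to
S = h²_guess · var(y) · (ν−2)/ν / (m · mean(2p(1−p))) so the prior-mean
marker variance matches a plausible genetic variance. The optional
polygenic term uses the inverse numerator relationship matrix of the sire
pedigree (Henderson's rules with one known parent). Chains are
deterministic given `seed`; defaults are 10,000 iterations, 2,000 burn-in,
thin 10, and the effective sample size of the σ²_e chain is reported as a
mixing diagnostic. With an enormous ν the sampler collapses to ridge
regression, which the tests exploit as an oracle.

`subset_accuracy()` ranks SNPs by |û| from a full-panel fit and refits on
the top-k subsets: traits governed by moderate loci approach full-panel
accuracy with a handful of SNPs, near-infinitesimal traits do not.

## 6. Segment variances and EM deconvolution

Following the regional-variance idea, `segment_variance_scan()` fits for
each 50-SNP segment y = µ + g₁ + g₂ + e with covariances **G₁**σ²_g1 and
**G₂**σ²_g2, and records p̂ᵢ = σ²_g1/(σ²_g1 + σ²_g2) (the proportion of
*genetic* variance; a phenotypic denominator is available). Because REML
truncates at zero, the p̂ᵢ of null segments are a ≈50:50 mixture of exact
zeros and the positive half of a squared normal; permuting phenotypes
(`permutation_sigma()`) and pooling gives the sampling standard deviation
σ = √(2·mean(null p̂)) of the square-root-scale error.

`em_effect_distribution()` treats each yᵢ = √p̂ᵢ as a censored noisy
observation of the true segment correlation tᵢ: yᵢ = max(tᵢ + eᵢ, 0) with
eᵢ ~ N(0, σ). The distribution of t is approximated on the grid
t = 0, 0.01, …, 1 (101 classes — fine enough to resolve sub-percent
variance classes on the t² scale while keeping the E-step a dense matrix
product) and class frequencies are estimated by EM, with
P(yᵢ | t) = φ(yᵢ − t; σ) for yᵢ > 0 and Φ(−t/σ) for yᵢ = 0. The
incomplete-data log-likelihood is non-decreasing every iteration (a tested
invariant). `bin_t_squared()` re-expresses the fitted distribution in bins
of variance explained, and `cumulative_variance_curve()` ranks segments
while zeroing segments within one segment of a selected one
(`exclusion_radius = 1`), so a major gene whose variance leaks into
flanking windows through linkage is not counted twice.

## 7. Deterministic accuracy theory

`accuracy_normal()` implements the closed-form prediction of GEBV accuracy
when effects are normally distributed, from N records of heritability h²
in a population of effective size Ne with genome length L Morgans:

q = 2NeL, k = 1/ln(2Ne), λ = qk/h², a = 1 + 2λ/N,

r = √(1 − λ/(2N√a) · ln((1 + a + 2√a)/(1 + a − 2√a))).

The logarithm in k is natural: only that reading reproduces the reference
accuracies 0.35 (N = 756, h² = 0.63), 0.26 (N = 327, h² = 0.74) and 0.39
(N = 756, h² = 0.83). The closed form has the exact integral representation
r² = ∫₀¹ (1 − u²)/(a − u²) du, i.e. an average of per-locus squared
accuracies v/(v + 2λ/N) over a distribution of standardised locus variances.

`accuracy_lepto()` generalises that representation to heavy-tailed effects,
for which no closed form exists: locus variances v ∝ 2p(1−p)β² with
β ~ t(4.012) and a U-shaped neutral allele-frequency density ∝ 1/(p(1−p))
truncated at 1/(4Ne), normalised to the same mean as the normal-case
calibration; loci are weighted by the variance they carry and the effective
residual is reduced by the variance already captured,
c = (2λ/N)(1 − r²h²), iterated to a fixed point, with quadrature refinement
until the accuracy is stable to 1e-4. This is a documented best-effort
reconstruction: it reproduces the qualitative behaviour (the leptokurtotic
accuracy exceeds the normal-effects accuracy throughout, markedly so for
high h²) but is not pinned to published second decimals, and the test suite
asserts only the ordering.

```{r theory}
p <- accuracy_params(N = 756, h2 = 0.63, Ne = 100, L = 30)
c(normal = accuracy_normal(p), leptokurtotic = accuracy_lepto(p))
```

## 8. Replication experiments

`architecture_contrast()` is the package's headline experiment: on each of
several replicate populations it simulates all three archetypes (record
heritabilities 0.63 / 0.83 / 0.74 and discovery sizes 756 / 756 / 327 for
type-like / fat-like / black-like — the spotting trait having fewer
recorded bulls), trains GBLUP and BayesA on the same discovery records and
compares realised validation accuracies pairwise. The paired design (same
genotypes, same trait, both methods) maximises the power of the method
contrast at desk scale. The expected qualitative pattern — BayesA beats
GBLUP under major-gene architectures and not under the near-infinitesimal
one — is asserted by sign tests in the test suite.

`run_pipeline()` drives the full analysis (simulate → QC → GWAS with
validation → GBLUP/BayesA → segment scan with permutation σ and EM
deconvolution → theory) from a YAML configuration, writes every artifact as
TSV under a run directory and records an md5 manifest; re-running the same
configuration reproduces identical files.

## 9. Limitations

The generator produces one discrete generation of paternal half-sib
families from a drift-equilibrium base: no multi-generation pedigrees,
selection, non-additive variance, sex chromosomes or genotyping error
beyond random missingness. Phenotypes are simple records with a set
heritability — progeny-mean deproofs are emulated only through `h2`.
Desk-scale genomes (a few Morgans) make absolute accuracies higher than
field values because the number of independent chromosome segments is
small; all claims tested are therefore comparative or structural, not
absolute reproductions of field numbers.
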