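---
title: "Single-step genomic prediction under selection: models and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic prediction under selection: models and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ssbreg studies a practical problem in animal breeding: when genotypes are
only available for *selected* individuals (elite sires and the newest
generation), single-step genomic evaluations must impute the marker
covariates of everyone else from the pedigree, and that imputation needs
the genotype means of the *unselected founders* — which are never observed.
The package implements the marker-effects-model answer to this: fit the
founder genotypic mean as a fixed regression on a pedigree-derived
covariate (the **J covariate**) instead of centering genotypes on an
unobtainable founder mean.

This vignette documents the models, the synthetic-data generator, the
numerical choices, and what the test suite does and does not establish.

## The genetic model

The genotypic value of individual $i$ is $g_i = \beta + m_i'\alpha$, where
$m_i'$ holds allele counts (0/1/2) at the panel loci and $\alpha$ the
substitution effects. Writing $k' = E(m_i')$ for the founder-generation
mean of the covariates, $\mu_g = k'\alpha$ is the mean of the linear
genotypic component in unselected founders, and $u_i = (m_i' - k')\alpha$
is the breeding value with null founder expectation.

For genotyped individuals the covariates are observed ($M_g$); for
nongenotyped individuals they are imputed by best linear prediction from
genotyped relatives through the numerator relationship matrix $A$:
$\hat M_n = A_{ng} A_{gg}^{-1} M_g$. Expanding the imputation around the
unknown $k'$ produces an extra regression term: the **J covariate**, equal
to $-1$ for every genotyped individual and $J_n = A_{ng}A_{gg}^{-1}(-\mathbf 1)$
for nongenotyped individuals, whose coefficient is $\mu_g$. The fitted
model is

$$ y = \mathbf 1 \mu + Z J \mu_g + Z M \alpha + U\epsilon + e, $$

with $\epsilon$ the imputation residuals of nongenotyped individuals
(prior precision the nn-block of $A^{-1}$ divided by $\sigma_g^2$), Gaussian
marker priors (BayesC with $\pi = 0$, equivalent to single-step GBLUP), and
fixed, known variance components. Predicted breeding values are
$\hat g = J\hat\mu_g + M\hat\alpha + U\hat\epsilon$.

Six analysis variants differ only in whether J is fitted and how the
covariates are centered:

| variant | J fitted | centering |
|---|---|---|
| `J`  | yes | none |
| `N`  | no  | none |
| `JC` | yes | whole matrix (observed + imputed rows) |
| `C`  | no  | whole matrix |
| `JCstar` | yes | observed rows only (single-step GBLUP convention) |
| `Cstar`  | no  | observed rows only |

Three exact identities structure the test suite: (i) with J fitted,
inference about $\alpha$ is invariant to any constant coding shift of the
covariates; (ii) whole-matrix centering changes the predictions by one
constant, so accuracy and bias are untouched; and (iii) centering observed
covariates by their own means reparameterises $\mu_g$ into
$\mu_g^* = \mu_g - v'\alpha$, the mean breeding value of the (selected)
genotyped individuals. All three are asserted to numerical precision.

## Why selection makes this matter

Under directional selection, allele frequencies move, so the genotyped
(selected) individuals' covariate means $v'$ are a poor stand-in for the
founder means $k'$. Without the J covariate, the missing term
$(J_n + 1)\mu_g$ is unmodelled signal that leaks into $\hat\alpha$ and
$\hat\epsilon$. The corruption is largest when $\mu_g$ is far from zero —
a QTL-bearing panel with all-positive effects — and negligible for
marker-only panels, where phase sign-symmetry drives $\mu_g$ toward zero.
With observed-only centering, however, $\mu_g^*$ is *guaranteed* nonzero
under selection even for marker-only panels, which is why `Cstar` (the
uncorrected single-step GBLUP convention) loses substantial accuracy while
`JCstar` does not. The evaluation layer reproduces all of these patterns.

## The simulator

`sim_study()` generates the complete study in three phases.

**Base population.** A pool (default 100 individuals) is initialised at
linkage equilibrium with allele frequencies uniform on $[0.2, 0.8]$ over an
oversampled candidate locus grid (default 8 candidates per retained locus,
evenly spaced on ten 0.1 Morgan chromosomes). Small-population random
mating is iterated; genetic drift builds linkage disequilibrium, monitored
each generation as the mean adjacent-locus $r^2$ on a panel selected
exactly as the final one will be (MAF $\ge$ 0.01, evenly spread). When the
target LD (default 0.30) is reached, one further round of random mating
yields the base diplotypes (default 721, half assigned male). Oversampling
matters because drift fixes loci; the panel is drawn from the survivors,
which mirrors how a real SNP panel is filtered on MAF before use. The
generator reproduces the two statistics reported for the real base
(MAF floor and adjacent LD) but *not* the bovine MAF spectrum, long-range
LD structure, or haplotype-block texture of a real genotyping array; tests
passing on these data show correctness of the machinery under a
plausible LD regime, not performance on cattle data.

**Expansion.** Base individuals are sampled in pairs with replacement to
produce the first recorded generation (one male and one female offspring
per pair; default 4000 pairs), followed by four nonoverlapping generations
of random mating (one male and one female offspring per dam, sires drawn
at random), ending in the founder generation G0. Meiosis uses Poisson
crossover counts (mean = map length), uniform crossover positions, no
interference, and no mutation. The pedigree is recorded from the first
offspring generation onward.

**Trait and selection.** QTL effects are Normal with mean $\mu_\alpha$
(default 0.2) and SD `sd_alpha`; TBV is the QTL allele-count row times the
effects; the genetic variance is the sample variance of TBV in G0 and the
residual variance is set from the target heritability. Five generations of
mass selection follow: the top `n_sires` males on own phenotype (ties
broken by id), each dam mated twice (independent sire draws by default,
a switch gives one-sire-per-dam), one offspring of each sex per dam.
Phenotypes cover G0–G4; genotypes cover the selected sires plus the whole
final generation, which is the validation set.

**Choice of `sd_alpha` (default 0.08).** Only the mean effect 0.2 is fixed
by the study design; the SD had to be inferred. Two published facts pin it
down: the effect vector is described as entirely positive (requires
SD $\lesssim 0.08$ at mean 0.2), and the printed generation means of TBV
advance by about 0.49 per generation, which against the expected sire-only
response $\tfrac12 i h^2 \sigma_P$ at the 5% male-selected proportion
implies $\sigma_g \approx 0.7$, i.e. an effect SD near 0.08–0.1. With
SD = 1 the founder mean is only about $2\sigma_g$, and the J covariate's
effect on accuracy — the phenomenon under study — all but disappears. The
value is a config knob (`sd_alpha`).

**Random numbers.** One master seed per replicate; the base, QTL
assignment, expansion and selection phases each draw from a named
substream derived from it, so any stage is independently reproducible.

## Numerical choices

- $A^{-1}$ is built directly from the pedigree by Henderson's rules with
  Mendelian sampling variances that account for parental inbreeding
  (ancestor-traversal inbreeding pass, compiled). The dense tabular $A$
  exists only as a small-instance oracle; block products
  $A_{ng}A_{gg}^{-1}V$ use the partitioned-inverse identity
  $-(A^{nn})^{-1}A^{ng}V$ through one cached sparse Cholesky factorisation
  of the nn-block, so $A_{gg}$ and $A_{ng}$ are never formed.
- The MME are solved exactly by block elimination: a Schur complement on
  the small dense block (intercept, J, markers) against the large sparse
  $\epsilon$ block, whose Cholesky factor is cached and shared across all
  variants and panels fitted to one dataset. Imputation residuals are
  instantiated for *all* nongenotyped pedigree members — with the sparse
  precision this costs little and keeps the model exactly equivalent to
  the full specification.
- Per-marker prior variance defaults to $\sigma_g^2 / \sum_j 2p_jq_j$ with
  frequencies from the observed genotypes of the fitted panel
  (`sigma2_alpha_rule = "sum2pq"`; `"per_marker"` gives $\sigma_g^2/m$).
  Frequencies are always taken from the raw allele counts, before any
  centering or coding shift, so shrinkage is coding-invariant.
- The Gibbs sampler (compiled, adjusted-residual bookkeeping, linear per
  sweep in the nonzeros) defaults to 50,000 iterations with 5,000 burn-in;
  burn-in is not dictated by the study design, so it is a config knob.
  Monte Carlo standard errors come from batch means. Everything the
  evaluation layer reports uses the exact MME path; the sampler exists to
  demonstrate the equivalence and for models where exact solves would not
  be available.
- Degenerate inputs: fixed loci are filtered from every panel; zero
  variance in TBV or predictions yields `NA` metrics rather than errors;
  fitting J when every phenotyped individual is genotyped is refused with
  advice (J is then collinear with the intercept); truncation-selection
  ties break by id for determinism.

## Problem sizes used by the checks

The full design (4000 dams, 200 sires, 40,000 phenotypes, 48,000
individuals) runs in this package but is not what the routine checks use.
The test suite and the acceptance script run the reduced design the
evaluation layer provides for desk-scale work: 800 dams / 40 sires — the
same 5% male-selected proportion — with 8,000 training phenotypes, 1,800
genotyped individuals and 3 replicates, which preserves every qualitative
pattern (J vs N gap on QTL panels, variant agreement on marker-only
panels, the observed-only-centering penalty, monotonicity in $h^2$, and
the PBLUP baseline level) at a few minutes per scenario. Accuracies at
this scale sit a few points below the full-scale ones for marker-only
panels, as expected from the smaller training set.

## Known limitations

- The founder generator matches two summary statistics of the real base
  population, not its full genetic architecture; absolute accuracies are
  therefore comparable only qualitatively to analyses of real cattle data.
- Variance components are treated as known (taken from the G0 calibration);
  no REML or sampling of variances is provided.
- Only $\pi = 0$ (pure ridge/ssGBLUP-equivalent) marker priors are
  implemented; variable-selection priors are out of scope.
- The H-matrix (breeding-value model) form of single-step GBLUP is
  discussed here only as the equivalent of the `Cstar`/`JCstar`
  conventions; it is not separately implemented.
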