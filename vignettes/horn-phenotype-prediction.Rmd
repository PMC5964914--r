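---
title: "Predicting polled and horned phenotypes: models and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting polled and horned phenotypes: models and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hornpred)
```

## The problem

Horn status in Merino sheep is scored in four classes — polled, knobs,
scurs, horned — and analysed through two derived binary traits:
polled/non-polled (P/NP: polled = 0, everything else = 1) and
horned/non-horned (H/NH: horned = 1, everything else = 0). The major
determinant is a biallelic insertion polymorphism in the 3'-UTR of *RXFP2*
on chromosome 10 (represented here as an ordinary biallelic marker at
position 29,456,047 bp), but penetrance is incomplete and strongly
sex-dependent: carrier males are frequently horned while females almost
never are. `hornpred` provides (i) a simulator that generates half-sib
populations with this architecture, and (ii) the prediction and inference
machinery used to evaluate marker-based prediction of the two traits:
single-SNP models, multi-SNP haplotype models, GBLUP with additive and
dominance genomic relationship matrices, causal-genotype prediction,
AIC-based mode-of-inheritance selection, and three validation designs.

## The mixed model

All traits are analysed as linear mixed models on the observed 0/1 scale:

$$\mathbf{y} = \mathbf{X}\mathbf{b} + \sum_k \mathbf{Z}_k \mathbf{u}_k +
\mathbf{e}, \qquad \mathbf{u}_k \sim N(0, \mathbf{K}_k \sigma^2_k), \quad
\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e).$$

Fixed effects are an intercept and a sex main effect. Random terms carry
arbitrary covariance structures: the pedigree numerator relationship matrix
$\mathbf{A}$ (tabular/Cholesky recursion, sparse inverse by Henderson's
rules with inbreeding), the VanRaden additive genomic relationship matrix
$\mathbf{G} = \mathbf{W}\mathbf{W}'/c$ with $w_{ij} = x_{ij} - 2p_j$ and
$c = 2\sum_j p_j(1-p_j)$, the classical dominance relationship matrix
$\mathbf{D} = \mathbf{H}\mathbf{H}'/\sum_j (2p_j(1-p_j))^2$ with dominance
codes $(-2p^2,\; 2p(1-p),\; -2(1-p)^2)$ for genotypes 0/1/2, or identity
covariances for marker, haplotype and sire effects.

Variance components are estimated by ML or REML through the profiled
likelihood of the variance ratios $\gamma_k = \sigma^2_k/\sigma^2_e$
(residual variance solved in closed form), optimised with `L-BFGS-B` on
$\log\gamma$. Likelihood evaluations use Henderson's mixed-model equations
with a sparse Cholesky factorisation whose symbolic pattern is computed
once and updated numerically, so a model with ~4,700 phenotyped offspring
and an 8,000-member pedigree fits in well under a second per likelihood
evaluation. Boundary estimates are allowed and flagged. AIC is always
computed from the ML likelihood with
`n_parameters = fixed effects + variance components`, which keeps Models
1-5 (below) comparable even though they differ only in random structure.

A deliberate design choice: the observed-scale *linear* mixed model is used
for every method, including the single-SNP fits for which a logistic mixed
model is the textbook alternative. A single engine keeps the four
prediction strategies directly comparable, and the accuracy metric (Pearson
correlation between prediction and the binary trait) is invariant to the
monotone rescaling a logistic link would introduce at a single locus. A
penalized-quasi-likelihood logistic option is left as future work, and AIC
values from the linear engine are not comparable in absolute terms with
values from logistic software — only the ranking semantics carry over.

## Modes of inheritance

Five single-locus models describe how the causal (or top-associated) marker
acts, with $\Lambda_i \in \{0,1,2\}$ the allele count and
$\Delta_i = 1$ for heterozygotes:

1. additive: one allele-substitution effect $\alpha$;
2. additive + dominance: adds a heterozygosity effect $\delta$;
3. sex-dependent additive: $\alpha_F, \alpha_M$;
4. additive + sex-dependent dominance: $\alpha, \delta_F, \delta_M$;
5. sex-dependent additive + dominance: $\alpha_F, \alpha_M, \delta_F,
   \delta_M$.

Marker effects are fitted as *random*, each sex-specific effect with its
own variance component (the most literal reading of a random effect with a
sex interaction; whether a common variance was intended is not documented,
so separate variances were chosen and recorded here). Sex always enters as
a fixed main effect so the marker terms are not confounded with the
overall sex difference. `select_mode_of_inheritance()` fits all five by
ML and reports the AIC improvement over Model 1; ties go to the lower
model id (parsimony by construction order). Incomplete penetrance is
deliberately *not* modelled in the fitting machinery — it lives only in
the simulator — so a perfectly specified fit still cannot reach accuracy 1,
which is the phenomenon the package exists to study.

The degree of dominance is summarised from genotype-class means
$m_0, m_1, m_2$ of the binary trait per sex: $a = |m_2 - m_0|/2$ with
orientation chosen so $a \ge 0$ (the flip is recorded),
$d = m_1 - (m_0 + m_2)/2$, degree $= d/a$; $|d/a| = 1$ is complete
dominance. Applied to the male horned-trait probabilities (0.67, 0.01,
0.00) this gives $|d/a| \approx 0.97$ — effectively complete dominance of
the non-horned allele in males.

## The simulator

`simulate_study()` composes four pieces, all reproducible from one seed:

* **Pedigree** (`simulate_pedigree`): 182 sires by default, each with a
  uniform 1-51 offspring, emulating a Merino resource population of 182
  sires with family sizes between 1 and 51 and roughly 4,000-5,000
  phenotyped sheep; the 1-51 range is the emulated condition, the uniform
  distribution over it is this package's choice. Offspring are spread over dams so a dam
  averages 1.5 offspring; sexes are independent Bernoulli(0.5) draws with
  labels `female`/`wether` (wethers are a label only; castration biology
  is out of scope).
* **Founder haplotypes** (`simulate_founder_haplotypes`): a mosaic copying
  model around the causal locus rather than a coalescent — simpler, and it
  makes the tag-causal r² directly controllable, which is all the
  prediction experiments need. Each haplotype draws a causal allele
  (frequency 0.3, matching the observed minor allele frequencies of
  0.29-0.30 at the predictive SNPs), then walks outward breaking a latent
  "linked" state with probability `switch_rate` per marker; designated tag
  markers instead copy the causal allele with exactly the probability that
  achieves the configured target r² (default 0.985, the LD observed
  between the two top predictive SNPs in Merino data), after a
  feasibility check against the Hill-Robertson bound. No attempt is made
  to reproduce a realistic LD *decay curve*: only a handful of pairwise
  r² values are known for this region, so both the tag r² and the
  background switch rate are exposed as configuration rather than
  guessed.
* **Gene dropping** (`gene_drop`): founders draw haplotype pairs from the
  pool; each offspring inherits one recombinant gamete per parent with
  Poisson crossovers along the physical map (default 1 cM/Mb). Phase is
  retained throughout, so haplotype construction never needs statistical
  phasing.
* **Phenotypes** (`assign_phenotypes`): each animal draws its horn-score
  class from the sex-by-genotype penetrance table. The default table is
  calibrated to the observed genotype-conditional probabilities:
  P(horned) of 0.67/0.01/0.00 (males) and 0.07/0.01/0.01 (females), and
  P(polled) of 0.04/0.53/0.78 (males) and 0.14/0.77/0.85 (females) for
  genotypes 0/1/2; knobs and scurs share the remaining mass equally. A
  polygenic liability value (gene-flow simulation down the pedigree,
  variance `sigma2_a`) shifts the horned-class probability on the logit
  scale; class probabilities of exactly 0 or 1 are left untouched. The
  default `sigma2_a = 0.2` leaves a residual polygenic liability
  heritability of about $0.2/(0.2 + \pi^2/3) \approx 0.06$ once the causal
  locus is accounted for, mirroring the drop of the underlying-scale H/NH
  heritability to about 0.06 that is observed when the top SNP is fitted
  in real Merino data. The logistic shift itself is a modelling choice of
  this package, not an asserted mechanism.

What the simulator does **not** emulate: realistic genome-wide LD
structure, selection and drift across generations, genotyping and
imputation error (a configurable `genotype_error` knob on the validation
genotypes stands in for imputation error when studying the causal-genotype
predictor), flock/year environmental effects, and the scoring difficulty
of wethers. Passing tests therefore demonstrate correctness of the
machinery under the stated generative model, not performance guarantees on
real chip data.

## Prediction strategies and validation

* **Single SNP** (`predict_marker_model` with a `moi_spec`): the marker is
  fitted — under its selected mode of inheritance — as random effect(s),
  optionally joint with a polygenic term using $\mathbf{A}$ or
  $\mathbf{G}$. Validation animals are predicted as intercept + sex effect
  + marker solutions applied to their genotypes + the BLUP of their
  polygenic value through its covariance with the training animals
  (validation animals sit in the mixed-model equations without records, so
  no phenotype leaks).
* **Haplotypes** (`build_haplotypes`, `pool_rare_haplotypes`,
  `haplotype_design`): alleles are bit-strings over the top 3/5/10 scan
  hits (or a window around the causal position); alleles under 2% copy
  frequency are pooled into one residual class; copy counts (rows sum
  to 2) enter as one random term with a shared variance. The pooling
  threshold applies to allele frequency, not carrier frequency.
* **GBLUP** (`gblup_predict`): additive and dominance genomic values with
  $\mathbf{G}$ and $\mathbf{D}$, variance components estimated on the
  training subset only; validation predictions either through the
  covariance blocks of $\mathbf{G}$/$\mathbf{D}$, or by back-solving
  per-marker effects
  $\hat{\alpha} = \mathbf{W}'\mathbf{G}_{tt}^{-1}\hat{\mathbf{g}}/c$ and
  applying them to validation genotypes. The two routes are algebraically
  identical; both are implemented and the equality is asserted in the test
  suite, which guards the back-solving code.
* **Causal genotype**: the simulator's true insertion genotype fitted as a
  single marker, optionally corrupted at a configurable error rate to
  emulate the imputation error that in practice degrades this predictor.

Validation designs: (i) fivefold cross-validation repeated five times with
animal-level random partitions; (ii) within-family prediction — every
half-sib family of an eligible sire (strictly more than 13 offspring) is
split roughly in half, odd counts toward training; (iii) across-family
prediction — approximately half of the eligible families wholly to
training, so no sire spans the split. Accuracy is the Pearson correlation
between prediction and the binary trait, reported per sex from the jointly
fitted model (a joint fit with per-sex scoring, rather than sex-stratified
refits, since the per-sex accuracies are descriptive summaries);
the standard error is the standard deviation across fold accuracies
divided by the square root of the number of contributing folds. Fold cells
with a constant observed trait are excluded from the mean with a warning.

## Numerical choices

* Covariance matrices receive a 1e-6 diagonal ridge before inversion.
* Variance-ratio optimisation: `L-BFGS-B` on $\log\gamma$ with box
  $[\log 10^{-8}, \log 10^{8}]$; estimates at the lower box are flagged as
  boundary (effectively zero) components.
* Henderson-system solutions are verified by a residual check
  ($\|C\theta - r\|/\|r\|$, reported as `mme_residual`) on every fit.
* Allele frequencies for $\mathbf{G}$ and $\mathbf{D}$ default to observed
  frequencies; externally supplied (e.g. base-population) frequencies are
  accepted.
* Missing dosages are excluded pairwise in QC and allele-frequency code;
  model fitting requires complete data, with mean imputation as an
  explicit, logged step.
* Tie-breaks: AIC ties go to the lower model id; p-value ties in marker
  selection go to the marker nearer the causal position, then lower bp.
* QC follows the chip rules: call rate < 0.90, Hardy-Weinberg 1-df
  chi-square > 600, minor allele frequency < 0.01, non-autosomal — a
  marker fails if any rule fires, and the report names every firing rule.
  (The chip-intensity GenCall score filter needs intensity data and is out
  of scope.)

## Problem sizes used in the checks

The test-suite and acceptance-script simulations use the full 182-sire
configuration (~4,700 offspring) where the claim under test concerns the
study scale — mode-of-inheritance recovery rates and the per-sex accuracy
benchmarks — and smaller half-sib designs (40-100 sires) where the claim
is algebraic and scale-free (solver equivalences, leakage checks,
relationship-matrix oracles). Heritability recovery uses 100 sires by 20
offspring (n = 2,000) with true $h^2 = 0.4$, averaged over seeds.
Mode-of-inheritance recovery uses 50 seeds in the test suite and a
15-seed summary rate in the acceptance script.

## Known limitations

* The linear observed-scale engine makes AIC values incomparable in
  absolute terms with logistic-software output; only rankings carry over.
* The mosaic founder model gives controllable pairwise LD, not a
  realistic decay profile; GBLUP results on simulated whole-genome
  backgrounds should be read qualitatively.
* `.ped`/`.map` text files carry no ref/alt orientation, so the PLINK
  reader orients alleles alphabetically; orientation never changes any
  downstream statistic, but dosage signs may differ from a VCF reading of
  the same data.
* Real-data phasing, chip-to-chip imputation and structural-variant
  detection are out of scope; the simulator always emits phase, and the
  causal insertion is modelled as an ordinary biallelic marker.
* Maternal-imprinting models and sex-chromosome handling are not
  implemented.
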