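# LPDstrat

Mixed-membership decomposition of bulk expression profiles and
DESNT-based stratification of prostate cancer cohorts.

## The problem

Prostate tumours are molecularly heterogeneous: a single prostatectomy
sample can contain regions carrying the poor-prognosis **DESNT**
expression signature alongside other expression programmes. Hard
clustering hides this, and it is the *proportion* of DESNT signal in a
sample — treated as a continuous variable — that tracks the risk of
biochemical (PSA) recurrence after surgery. This package is for
computational biologists and biostatisticians who want to

* decompose a gene-by-sample expression matrix into latent expression
  signatures with per-sample mixture proportions,
* classify *new* samples against a frozen decomposition, one sample at
  a time (the clinical use case), and
* relate a signature's proportion to time-to-event outcomes, up to a
  bootstrap-validated Cox model and a points-based nomogram.

## The model

Latent process decomposition (LPD): for sample $a$ and gene $g$,

$$\theta_a \sim \mathrm{Dirichlet}(\alpha), \qquad
  z_{ga}\mid\theta_a \sim \mathrm{Categorical}(\theta_a), \qquad
  e_{ga}\mid z_{ga}{=}k \sim N(\mu_{gk}, \sigma^2_{gk}),$$

fitted by variational EM with responsibilities $Q_{kga}$ and
per-sample Dirichlet posteriors $\gamma_{ak}$:

$$Q_{kga} \propto N(e_{ga};\mu_{gk},\sigma^2_{gk})\,
  e^{\psi(\gamma_{ak})}, \qquad
  \gamma_{ak} = \alpha_k + \sum_g Q_{kga}.$$

Signature proportions are $\hat\theta_{ak} = \gamma_{ak} / \sum_k
\gamma_{ak}$. The number of signatures is chosen by cross-validated
hold-out predictive log-likelihood; **OAS-LPD** ("one added sample")
projects new profiles by iterating only the sample's $Q$ and $\gamma$
with $\mu, \sigma^2, \alpha$ frozen. Cohorts are stratified by their
DESNT proportion into four bands (< 0.001, 0.001–0.3, 0.3–0.6,
> 0.6) and analysed with Kaplan–Meier/log-rank/Cox machinery. A
synthetic-cohort generator with full ground truth (expression,
survival with a planted log hazard ratio, binary genomic labels)
backs the validation suite. See `vignettes/lpd-stratification.Rmd`
for the methods account.

## Worked example

```r
library(LPDstrat)

# a synthetic prostatectomy-like cohort: 150 samples x 300 genes,
# 4 signatures, sparse mixing, planted risk signature, 30% censoring
sim <- simulateLPDCohort(lpdSimControl(seed = 42))

fit <- fitLPD(sim$expression, K = 4, priorMode = "estimated",
              control = lpdFitControl(seed = 42))
fit
#> LPDFit
#> LPDModel: 300 genes, 4 signatures
#>   prior mode: estimated  alpha: 0.0577 0.0667 0.0639 0.0769
#>   labels: sig1, sig2, sig3, sig4
#>   reference quantiles stored for 150 training samples
#> LPDDecomposition: 150 samples, 4 signatures
#>   bound: -66586.62  converged: TRUE ( 18 iterations )
#>   mean proportions: 0.227 0.243 0.263 0.267
```

The fitted Dirichlet concentrations (~0.06–0.08) recover the sparse
mixing of the generator, and the bound trace is non-decreasing. Now
stratify by the signature matching the planted risk profile and band
the DESNT proportion:

```r
desnt <- which.max(cor(signatureProportions(fit), sim$truth$theta[, 1]))
strat <- stratifyCohort(fit, desntSignature = desnt)
head(strat, 4)
#>   sample_id assigned_signature desnt_proportion desnt_band
#> 1     s0001                  4     0.2385002763          2
#> 2     s0002                  1     0.0002139038          1
#> 3     s0003                  3     0.5714143663          3
#> 4     s0004                  3     0.9993261522          4
table(band = strat$desnt_band)
#> band
#>  1  2  3  4
#> 81 23 10 36
```

About half the cohort carries essentially no DESNT (band 1), the rest
a continuum up to nearly pure — the banding used for Kaplan–Meier
group comparisons. The proportion itself goes into a Cox model with
the usual clinical covariates:

```r
d <- merge(sim$clinical, strat[, c("sample_id", "desnt_proportion")])
d$desnt <- d$desnt_proportion
fitCoxModel(d, c("desnt", "gleason", "psa", "stage", "margins"))
#> Cox proportional-hazards model (Breslow ties): 150 samples, 105 events
#>         term    coef     se      z        p    hr lower95 upper95
#> 1      desnt  0.9323 0.2649  3.519 0.000433 2.540   1.511    4.27
#> 2 gleason3+4  0.2611 0.2290  1.140 0.254114 1.298   0.829    2.03
#> 3 gleason4+3 -0.1789 0.2928 -0.611 0.541124 0.836   0.471    1.48
#> 4 gleasongt7 -0.3647 0.4570 -0.798 0.424821 0.694   0.284    1.70
#> 5        psa  0.0222 0.0139  1.592 0.111428 1.022   0.995    1.05
#> 6 stageT3-T4  0.0377 0.2161  0.175 0.861447 1.038   0.680    1.59
#> 7    margins  0.2137 0.2150  0.994 0.320048 1.238   0.813    1.89
#> training concordance: 0.5949
```

The DESNT proportion comes out as the only significant predictor
(planted log HR = ln 2 ≈ 0.69 per unit proportion; the estimate 0.93
± 0.26 is within sampling error at n = 150), while the clinical
covariates — generated independently of the signature — are correctly
null. `buildNomogram(coxFit)` re-parameterises such a model on a
0–100 point scale with survival tables at 1/3/5/7 years, and
`projectSamples(x, lpdModel(fit))` classifies new cohorts against the
frozen model.

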