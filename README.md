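# nefr

Tools for the **new extended Frechet (NE-Fr) distribution**, a
three-parameter heavy-tailed lifetime model for positive durations —
remission times, failure times, daily epidemic counts — whose density can
be decreasing or unimodal right-skewed and whose hazard can be decreasing
or upside-down.  It is aimed at survival and reliability analysts who need
a Frechet-type model with one extra shape parameter, together with the
standard machinery around it: estimation, goodness of fit, and simulation.

## The model

With $u = e^{-2\alpha z^{-\beta}}$ and $\bar\lambda = 1-\lambda$,

$$F(z;\alpha,\beta,\lambda)
  = 1-\left[\frac{1-u}{1-\bar\lambda u}\right]^{\lambda},\qquad
  f(z) = \frac{2\lambda^{2}\alpha\beta\,z^{-\beta-1}\,u\,(1-u)^{\lambda-1}}
              {(1-\bar\lambda u)^{\lambda+1}},\qquad z>0,$$

with scale-type $\alpha>0$ and shapes $\beta,\lambda>0$.  At $\lambda=1$
this is exactly the Frechet (inverse Weibull) distribution with scale
$2\alpha$ and shape $\beta$.  The survival tail is
$S(z)\sim(2\alpha/\lambda)^{\lambda} z^{-\beta\lambda}$, so the $r$-th
moment exists iff $r<\beta\lambda$.

The package provides:

* `dnefr` / `pnefr` / `qnefr` / `rnefr` / `hnefr` (plus the `*frechet`
  baseline), all computed on the log scale so nothing turns `NaN` at
  extreme arguments;
* derived properties: moments and incomplete/conditional moments (series
  and quadrature routes), the Laplace-type generating integral, mean
  residual life and mean inactivity time, Bonferroni/Lorenz curves,
  quantile summaries (Bowley skewness, Moors kurtosis), order-statistic
  densities, and four entropy measures (Renyi, q, Havrda-Charvat,
  Arimoto) through the shared integral $\int f^{\rho}$;
* `nefr_fit()`: maximum likelihood, (weighted) least squares and minimum
  Anderson-Darling estimation by multi-start Nelder-Mead on
  log-parameters, with observed-information standard errors and
  `print`/`summary`/`coef`/`logLik`/`vcov`/`plot`/`simulate` methods;
* `gof_criteria()` (deviance, AIC/AICc/BIC/HQIC, Cramer-von Mises,
  Kolmogorov-Smirnov p-value, Anderson-Darling), `descriptive_stats()`
  and the `ttt_curve()` hazard-shape diagnostic;
* `run_scenario()` / `rank_methods()`: a reproducible Monte-Carlo harness
  comparing the four estimators by bias, MSE and tie-averaged rank
  aggregation;
* three published datasets as plain-text fixtures (`nefr_data()`):
  `bladder_cancer` (n = 128), `pakistan_covid_cases` (n = 36),
  `who_covid_deaths` (n = 104), plus simple sample/report I/O and a thin
  command-line wrapper in `inst/cli/nefr-cli.R`.

## Worked example

```r
library(nefr)
z <- nefr_data("bladder_cancer")          # 128 remission times (months)
fit <- nefr_fit(z, method = "mle", label = "bladder_cancer")
print(fit)
#> NE-Fr fit by MLE (n = 128, sample: bladder_cancer)
#>          alpha    beta     lambda
#> estimate  4.8440   0.1545  32.0900
#> se        1.06700  0.05212 35.88000
#> log-likelihood: -410.9511
gof_criteria(fit)
#> Goodness of fit: NE-Fr on bladder_cancer (n = 128, k = 3)
#> tau1 (-2logL)    tau2 (AIC)   tau3 (AICc)    tau4 (BIC)   tau5 (HQIC)
#>     821.90000     827.90000     828.10000     836.50000     831.40000
#> tau6 (CvM W2)   tau7 (KS p)  tau8 (AD A2)
#>       0.04545       0.91750       0.30690
```

The fitted tail index is $\hat\beta\hat\lambda \approx 4.96$, so the
fitted law has about five finite moments.  The large SE on
$\hat\lambda$ flags a nearly flat likelihood direction (see the methods
vignette): the maximised likelihood is stable, the $\lambda$ coordinate
much less so.  The KS p-value 0.9175 says the fitted cdf is entirely
compatible with the sample.  Closed-form quantile summaries need no
moments at all:

```r
nefr_quantile_summary(0.4, 0.4, 0.9)
#>         Q1         Q2         Q3        BSK       MKUR
#>  0.3477022  2.2908123 25.3506743  0.8445697  8.1027043
```

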