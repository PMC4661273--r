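# pebgroup

Iterative empirical-Bayes (parametric empirical Bayes, PEB) inversion of
nonlinear dynamic models for multi-subject, multi-condition time-series
studies — the setting of dynamic causal modelling (DCM) group studies of
evoked responses.

## The problem and the method

A group study yields one nonlinear model inversion per subject, and those
inversions are plagued by local maxima of the variational objective. This
package treats the group hierarchically,

    y_i      ~ N(Gamma(theta_i), Sigma_e)          (subject data)
    theta_i  ~ N((X_i ⊗ I) beta, Sigma_2(gamma))   (random effects)
    beta     ~ N(eta, Sigma_beta)                  (group-level prior)

and iterates: (1) invert each subject by variational Laplace (Gauss–Newton
maximization of the free energy F); (2) estimate the group posterior over
`(beta, gamma)` by maximizing a second-level free energy built from
*Bayesian model reduction* of the subject posteriors — no re-inversion
needed; (3) replace each subject's prior with the empirical prior
`N((X_i ⊗ I) E[beta], Sigma_2 + (X_i ⊗ I) Cov[beta] (X_i ⊗ I)')` and
re-invert, warm-started. Shrinkage toward the group mean pulls subject
estimates out of local maxima; the loop stops when the mean
log-determinant of the subject posterior covariances stops decreasing.
Exhaustive Bayesian model comparison over condition-specific effects, with
moment-matched Bayesian model averaging (BMA), summarizes which
connections changed between conditions.

The core analytic step, for precisions `Pi` (full prior), `Pi_r` (reduced
prior), `P` (posterior):

    P_r = P + Pi_r - Pi
    dF  = 1/2 (ln|P| + ln|Pi_r| - ln|Pi| - ln|P_r|)
        + 1/2 (mu_r' P_r mu_r + eta' Pi eta - mu' P mu - eta_r' Pi_r eta_r)

is exact for linear-Gaussian models, and the test suite holds the package
to that.

A packaged synthetic study (16 subjects, two conditions, a three-source
evoked-response network observed through 8 channels × 128 4-ms bins;
between-subject variance = prior variance/16; smoothed sensor noise at 1/8
of the signal SD) makes every stage testable without downloads.

## Worked example

```r
library(pebgroup)
model <- erpNetworkModel()                       # 3-source network, 24 parameters
group <- generateGroup(model, config = simulationConfig(seed = 1))
fit   <- fitGroup(group, model, verbose = TRUE)
recoveryReport(fit, groupTruth(group))
```

which prints (seed 1):

```
iteration 1: F2 = 95797.119, mean logdet post-cov = -125.744
iteration 2: F2 = 95793.944, mean logdet post-cov = -128.233
iteration 2: second-level free energy decreased (95797.119 -> 95793.944)
iteration 3: F2 = 95793.988, mean logdet post-cov = -128.198

  iteration corAll corEffects sampleVarEffects postVarEffects    F2 meanLogdetPostCov
1         1 0.8385     0.7749          0.03386       0.004178 95797            -125.7
2         2 0.9056     0.8649          0.01961       0.002521 95794            -128.2
3         3 0.9056     0.8650          0.01963       0.002522 95794            -128.2
```

Read: after the first re-inversion under empirical priors the pooled
correlation between subject-level estimates and the generating truth rises
from 0.84 to 0.91 (condition-specific effects: 0.77 to 0.86), while the
sample and posterior variances of the effects fall by roughly half —
shrinkage is destroying local maxima. (The slight F2 decrease at
iteration 2 is logged, not fatal; it is a known signature of the very
local-maxima problem the scheme addresses.) The log-determinant criterion
decreases, then ticks up at iteration 3, so the loop halts and selects
iteration 2.

Model comparison over the condition-specific effects:

```r
peb   <- fit@iterations[[fit@selectedIteration]]$peb
space <- exhaustiveSearch(
  peb, grep("^mean:B_", parameterNames(posterior(peb)), value = TRUE))
round(inclusionProb(space), 3)
```

```
 mean:B_int_1  mean:B_int_2  mean:B_int_3 mean:B_fwd_12 mean:B_fwd_23
        1.000         1.000         1.000         1.000         1.000
mean:B_bwd_21 mean:B_bwd_32
        0.062         0.073
```

Every condition effect the generator actually produced (intrinsic and
forward connections) is detected with posterior probability ~1; the
backward effects, generated at exactly zero, rank far below. The same
machinery applied to the grand average (`grandAverage(group)`, one
first-level fit, then `exhaustiveSearch` on the fit) yields group-mean BMA
estimates that correlate at 0.98 with the PEB ones on this run.

An end-to-end, file-based version of this analysis (delimited-text data,
JSON results, TSV report tables, checksummed manifest) is available as
`runPipeline()` and as the bundled CLI script
`system.file("scripts", "peb-group", package = "pebgroup")`.

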