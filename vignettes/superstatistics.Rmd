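---
title: "Superstatistics of cortical spike trains: model, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superstatistics of cortical spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superspike)
```

## The model

A cortical neuron driven by stationary fluctuating input emits a renewal
spike train whose inter-spike intervals (ISIs) follow a gamma law,

$$q(T\mid\xi) \;=\; \frac{(\kappa\xi)^\kappa}{\Gamma(\kappa)}\,
T^{\kappa-1} e^{-\kappa\xi T},$$

with rate parameter $\xi$ (conditional mean ISI $1/\xi$) and shape
$\kappa$; $1/\kappa$ measures firing irregularity at fixed rate. In vivo,
the rate is set by synaptic input and fluctuates on a timescale slower than
the typical ISI. If the stationary rate distribution is a gamma law
$k(\xi)$ with shape $\alpha$ and mean $R$, the marginal ISI law — the
observable — is the generalized beta distribution of the second kind
("beta-2"),

$$P(T) \;=\;
\frac{\Gamma(\alpha+\kappa)}{\Gamma(\alpha)\Gamma(\kappa)}\,
\frac{1}{\tau}\Big(\frac{T}{\tau}\Big)^{\kappa-1}
\Big(1+\frac{T}{\tau}\Big)^{-(\alpha+\kappa)},
\qquad \tau = \frac{\alpha}{R\,\kappa},$$

whose tail decays as a power law $T^{-\eta}$ with $\eta = \alpha + 1$ and
whose small-$T$ log-log slope is $\kappa - 1$ (mode at
$\tau(\kappa-1)/(\alpha+1)$ for $\kappa > 1$, monotone decreasing
otherwise). The compounding integral and this closed form are an exact pair:
`mixture_pdf()` evaluates the integral by adaptive quadrature and is used
throughout the tests as the independent oracle for the identification
(they agree to better than $10^{-8}$ relative error).

The inverse direction — from a fitted beta-2 law back to the rate
distribution — is the parameter identification
$(\alpha, \kappa, \tau) \mapsto (\text{shape } \alpha, \text{mean }
R = \alpha/(\tau\kappa))$, the closed-form result of the inverse Laplace
transform. We implement the identification rather than a numerical inverse
Laplace routine: it is exact, stable, and testable against the forward
quadrature.

### Information measures and the coding hypotheses

With ISIs in milliseconds and rates in 1/ms (the package's internal units;
user-facing rates are spikes/s), the package computes, in nats:

* $S(\kappa) = \kappa - \log\kappa + \log\Gamma(\kappa) +
  (1-\kappa)\psi(\kappa)$, the rate-independent entropy of the unit-mean
  generator. $S(1) = 1$; the exponential maximizes entropy among unit-mean
  laws, so $S$ rises on $(0,1)$ and falls on $(1,\infty)$.
* $H[\Xi]$, the differential entropy of the gamma rate law.
* $H[T\mid\Xi] = S(\kappa) - E_k[\log\xi]$, the conditional response
  entropy ("neuronal noise"), with
  $E[\log\xi] = \psi(\alpha) + \log(R_{ms}/\alpha)$.
* $H[T]$, the ISI entropy of the beta-2 marginal, by quadrature.
* $I[T,\Xi] = H[T] - H[T\mid\Xi] \ge 0$, the rate–interval mutual
  information.

Three coding hypotheses are expressed through `solve_mfe()`,
`solve_cmfe()` and `mmi_contrast()`:

* **MFE** — maximize $H[\Xi]$ under a mean-rate (energy) constraint. The
  solution is the exponential rate law ($\alpha = 1$), hence a single
  admissible asymptotic tail exponent $\eta = 2$.
* **CMFE** — add an upper bound $I$ on $H[T\mid\Xi]$. The solution is the
  gamma family: $\alpha$ solves
  $S(\kappa) - \psi(\alpha) - \log(R_{ms}/\alpha) = I$, which has a unique
  root because $\psi(\alpha) - \log\alpha$ increases strictly toward 0;
  when the bound is loose the constraint is inactive and $\alpha = 1$.
  A whole family of exponents $\eta = \alpha + 1$ becomes admissible — the
  feature that matches the wide spread of exponents across real neurons.
* **MMI** — maximizing rate–interval mutual information in gamma-interval
  channels requires discrete rate distributions, whose compound ISI law is
  a finite gamma superposition with an asymptotically exponential tail:
  the observable contrast with the power-law tails of the CMFE.

`grid_maxent()` solves the same constrained problems numerically on a
discrete rate grid (exponential-family fixed point with multipliers found
by nested root finding) and serves as the independent check on both closed
forms; `duality_check()` verifies that minimizing $H[T\mid\Xi]$ under a
rate-entropy floor returns the same gamma member.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| $\kappa$ | — | per analysis | interval-generator shape; intrinsic to the neuron, assumed constant over a recording |
| $\alpha$ | — | per analysis | rate-distribution shape; $1/\alpha$ = degree of rate modulation |
| $R$ | spikes/s | per analysis | mean firing rate |
| `M` | bins/decade | 20 | logarithmic binning; $4M = 80$ bins on $[1, 10^4]$ ms, widths $\Delta T_j = (1-10^{-1/M})10^{j/M}$ ms |
| c.d. threshold | — | 0.95 | goodness criterion of the tail regressions |
| tail window | — | $[2\times\text{mode}, \text{last nonzero bin}]$ | regression range; see the bias discussion below |
| min spikes | — | 2000 | analysis refuses shorter trains (overridable) |
| min tail bins | — | 5 | below this the tail is "insufficient" and the verdict is `neither` |

All thresholds live in one place, `default_config()`, and are recorded in
every `neuron_report`.

## What the synthetic generator emulates — and what it does not

`simulate_superstat()` draws a fresh rate per interval (the default
"per-interval" scheme), which realizes the beta-2 marginal *exactly* —
the object every fit targets. The "blockwise" scheme holds each rate for a
block of ISIs, emulating modulation slower than the typical interval with
the same marginal. `make_fixtures()` spans $\alpha \in \{0.8, 1, 1.5,
1.91, 3\}$ (including the $\alpha<1$ minority seen in the recorded
cohort), $\kappa \in \{1, 2, 3.49\}$, rates within the recorded 2.5–50.9
spikes/s, and 2000+ spikes per train, with JSON sidecars holding the
generation truth so that recovery tests need no rate estimator.

Features of real recordings the generator deliberately omits: refractory
structure beyond the gamma shape, nonstationary drift, measurement jitter,
bursting, and any temporal autocorrelation of the rate beyond the block
structure (the autocorrelation timescale of in-vivo rate fluctuations is
not known; `block_size` has no empirically pinned value). A green test
therefore establishes correctness of the *statistical machinery* under the
stated model, not fidelity of the model to any particular neuron.

Two ergodicity facts worth knowing when interpreting simulations:

* Under per-interval (and blockwise) compounding, the time-averaged rate
  `n_spikes/duration` converges to $1/E[T] = (\alpha-1)R/\alpha$ for
  $\alpha>1$, *not* to $R$: sampling one rate per interval length-biases
  time toward slow rates. The ensemble mean of the drawn rates is $R$.
* For $\alpha \le 2$ the ISI variance is infinite, so time averages
  converge slowly; fits are made on the binned density, not on moments.

## Numerical choices

* **Tail regressions.** Ordinary least squares of $\log_{10}$ density
  against $\log_{10} T$ (double-log) or $T$ (semi-log), over nonzero bins
  from twice the histogram mode (geometric center of the maximal-density
  bin, ties to the smallest ISI) to the last nonzero bin; both scales use
  the log ordinate, unweighted, as the regression formulas imply. Zero
  bins are dropped (log undefined).
* **The finite-window bias.** The beta-2 approaches its asymptote slowly:
  its local log-log slope is $(\kappa-1) - (\alpha+\kappa)T/(T+\tau)$,
  which reaches $-(\alpha+1)$ only for $T \gg \tau$. The regression over
  the standard window therefore measures a *chord* and systematically
  underestimates $\eta$: for $\alpha=1,\kappa=2,R=10$ spikes/s the exact
  OLS slope over the window is 1.687, not the asymptotic 2. This is a
  property of the printed procedure, not of sampling noise; the package
  reports what the procedure measures. (A tabulated-density test verifies
  that the bias shrinks monotonically as the window lower bound grows.)
* **Beta-2 fitting.** Nonlinear least squares on log densities in the
  $(c_1,c_2,c_3)$ parameterization
  ($\kappa = c_1{+}1$, $\alpha = c_2{-}c_1{-}1$, $\tau = c_3$), bounded
  quasi-Newton over $(\log\kappa, \log\alpha, \log\tau)$ with
  multi-start (histogram-derived initialization plus fixed fallbacks) and
  a simplex polish. Bounds: $\kappa \in (0.01, 51)$,
  $\alpha \in (0.01, 99)$, $\tau \in (0.01, 10^5)$ ms. Near-degenerate
  (constant-rate) data leave $\alpha$ unidentified — the beta-2 tends to a
  gamma as $\alpha \to \infty$ — so the fit is *flagged* when doubling
  $\alpha$ (re-optimizing $\kappa,\tau$) raises the residual by less than a
  factor of 2, or when a bound is hit.
* **Quadrature.** Rate mixtures integrate on a log-substituted axis with
  the integrand scaled by its analytic peak; entropies likewise
  ($10^{-10}$ absolute tolerances). Narrow densities need
  quantile-informed bounds, which the test oracles use.
* **Max-ent grid.** 4000 log-spaced points on $[R/10^5, 100R]$ with
  trapezoidal weights. (A coarser $[R/10^3, 100R]$ grid shifts the
  constrained mean by $\sim 10^{-3}R$ and visibly distorts the exponential
  solution; the wider grid keeps the discrete solution within $10^{-4}$ of
  the closed forms at the peak.) Multipliers are found by nested Brent
  root finding on the constraint residuals, which is monotone in each
  level.
* **Stationarity.** The early/late half split (first half gets the extra
  spike) is compared by a two-sample KS statistic against the 1% critical
  value — a quantitative stand-in for the visual overlay used on the
  recordings.
* **Cell typing.** Putative pyramidal iff rate $< 30$ spikes/s (strict)
  and spike width $> 0.2$ ms (strict); refused, not defaulted, when the
  width is missing.

## Known limitations

* Fitted $\eta$ from the standard window is a biased (low) estimate of
  $\alpha+1$ for moderate $\alpha$ or $\tau$ comparable to the window
  start; compare with the beta-2 fit's $\alpha+1$ rather than treating the
  regression slope as the exponent.
* Binary (two-rate) mixtures place the knee between their exponential
  components inside the regression window, so the semi-log c.d. of an MMI
  train can stay below 0.95 even though its *asymptotic* tail is
  exponential; the asymptotic statement is verified on the exact density
  instead.
* $\kappa$ estimates from binned least squares degrade for large $\kappa$
  (the small-$T$ rise falls below the 1 ms bin floor), mirroring the
  fitting errors reported for high-$\kappa$ neurons in vivo.
* Entropies are computed from fitted models, not estimated directly from
  finite spike samples; no bias-corrected empirical entropy estimation is
  attempted.
* Estimation of time-resolved instantaneous rates from data is out of
  scope; simulated trains carry their true rates instead.
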