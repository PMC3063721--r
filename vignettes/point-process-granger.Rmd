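---
title: "Directed connectivity from spike trains: the point-process Granger framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed connectivity from spike trains: the point-process Granger framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Simultaneously recorded neurons influence each other's firing, and the
direction of that influence matters: knowing that neuron $j$ drives neuron
$i$ (rather than the converse, or both responding to a common input) is what
separates a functional circuit diagram from a correlation matrix. Classical
Granger causality answers this question for continuous-valued signals
through autoregressive modelling, but spike trains are point processes —
sequences of all-or-nothing events — and do not fit the autoregressive
framework or its mean-squared-error loss. `ppgranger` implements a
likelihood-based analogue built directly on point-process models.

## Model

Time is discretised into bins of width $\delta$ (1 ms by default), small
enough that each neuron spikes at most once per bin. The conditional
intensity of target neuron $i$ — its instantaneous firing rate given the
ensemble history — is modelled log-linearly:

$$
\log\big(\lambda_i[k]\,\delta\big) \;=\; \beta_0^{(i)}
  + \sum_{j=1}^{N}\sum_{r=1}^{R_i} \gamma^{(i)}_{j,r}\, c_{j,r}[k],
$$

where $c_{j,r}[k]$ is the spike count of neuron $j$ in the $r$-th causal
history window — windows of duration $W$ (2 ms by default) tiling the
$R_i W$ seconds strictly before bin $k$ — and $\beta_0^{(i)}$ sets the
background rate. This is a generalized linear model with the canonical log
link. Its discrete point-process log-likelihood is

$$
\log L_i \;=\; \sum_k \Big[\,\Delta N_i[k]\,\log\big(\lambda_i[k]\delta\big)
  - \lambda_i[k]\delta\,\Big],
$$

with $\Delta N_i[k] \in \{0,1\}$ the spike indicator. Because binning
enforces at most one spike per bin, the higher-order term that would account
for multiple spikes per bin vanishes; the likelihood is then formally that
of a Poisson regression on indicators, which is how it is maximised.

### Fitting

`fit_cif()` maximises this likelihood by Fisher scoring (IRLS for the
canonical link) from a deterministic start — intercept at the log mean rate,
history coefficients at zero — to a relative tolerance of $10^{-8}$ with at
most 100 iterations and step-halving to keep the ascent monotone. There is
no random initialisation anywhere in the fitting path, so results are exactly
reproducible. Numerical guards: $\lambda\delta$ is floored at $10^{-12}$
inside logarithms; any coefficient exceeding 30 in magnitude flags the fit
as non-converged (a practical separation guard — at 1-ms resolution a
coefficient of 30 is astronomically beyond physiological effect sizes);
all-zero covariate columns (a silent source) are dropped from the
optimisation and reported as zero coefficients rather than poisoning the
Fisher matrix. The design matrix is held in sparse form: at physiological
rates ~95% of window counts are zero, and sparse cross-products make the
full pairwise analysis of a nine-neuron, 100,000-bin recording a matter of
seconds rather than minutes.

## The causality measure

Neuron $j$ Granger-causes neuron $i$ if deleting $j$'s history from $i$'s
model worsens the fit. The reduced model structurally excludes $j$'s $R_i$
columns and **re-optimises all remaining coefficients** — this matters:
merely zeroing the coefficients would overstate every influence, because the
other covariates partially absorb the deleted one. The log-likelihood ratio

$$
\log\Lambda_{j\to i} \;=\; \log L_i^{(\text{without } j)} - \log L_i^{(\text{full})} \;\le\; 0
$$

is zero exactly when $j$'s history adds nothing. Its sign-decorated
magnitude is the causality measure reported in the `gamma` column:
$\Gamma_{j\to i} = s_{j\to i}\cdot(-\log\Lambda_{j\to i})$, where the sign
$s_{j\to i}$ is that of the unweighted mean of the full model's
$\gamma^{(i)}_{j,1..R_i}$ — positive for a net excitatory influence,
negative for inhibitory. For self-pairs the first window's coefficient is
omitted from that mean: the absolute refractory period forces it strongly
negative in every neuron, so including it would misclassify genuinely
self-excitatory neurons. (With $R_i = 1$ nothing would remain and the sole
coefficient is used.) Re-optimisation can leave the ratio a hair above zero
at solver tolerance; values within $10^{-6}\lvert\log L\rvert$ are clipped
to zero and anything larger is treated as a failed re-fit and reported `NA`.

## Significance

Twice the negative log-likelihood ratio is the deviance difference between
two nested GLMs, asymptotically $\chi^2$ with degrees of freedom equal to
the number of deleted coefficients, here $R_i$. `infer_network()` tests all
$N^2$ ordered pairs — self-pairs included, since self-coupling is read off
the same machinery — and controls the false discovery rate by the
Benjamini–Hochberg step-up rule over all finite p-values at level
$q = 0.05$ by default. The result is a trichotomous connectivity map:
$+1$ excitatory, $-1$ inhibitory, $0$ no detected interaction, `NA` where a
fit failed (failures never abort the rest of the matrix). Lowering $q$ can
only remove links, never add them.

Two honest caveats about map-level accuracy. First, FDR control is a
statement about the *expected proportion* of false links: with ~45 true
detections at $q = 0.05$ the procedure tolerates about one false link per
map on average, so even a well-calibrated analysis will show a spurious
link in a sizeable fraction of single realisations. Second, the fitted
model bins history into $W$-wide windows; when the true lag structure
varies inside a window, the residual misspecification can leak into other
neurons' coefficients and occasionally reach significance at large sample
sizes. Both effects are visible in the package's own Monte-Carlo tests and
are discussed with the results they qualify.

## History-order selection

The order $R_i$ — how many windows of ensemble history drive neuron $i$ —
is chosen by Akaike's information criterion over a candidate list (1..10 by
default; the benchmark studies use 1..6, the hidden-feedback study 1..8).
One detail is easy to get wrong: models of different order have different
fittable ranges (the first $R W/\delta$ bins lack full history), and
likelihoods over different data are not comparable. `select_order_aic()`
therefore evaluates every candidate on the common fittable range implied by
the largest candidate, and breaks ties toward the smaller order. A single
$R_i$ governs all sources of a target; per-source orders are not supported.

## The simulator

`simulate_ensemble()` generates ground-truth data by per-bin Bernoulli
thinning: at each bin, each neuron's $\lambda\delta$ is computed from its
baseline and the lagged spikes along its incoming edges, clamped to
$[0, 1]$, and compared with a uniform draw; an absolute refractory period
(1 ms by default) vetoes spikes in adjacent bins. Edge kernels are per-bin
lag vectors, so a kernel of length 3 acts over the 3 ms after a trigger
spike. The bundled benchmark (`preset_network("ninenet")`) uses short
within-assembly kernels — excitatory $[1, 2, 2]$, inhibitory
$[-0.8, -0.6, -0.3]$, self-inhibition $[-0.6, -0.5, -0.4]$ — spanning 3 ms,
and long cross-assembly kernels — $[0, 0, 0, 1, 2, 1]$ and
$[0, 0, 0, -0.8, -0.9, -0.5]$ — spanning 6 ms. With 2-ms analysis windows
this split is exactly what order selection should resolve: two windows
(4 ms) suffice for targets with only within-assembly inputs, three windows
(6 ms) are needed where a cross-assembly kernel arrives. All neurons share
an 18 Hz spontaneous rate ($e^{\beta_0} = 0.018$ per bin).

The nine-neuron wiring follows a cyclic pattern within each three-neuron
assembly — every neuron excites its successor and is inhibited by it — plus
self-inhibition everywhere, three long excitatory edges linking the
assemblies' two-excitatory-input neurons (4→1, 8→4, 1→8) and three long
inhibitory edges (6→3, 8→5, 1→9) whose targets forgo their within-assembly
inhibition, keeping every neuron at exactly two inhibitory inputs (counting
self-inhibition) and one or two excitatory inputs. Under this wiring the
realised per-neuron totals over 100,000 bins fall in the 2,100–2,900 range
and AIC resolves the 3/2 order split, which is what the acceptance checks
assert. Wiring lives in JSON files under `inst/extdata/networks/`, so a
topology correction is a data edit, not a code change.

The five-neuron hidden-feedback preset (`preset_network("hidden5")`)
augments an observed three-neuron assembly with two hidden neurons, each
reciprocally coupled to neuron 1 through the long excitatory kernel
$[0, 0, 1, 2, 2, 1]$. Only neurons 1–3 are returned by the simulator. The
loop sends a neuron-1 spike out and back in 6–12 ms, which is why neuron 1
fires well above its peers (~4,200 vs ~2,400 spikes per 100 s), selects a
long history (modal $R = 6$, i.e. 12 ms, against 4 ms for its peers), and — the scientifically
interesting signature — classifies as *self-excitatory* even though its
direct self-coupling is inhibitory: unobserved positive feedback masquerades
as self-excitation.

Refractoriness is enforced per neuron, and only for neurons that carry a
self-interaction edge. The sparse density presets declare some neurons
history-free (homogeneous Poisson); a refractory veto would make their own
history genuinely informative, so the self-interaction null would be false
and every "false positive" on those self-pairs would actually be a correct
detection — exempting them keeps the FDR experiment's ground truth honest.
In the nine-neuron and hidden-feedback presets every neuron self-inhibits,
so refractoriness is active everywhere.

`add_log_cif_noise()` perturbs the log intensity with i.i.d. Gaussian noise,
independently per neuron and bin. The variance is set from the requested SNR
against the *uncentred* time-average power of the unperturbed log intensity
(measured on a noiseless pass with the same seed); at a 1-ms bin and 18 Hz
the log intensity is about $-4$, so 0 dB means noise of standard deviation
~4 on the log scale — a violent perturbation, which is the point of the
low-SNR stress tests. Thinning draws and noise draws come from separate
streams so that the thinning sequence is identical with and without noise,
and the infinite-SNR limit reproduces the noiseless run bit for bit.

## Goodness of fit

By the time-rescaling theorem, integrating the true conditional intensity
over interspike intervals yields unit-rate exponential variables;
`rescale_times()` applies the fitted intensity, maps intervals through
$z = 1 - e^{-\tau}$, and compares the ordered $z$ against uniform quantiles
$(k - 0.5)/n$ with a Kolmogorov–Smirnov statistic and the 95% band
$1.36/\sqrt{n}$ (a Stephens-corrected constant below $n = 36$). The
discrete sum $\tau = \sum \lambda\delta$ stands in for the integral without
a discreteness correction — adequate at $\lambda\delta \approx 0.02$, but a
known source of mild bias at substantially higher per-bin intensities, and
the main reason not to push $\delta$ coarser than a few milliseconds.

## What the synthetic studies do and do not show

The generator reproduces the features the method is sensitive to — log-
linear history coupling, refractoriness, excitatory and inhibitory kernels
with realistic magnitudes and delays, hidden units, stationary baselines —
and none of the features it is not designed for: no bursting dynamics, no
oscillatory common drive, no slow nonstationarity (beyond the optional
log-intensity noise), no measurement noise in spike times, no spike-sorting
errors. Passing the bundled tests therefore demonstrates correctness of the
machinery and calibration under the model class, not robustness to every
pathology of real recordings. The Monte-Carlo problem sizes — 100,000 bins
per realisation, 20 replicates for the FDR studies, 200 small-sample
replicates for null calibration — were chosen as the smallest runs whose
Monte-Carlo error is comfortably below the effects being checked.

## Known limitations

- Influences are conditional on the *recorded* ensemble: hidden common
  inputs and hidden loops are attributed to the observed neurons' couplings
  (the hidden-feedback study shows exactly how).
- The window-binned history model is an approximation; with very long
  recordings, within-window lag structure can surface as weak spurious
  links and occasional over-selection of the history order.
- The history order is selected by AIC on the same data that is then
  tested. This post-selection reuse mildly inflates the null tails —
  measurably so on sparse networks where adjacent orders are near-ties — so
  the realised false-discovery proportion can sit somewhat above the nominal
  level even though the identical pipeline with pre-specified orders is
  calibrated.
- Stationarity is assumed throughout; trial-varying models are out of scope.
- Inference is asymptotic ($\chi^2$); with very few spikes per neuron the
  deviance calibration degrades before the fits do.
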