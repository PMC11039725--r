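---
title: "Evaluating and forecasting medical-equipment effectiveness with conedea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and forecasting medical-equipment effectiveness with conedea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conedea)
```

## The problem

A hospital running several large imaging scanners wants to know which
machines deliver the most value per unit of input, why, and where each
machine's efficiency is heading. `conedea` answers this with a four-stage
pipeline: operational indicators per device-month, combined
subjective/objective indicator weights, cone-constrained data envelopment
analysis (DEA), and a recurrent forecaster for the resulting efficiency
series. This vignette explains each stage's model, its assumptions, the
parameters that matter, and the design decisions taken where more than one
reasonable construction exists.

## Indicators

`monthly_panel()` reduces an examination event log (booking, scan start and
end, report-ready timestamps, per-exam revenue) and a device-month cost
table to eight indicators per device-month. Inputs: the utilization rate
$X_1 = (\tau + 2)\,n / \sigma_b$ (with $\tau$ the mean scan duration in
minutes, 2 minutes of preparation per exam, $\sigma_b$ the energized
minutes — all in minutes so $X_1$ is a dimensionless load ratio, typically
near 1 for a busy scanner), average daily working hours $X_2$ (total scan
hours over calendar days), operating cost $X_3$, and average cost per
inspection $X_4 = (C_t + P)/n$ including depreciation $P$. Outputs:
revenue $X_5$, mean appointment wait $X_6$ (minutes), cost–benefit ratio
$X_7 = X_5/X_3$, and mean report wait $X_8$ (minutes).

Two conventions are worth noting. $X_2$ is normalized by calendar days so
it is an intensity, comparable across months of different lengths. And a
device-month with zero exams is dropped (with a warning) rather than
carried as zeros, because the DEA stage requires strictly positive inputs.
`indicator_correlations()` provides a descriptive Pearson screen (it does
not filter indicators — moderate correlations across indicators are
expected and unproblematic for DEA).

## Weighting

**AHP.** `ahp()` derives priorities from a positive reciprocal 4×4
comparison matrix by row geometric means, the classical alternative to the
principal eigenvector that is exact for consistent matrices and simpler to
audit; an eigenvector mode is available via `method = "eigen"`. Consistency
uses $\lambda_{\max} = \sum_i (Aw)_i/(n w_i)$,
$CI = (\lambda_{\max}-n)/(n-1)$ and Saaty's random index
($RI(4) = 0.90$), accepting $CR < 0.10$. Printed matrices round their
reciprocal entries (e.g. 0.476 for 1/2.1), so reciprocity is validated at
a relative tolerance of $10^{-2}$; the residual consistency ratio this
induces is well below the acceptance band.

**Improved CRITIC.** `critic()` works on the min-max standardized panel
(`minmax_standardize()`, with $X_3, X_4, X_6, X_8$ oriented as cost-type).
Each column $j$ contributes an information volume
$(\sigma_j + h_j)\sum_i (1-|r_{ij}|)$: $\sigma_j$ is the entropy-method
*value* of the column (Shannon entropy of the column normalized to a
probability mass, scaled by $1/\log n$, shifted by $10^{-12}$ before
taking logs), $h_j$ its sample standard deviation, and the sum its
conflict with the other columns. Using $|r|$ treats positively and
negatively correlated pairs as equally redundant. The entropy term is the
*value*, not the entropy weight: this is the only reading under which the
three components recompose into the volumes and weights consistently, and
it is what `critic_combine()` implements. Weights are normalized within
the input group ($X_1$–$X_4$) and output group ($X_5$–$X_8$) separately,
because the DEA multipliers for the two sides are independent.

**Game combination.** `game_weights()` fuses the AHP and CRITIC vectors by
solving the Gram system $[W_k \cdot W_l]\,\lambda = [W_k \cdot W_k]$. This
system is the Nash-equilibrium condition of a two-player game in which
each method's coefficient is a best response minimizing its own deviation
$\lVert \lambda_1 W_1 + \lambda_2 W_2 - W_k \rVert^2$ given the other; it
is *not* the minimizer of the summed deviation, which is flat along the
entire segment between the two vectors and therefore cannot identify a
unique fusion. The tests verify the best-response property against a dense
grid search. Degenerate systems (parallel vectors) fall back to a
pseudo-inverse solution; identical vectors short-circuit to equal
coefficients. Solved coefficients are normalized to sum 1 and the
combination renormalized.

## Cone-constrained DEA

`dea()` scores each DMU with the input-oriented multiplier-form CCR model
under constant returns to scale, solved as a linear program (via the
simplex solver in the recommended `boot` package) after the
Charnes–Cooper normalization $w^\top x_0 = 1$. Constant returns is the
appropriate assumption here because device-months of the same modality are
technologically comparable and scale differences are exactly what the
utilization indicators measure.

The cone constraints encode the combined weights as decision-maker
priorities. From a positive generator $w^\*$ the consistent ratio matrix
$W_{ij} = w^\*_i/w^\*_j$ has principal eigenvalue equal to its order $k$,
so `build_cone()` sets $B = W - kI$ and the admissible region is
$\{Bw \ge 0,\ w \ge 0\}$. A consequence worth stating plainly: for a
consistent ratio matrix this region is exactly the ray spanned by $w^\*$,
so the cone-constrained score reduces to a weighted output/input ratio
normalized by the frontier maximum. That is the source of the model's
discriminating power — unconstrained CCR lets every DMU pick the
multipliers most flattering to itself (on the default fleet, 12 of 96
DMUs are CCR-efficient), while the cone model ranks everyone against the
same priorities and still guarantees feasibility (the generator itself
always satisfies the constraints, so the LP cannot be infeasible for valid
data). The tests exploit this closed form as an independent oracle.

The two waiting-time outputs are undesirable (smaller is better), and the
multiplier-form model needs larger-is-better outputs, so
`dea_instance()` reverses them by the linear translation
$v' = \max_j v_j + \varepsilon - v$ with $\varepsilon$ equal to 1% of the
column range, keeping all values strictly positive and the ordering
exactly reversed. A reciprocal transform was considered and rejected as a
default because it distorts relative spacing nonlinearly.

Two frontier modes exist. The default pools all device-months into one
frontier (96 DMUs in the default configuration), which is the meaningful
comparison when months are technologically comparable — a 4-DMU monthly
cross-section with eight indicators would make nearly everything
efficient. `mode = "per_month"` keeps the monthly cross-sections for
fidelity checks; months with fewer than two DMUs score 1 by convention and
are flagged. Scores within $10^{-7}$ of the boundary are clipped to
$[0, 1]$; anything further out is reported as-is so solver trouble stays
visible.

## Forecasting

`forecast_efficiency()` fits a small sequence model to one device's
monthly score series: a single bidirectional LSTM layer (default width 32
per direction) encodes a window of $L = 6$ past scores into states
$H_t = [H_t^f, H_t^b]$; scaled dot-product attention against the query
$s$ (the encoder state at the final window position — the natural
"current" state in one-step-ahead forecasting) yields weights
$\alpha_i$, a context $c = \sum_i \alpha_i H_i$, and the enhanced state
$H' = c + s$ feeding a linear head. Training is full-batch Adam (learning
rate 0.01) on mean squared error for 200 epochs. An additive
(Bahdanau-style) score and a no-attention ablation are available via the
`attention` argument.

There is no deep-learning framework among the package's dependencies, so
the forward pass and backpropagation through time are implemented directly
in base R; the gradients are exact and are checked against central finite
differences (to ~$10^{-11}$) in the test suite. At these problem sizes
(tens of windows, width 32) a fit takes well under a second.

Preprocessing follows standard hygiene: internal gaps are filled by linear
interpolation (`fill_gaps()`); min-max normalization is fitted on the
training segment only and applied everywhere, so the held-out months never
influence the scaling; a constant training segment falls back to a unit
scale. The chronological train/test split defaults to 80/20 of the
windows. `forecast_metrics()` reports MSE, RMSE, MAE, MAPE (points with a
zero actual are excluded with a warning) and
$R^2 = 1 - \sum(M-P)^2/\sum(M-\bar M)^2$.

The learning-sanity benchmark used in the tests is a noiseless seasonal
series $x_t = 0.5 + 0.3\sin(2\pi t/12)$ of 48 months — four full cycles,
long enough that the 80/20 split leaves a meaningful held-out segment —
on which the model must reach held-out $R^2 \ge 0.85$ and
$\mathrm{MSE} \le 0.01$; in practice it fits to $R^2 > 0.999$. On real
24-month series with noise, held-out performance over four test points is
necessarily weaker and should be read as indicative only.

## The synthetic fleet

`simulate_fleet()` exists because real hospital event logs are not
redistributable. Its default emulates a 4-scanner MRI service over 24
months from 2021-01: about 25 exams per device-day (at least one per day —
a busy service), truncated-normal scan durations (mean 28, sd 6 minutes,
floor 5), gamma appointment leads (mean 1 day) and report delays (mean 12
hours), a flat tariff of 600 per exam, lognormal monthly operating-cost
noise around a base of 150,000 with 120,000 straight-line depreciation,
and 960 energized minutes per day (expanded by calendar days, and never
less than 105% of the scheduled scan time, so the monthly schedule is
always feasible). These values are chosen once as representative of a
busy tertiary-care MRI service; the right-skewed gamma/lognormal choices
reflect that waits and costs are positive and occasionally long.

One device (A by default) carries an efficiency multiplier of 1.3,
realized as a faster sweep speed: more exams per day, proportionally
shorter scans and shorter waits, with tariffs and the cost base untouched.
This plants a ground truth the pipeline must recover — device A should
attain the highest mean cone-DEA score — which the acceptance tests check
end to end.

What the generator does **not** emulate: case-mix differences between
scanners, scheduled maintenance windows and breakdowns, seasonal demand,
tariff changes, or queueing interactions between devices. Passing the
planted-signal test therefore shows that the pipeline recovers a known
throughput/wait advantage under clean conditions; it does not certify
behaviour under the messier confounders of real operations.

## Numerical choices, degenerate inputs, limitations

* LP feasibility tolerance $10^{-10}$ with one retry at $10^{-9}$; an
  infeasible report after retry is a hard error (it cannot occur for
  valid positive data).
* Reciprocity tolerance $10^{-2}$ for judgement matrices (printed
  rounding); entries outside $[1/9, 9]$ rejected; order $\le 2$ matrices
  have $CR = 0$ by definition.
* Constant indicator columns: an error in standardization (named by
  indicator); flagged with `NA` correlations in the screen.
* Mutually collinear standardized columns give zero total information
  volume and a deliberate error rather than arbitrary weights.
* All randomness flows from explicit seeds (fleet config, forecaster), so
  every result in this vignette and the tests is exactly reproducible.
* Problem sizes used throughout the documentation and tests — 96 pooled
  DMUs, 48-month benchmark series, width-32 networks — keep every stage
  comfortably under a second while matching the scale the model is
  designed for.

Known limitations: no slack-based, additive or super-efficiency DEA
variants and no envelopment-form projections; the forecaster is
univariate per device and makes no uncertainty statement; and the AHP
matrices are inputs — the package does not elicit them.
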