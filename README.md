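# conedea

Composite effectiveness evaluation and forecasting for hospital imaging
equipment, built for health-services operations analysts who need to rank
scanners (the motivating case is an MRI fleet), justify the ranking with
transparent indicator weights, and project where each scanner's efficiency
is heading.

## The model

Each device-month is a decision-making unit (DMU) described by eight
operational indicators computed from examination event logs and monthly
cost records:

| inputs | outputs |
|---|---|
| X1 utilization rate `(τ + 2)·ΣZ / σ_b` | X5 inspection revenue `R_t` |
| X2 average daily working hours | X6 mean appointment wait (min) |
| X3 operating cost `C_t` | X7 cost–benefit ratio `R_t / C_t` |
| X4 average cost per inspection `(C_t + P)/ΣZ` | X8 mean report wait (min) |

Indicator weights combine a subjective and an objective source:

* **AHP** — row-geometric-mean priorities from 4×4 pairwise-comparison
  matrices, with Saaty's consistency test
  `CR = (λ_max − n) / ((n − 1)·RI)`, accepted when `CR < 0.10`;
* **improved CRITIC** — per indicator, information volume
  `(σ_j + h_j)·Σ_i(1 − |r_ij|)` combining the entropy value, the
  dispersion of the min-max standardized column and its conflict with the
  other indicators;
* **game-theoretic combination** — coefficients `λ` solving the Gram
  system `[W_k·W_l] λ = [W_k·W_k]` (each method's best response),
  normalized and applied as `W = λ₁W_AHP + λ₂W_CRITIC`.

Efficiency is scored by the input-oriented multiplier-form CCR model under
constant returns to scale, `max μᵀy₀ s.t. wᵀx_j ≥ μᵀy_j, wᵀx₀ = 1`,
sharpened by assurance-region (cone) constraints `Bw ≥ 0`, `Cμ ≥ 0` whose
matrices `B = W_A − m·I` are built from the consistent ratio matrix of the
combined weights — this pins the admissible multipliers to the combined-
weight ray and makes the scores strictly comparable across DMUs. The two
waiting-time outputs are direction-reversed (`v' = max(v) + ε − v`) before
entering the output matrix.

Each device's monthly efficiency series is then forecast one step ahead by
an attention-based bidirectional LSTM (windows of `L = 6` months, softmax
attention over the encoder states, Adam on MSE for 200 epochs), evaluated
by RMSE, MAPE and R².

Because real hospital information-system extracts are not redistributable,
the package ships a seeded synthetic fleet simulator
(`simulate_fleet()`) whose default emulates a 4-scanner × 24-month MRI
service with one deliberately more efficient scanner, so the entire
pipeline is reproducible end to end.

## Worked example

```r
library(conedea)

fleet <- simulate_fleet(fleet_config(seed = 42))   # 4 devices x 24 months
panel <- monthly_panel(fleet$events, fleet$costs)  # 96 device-months
w     <- combined_weights(panel)                   # AHP + CRITIC + game
fit   <- dea(panel, weights = w)                   # cone-constrained CCR
summary(fit)
#> Efficiency by device (cone scores, pooled frontier):
#>   device_id   mean    min    max
#> 1         A 0.8493 0.7189 1.0000
#> 2         D 0.6749 0.5283 0.8717
#> 3         B 0.6622 0.5684 0.7843
#> 4         C 0.6593 0.5487 0.7611
#> 12 of 96 DMUs CCR-efficient
```

Device A is the simulator's planted high-efficiency scanner (faster sweep
speed: more exams, shorter waits); the cone-constrained scores recover it
as the clear leader, with a gap of ~0.18 over the rest of the fleet — the
pattern the model is designed to surface. Forecasting its series:

```r
forecast_efficiency(efficiency_series(fit, "A"))
#> Attention Bi-LSTM forecaster (dot attention, L = 6, hidden = 32)
#> trained 200 epochs, final training MSE 0.01125 (normalized scale)
#> held-out: n = 4, RMSE 0.0613, MAPE 6.70%, R2 0.3863
```

On a noisy 24-point series four held-out months is a hard target; on
longer or cleaner series (see the tests) the model reaches R² > 0.85.
`run_pipeline()` chains all stages and writes every artifact
(panel, weights, scores, forecasts, manifest) to a directory;
`inst/scripts/run-pipeline.R` wraps it for the shell.

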