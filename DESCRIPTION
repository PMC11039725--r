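Package: conedea
Title: Cone-Constrained DEA Evaluation and Forecasting of Medical Equipment Effectiveness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the operational effectiveness of hospital
    imaging equipment from examination event logs. Computes an eight-indicator
    device-month panel (utilization, working hours, costs, revenue, waiting
    times), derives indicator weights by the analytic hierarchy process and an
    improved CRITIC method fused through a game-theoretic combination scheme,
    scores device-months with a cone-constrained multiplier-form CCR data
    envelopment analysis model, and forecasts the resulting efficiency series
    with an attention-based bidirectional LSTM. Includes a seeded synthetic
    fleet simulator so the full pipeline is reproducible without hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
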