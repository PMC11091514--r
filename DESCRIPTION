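Package: ortime
Title: Real-Time Intraoperative Duration Prediction on Simulated Operating-Room Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Minute-by-minute probabilistic prediction of total anaesthesia time
    from streaming intraoperative data, evaluated prospectively with the
    continuous ranked probability score (CRPS) against a bias-corrected
    scheduled-duration benchmark. Includes a discrete-event synthetic
    operating-room data generator (cases, intraoperative event/medication/
    flowsheet streams, EHR ingestion latency, an operating-window capture
    model), latency-respecting minute-level replay and tokenization that
    prevents information leaks, a histogram-output neural duration model
    trained with a discretized CRPS loss, closed-form CRPS scoring with
    stratified aggregation, weekly-batched performance-drift regression, and
    a primary-versus-secondary retraining comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
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
RoxygenNote: 7.3.3
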