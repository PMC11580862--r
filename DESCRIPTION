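Package: abmkf
Title: Ensemble Kalman Filtering and Microstate Synthesis for Agent-Based Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data assimilation for stochastic, spatially heterogeneous
    agent-based models. Applies an ensemble Kalman filter to low-dimensional
    macrostate summaries (agent counts, molecular totals) and links the
    macrostate update back to the full agent-level microstate through
    microstate-synthesis algorithms, including a spatially aware
    one-hot / rescale / quantization-with-error-diffusion pipeline for
    categorical lattices. Ships two example models (a wolf-sheep-grass
    predator-prey simulator and a minimal spatial viral-infection model),
    virtual-patient twin experiments, surprisal-based filter evaluation,
    Gaussian Wasserstein-2 distances, and trajectory phenotype clustering.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
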