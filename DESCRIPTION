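Package: presynaptica
Title: Simulation and Quantal Analysis of Presynaptic Short-Term Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing patch-clamp recordings of evoked and
    spontaneous excitatory postsynaptic currents (EPSCs) and presynaptic
    calcium imaging, together with a ground-truthed generative simulator of
    vesicle-pool and calcium dynamics. Implements per-stimulus amplitude and
    synchronous/asynchronous charge decomposition of high-frequency trains,
    readily-releasable-pool (RRP) estimation by cumulative-charge
    back-extrapolation and by hypertonic sucrose, release probability,
    paired-pulse ratio and short-term plasticity classification, exponential
    recovery-kinetics fitting, miniature-EPSC detection with amplitude and
    charge criteria, agonist response quantification, and per-ROI
    delta-F/F0 quantification of genetically encoded calcium indicator
    stacks. The simulator couples voltage-gated calcium influx with a
    calcium-activated TRPC-like conductance feeding calcium-dependent
    vesicle replenishment, so every analysis stage can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
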