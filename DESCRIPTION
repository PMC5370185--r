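Package: ampafluct
Title: Fluctuation Analysis of Synaptic Currents and Receptor Mobility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of AMPA-receptor physiology
    recordings: template-based detection and quality control of miniature
    excitatory postsynaptic currents (mEPSCs), peak-scaled non-stationary
    fluctuation analysis (NSFA) yielding single-channel current and
    conductance, evoked-response metrics (rectification index, KA/Glu,
    AMPAR/NMDAR and paired-pulse ratios, LTP timecourse normalization), and
    fluorescence-recovery-after-photobleaching (FRAP) fitting with
    acquisition-bleach correction.  Includes stochastic channel-gating and
    recording simulators with exported ground truth, so every stage of the
    analysis can be validated by parameter recovery on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
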