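Package: striatobot
Title: Striatal Spiking-Network Model of Action Selection with a Virtual Robot
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-hemisphere spiking network of striatal D1 and D2
    medium spiny neurons (conductance-based leaky integrate-and-fire) arranged
    on a toroidal grid of action channels with non-monotonic distance-dependent
    lateral inhibition, and couples the activity of two designated action
    channels to a planar unicycle robot through an exponential rate filter and
    sigmoid-bounded motor equations. Includes optogenetic-style stimulation
    paradigms (bilateral/unilateral excitation and inhibition, channel
    sequences, competing actions, simulated GABA-antagonist disinhibition) and
    the accompanying analyses: binned rates, calcium-like filtered spike-train
    Pearson correlations by spatial distance, correlation matrices,
    instantaneous population correlations with shuffle controls,
    winning-channel detection, and recruitment-distance distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
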