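Package: cbgt
Title: Spiking Cortico-Basal Ganglia-Thalamic Network Agents for Decision Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates decision making with a spiking cortico-basal
    ganglia-thalamic (CBGT) network agent embedded in configurable task
    environments. Conductance-based integrate-and-fire populations organised
    into action channels select among options when thalamic firing crosses a
    decision boundary; dopamine-dependent corticostriatal plasticity links
    reward prediction errors to future choices. Supports n-choice
    probabilistic reward tasks with conflict and volatility, stop-signal
    tasks with subthalamic and arkypallidal stop currents, and simulated
    optogenetic stimulation of any nucleus. Behavioural and neural outputs
    are returned as plain data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
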