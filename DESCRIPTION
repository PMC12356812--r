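Package: gradcpt
Title: Analysis of Gradual-Onset Continuous Performance Task Sessions with
    Refresh-Rate Change Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for behavioral experiments that pair the gradual-onset
    continuous performance task (gradCPT) with a peripheral window whose
    display refresh rate is covertly lowered. Models the stimulus timeline
    (scene-morph dynamics, dot kinematics, stepped refresh-rate schedules),
    classifies go/no-go keypresses with the gradCPT ambiguous-response
    rules, estimates moment-to-moment attentional state from the smoothed
    reaction-time variance time course, codes change-detection presses
    against the critical period under liberal and conservative criteria,
    and summarizes evidence with JZS Bayes factors. A synthetic-session
    generator with a latent attentional-state chain makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
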