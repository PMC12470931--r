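Package: ffrct
Title: Reduced-Order Coronary FFR-CT Simulation, Virtual Stenting, and
    Method-Agreement Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for computing fractional flow reserve (FFR) on coronary
    vessel trees with a reduced-order pulsatile network model (allometric
    inflow scaled from myocardial volume, three-element Windkessel outlets
    distributed by Murray's law, Young-Tsai stenosis losses, BDF2 time
    integration), for planning and applying virtual stents (blinded
    algorithmic sizing or externally specified clinical stents) as lumen
    modifications, and for the full method-agreement statistics battery used
    in FFR validation studies (Bland-Altman, Passing-Bablok, one-way
    random-effects ICC with exact F confidence intervals, Cohen's kappa,
    exact McNemar, diagnostic 2x2 metrics with Clopper-Pearson and
    standard-logit confidence intervals, Spearman, RMSE, Wilcoxon tests).
    A synthetic-cohort generator emulates paired pre/post-intervention FFR
    studies with discovery/validation splits, and a pipeline runs the whole
    analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
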