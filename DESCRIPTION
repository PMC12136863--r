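Package: lodxa
Title: Quantification of Lateralized Overgrowth from Regional DXA Body Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies lateralized overgrowth (LO) from total-body
    dual-energy X-ray absorptiometry (TB-DXA) regional composition tables.
    Regions are compared with their contralateral homologues via the total
    mass discrepancy ratio, the relative tissue composition (RC) of adipose,
    muscle and bone compartments, and the composition discrepancy (dRC);
    regions with a mass discrepancy at or above a configurable 10% cut-off
    are called as overgrown and the tissue with the largest dRC is reported
    as the predominant overgrown tissue. Includes the cohort-level
    statistical battery (paired and unpaired t tests, one-way ANOVA,
    Fisher's exact r x c tests, Shapiro-Wilk normality annotation), a
    clinical-concordance analysis comparing DXA calls with clinical labels,
    and a synthetic bilateral cohort generator for the PROS, BWSp and ILO
    diagnostic subgroups so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
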