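Package: escalape
Title: Bayesian Dose Escalation with Overdose Control and Mechanistic
    PK/PD for Phase I Oncology Trials
Version: 0.1.0
Authors@R:
    person("Escalape", "Developers", email = "escalape@example.org",
           role = c("aut", "cre"))
Description: Tools for model-guided phase I dose-finding and early-phase
    pharmacology. Implements the two-parameter Bayesian logistic
    regression model (BLRM) for dose-limiting toxicity with escalation
    with overdose control (EWOC): deterministic grid-quadrature
    posteriors, toxicity-interval summaries, escalation caps, next-dose
    recommendation and maximum-tolerated-dose declaration. Also provides
    a mechanistic two-compartment pharmacokinetic model with mass-action
    reversible binding of drug to circulating ligands (target-mediated
    suppression of free ligand) including population simulation of
    target engagement, noncompartmental exposure analysis (Cmax, AUC to
    the last quantifiable concentration, terminal half-life,
    dose-proportionality), trial replay and operating-characteristics
    simulation for BLRM-EWOC designs, RECIST 1.1-style response
    endpoints from target-lesion sums, and seeded synthetic-data
    generators for every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
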