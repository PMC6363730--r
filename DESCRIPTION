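Package: coptipkpd
Title: Pharmacokinetic-Pharmacodynamic Modelling of Coptisine in
    LPS-Stimulated Rats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and fits a mechanism-based pharmacokinetic-
    pharmacodynamic (PK-PD) model of the inflammatory cascade triggered by
    intravenous lipopolysaccharide (LPS) in rats and its inhibition by the
    isoquinoline alkaloid coptisine.  The model couples two-compartment
    coptisine kinetics with first-order lung distribution to a ten-state
    cytokine cascade: piecewise zero-order plasma TNF-alpha production with
    Michaelis-Menten elimination, diffusion-delayed lung TNF-alpha, an iNOS
    mRNA/protein/plasma turnover chain, and a precursor-pool indirect-response
    model of plasma nitric oxide.  Includes stiff ODE simulation with bolus
    dosing events, closed-form two-compartment oracles, trapezoidal AUC and
    Cmax/Tmax exposure metrics, synthetic preclinical study generation with
    log-normal between-animal variability and additive residual error, pooled
    maximum-likelihood estimation with AIC/BIC, and simulation-based model
    qualification (VPC, NPC, NPDE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
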