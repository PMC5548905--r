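Package: coralcarb
Title: Coral Calcifying-Fluid Carbonate Chemistry from Boron Proxies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the carbonate chemistry of the coral calcifying fluid
    from skeletal boron geochemistry. Provides a total-scale seawater CO2-system
    solver (pH + total alkalinity input), the delta-11-B pH proxy and the B/Ca
    carbonate-ion proxy for calcifying-fluid pH, carbonate ion, DIC and aragonite
    saturation state, Monte-Carlo propagation of analytical uncertainty,
    buoyant-weight net calcification rates, an abiotic precipitation-kinetics
    (IpHRAC-style) rate model, the nested tank-design ANOVA workflow used in
    mesocosm acidification experiments, and a synthetic mesocosm data generator
    for end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
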