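Package: aapflux
Title: Photoheterotrophic Modulation of Lake Carbon Fluxes by Aerobic Anoxygenic Phototrophs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the contribution of aerobic anoxygenic phototrophic
    (AAP) bacteria to freshwater microbial metabolism from paired dark and
    infrared-light bottle incubations.  Converts raw Winkler titration
    records into dissolved-oxygen concentrations and respiration and net
    primary production rates, derives dissolved inorganic carbon from Gran
    alkalinity titrations, turns scintillation counts into radiotracer
    assimilation rates, estimates the infrared-light effect with
    random-intercept linear mixed models fitted by maximum likelihood,
    relates community composition to environmental drivers with
    distance-based linear models (DistLM) and distance-based redundancy
    analysis, and upscales the dark-versus-infrared respiration difference
    to a whole-lake seasonal CO2 budget.  Includes a synthetic-data
    generator with known ground truth covering every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
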