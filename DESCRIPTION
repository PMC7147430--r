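Package: hydrotime
Title: Hydrotime and Hydrothermal-Time Models of Seed Germination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Population-based threshold models for seed germination
    kinetics. Fits the hydrotime model (per-temperature hydrotime
    constant, median base water potential and its standard deviation)
    and the two-branch hydrothermal-time model (hydrothermal time
    constant, base temperature, optimum temperature, ceiling
    temperature and the supra-optimal threshold shift rate) to
    interval-censored germination count data by maximum-likelihood
    binomial probit regression with profiled model constants. Includes
    prediction and time-course normalization utilities, a forward
    simulator of germination experiments under the fitted threshold
    model, and JSON/CSV fit reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
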