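Package: pyrogam
Title: Annual Wildfire Probability Modelling with Penalized-Spline Binomial GAMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for estimating annual wildfire probability on a
    gridded landscape. Simulates spatially structured synthetic landscapes
    (climate normals and anomalies, housing density, cultivation, roads and
    electrical infrastructure, fire history) from a known additive ground
    truth; derives the standard covariate set (climate normals, three-year
    deviations, 25-km focal housing density, years since fire, distances to
    infrastructure); thins training pixels by Poisson-disk sampling; fits a
    binomial generalized additive model with penalized cubic regression
    splines by penalized IRLS with GCV smoothness selection; evaluates
    predictive skill under novel years, novel locations and both via
    multidimensional spatiotemporal blocked cross-validation; and decomposes
    predictions into climate, human-activity and time-since-fire
    contributions by counterfactual parameter elimination.
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
    mgcv,
    optparse
Config/testthat/edition: 3
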