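Package: ilrpower
Title: Power of Two-Sample t-Tests on Ilr-Transformed Bipolar Likert Scale Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats bipolar Likert-scale responses as two-part compositional data:
    the response scale is mapped onto the trait continuum under a psychometric
    limit of quantification (LOQ), closed to a two-part composition of agreement
    and disagreement, and carried to the real line by the isometric log-ratio
    (ilr) transformation. On top of that scale machinery the package provides a
    Monte-Carlo engine that simulates heavy-tailed (Laplace) distributions of
    item-response means, replaces simulated means by their nearest achievable
    means on the ilr scale and on the original response scale, applies paired,
    Student and Welch two-sample t-tests to both representations, and estimates
    the resulting difference in statistical power across large scenario grids,
    together with aggregation and findings-report utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
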