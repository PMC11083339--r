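Package: odshelf
Title: Kinetic Modelling of Osmotic Dehydration and Shelf Life of Leafy Greens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the kinetic-modelling chain used in shelf-life studies
    of osmotically dehydrated leafy vegetables: water loss and solid gain from
    gravimetric data with the square-root-of-time penetration model, modified
    Gompertz fits of total viable counts, zero-order sensory decay, Arrhenius
    secondary modelling of rate constants across storage temperatures, and
    composite shelf-life prediction from microbial and sensory limits at
    constant temperatures and under piecewise-constant temperature-abuse
    profiles. Includes a synthetic-study generator with known ground truth so
    the full pipeline can be validated by closed-loop parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
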