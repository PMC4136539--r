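Package: groomSim
Title: Hierarchical Suppression Modelling of the Drosophila Grooming Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates winner-take-all action selection among competing body-cleaning
    modules in dust-covered Drosophila, in two published flavours of the suppression
    hierarchy: graded sensory gain and unidirectional lateral inhibition. Includes leg
    rubbing with dust transfer onto the legs, constitutive-activation perturbations,
    and the companion quantification toolkit: ethogram bout statistics, first-order
    transition matrices, change-from-control tables, half-clearance (t50) decay fits,
    and groomogram-style per-pixel dust maps with mask-based region fractions. A
    synthetic-data module generates Markov ethograms, binary dust image stacks and
    decay series with known ground truth so every stage is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    png,
    tiff,
    minpack.lm,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'dustmaps.R'
    'groomConfig.R'
    'ethogram.R'
    'io.R'
    'simulate.R'
    'synthetic.R'
    'cli.R'
    'decay.R'
    'groomSim-package.R'
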