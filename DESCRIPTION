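Package: nasalcycle
Title: Two-Airway Nasal Air-Conditioning and Airway Surface Liquid Hydration Model
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transient one-dimensional heat and water-vapour transport
    simulator for the paired human nasal passages. Represents each passage
    as a series of narrow-gap geometric lumps, partitions tidal airflow
    between the two sides with a laminar parallel-resistance network,
    and tracks hydration of the airway surface liquid (ASL) lining each
    passage as a water-equivalent height ledger with physiological supply
    and reabsorption caps. Includes a parameterised synthetic nasal
    geometry generator, a tidal breathing waveform generator, psychrometric
    property correlations, and an experiment driver that contrasts the
    patent (low-resistance) and congested airway roles across a simulated
    nasal cycle state swap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
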