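Package: reefwatch
Title: Detection of Artificial-Island Building and Turbidity Plumes from
    Multi-Band Satellite Reflectance Time Series
Version: 0.1.0
Authors@R:
    person("Reef", "Watch", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect construction of artificial islands on coral
    reefs and to quantify the resulting turbidity plumes from time series of
    Rayleigh-corrected multi-band reflectance imagery (469, 555, 645 and 859
    nm at 250-m nominal resolution). Includes a synthetic multi-band scene
    generator with known ground truth (island growth, plumes, sunglint,
    clouds), Rayleigh-corrected reflectance and sunglint correction,
    a blue-minus-red Turbidity Index, cloudmask dilation with manual
    overrides, per-pixel near-infrared trend fitting for island detection,
    plume delineation and area accounting, and tabular reporting of
    island-building projects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
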