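Package: hazedea
Title: Chance-Constrained Stochastic DEA for Attributing PM2.5 Pollution Days
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links meteorological "disaster point" days and human-activity
    indicators to PM2.5 pollution days. Extracts threshold-based day counts
    from daily weather and air-quality series (wind speed below 1.5 m/s, no
    precipitation, day-over-day temperature rise, day-over-day pressure drop,
    relative humidity 60-90% on dry days, 24-h PM2.5 above 75 ug/m3), builds
    a decision-making-unit panel of means and standard deviations, solves an
    output-oriented variable-returns-to-scale chance-constrained stochastic
    data envelopment analysis model across risk levels, attributes influential
    factors by re-solving after deleting grouped or single input variables,
    and screens disaster-point series against pollution days with grey
    relational analysis. Includes seeded synthetic generators for daily
    weather, coupled PM2.5 and socioeconomic panels with planted frontier
    structure, so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
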