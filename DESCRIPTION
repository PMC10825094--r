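Package: ventbench
Title: Bench Simulation of the Mechanical Power Cost of Inhaled-Sedation Dead Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates volume-controlled ventilation of a passive
    single-compartment test lung with inhaled-sedation devices (AnaConDa-50,
    AnaConDa-100, MIRUS) inserted as additional effective dead space.
    Provides steady-state breath mechanics with auto-PEEP, a constant-inflow
    end-tidal CO2 model over a series dead space, calibration of device
    effective dead space from observed EtCO2 increases, a stepwise
    EtCO2-correction titration protocol (15 percent increments of tidal
    volume or respiratory rate), and derived lung-stress indices: simplified
    mechanical power, driving pressure and the Costa index. A factorial
    experiment driver assembles results over compliance, PEEP and device
    arms and reports deviations from a packaged reference table; a synthetic
    bench-record generator emulates the measurement process (integer
    pressure rounding, seeded noise).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
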