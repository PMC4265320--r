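Package: habitviz
Title: Habits-Monitoring Analytics and Visualization for Home Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts discrete home-monitoring sensor events (passive-infrared
    motion triggers and bed usage start/end messages) into continuous activity
    functions, day-part event counts and per-night behavioral features
    (bed/wake times, occupancy, continuity, nocturnal inactivity), computes
    usual-pattern and running-average baselines with deviation bounds, and
    renders a catalogue of clinician-oriented static visualizations. Includes
    a synthetic patient/sensor simulator with configurable sensor physics
    (motion dead time, usage minimum-registration debounce) so the full
    pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
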