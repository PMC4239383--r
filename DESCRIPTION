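Package: malvac
Title: Thermodynamic Modelling of Vacuolar Malate Storage in Fleshy Fruit
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic model of malate accumulation in the vacuole of
    fruit pulp cells, built on the thermodynamics of the tonoplast: passive
    di-anion malate transport at electrochemical equilibrium, proton pumping
    by the vacuolar H+-ATPase with a pH-dependent coupling ratio, and
    acid-base speciation of the vacuolar medium with Davies activity
    corrections. Solves the coupled stationary-state system for vacuolar
    malate and pH per sampling date, calibrates the free energy of ATP
    hydrolysis (constant during growth, quadratic in days after ethylene
    during post-harvest ripening) by particle swarm optimization, computes
    normalized local sensitivity coefficients to parameters and pulp
    composition, and ships a synthetic cultivar generator so the whole
    pipeline is testable without field data.
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
    pracma,
    optparse
Config/testthat/edition: 3
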