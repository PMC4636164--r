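Package: crisprcoevo
Title: Dynamical Models of Regulated CRISPR Immunity in Prokaryote-Phage
    Coevolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for deterministic models of
    CRISPR-mediated prokaryote-phage coevolution with infection-induced
    activation and autoimmunity side effects.  Implements a three-variable
    immune model with regulated autoimmunity and a ten-variable model with
    explicit spacer-quota kinetics, together with their analytic fixed
    points, survival thresholds, Routh-Hurwitz stability analysis, stiff
    numerical integration, one- and two-parameter bifurcation/boundary
    mapping, and classification of steady states into four qualitative
    regimes of CRISPR activity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
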