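Package: vestsim
Title: Reduced-Order Simulation of Hydrops-Enhanced Vestibulo-Ocular Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the angular vestibulo-ocular reflex (aVOR) response of
    the horizontal semicircular canal to video head impulse test (vHIT)
    stimuli under endolymphatic hydrops. A planar-loop reduction of the
    membranous labyrinth feeds a rigid-wall, rigid-cupula transcupular
    pressure law; an overdamped torsion-pendulum transduction model converts
    pressure to cupular volume displacement and equivalent head velocity;
    area-under-curve aVOR gains are computed for normal, canal-hydrops and
    utricular-hydrops geometries across a grid of synthetic head impulses.
    Includes a synthetic vHIT impulse generator, STL export of the
    parametric labyrinth surface, and tidy accessors for results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
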