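Package: vtemaze
Title: Embodied T-Maze Simulation of Vicarious Trial-and-Error
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a differential-drive robot solving a T-maze under a
    plastic two-unit Hebbian neural controller, in the tradition of embodied
    evolutionary-robotics models of vicarious trial-and-error (VTE). Provides
    the full experimental stack: the maze world with whisker, omnidirectional
    camera, infrared and reward channels; the five-module controller with
    separated state/virtual units and a modified Hebbian rule; a genetic
    algorithm over the 49 controller parameters; Schmitt-trigger VTE
    detection, counting and online suppression; maximum-Lyapunov-exponent
    estimation for short neural time series by the Rosenstein method; and
    robustness experiment harnesses (start-position grids, maze-size and
    reward-distance sweeps, learning-on/off replays).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
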