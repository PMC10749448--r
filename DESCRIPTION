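Package: lpshells
Title: Lone-Pair Decomposition of Ion Hydration Shells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of halide-ion hydration structure and dynamics from molecular
    dynamics trajectories that carry the ion lone-pair sites (e.g. maximally localized
    Wannier-function centers) as pseudo-atoms. Implements the angle-weighted lone-pair
    to hydrogen distance descriptor eta, splits the conventional first hydration shell
    into tight and loose subshells by an eta cutoff, and characterizes their structure
    (radial and spatial distribution functions, coordination-number distributions,
    misoriented-water detection) and dynamics (committed exchange events with a
    transient filter and normalized mean residence times by the direct method).
    Includes a synthetic-trajectory generator with tetrahedrally anchored tight waters
    and Markovian inter-region exchange for validation, plus readers and writers for
    extended XYZ trajectories, Gaussian cube grids and two-column curve files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
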