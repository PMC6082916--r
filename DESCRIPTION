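Package: lipsfft
Title: Isotropic Periodic Sum Electrostatics with FFT-Accelerated
    Long-Range Summation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes electrostatic energies and forces of periodic
    point-charge systems with linear-combination-based isotropic periodic
    sum (LIPS) pseudo pair potentials. The pseudo pair potential is split
    into short-range, long-range and boundary parts; the short-range and
    boundary parts are summed in real space and the long-range part is
    evaluated on a mesh by cardinal B-spline charge spreading and FFT
    convolution, in the manner of smooth particle mesh Ewald. Includes a
    brute-force pairwise oracle, synthetic-system generators, trajectory
    observables (radial distribution function, velocity autocorrelation,
    Einstein diffusion, density and electrostatic potential profiles), a
    minimal leapfrog molecular-dynamics loop, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
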