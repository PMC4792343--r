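Package: polycell
Title: Polyline Finite-Element Mechanics of Planar Cell Aggregates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the mechanics of two-dimensional cell aggregates in
    which every cell boundary carries an interfacial tension and the cytoplasm
    acts as a viscous dashpot system.  Cell edges are represented as polylines
    (chains of straight rod elements joined by intermediate nodes) so that
    boundaries can curve under intracellular pressure differences; the
    classical straight-edge (monoline) vertex model is recovered as the
    special case with no intermediate nodes.  Includes seeded Voronoi
    tessellation initial conditions, Lagrange-multiplier area constraints,
    T1 neighbour exchanges with an optional embargo timer, automatic segment
    refinement and coarsening, and the quantitative comparison metrics used
    to contrast the two edge representations: circular-arc fits, Young-angle
    errors at triple junctions, interface curvature and length, and cell
    displacement, across annealing, engulfment, sorting, invasion and
    checkerboard scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
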