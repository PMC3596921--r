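Package: leafcycle
Title: Leaf Meshing, Mass-Spring Deformation and Markov Senescence
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the seasonal life cycle of broadleaf foliage. A
    smooth closed boundary is fitted through key points on the leaf edge
    with a periodic interpolating cubic spline, triangulated by
    incremental-insertion Delaunay triangulation, and improved by an
    iterative optimization loop (vertex relocation plus edge flips) that
    removes long, narrow triangles. The mesh is deformed with a
    mass-spring model integrated by explicit Euler under a velocity
    constraint that caps over-elastic spring stretch, with per-particle
    masses taken from a grayscale mask map so that darker regions curl
    more. Populations of leaves then age through user-defined senescence
    states via a Markov chain whose half-lives and transition weights are
    bilinear functions of normalized temperature and humidness. Includes
    procedural generators for leaf outlines, mask maps and senescence
    specifications, Wavefront OBJ / binary PLY / PNG / JSON / CSV
    interchange, and a batch pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
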