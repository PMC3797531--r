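Package: tessella
Title: Two-Dimensional Multicellular Plant Tissue Simulation with
    Arrow-Based Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A vertex-based simulator for two-dimensional plant tissues.
    Biochemical networks are written as compact reaction arrows with
    mass-action and regulatory (Hill, GRN, S-System, NHCA, Michaelis-Menten,
    MWC) rate laws and compiled automatically into per-cell ordinary
    differential equations over a polygonal mesh of well-mixed cell
    compartments.  Species move between adjacent cells by Fickian membrane
    diffusion, facilitated transport, or act at a distance through saturating
    intercellular regulation.  Tissues grow by overdamped spring-pressure
    vertex dynamics with irreversible rest-length extension, and cells divide
    when a constituent (or cell area) crosses a normally distributed
    threshold, with new walls placed by Errera's shortest-bisecting-wall rule
    or by a weighted potential model.  Ships ready-to-run demonstration
    models of Brusselator reaction-diffusion patterning, the WUSCHEL/CLAVATA
    shoot apical meristem stem-cell niche, and organizer-maintained tissue
    growth, together with hexagonal and clipped-Voronoi tissue template
    generators and CSV mesh persistence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
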