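Package: channelkit
Title: Exploded Views, Surface Panoramas and Pore Profiles for Ion Channel Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry toolkit for illustration-driven analysis of oligomeric
    membrane channels. Reads atomic structures (PDB, including multi-model
    trajectory stacks), detects the channel symmetry axis and aligns assemblies
    into a canonical cylindrical frame, computes exploded-view layouts of
    subunits (radial, vertical across the membrane plane, or combined),
    abstracts subunits into simplified convex hull meshes, unrolls the surface
    onto a flat (theta, z) panorama by radial ray casting, profiles the ion
    permeation pore along the axis with constriction detection and tracking
    over trajectory frames, and condenses contour time series and trajectories
    into single still images (transparency compositing and motion-averaged
    blur). Ships a deterministic synthetic-assembly generator with analytic
    ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
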