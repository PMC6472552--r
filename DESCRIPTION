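Package: pneumosim
Title: Position-Based-Dynamics Simulation of Pneumoperitoneum for Surgical Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates subject-specific pneumoperitoneum (laparoscopic CO2
    insufflation of the abdominal cavity) from segmented triangle surface
    meshes of the abdominal wall, viscera and deflated peritoneal boundary.
    The deflated cavity is modelled as a position-based-dynamics inflatable
    (a closed cloth of distance constraints under a global overpressure
    volume constraint) interacting with shape-matched soft bodies for the
    wall and viscera. Includes mesh I/O (STL/PLY/OBJ), volume-preserving HC
    Laplacian smoothing, voxelisation, calibration by exhaustive grid
    search, voxel-overlap and Hausdorff validation metrics, a cubic mapping
    between the simulation pressure parameter and insufflation pressure in
    mmHg, geodesic landmark measurements, and a deterministic synthetic
    abdomen phantom for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
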