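Package: hierSDM
Title: Hierarchical Species Distribution Models for Invasive Species
    Hotspot Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Presence-only species distribution modelling for invasive
    terrestrial vertebrates on a regular geographic grid. Fits global
    climate-only ensemble models whose projections weight the
    pseudo-absences of regional full-predictor ensemble models, stacks
    per-species binary predictions into richness maps, classifies grid
    cells into six priority-management zones, and quantifies
    non-model uncertainty with multivariate environmental similarity
    surfaces (MESS), half-ignorance sampling-effort maps and
    Bhattacharyya distances between prediction maps. Includes a virtual
    species simulator (biased presence-only sampling from a known
    suitability surface, with coordinate-uncertainty annotation and
    common coordinate errors) so the whole pipeline runs at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    splines,
    mgcv,
    xgboost,
    glmnet,
    geosphere,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
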