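Package: fismd
Title: Organoid Swelling Quantification and Structure-Geometry Analysis
Version: 0.1.0
Authors@R:
    person("FISMD", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies forskolin-induced swelling (FIS) of intestinal
    organoids from brightfield time-lapse stacks using a gradient-based
    ridge/valley pixel-classification segmentation, normalized swelling
    curves and area-under-curve response metrics (baseline correction,
    fold change, synergy).  Also provides molecular structure and
    trajectory geometry: least-squares superposition, global and
    residue-wise RMSD, RMSF, minimum-distance series, salt-bridge
    contact fractions, and a sliding-window assignment scan that ranks
    candidate sequence registers for an unresolved protein segment by
    backbone-RMSD stability.  Ships seeded synthetic-data generators
    (organoid wells with known ground truth; coordinate trajectories
    with programmed fluctuations) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
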