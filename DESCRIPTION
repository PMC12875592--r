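Package: energymaps
Title: Cortical Mapping and Lifespan Trajectories of Energy-Metabolism
    Pathway Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds parcel-level cortical expression maps for curated
    energy-metabolism pathway gene sets (glycolysis, pentose phosphate
    pathway, TCA cycle, oxidative phosphorylation, lactate metabolism)
    from donor microarray sample tables, using intensity-based probe
    filtering, differential-stability probe selection, bilateral sample
    mirroring, distance-based parcel assignment and robust-sigmoid
    normalization.  Tests enrichment of pathway maps in structural and
    functional parcel classes, and map-map correlations, against
    spatial-autocorrelation-preserving spin null ensembles with
    Benjamini-Hochberg FDR control.  Charts pathway expression
    trajectories across eight developmental stages from RPKM-scale
    RNA-seq tables with upper-quartile normalization and LOESS
    smoothing.  A synthetic-data module generates every input the
    pipeline consumes, with controllable spatial autocorrelation,
    planted class effects and planted stage trajectories, so the whole
    pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
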