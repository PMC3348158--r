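Package: divtime
Title: Diversification Timing Analysis on Dated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the timing of diversification events in dated
    (ultrametric) phylogenies of regional species assemblages. Given a
    chronogram with node ages in millions of years, optional node-age
    credibility intervals, and a species table assigning each tip to a
    taxonomic hierarchy and a biogeographic status (endemic, non-endemic
    native, exotic, outgroup), the package prunes the tree to a status class,
    extracts split ages, and tests whether their median differs from a null
    distribution built by repeatedly resampling equally sized random tip sets
    from the full tree. Sensitivity reruns use the lower or upper bound of
    each node-age interval. Species without sequence data can be grafted onto
    the backbone as polytomies at the most recent common ancestor of
    congeners, family members or order members, producing a series of
    chronograms of increasing taxonomic coverage. Supporting utilities
    simulate birth-death chronograms with clade-structured category labels,
    filter alignment blocks by conservation rules, and concatenate per-locus
    alignments into a partitioned supermatrix with missing-data accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
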