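Package: playseq
Title: State-Sequence Analysis of Object Play in Groups of Juvenile Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing categorical behavioural state sequences
    recorded at fixed 5-second resolution in small social groups, built
    around a home-pen object-play paradigm in juvenile pigs. Sequences over
    a merged three-state alphabet (no play, object play, locomotor/social
    play) are constructed from raw interval records; within-sequence
    complexity is quantified by longitudinal entropy, turbulence and the
    complexity index; pairwise dissimilarity uses optimal matching with
    indel cost 1 and transition-rate substitution costs; play patterns are
    identified by Ward clustering validated with average silhouette width
    and Hubert's C; individuals are typed as initiators/joiners and
    solitary/social players by one-sample proportion tests; transition
    rates are compared by stratified Cochran-Mantel-Haenszel tests; and
    play synchrony is tested against independence and cyclic-shift null
    models. A seeded generator of group-coupled play datasets with planted
    ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    car,
    mclust,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
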