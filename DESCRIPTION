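Package: isbreach
Title: Detection and Analysis of Insertion-Sequence Transpositions into
    Defense Loci
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for locating exact insertion-sequence (IS) copies in
    bacterial replicons, calling the flanking target-site duplications
    (TSDs) as direct repeats, annotating disrupted genes and defense-system
    context, summarising TSD motifs as position frequency matrices with
    IUPAC consensus and Pearson comparisons, matching CRISPR spacers to
    protospacers with optional PAM checking, and synonymously recoding
    coding sequences to remove IS target-site motifs and internal repeats.
    Includes a ground-truthed synthetic-data generator (cas-like loci, IS
    implants with controlled TSD length mixtures and motif-biased sites)
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
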