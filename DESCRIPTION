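Package: microdna
Title: MicroDNA Circle Calling, Annotation, and Biomarker Panel Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls microDNA (small extrachromosomal circular DNA, <2 kb) from
    chimeric-junction alignments, annotates circle origins against gene models
    (promoter, UTR, exon, intron) and open-chromatin peak sets, builds gene-by-sample
    presence matrices across disease stages and tissues, tests cross-stage sharing of
    microDNA-producing genes against a binomial null, derives disease- and
    relapse-specific gene signature panels by stepwise presence/absence filtering,
    and evaluates panel prognostic value with gene-by-patient binary events (odds
    ratios with Woolf confidence intervals and one-tailed chi-squared tests). A
    seeded synthetic-cohort generator with a ground-truth manifest supports
    end-to-end testing without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
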