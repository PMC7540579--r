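Package: segshare
Title: Shared Genomic Segment Analysis via Heterozygosity Scans and
    Permutation Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps dominantly inherited disease variants by detecting genomic
    segments shared by affected individuals more often than expected by
    chance. Per-individual sliding-window heterozygosity scans nominate
    candidate disease-variant positions (peaks of local heterozygote excess);
    a per-variant sharing statistic counts how many individuals place a
    candidate within a distance d of each variant; a permutation null, built
    by re-drawing each individual's candidate positions uniformly over the
    variant universe, yields empirical p-values in an equivalence-testing
    framework where heterogeneity is the null hypothesis. Significant runs of
    consecutive shared variants are reported as candidate regions. Includes a
    synthetic-data generator for diploid genotype matrices with an implanted
    heterozygote-excess signal, VCF and TSV input, and a pipeline driver with
    reproducible manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
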