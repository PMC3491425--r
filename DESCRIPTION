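Package: methelim
Title: Methylation-Marked DNA Elimination Analysis for Ciliate Genome
    Rearrangement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking cytosine methylation and hydroxymethylation to
    programmed DNA elimination in ciliates such as Oxytricha trifallax.
    Implements meDIP-seq enrichment normalization (RPKM and
    vegetative-subtracted signal), copy-number classification of
    germline-limited (polytenized) contigs, threshold-based calling of
    methylation, hydroxymethylation and motif cohorts, exact-null position
    weight matrix scanning with per-occurrence false-discovery calibration,
    all-context bisulfite methylation calling with skip-run statistics and
    conversion QC, detection of aberrant rearrangement junctions at cryptic
    pointer microhomologies against scrambled locus maps, and ddCt qPCR
    quantification with one-tailed Welch tests.  A seeded synthetic-data
    generator emulates the study design (telomere-capped nanochromosomes,
    polytenized satellite and transposon contigs, antibody
    immunoprecipitation libraries, bisulfite clones, rearrangement products
    and Ct tables) so that every stage can be exercised against ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    cluster,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
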