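Package: editcall
Title: Genotyping CRISPR-Cas9-Edited Cells from Deep Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls the major genotypes of CRISPR-Cas9-edited cell clones or
    bulk populations from deep amplicon sequencing. Reads demultiplexed FASTQ
    files, joins paired-end mates by overlap, collapses reads to unique
    sequences, applies a read-count cutoff, aligns retained reads to the
    target region with an affine-gap local aligner, extracts and
    left-normalizes indels into VCF CHR-POS-REF-ALT form, and reports the
    genotype signatures supported by at least 1% of a sample's reads as major
    genotypes. Includes per-sample summary, VCF and plot output, a cohort
    genotype-by-sample proportion matrix, and a read simulator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
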