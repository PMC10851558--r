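Package: generosion
Title: Comparative Genomics of Reduced Endosymbiont Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of highly reduced bacterial
    endosymbiont genomes (Buchnera aphidicola and relatives): genome- and
    gene-level GC composition statistics, reciprocal-best-hit homology to a
    free-living reference proteome, a synteny-ordered cross-genome gene array
    with pan/core genome, split-gene, duplication, inversion and syntenic-block
    detection, the GC-versus-homolog-identity quadrant framework with its
    multiple regression model, allele-frequency analytics for detecting
    co-resident endosymbiont strains, and expression summaries (logCPM tiers,
    Ex90). A synthetic genome-reduction simulator with a complete ground-truth
    ledger backs every stage for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
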