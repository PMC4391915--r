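#!/usr/bin/env Rscript
# One-time fetch of the deposited receptor cDNA sequences from GenBank into
# inst/extdata/, enabling the sequence-level checks in the test suite.
# Requires network access; run from the repository root.

accessions <- c("KJ925051", "KJ925050")  # skate and bichir receptor cDNAs

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
for (acc in accessions) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=", acc, "&rettype=fasta&retmode=text")
  dest <- file.path("inst", "extdata", paste0(acc, ".fasta"))
  message("fetching ", acc, " -> ", dest)
  download.file(url, dest, quiet = TRUE)
  stopifnot(file.size(dest) > 500)
}
message("done; reinstall the package so system.file() can locate the files")
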