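#!/usr/bin/env Rscript
# Download the UniProt sequences used by the published BRCA2 / HAT case
# studies into the package's per-user cache, for fragal_reproduction().
# Usage: Rscript scripts/fetch_uniprot.R [dir]
# Requires network access.

suppressPackageStartupMessages(library(fragal))

args <- commandArgs(trailingOnly = TRUE)
dir <- if (length(args)) args[1] else uniprot_cache_dir()
dir.create(dir, recursive = TRUE, showWarnings = FALSE)

accessions <- c(
  "Q9W157",  # Drosophila melanogaster BRCA2
  "P51587",  # human BRCA2
  "Q02354",  # S. cerevisiae Utp6
  "Q9NYH9")  # human U3 snoRNP protein with HAT repeats

for (acc in accessions) {
  dest <- file.path(dir, paste0(acc, ".fasta"))
  if (file.exists(dest)) {
    message(acc, ": already cached")
    next
  }
  url <- sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta", acc)
  message("fetching ", url)
  utils::download.file(url, dest, quiet = TRUE)
}
message("cached in ", dir)
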