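#!/usr/bin/env Rscript
# Download the seven Chloranthus chloroplast genome GenBank records from
# NCBI into inst/extdata/genomes/ so that the full-reproduction test in
# tests/testthat/test-acceptance.R (and any pipeline run on the real
# data) can execute. Requires network access; run from the package root:
#   Rscript scripts/fetch_genomes.R

accessions <- c("MW581013", "NC_082096", "NC_009598", "NC_026565",
                "NC_039627", "MK922064", "NC_065306")
dest_dir <- file.path("inst", "extdata", "genomes")
dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)

base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
for (acc in accessions) {
  dest <- file.path(dest_dir, paste0(acc, ".gb"))
  if (file.exists(dest)) {
    cat(acc, "already present\n")
    next
  }
  url <- paste0(base, "?db=nuccore&id=", acc,
                "&rettype=gbwithparts&retmode=text")
  cat("fetching", acc, "...\n")
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  Sys.sleep(0.5)  # NCBI rate limit
}
cat("done;", length(accessions), "records under", dest_dir, "\n")
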