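# Programmatic fixtures: valid/invalid CDS strings and a small
# synthetic GenBank flat file exercising join/complement locations.

# a clean CDS: ATG + n internal sense codons + stop
make_cds <- function(n_internal, stop = "TAA", pool = NULL) {
  if (is.null(pool)) pool <- setdiff(sense_codons(), "ATG")
  paste(c("ATG", sample(pool, n_internal, replace = TRUE), stop),
        collapse = "")
}

# GenBank record with a plus-strand CDS, a minus-strand spliced CDS and
# a multi-line join; the minus-strand coding sequence is ATGAAACCCTAA.
write_test_genbank <- function(path) {
  genome <- paste0(
    "AAACCCGGG",            # 1..9   plus-strand CDS
    "TTAGGG",               # 10..15 exon 2 (minus strand)
    "ACGT",                 # 16..19 intron
    "TTTCAT",               # 20..25 exon 1 (minus strand)
    "GGGGG"                 # 26..30 spacer
  )
  lines <- c(
    "LOCUS       SYNTEST                   30 bp    DNA     circular PLN 01-JAN-2026",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..30",
    "     CDS             1..9",
    '                     /gene="plusg"',
    "     CDS             complement(join(10..15,20..25))",
    '                     /gene="minusg"',
    "     CDS             join(1..6,",
    "                     7..9)",
    '                     /gene="splitg"',
    "ORIGIN",
    paste0("        1 ", tolower(genome)),
    "//"
  )
  writeLines(lines, path)
  invisible(genome)
}

# a mixed bag of records covering every filter reason plus clean genes
make_filter_testset <- function() {
  withr::with_seed(101, {
    good1 <- make_cds(120)
    good2 <- make_cds(150)
    internal <- paste(c("ATG", sample(setdiff(sense_codons(), "ATG"), 50,
                                      replace = TRUE),
                        "TAA",
                        sample(setdiff(sense_codons(), "ATG"), 49,
                               replace = TRUE), "TAA"), collapse = "")
    cds_set(
      gene_id = c("ok1", "ok2", "ok2", "short300", "gtgstart", "midstop",
                  "frameoff", "ambig", "nostop"),
      sequence = c(
        good1, good2, good2,
        make_cds(98),                           # exactly 300 nt
        sub("^ATG", "GTG", make_cds(120)),
        internal,
        paste0(make_cds(120), "AC"),
        sub("^ATGAAA", "ATGANA", paste(c("ATG", rep("AAA", 110), "TAA"),
                                       collapse = "")),
        sub("TAA$", "AAA", make_cds(120))
      ),
      species_id = "testsp"
    )
  })
}
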