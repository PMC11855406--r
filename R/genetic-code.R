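#' @keywords internal
"_PACKAGE"

# Standard genetic code (NCBI table 1; identical to the plastid/bacterial
# table 11 over sense codons). Stops are TAA/TAG/TGA in both.
.STOP_CODONS <- c("TAA", "TAG", "TGA")

.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  # enumerate in a fixed T/C/A/G order so the table matches the textbook layout
  codons <- sort(codons)
  aa <- as.character(Biostrings::GENETIC_CODE[codons])
  names(aa) <- codons
  aa
})

#' All 64 codons (DNA alphabet)
#'
#' @return Character vector of the 64 trinucleotides in alphabetical order.
#' @export
codons <- function() names(.codon_table)

#' Stop and sense codons of the standard/plastid genetic code
#'
#' The standard code (NCBI table 1) and the bacterial/plastid code
#' (table 11) agree on every sense codon and on the three stops
#' TAA/TAG/TGA, so a single table serves chloroplast CDS analysis.
#'
#' @return `stop_codons()`: the three stop trinucleotides.
#'   `sense_codons()`: the 61 coding trinucleotides.
#' @export
stop_codons <- function() .STOP_CODONS

#' @rdname stop_codons
#' @export
sense_codons <- function() setdiff(codons(), .STOP_CODONS)

#' Amino acid encoded by each codon
#'
#' @param codon Character vector of trinucleotides (DNA alphabet).
#' @return Character vector of one-letter amino acids, `"*"` for stops.
#' @export
codon_aa <- function(codon = codons()) {
  out <- .codon_table[toupper(codon)]
  names(out) <- codon
  out
}

# amino acid -> codons, sense only
.aa_families <- local({
  sense <- setdiff(names(.codon_table), .STOP_CODONS)
  split(sense, .codon_table[sense])
})

#' Synonymous-codon families
#'
#' @return `aa_families()`: named list mapping each amino acid (one-letter)
#'   to its synonymous sense codons. `aa_degeneracy()`: named integer vector
#'   of family sizes (1, 2, 3, 4 or 6).
#' @examples
#' aa_degeneracy()[c("M", "W", "I", "L")]  # 1 1 3 6
#' @export
aa_families <- function() .aa_families

#' @rdname aa_families
#' @export
aa_degeneracy <- function() vapply(.aa_families, length, integer(1))

#' Synonymously degenerate sense codons
#'
#' The 59 sense codons whose amino acid has at least two synonyms;
#' ATG (Met) and TGG (Trp) are excluded. This is the codon set over
#' which GC3s and RSCU-based preference statements are defined.
#'
#' @return Character vector of 59 codons.
#' @export
degenerate_codons <- function() {
  multi <- names(.aa_families)[vapply(.aa_families, length, integer(1)) >= 2L]
  unlist(.aa_families[multi], use.names = FALSE)
}

#' Convert codons between DNA and RNA spelling
#'
#' Reports in the field conventionally spell codons with U; sequences are
#' handled internally with T.
#'
#' @param codon Character vector of trinucleotides.
#' @return Recoded character vector.
#' @export
codon_to_rna <- function(codon) chartr("Tt", "Uu", codon)

#' @rdname codon_to_rna
#' @export
codon_to_dna <- function(codon) chartr("Uu", "Tt", codon)
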