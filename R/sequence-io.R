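# CDS extraction and filtering.
#
# A CDS set is a plain data.frame with columns gene_id, species_id and
# sequence (coding-strand DNA, uppercase). filter_cds() attaches the
# exclusion report as an attribute so every dropped gene is auditable.

#' Construct a CDS set
#'
#' @param gene_id Character vector of gene identifiers.
#' @param sequence Character vector of coding-strand nucleotide sequences.
#' @param species_id Single species/genome label or vector.
#' @return A `data.frame` with columns `gene_id`, `species_id`, `sequence`.
#' @export
cds_set <- function(gene_id, sequence, species_id = "unknown") {
  stopifnot(length(gene_id) == length(sequence))
  data.frame(
    gene_id = as.character(gene_id),
    species_id = rep_len(as.character(species_id), length(gene_id)),
    sequence = toupper(as.character(sequence)),
    stringsAsFactors = FALSE
  )
}

#' Read coding sequences from a GenBank flat file or FASTA
#'
#' GenBank input is parsed for `CDS` features: `join()` locations are
#' spliced in the stated exon order and `complement()` segments are
#' reverse-complemented, so the returned sequence is always the coding
#' strand. FASTA input is taken as pre-extracted CDSs, one per entry,
#' with the first word of each header as `gene_id`.
#'
#' No filtering happens here; see [filter_cds()].
#'
#' @param path Path to a GenBank flat file (`LOCUS`/`FEATURES`/`ORIGIN`)
#'   or a (multi-)FASTA file.
#' @param species_id Label for the genome; defaults to the GenBank LOCUS
#'   name or the file name.
#' @param format `"auto"` (sniff first non-blank character), `"genbank"`
#'   or `"fasta"`.
#' @return A CDS set data.frame (see [cds_set()]), one row per CDS
#'   feature occurrence, in genomic order for GenBank input.
#' @export
read_genome <- function(path, species_id = NULL,
                        format = c("auto", "genbank", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") {
    head_lines <- readLines(path, n = 50L, warn = FALSE)
    head_lines <- head_lines[nzchar(trimws(head_lines))]
    if (length(head_lines) == 0L) stop("cannot parse '", path, "': file is empty")
    first <- head_lines[[1L]]
    format <- if (startsWith(first, ">")) "fasta"
      else if (grepl("^LOCUS", first)) "genbank"
      else stop("cannot parse '", path,
                "': neither FASTA ('>') nor GenBank ('LOCUS') signature found")
  }
  if (format == "fasta") {
    seqs <- Biostrings::readDNAStringSet(path)
    if (is.null(species_id))
      species_id <- sub("\\.[^.]*$", "", basename(path))
    ids <- sub("\\s.*$", "", names(seqs))
    cds_set(ids, as.character(seqs), species_id)
  } else {
    read_genbank_cds(path, species_id = species_id)
  }
}

#' @rdname read_genome
#' @export
read_genbank_cds <- function(path, species_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L)
    stop("cannot parse '", path, "' as GenBank: no LOCUS line")
  if (is.null(species_id)) {
    toks <- strsplit(trimws(lines[locus_i[[1L]]]), "\\s+")[[1L]]
    species_id <- if (length(toks) >= 2L) toks[[2L]] else basename(path)
  }

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(feat_i) == 0L || length(orig_i) == 0L)
    stop("cannot parse '", path, "' as GenBank: missing FEATURES or ORIGIN")
  feat_i <- feat_i[[1L]]; orig_i <- orig_i[[1L]]

  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > orig_i][1L] else length(lines) + 1L
  if (is.na(end_i)) end_i <- length(lines) + 1L
  seq_lines <- lines[(orig_i + 1L):(end_i - 1L)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(genome)) stop("GenBank record has an empty ORIGIN section")

  flines <- lines[(feat_i + 1L):(orig_i - 1L)]
  # feature keys sit at column 6; qualifier/continuation lines start deeper
  is_key <- grepl("^ {5}\\S", flines)
  key_idx <- which(is_key)
  keys <- sub("^ {5}(\\S+).*$", "\\1", flines[is_key])

  out_gene <- character(0)
  out_seq <- character(0)
  cds_n <- 0L
  for (k in seq_along(key_idx)) {
    if (keys[[k]] != "CDS") next
    cds_n <- cds_n + 1L
    from <- key_idx[[k]]
    to <- if (k < length(key_idx)) key_idx[[k + 1L]] - 1L else length(flines)
    block <- flines[from:to]
    # location = text after the key, continued until the first qualifier line
    loc <- sub("^ {5}\\S+\\s*", "", block[[1L]])
    j <- 2L
    while (j <= length(block) && !grepl("^\\s+/", block[[j]])) {
      loc <- paste0(loc, trimws(block[[j]]))
      j <- j + 1L
    }
    quals <- block[grepl("^\\s+/", block)]
    gene <- .gb_qualifier(quals, "gene")
    if (is.na(gene)) gene <- .gb_qualifier(quals, "locus_tag")
    if (is.na(gene)) gene <- sprintf("CDS_%03d", cds_n)
    seq <- tryCatch(.gb_extract(genome, loc),
                    error = function(e) {
                      warning("skipping CDS '", gene, "': ", conditionMessage(e))
                      NA_character_
                    })
    if (is.na(seq)) next
    out_gene <- c(out_gene, gene)
    out_seq <- c(out_seq, seq)
  }
  cds_set(out_gene, out_seq, species_id)
}

.gb_qualifier <- function(qual_lines, name) {
  pat <- paste0("^\\s+/", name, "=")
  hit <- grep(pat, qual_lines, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  val <- sub(pat, "", hit[[1L]])
  gsub("\"", "", val)
}

# Evaluate a GenBank location string over the full genome sequence.
# Handles n..m, single positions, join(), order() and complement(),
# arbitrarily nested; partial markers (<, >) are ignored.
.gb_extract <- function(genome, loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  .eval_loc <- function(s) {
    if (grepl("^complement\\(", s)) {
      inner <- substr(s, nchar("complement(") + 1L, nchar(s) - 1L)
      return(.revcomp(.eval_loc(inner)))
    }
    if (grepl("^(join|order)\\(", s)) {
      inner <- sub("^(join|order)\\(", "", s)
      inner <- substr(inner, 1L, nchar(inner) - 1L)
      parts <- .split_top_level(inner)
      return(paste(vapply(parts, .eval_loc, character(1)), collapse = ""))
    }
    if (grepl("^[0-9]+\\.\\.[0-9]+$", s)) {
      se <- as.integer(strsplit(s, "\\.\\.")[[1L]])
      if (se[[2L]] > nchar(genome) || se[[1L]] < 1L)
        stop("location ", s, " outside sequence of length ", nchar(genome))
      return(substr(genome, se[[1L]], se[[2L]]))
    }
    if (grepl("^[0-9]+$", s)) return(substr(genome, as.integer(s), as.integer(s)))
    stop("unsupported location syntax: ", s)
  }
  .eval_loc(loc)
}

# split "a,b,c" at commas not enclosed in parentheses
.split_top_level <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  depth <- 0L; start <- 1L; out <- character(0)
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == "," && depth == 0L) {
      out <- c(out, substr(s, start, i - 1L)); start <- i + 1L
    }
  }
  c(out, substr(s, start, nchar(s)))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Filter raw CDS records to the analysis gene set
#'
#' Applies, in order: de-duplication of repeated gene names (inverted-repeat
#' duplicates such as *rps12*/*ndhB* are kept once, first occurrence by
#' input order), exclusion of sequences with non-ACGT characters, length
#' not a multiple of 3, length not strictly greater than `min_len - 1`
#' nucleotides, missing ATG start, missing terminal TAA/TAG/TGA stop, and
#' premature (internal) stop codons. Every exclusion is recorded with its
#' reason in the `"exclusions"` attribute (a data.frame `gene_id`,
#' `species_id`, `reason`), retrievable with [cds_exclusions()].
#'
#' @param x A CDS set data.frame (from [read_genome()] or [cds_set()]).
#' @param min_len Minimum retained length in nucleotides, exclusive lower
#'   bound at `min_len - 1`; the default 301 retains genes strictly longer
#'   than 300 bp.
#' @return The retained CDS set (same columns), with the exclusion report
#'   attached. Errors if no gene survives.
#' @export
filter_cds <- function(x, min_len = 301L) {
  stopifnot(is.data.frame(x), all(c("gene_id", "species_id", "sequence") %in% names(x)))
  prior <- attr(x, "exclusions")
  x$sequence <- toupper(x$sequence)
  drop_reason <- rep(NA_character_, nrow(x))

  mark <- function(idx, reason) {
    sel <- idx & is.na(drop_reason)
    drop_reason[sel] <<- reason
  }
  mark(duplicated(paste(x$species_id, x$gene_id, sep = "\r")), "duplicate_gene_copy")
  mark(grepl("[^ACGT]", x$sequence), "ambiguous_bases")
  len <- nchar(x$sequence)
  mark(len %% 3L != 0L, "length_not_multiple_of_3")
  mark(len < min_len, "too_short")
  mark(substr(x$sequence, 1L, 3L) != "ATG", "no_atg_start")
  last <- substr(x$sequence, len - 2L, len)
  mark(!(last %in% stop_codons()), "no_terminal_stop")
  internal_stop <- vapply(seq_len(nrow(x)), function(i) {
    if (!is.na(drop_reason[[i]])) return(FALSE)
    cod <- codon_split(x$sequence[[i]])
    any(cod[-length(cod)] %in% stop_codons())
  }, logical(1))
  mark(internal_stop, "internal_stop")

  keep <- is.na(drop_reason)
  if (!any(keep))
    stop("no genes pass the CDS filters (", nrow(x), " examined)")
  excl <- data.frame(
    gene_id = x$gene_id[!keep],
    species_id = x$species_id[!keep],
    reason = drop_reason[!keep],
    stringsAsFactors = FALSE
  )
  if (is.data.frame(prior)) excl <- rbind(prior, excl)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' @rdname filter_cds
#' @export
cds_exclusions <- function(x) {
  excl <- attr(x, "exclusions")
  if (is.null(excl))
    excl <- data.frame(gene_id = character(0), species_id = character(0),
                       reason = character(0), stringsAsFactors = FALSE)
  excl
}

#' Write a CDS set to FASTA
#'
#' @param x CDS set data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(x, path) {
  seqs <- Biostrings::DNAStringSet(x$sequence)
  names(seqs) <- x$gene_id
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Split a coding sequence into codons
#'
#' @param sequence A single nucleotide string whose length is a multiple
#'   of 3.
#' @return Character vector of consecutive trinucleotides.
#' @export
codon_split <- function(sequence) {
  n <- nchar(sequence)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not a multiple of 3")
  substring(sequence, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}
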