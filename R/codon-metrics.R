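# Per-gene and pooled codon statistics: counts, RSCU, positional GC,
# Wright's effective number of codons and its mutation-only expectation.
#
# Conventions used throughout: statistics are defined over sense codons
# only. The initial ATG is counted (it is a Met codon); the terminal stop
# is carried in the 64-long count vector but excluded from every
# statistic, so a clean CDS of length L contributes L/3 - 1 sense codons.

#' Count codons in a coding sequence
#'
#' @param sequence A single CDS string (length a multiple of 3), or a
#'   character vector of codons.
#' @return Named integer vector of length 64 (all codons, alphabetical),
#'   including stop-codon counts.
#' @examples
#' count_codons("ATGAAATAA")[c("ATG", "AAA", "TAA")]
#' @export
count_codons <- function(sequence) {
  cod <- if (length(sequence) == 1L && nchar(sequence[[1L]]) > 3L)
    codon_split(sequence) else toupper(sequence)
  bad <- setdiff(unique(cod), codons())
  if (length(bad))
    stop("non-ACGT codons present: ", paste(utils::head(bad, 5), collapse = ", "))
  counts <- integer(64L)
  names(counts) <- codons()
  tab <- table(cod)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Codon count matrix for a CDS set
#'
#' @param x CDS set data.frame.
#' @return Integer matrix, genes in rows (named by `gene_id`), 64 codons
#'   in columns.
#' @export
codon_count_matrix <- function(x) {
  m <- t(vapply(x$sequence, count_codons, integer(64L)))
  rownames(m) <- x$gene_id
  m
}

.as_counts <- function(counts) {
  if (is.null(names(counts))) {
    if (length(counts) != 64L)
      stop("unnamed codon counts must have length 64")
    names(counts) <- codons()
  }
  full <- stats::setNames(numeric(64L), codons())
  full[names(counts)] <- counts
  if (any(full < 0)) stop("negative codon counts")
  full
}

#' Relative synonymous codon usage
#'
#' For a codon with count x in a synonymous family of size k whose family
#' total is n, RSCU = x * k / n: the observed count relative to the
#' expectation under uniform synonymous usage. Single-codon families
#' (Met, Trp) have RSCU 1 whenever observed. A family with zero total
#' yields RSCU 0 for all its codons and is listed in the `"unobserved"`
#' attribute.
#'
#' @param counts Codon counts (named vector over any subset of the 64
#'   codons, or unnamed length-64); stop codons are ignored.
#' @return Named numeric vector over the 61 sense codons.
#' @export
rscu <- function(counts) {
  counts <- .as_counts(counts)
  out <- stats::setNames(numeric(length(sense_codons())), sense_codons())
  unobserved <- character(0)
  for (aa in names(aa_families())) {
    fam <- aa_families()[[aa]]
    x <- counts[fam]
    tot <- sum(x)
    if (tot == 0) {
      out[fam] <- 0
      unobserved <- c(unobserved, aa)
    } else {
      out[fam] <- x * length(fam) / tot
    }
  }
  attr(out, "unobserved") <- unobserved
  out
}

#' Positional base composition of a codon count vector
#'
#' GCp is the fraction of G or C among position-p bases of sense codons.
#' GC3s restricts position 3 to codons whose amino acid has at least two
#' synonyms (Met, Trp and stops excluded). A3/T3/G3/C3 are third-position
#' base counts over all sense codons.
#'
#' @param counts Codon counts as in [rscu()].
#' @return Named list with `n_codons`, `gc1`, `gc2`, `gc3`, `gc12`,
#'   `gc_all`, `gc3s`, `a3`, `t3`, `g3`, `c3`.
#' @export
composition <- function(counts) {
  counts <- .as_counts(counts)
  sc <- sense_codons()
  x <- counts[sc]
  n <- sum(x)
  if (n == 0) stop("no sense codons observed")
  base_at <- function(p) substr(sc, p, p)
  gc_at <- function(p) sum(x[base_at(p) %in% c("G", "C")]) / n
  gc1 <- gc_at(1L); gc2 <- gc_at(2L); gc3 <- gc_at(3L)
  deg <- degenerate_codons()
  xs <- counts[deg]
  gc3s <- if (sum(xs) > 0)
    sum(xs[substr(deg, 3L, 3L) %in% c("G", "C")]) / sum(xs) else NA_real_
  b3 <- base_at(3L)
  list(
    n_codons = as.integer(n),
    gc1 = gc1, gc2 = gc2, gc3 = gc3,
    gc12 = (gc1 + gc2) / 2,
    gc_all = (gc1 + gc2 + gc3) / 3,
    gc3s = gc3s,
    a3 = as.integer(sum(x[b3 == "A"])),
    t3 = as.integer(sum(x[b3 == "T"])),
    g3 = as.integer(sum(x[b3 == "G"])),
    c3 = as.integer(sum(x[b3 == "C"]))
  )
}

#' Wright's effective number of codons (observed)
#'
#' Computes ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, where Fk is the mean
#' codon homozygosity of the degeneracy-k families. For a family with n
#' observed codons and within-family frequencies p,
#' F = (n * sum(p^2) - 1) / (n - 1), computed only when n >= 2; families
#' with F <= 0 are dropped from the class mean. If no 3-fold family
#' (Ile) is computable, F3 is imputed as (F2 + F4)/2. The result is
#' capped at 61 (uniform usage); 20 (one codon per amino acid) is the
#' floor by construction.
#'
#' @param counts Codon counts as in [rscu()].
#' @return ENC value in `[20, 61]`, or `NA` (flagged undefined) if a
#'   2-, 4- or 6-fold class has no computable family.
#' @export
enc_observed <- function(counts) {
  counts <- .as_counts(counts)
  deg <- aa_degeneracy()
  fam_F <- lapply(c(2L, 3L, 4L, 6L), function(k) {
    aas <- names(deg)[deg == k]
    Fv <- vapply(aas, function(aa) {
      x <- counts[aa_families()[[aa]]]
      n <- sum(x)
      if (n < 2) return(NA_real_)
      p <- x / n
      (n * sum(p^2) - 1) / (n - 1)
    }, numeric(1))
    Fv[!is.na(Fv) & Fv > 0]
  })
  names(fam_F) <- c("F2", "F3", "F4", "F6")
  Fbar <- vapply(fam_F, function(v) if (length(v)) mean(v) else NA_real_,
                 numeric(1))
  if (is.na(Fbar[["F3"]]) && !is.na(Fbar[["F2"]]) && !is.na(Fbar[["F4"]]))
    Fbar[["F3"]] <- (Fbar[["F2"]] + Fbar[["F4"]]) / 2
  if (anyNA(Fbar)) return(NA_real_)
  enc <- 2 + 9 / Fbar[["F2"]] + 1 / Fbar[["F3"]] +
    5 / Fbar[["F4"]] + 3 / Fbar[["F6"]]
  min(enc, 61)
}

#' Expected ENC under mutation pressure alone
#'
#' The null ENC-plot curve: ENCexp = 2 + s + 29 / (s^2 + (1 - s)^2),
#' where s is GC3s. Under pure mutation pressure a gene's observed ENC
#' falls on this curve; selection on codon choice pulls it below.
#'
#' @param gc3s GC content at synonymous third positions, in `[0, 1]`
#'   (vectorized).
#' @return Expected ENC value(s).
#' @examples
#' enc_expected(0.5)  # 60.5, the curve maximum region
#' enc_expected(0)    # 31
#' @export
enc_expected <- function(gc3s) {
  if (any(is.na(gc3s)) || any(gc3s < 0 | gc3s > 1))
    stop("gc3s must lie in [0, 1]")
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Per-gene codon usage statistics
#'
#' One row per gene: sense-codon number N, GC1/GC2/GC3/GC12/GCall/GC3s,
#' third-position base counts, observed ENC, expected ENC at the gene's
#' GC3s, and the ENC ratio (ENCexp - ENCobs)/ENCexp.
#'
#' @param x CDS set data.frame (already filtered; see [filter_cds()]).
#' @return data.frame with one row per gene.
#' @export
gene_stats <- function(x) {
  m <- codon_count_matrix(x)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    cmp <- composition(m[i, ])
    enc_o <- enc_observed(m[i, ])
    enc_e <- if (is.na(cmp$gc3s)) NA_real_ else enc_expected(cmp$gc3s)
    data.frame(
      gene_id = rownames(m)[[i]],
      species_id = x$species_id[[i]],
      n_codons = cmp$n_codons,
      gc1 = cmp$gc1, gc2 = cmp$gc2, gc3 = cmp$gc3,
      gc12 = cmp$gc12, gc_all = cmp$gc_all, gc3s = cmp$gc3s,
      a3 = cmp$a3, t3 = cmp$t3, g3 = cmp$g3, c3 = cmp$c3,
      enc_obs = enc_o, enc_exp = enc_e,
      enc_ratio = if (is.na(enc_o) || is.na(enc_e)) NA_real_
                  else (enc_e - enc_o) / enc_e,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species-level codon usage summary
#'
#' Pools the codon counts of all genes of each species and recomputes the
#' composition on the pooled counts. Two ENC variants are reported:
#' `enc_pooled`, Wright's statistic on the pooled counts, and `enc_mean`,
#' the unweighted mean of per-gene ENC values.
#'
#' @param x CDS set data.frame (filtered).
#' @return data.frame with one row per species: `species_id`, `n_genes`,
#'   `n_codons`, `gc1`, `gc2`, `gc3`, `gc_all`, `gc3s`, `enc_pooled`,
#'   `enc_mean`.
#' @export
species_summary <- function(x) {
  rows <- lapply(split(x, x$species_id), function(sp) {
    m <- codon_count_matrix(sp)
    pooled <- colSums(m)
    cmp <- composition(pooled)
    per_gene_enc <- apply(m, 1L, enc_observed)
    data.frame(
      species_id = sp$species_id[[1L]],
      n_genes = nrow(sp),
      n_codons = cmp$n_codons,
      gc1 = cmp$gc1, gc2 = cmp$gc2, gc3 = cmp$gc3,
      gc_all = cmp$gc_all, gc3s = cmp$gc3s,
      enc_pooled = enc_observed(pooled),
      enc_mean = mean(per_gene_enc, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$species_id), , drop = FALSE]
}

#' RSCU profiles per species
#'
#' @param x CDS set data.frame.
#' @return Numeric matrix, 61 sense codons in rows (RNA spelling),
#'   species in columns, of RSCU computed on pooled per-species counts.
#' @export
species_rscu <- function(x) {
  sp <- split(x, x$species_id)
  m <- vapply(sp, function(s) {
    as.numeric(rscu(colSums(codon_count_matrix(s))))
  }, numeric(length(sense_codons())))
  rownames(m) <- codon_to_rna(sense_codons())
  m <- as.matrix(m)
  colnames(m) <- names(sp)
  m
}
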