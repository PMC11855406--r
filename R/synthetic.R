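# Seeded synthetic CDS generator. Genes are built codon-by-codon from
# explicit per-family synonymous-codon probabilities (or, in the
# mutation regime, from a nucleotide-level GC weight), so the generating
# distribution of every sense codon is known exactly and downstream
# estimates can be checked against ground truth. Sampling is restricted
# to sense codons, which is the stationary form of resampling any
# stop-prone draw: internal stops never occur and sense-codon
# probabilities stay exact.

#' Specify a synthetic CDS set
#'
#' @param n_genes Number of genes to generate.
#' @param length_range Two nucleotide lengths (multiples of 3, > 300);
#'   gene lengths are drawn uniformly from the multiples of 3 in this
#'   range (inclusive).
#' @param regime One of `"uniform"`, `"mutation"`, `"selection"`,
#'   `"planted-optimal"`; see Details.
#' @param aa_freqs Named amino-acid frequency vector (one-letter codes,
#'   sums to 1). Default: uniform over the 20 amino acids. Ignored by
#'   the mutation regime, whose amino-acid usage emerges from the
#'   nucleotide weights.
#' @param family_probs Named list: amino acid -> probability vector over
#'   its synonymous codons (sums to 1). Default: uniform within each
#'   family. Used by the uniform regime; the other regimes derive their
#'   own per-gene probabilities.
#' @param gc_range For `regime = "mutation"`: range of the per-gene
#'   mutational GC pressure applied at all three codon positions,
#'   spread evenly across genes.
#' @param gc3_range For `regime = "selection"`: range of the per-gene
#'   third-position GC target, spread evenly across genes while the
#'   amino-acid (hence GC12) composition stays fixed.
#' @param planted_codons For `regime = "planted-optimal"`: sense codons
#'   (DNA spelling, degenerate families) enriched in the planted
#'   low-ENC gene subset.
#' @param planted_fraction Fraction of genes carrying the planted bias
#'   (default 0.10, matching the pool fraction used downstream).
#' @param planted_bias Within-family probability of a planted codon in
#'   planted genes (default 0.85).
#' @param background_bias Within-family probability of the reference
#'   codon in non-planted families of the planted regime (default
#'   0.999; near-deterministic background so that pool-level delta-RSCU
#'   noise stays well below the 0.08 decision threshold).
#' @param stop_probs Probabilities of the terminal stop TAA/TAG/TGA
#'   (default 0.5/0.25/0.25, the TAA preference typical of plastid
#'   genes).
#' @param seed Integer seed; the same spec always generates
#'   byte-identical output.
#'
#' @details
#' Regimes:
#' * `uniform` — every family uses `family_probs` (default uniform);
#'   RSCU tends to 1 and ENC to 61 as counts grow.
#' * `mutation` — each gene g has one GC pressure theta_g; codons are
#'   drawn from the 61 sense codons with probability proportional to
#'   the product of per-base weights (G and C weight theta/2, A and T
#'   weight (1-theta)/2). All three positions track theta, so the
#'   neutrality regression of GC12 on GC3 has slope near 1.
#' * `selection` — amino-acid composition is fixed; within each family,
#'   codons are grouped by their first two bases and only the
#'   third-base choice follows the gene's GC3 target s_g (G/C weight s,
#'   A/T weight 1-s, block mass fixed). GC12 is independent of s by
#'   construction, so the neutrality slope is near 0.
#' * `planted-optimal` — a designated `planted_fraction` of genes is
#'   strongly biased (`planted_bias`) toward `planted_codons`, giving
#'   them the lowest ENC; all other families use a near-deterministic
#'   reference codon identically in every gene. The delta-RSCU
#'   procedure applied downstream should recover exactly the planted
#'   set.
#'
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_genes = 50L,
                           length_range = c(900L, 1800L),
                           regime = c("uniform", "mutation", "selection",
                                      "planted-optimal"),
                           aa_freqs = NULL,
                           family_probs = NULL,
                           gc_range = c(0.25, 0.55),
                           gc3_range = c(0.15, 0.55),
                           planted_codons = c("GCT", "AAA", "TTA", "GTT"),
                           planted_fraction = 0.10,
                           planted_bias = 0.85,
                           background_bias = 0.999,
                           stop_probs = c(TAA = 0.5, TAG = 0.25, TGA = 0.25),
                           seed = 1L) {
  regime <- match.arg(regime)
  n_genes <- as.integer(n_genes)
  if (n_genes < 1L) stop("n_genes must be >= 1")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || any(length_range %% 3L != 0L) ||
      any(length_range <= 300L) || length_range[[1L]] > length_range[[2L]])
    stop("length_range must be two multiples of 3, each > 300, lo <= hi")
  if (is.null(aa_freqs)) {
    aas <- names(aa_families())
    aa_freqs <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  }
  if (abs(sum(aa_freqs) - 1) > 1e-8) stop("aa_freqs must sum to 1")
  if (!all(names(aa_freqs) %in% names(aa_families())))
    stop("aa_freqs has unknown amino acids")
  if (is.null(family_probs)) {
    family_probs <- lapply(aa_families(), function(fam)
      stats::setNames(rep(1 / length(fam), length(fam)), fam))
  }
  for (aa in names(family_probs)) {
    p <- family_probs[[aa]]
    if (!setequal(names(p), aa_families()[[aa]]) || abs(sum(p) - 1) > 1e-8)
      stop("family_probs[['", aa, "']] must be a probability vector over ",
           "that family's codons")
  }
  if (regime == "planted-optimal") {
    planted_codons <- toupper(codon_to_dna(planted_codons))
    if (!all(planted_codons %in% degenerate_codons()))
      stop("planted_codons must be degenerate sense codons")
    aa_of <- codon_aa(planted_codons)
    if (anyDuplicated(aa_of))
      stop("planted_codons must come from distinct families")
  }
  if (abs(sum(stop_probs) - 1) > 1e-8 ||
      !setequal(names(stop_probs), stop_codons()))
    stop("stop_probs must be a probability vector over TAA/TAG/TGA")
  out <- list(
    n_genes = n_genes, length_range = length_range, regime = regime,
    aa_freqs = aa_freqs, family_probs = family_probs,
    gc_range = gc_range, gc3_range = gc3_range,
    planted_codons = planted_codons,
    planted_fraction = planted_fraction,
    planted_bias = planted_bias, background_bias = background_bias,
    stop_probs = stop_probs, seed = as.integer(seed)
  )
  class(out) <- "synthetic_spec"
  out
}

#' Preset synthetic regimes
#'
#' Ready-made specs for the three validation regimes, at sizes where the
#' targeted signal clears sampling noise (see the methods vignette):
#' `"mutation"` and `"selection"` use 200 genes of 900-1800 nt;
#' `"planted-optimal"` uses 50 genes of 2400-3600 nt so that 10% pools
#' hold enough codons to decide delta-RSCU at 0.08.
#'
#' @param name `"mutation"`, `"selection"` or `"planted-optimal"`.
#' @param n_genes Optional override of the preset gene count.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [synthetic_spec()].
#' @return A `"synthetic_spec"` object.
#' @export
regime_preset <- function(name = c("mutation", "selection", "planted-optimal"),
                          n_genes = NULL, seed = 1L, ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    "mutation" = list(n_genes = 200L, length_range = c(900L, 1800L)),
    "selection" = list(n_genes = 200L, length_range = c(900L, 1800L)),
    "planted-optimal" = list(n_genes = 50L, length_range = c(2400L, 3600L))
  )
  if (!is.null(n_genes)) defaults$n_genes <- as.integer(n_genes)
  do.call(synthetic_spec,
          c(defaults, list(regime = name, seed = seed), list(...)))
}

#' Generate a synthetic CDS set
#'
#' @param spec A `"synthetic_spec"` object.
#' @return A CDS set data.frame (gene_id, species_id, sequence) whose
#'   rows all satisfy the CDS filters; the `"ground_truth"` attribute
#'   records the regime, seed, per-gene parameters and, for the planted
#'   regime, the planted codons and gene ids.
#' @export
generate_cds <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_genes
  len_choices <- seq.int(spec$length_range[[1L]], spec$length_range[[2L]], by = 3L)
  lens <- if (length(len_choices) == 1L) rep(len_choices, n)
          else sample(len_choices, n, replace = TRUE)
  gene_ids <- sprintf("gene_%03d", seq_len(n))

  param <- rep(NA_real_, n)
  planted_genes <- character(0)
  if (spec$regime == "mutation") {
    param <- if (n == 1L) mean(spec$gc_range)
             else seq(spec$gc_range[[1L]], spec$gc_range[[2L]], length.out = n)
  } else if (spec$regime == "selection") {
    param <- if (n == 1L) mean(spec$gc3_range)
             else seq(spec$gc3_range[[1L]], spec$gc3_range[[2L]], length.out = n)
  } else if (spec$regime == "planted-optimal") {
    n_planted <- max(1L, .round_half_up(spec$planted_fraction * n))
    planted_genes <- gene_ids[seq_len(n_planted)]
  }

  seqs <- vapply(seq_len(n), function(g) {
    internal <- lens[[g]] %/% 3L - 2L
    body <- switch(spec$regime,
      "uniform" = .sample_by_family(internal, spec$aa_freqs, spec$family_probs),
      "mutation" = .sample_by_gc(internal, param[[g]]),
      "selection" = .sample_by_family(internal, spec$aa_freqs,
                                      .selection_probs(param[[g]])),
      "planted-optimal" = .sample_by_family(internal, spec$aa_freqs,
        .planted_probs(spec, planted = gene_ids[[g]] %in% planted_genes))
    )
    stop <- sample(names(spec$stop_probs), 1L, prob = spec$stop_probs)
    paste(c("ATG", body, stop), collapse = "")
  }, character(1))

  out <- cds_set(gene_ids, seqs, paste0("synthetic_", spec$regime))
  attr(out, "ground_truth") <- list(
    regime = spec$regime, seed = spec$seed,
    gene_param = stats::setNames(param, gene_ids),
    planted_codons = if (spec$regime == "planted-optimal")
      codon_to_rna(spec$planted_codons) else character(0),
    planted_genes = planted_genes,
    family_probs = spec$family_probs
  )
  out
}

#' @rdname generate_cds
#' @param x A generated CDS set.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

# draw `n` sense codons: amino acid from aa_freqs, codon from its family
.sample_by_family <- function(n, aa_freqs, family_probs) {
  if (n <= 0L) return(character(0))
  aas <- sample(names(aa_freqs), n, replace = TRUE, prob = aa_freqs)
  out <- character(n)
  for (aa in unique(aas)) {
    idx <- which(aas == aa)
    p <- family_probs[[aa]]
    fam <- names(p)
    out[idx] <- if (length(fam) == 1L) fam
                else sample(fam, length(idx), replace = TRUE, prob = p)
  }
  out
}

# draw `n` sense codons from the product-of-base-weights distribution
.sample_by_gc <- function(n, theta) {
  if (n <= 0L) return(character(0))
  w_base <- c(A = (1 - theta) / 2, C = theta / 2,
              G = theta / 2, T = (1 - theta) / 2)
  sc <- sense_codons()
  w <- w_base[substr(sc, 1, 1)] * w_base[substr(sc, 2, 2)] *
       w_base[substr(sc, 3, 3)]
  sample(sc, n, replace = TRUE, prob = w / sum(w))
}

# family probs with third-base GC preference s, block (first two bases)
# mass fixed so positions 1-2 are independent of s
.selection_probs <- function(s) {
  lapply(aa_families(), function(fam) {
    block <- substr(fam, 1L, 2L)
    w3 <- ifelse(substr(fam, 3L, 3L) %in% c("G", "C"), s, 1 - s)
    p <- numeric(length(fam))
    for (b in unique(block)) {
      idx <- block == b
      p[idx] <- (sum(idx) / length(fam)) * w3[idx] / sum(w3[idx])
    }
    stats::setNames(p, fam)
  })
}

# planted regime: planted families biased toward the planted codon in
# planted genes and uniform elsewhere; all other families use a
# near-deterministic reference codon identically in every gene
.planted_probs <- function(spec, planted) {
  planted_aa <- unname(codon_aa(spec$planted_codons))
  lapply(stats::setNames(nm = names(aa_families())), function(aa) {
    fam <- aa_families()[[aa]]
    k <- length(fam)
    if (aa %in% planted_aa) {
      target <- spec$planted_codons[[match(aa, planted_aa)]]
      if (planted && k > 1L) {
        p <- rep((1 - spec$planted_bias) / (k - 1L), k)
        p[fam == target] <- spec$planted_bias
      } else {
        p <- rep(1 / k, k)
      }
    } else if (k == 1L) {
      p <- 1
    } else {
      p <- rep((1 - spec$background_bias) / (k - 1L), k)
      p[[1L]] <- spec$background_bias
    }
    stats::setNames(p, fam)
  })
}
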