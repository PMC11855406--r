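# Optimal-codon identification: rank genes by ENC, pool the most- and
# least-biased 10%, compare pool-level RSCU, and keep codons that are
# both preferred in the putative high-expression pool (RSCU > 1) and
# markedly more used there (delta-RSCU >= 0.08).

.round_half_up <- function(x) floor(x + 0.5)

#' Build high- and low-expression gene pools by ENC ranking
#'
#' Genes are sorted by observed ENC (ascending), ties broken by
#' `gene_id`. The lowest-ENC genes — the most codon-biased, hence the
#' putatively highly expressed — form the high-expression pool; the
#' highest-ENC genes form the low-expression pool. Each pool holds
#' `round(fraction * n)` genes (half-up, minimum 1).
#'
#' @param stats Per-gene statistics from [gene_stats()] for one species.
#' @param fraction Pool fraction of the gene set (default 0.10).
#' @return List with character vectors `high` and `low` of gene ids.
#' @export
build_pools <- function(stats, fraction = 0.10) {
  n <- nrow(stats)
  if (n < 10L) stop("pool construction needs at least 10 genes; got ", n)
  size <- max(1L, .round_half_up(fraction * n))
  if (2L * size > n)
    stop("pools of ", size, " genes would overlap with only ", n, " genes")
  if (anyNA(stats$enc_obs))
    stop("pool construction needs a finite ENC for every gene")
  ord <- order(stats$enc_obs, stats$gene_id)
  if (length(unique(stats$enc_obs)) == 1L)
    warning("all genes have identical ENC; pools chosen by gene_id only")
  list(
    high = stats$gene_id[ord][seq_len(size)],
    low = stats$gene_id[ord][seq.int(n - size + 1L, n)]
  )
}

#' Identify optimal codons from high/low-pool RSCU profiles
#'
#' A codon is optimal when its RSCU in the high-expression pool exceeds
#' 1 and delta-RSCU = RSCU_high - RSCU_low is at least `delta_min`.
#' Single-codon families (Met, Trp) and stops are never optimal.
#'
#' @param rscu_high,rscu_low RSCU profiles (from [rscu()]) computed on
#'   the pooled codon counts of each pool.
#' @param delta_min Minimum delta-RSCU (default 0.08).
#' @param species_id Label carried into the result.
#' @param high_pool,low_pool Optional gene-id vectors recorded in the
#'   result.
#' @return Object of class `"optimal_codons"`: list with `species_id`,
#'   `table` (data.frame codon [RNA spelling], aa, rscu_high, rscu_low,
#'   delta_rscu, optimal), `optimal` (RNA-spelled codon set), pools and
#'   `delta_min`.
#' @export
identify_optimal <- function(rscu_high, rscu_low, delta_min = 0.08,
                             species_id = "unknown",
                             high_pool = character(0),
                             low_pool = character(0)) {
  sc <- sense_codons()
  hi <- rscu_high[sc]; lo <- rscu_low[sc]
  delta <- hi - lo
  eligible <- aa_degeneracy()[codon_aa(sc)] >= 2L
  optimal <- eligible & hi > 1 & delta >= delta_min
  tab <- data.frame(
    codon = codon_to_rna(sc),
    aa = unname(codon_aa(sc)),
    rscu_high = unname(hi),
    rscu_low = unname(lo),
    delta_rscu = unname(delta),
    optimal = unname(optimal),
    stringsAsFactors = FALSE
  )
  out <- list(
    species_id = species_id,
    table = tab,
    optimal = tab$codon[tab$optimal],
    high_pool = high_pool,
    low_pool = low_pool,
    delta_min = delta_min
  )
  class(out) <- "optimal_codons"
  out
}

#' Optimal codons of a species' gene set
#'
#' Convenience wrapper: computes per-gene statistics (unless supplied),
#' builds the ENC-ranked pools, computes pool RSCU on pooled codon
#' counts, and applies the optimality criteria.
#'
#' @param x CDS set data.frame (filtered) for one species.
#' @param stats Optional precomputed [gene_stats()] for `x`.
#' @param fraction Pool fraction (default 0.10).
#' @param delta_min Minimum delta-RSCU (default 0.08).
#' @return An `"optimal_codons"` object; see [identify_optimal()].
#' @export
optimal_codons <- function(x, stats = NULL, fraction = 0.10,
                           delta_min = 0.08) {
  if (is.null(stats)) stats <- gene_stats(x)
  pools <- build_pools(stats, fraction)
  m <- codon_count_matrix(x)
  hi_counts <- colSums(m[x$gene_id %in% pools$high, , drop = FALSE])
  lo_counts <- colSums(m[x$gene_id %in% pools$low, , drop = FALSE])
  identify_optimal(rscu(hi_counts), rscu(lo_counts), delta_min,
                   species_id = unique(x$species_id)[[1L]],
                   high_pool = pools$high, low_pool = pools$low)
}

#' @export
print.optimal_codons <- function(x, ...) {
  cat("Optimal codons, species:", x$species_id, "\n")
  cat(sprintf("  pools: %d high-expression / %d low-expression genes\n",
              length(x$high_pool), length(x$low_pool)))
  cat(sprintf("  criteria: RSCU_high > 1 and delta-RSCU >= %.2f\n",
              x$delta_min))
  cat(sprintf("  %d optimal codons: %s\n", length(x$optimal),
              paste(x$optimal, collapse = " ")))
  invisible(x)
}

#' Optimal codons shared across species
#'
#' @param results List of `"optimal_codons"` objects (>= 2).
#' @return List with `shared` (intersection of the per-species optimal
#'   sets, RNA spelling), `n_shared`, and `n_au_ending` (members whose
#'   third base is A or U).
#' @export
shared_optimal <- function(results) {
  if (length(results) < 2L) stop("need results from at least 2 species")
  sets <- lapply(results, function(r) r$optimal)
  shared <- Reduce(intersect, sets)
  list(
    shared = shared,
    n_shared = length(shared),
    n_au_ending = sum(substr(shared, 3L, 3L) %in% c("A", "U"))
  )
}
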