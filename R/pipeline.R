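# End-to-end orchestration: extract -> filter -> per-gene stats ->
# diagnostics -> optimal codons across one or many genomes, with every
# table written as TSV at fixed precision so re-runs are byte-identical.

.fmt <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  nrow(d)
}

# fixed-precision copies for output: 3 decimals for fractions, 2 for
# ENC, 4 for slopes/correlations/R^2
.format_gene_stats <- function(stats) {
  d <- stats
  for (v in c("gc1", "gc2", "gc3", "gc12", "gc_all", "gc3s"))
    d[[v]] <- .fmt(d[[v]], 3L)
  for (v in c("enc_obs", "enc_exp")) d[[v]] <- .fmt(d[[v]], 2L)
  d$enc_ratio <- .fmt(d$enc_ratio, 4L)
  d
}

#' Run the full codon-usage-bias pipeline
#'
#' For each input genome: read (GenBank or FASTA), filter the CDS set,
#' compute per-gene statistics, the species summary, the neutrality
#' fit, ENC-ratio classification, PR2 coordinates and the correlation
#' table; species with at least 10 genes also get optimal codons, and
#' the per-species optimal sets are intersected when two or more
#' species are analyzed. All tables are written to `out_dir` as TSV,
#' sorted by (species, gene), and listed in `manifest.tsv` with row
#' counts.
#'
#' @param inputs Named character vector of input file paths; names are
#'   the species labels (file names are used if unnamed).
#' @param out_dir Output directory, created if needed. `NULL` skips all
#'   file output.
#' @param min_len Minimum CDS length in nt passed to [filter_cds()].
#' @param fraction,delta_min Optimal-codon parameters; see
#'   [optimal_codons()].
#' @param pooled If TRUE, optimal codons are additionally computed on
#'   the concatenated multi-species gene set.
#' @return Object of class `"cub_pipeline"`: list with `summary`,
#'   `gene_stats`, `rscu`, `neutrality`, `enc_ratio`, `pr2`,
#'   `correlations`, `optimal`, `shared`, `exclusions`, `manifest`.
#' @export
run_codon_pipeline <- function(inputs, out_dir = NULL, min_len = 301L,
                               fraction = 0.10, delta_min = 0.08,
                               pooled = FALSE) {
  if (length(inputs) == 0L) stop("no input files given")
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    names(inputs) <- sub("\\.[^.]*$", "", basename(inputs))

  sets <- lapply(names(inputs), function(sp) {
    raw <- read_genome(inputs[[sp]], species_id = sp)
    filter_cds(raw, min_len = min_len)
  })
  names(sets) <- names(inputs)

  all_cds <- do.call(rbind, sets)
  exclusions <- do.call(rbind, lapply(sets, cds_exclusions))
  rownames(exclusions) <- NULL

  stats_by_sp <- lapply(sets, gene_stats)
  all_stats <- do.call(rbind, stats_by_sp)
  all_stats <- all_stats[order(all_stats$species_id, all_stats$gene_id), ]
  rownames(all_stats) <- NULL

  summary_tab <- species_summary(all_cds)
  rscu_mat <- species_rscu(all_cds)

  neutrality <- lapply(stats_by_sp, neutrality_fit)
  neut_tab <- do.call(rbind, lapply(neutrality, function(f) data.frame(
    species_id = f$species_id, slope = f$slope, intercept = f$intercept,
    r_squared = f$r_squared, n_genes = f$n_genes,
    stringsAsFactors = FALSE)))
  rownames(neut_tab) <- NULL

  enc_ratio <- lapply(stats_by_sp, enc_ratio_classify)
  pr2 <- lapply(stats_by_sp, pr2_points)
  correlations <- do.call(rbind, lapply(stats_by_sp, correlation_matrix))
  rownames(correlations) <- NULL

  optimal <- list()
  for (sp in names(sets)) {
    if (nrow(sets[[sp]]) < 10L) {
      warning("species '", sp, "' has fewer than 10 genes; ",
              "optimal-codon stage skipped")
    } else {
      optimal[[sp]] <- optimal_codons(sets[[sp]], stats = stats_by_sp[[sp]],
                                      fraction = fraction,
                                      delta_min = delta_min)
    }
  }
  shared <- if (length(optimal) >= 2L) shared_optimal(optimal) else NULL
  pooled_optimal <- if (pooled && nrow(all_cds) >= 10L) {
    pooled_set <- all_cds
    pooled_set$gene_id <- paste(pooled_set$species_id, pooled_set$gene_id,
                                sep = ":")
    pooled_set$species_id <- "pooled"
    optimal_codons(pooled_set, fraction = fraction, delta_min = delta_min)
  } else NULL

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(d, file) {
      n <- .write_tsv(d, file.path(out_dir, file))
      data.frame(file = file, rows = n, stringsAsFactors = FALSE)
    }
    sm <- summary_tab
    for (v in c("gc1", "gc2", "gc3", "gc_all", "gc3s"))
      sm[[v]] <- .fmt(sm[[v]], 3L)
    for (v in c("enc_pooled", "enc_mean")) sm[[v]] <- .fmt(sm[[v]], 2L)
    nt <- neut_tab
    for (v in c("slope", "intercept", "r_squared"))
      nt[[v]] <- .fmt(nt[[v]], 4L)
    ct <- correlations
    ct$r <- .fmt(ct$r, 4L); ct$p <- .fmt(ct$p, 4L)
    rscu_out <- data.frame(codon = rownames(rscu_mat),
                           round(rscu_mat, 3L),
                           check.names = FALSE, stringsAsFactors = FALSE)
    er_tab <- do.call(rbind, lapply(names(enc_ratio), function(sp) {
      d <- enc_ratio[[sp]]$records
      d$species_id <- sp
      d$enc_ratio <- .fmt(d$enc_ratio, 4L)
      d[order(d$gene_id), c("species_id", "gene_id", "enc_ratio",
                            "bin", "mutation_consistent")]
    }))
    pr2_tab <- do.call(rbind, lapply(names(pr2), function(sp) {
      d <- pr2[[sp]]
      d$species_id <- sp
      d$x <- .fmt(d$x, 4L); d$y <- .fmt(d$y, 4L)
      d[order(d$gene_id), c("species_id", "gene_id", "x", "y",
                            "quadrant", "defined")]
    }))
    opt_tab <- do.call(rbind, lapply(optimal, function(o) {
      d <- o$table
      d$species_id <- o$species_id
      for (v in c("rscu_high", "rscu_low", "delta_rscu"))
        d[[v]] <- .fmt(d[[v]], 3L)
      d[, c("species_id", "codon", "aa", "rscu_high", "rscu_low",
            "delta_rscu", "optimal")]
    }))
    manifest <- rbind(
      wr(.format_gene_stats(all_stats), "gene_stats.tsv"),
      wr(sm, "species_summary.tsv"),
      wr(rscu_out, "rscu.tsv"),
      wr(nt, "neutrality.tsv"),
      wr(er_tab, "enc_ratio.tsv"),
      wr(pr2_tab, "pr2.tsv"),
      wr(ct, "correlations.tsv"),
      wr(exclusions, "exclusions.tsv")
    )
    if (!is.null(opt_tab))
      manifest <- rbind(manifest, wr(opt_tab, "optimal_codons.tsv"))
    if (!is.null(shared))
      manifest <- rbind(manifest, wr(
        data.frame(codon = shared$shared,
                   au_ending = substr(shared$shared, 3, 3) %in% c("A", "U")),
        "shared_optimal.tsv"))
    .write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  }

  out <- list(
    summary = summary_tab, gene_stats = all_stats, rscu = rscu_mat,
    neutrality = neutrality, enc_ratio = enc_ratio, pr2 = pr2,
    correlations = correlations, optimal = optimal, shared = shared,
    pooled_optimal = pooled_optimal, exclusions = exclusions,
    manifest = manifest
  )
  class(out) <- "cub_pipeline"
  out
}

#' @export
print.cub_pipeline <- function(x, ...) {
  cat("Codon usage bias pipeline:",
      nrow(x$summary), "species,",
      nrow(x$gene_stats), "genes total\n")
  cat("\nSpecies summary (pooled counts):\n")
  sm <- x$summary
  for (v in c("gc1", "gc2", "gc3", "gc_all", "gc3s")) sm[[v]] <- round(sm[[v]], 3)
  for (v in c("enc_pooled", "enc_mean")) sm[[v]] <- round(sm[[v]], 2)
  print(sm, row.names = FALSE)
  if (length(x$neutrality)) {
    cat("\nNeutrality slopes:\n")
    for (f in x$neutrality)
      cat(sprintf("  %s: slope %.4f (R^2 %.4f, n = %d)\n",
                  f$species_id, f$slope, f$r_squared, f$n_genes))
  }
  if (!is.null(x$shared))
    cat("\nShared optimal codons (", x$shared$n_shared, "): ",
        paste(x$shared$shared, collapse = " "), "\n", sep = "")
  invisible(x)
}
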