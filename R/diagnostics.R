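# Diagnostics separating mutation pressure from natural selection:
# neutrality plot (GC12 ~ GC3), ENC-plot ratio classification, PR2 bias
# coordinates, and the Pearson correlation matrix of codon parameters.

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 (mean GC of codon positions 1-2) on
#' GC3 across the genes of one species. A slope near 1 indicates that a
#' common mutational pressure drives all three positions; a slope near 0
#' indicates selection decoupling positions 1-2 from the (more neutral)
#' third position. The slope is conventionally read as the mutational
#' share of codon-usage bias and 1 - slope as the selective share.
#'
#' @param stats Per-gene statistics from [gene_stats()] (needs columns
#'   `gc12`, `gc3`), for a single species.
#' @return Object of class `"neutrality_fit"`: list with `species_id`,
#'   `slope`, `intercept`, `r_squared`, `n_genes`, `degenerate` (TRUE
#'   when GC3 has zero variance and the slope is undefined) and the
#'   underlying `lm` fit.
#' @export
neutrality_fit <- function(stats) {
  ok <- stats::complete.cases(stats[, c("gc12", "gc3")])
  d <- stats[ok, , drop = FALSE]
  if (nrow(d) < 3L) stop("neutrality fit needs at least 3 genes")
  species <- if ("species_id" %in% names(d)) unique(d$species_id) else "unknown"
  if (length(species) > 1L)
    stop("neutrality_fit expects a single species; got ",
         paste(species, collapse = ", "))
  if (stats::var(d$gc3) == 0) {
    out <- list(species_id = species, slope = NA_real_,
                intercept = mean(d$gc12), r_squared = NA_real_,
                n_genes = nrow(d), degenerate = TRUE, fit = NULL)
    class(out) <- "neutrality_fit"
    return(out)
  }
  fit <- stats::lm(gc12 ~ gc3, data = d)
  ss_tot <- sum((d$gc12 - mean(d$gc12))^2)
  out <- list(
    species_id = species,
    slope = unname(stats::coef(fit)[["gc3"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot,
    n_genes = nrow(d),
    degenerate = FALSE,
    fit = fit
  )
  class(out) <- "neutrality_fit"
  out
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat("Neutrality plot fit (GC12 ~ GC3), species:", x$species_id, "\n")
  if (x$degenerate) {
    cat("  GC3 has zero variance; slope undefined\n")
  } else {
    cat(sprintf("  slope = %.4f  intercept = %.4f  R^2 = %.4f  n = %d\n",
                x$slope, x$intercept, x$r_squared, x$n_genes))
    cat(sprintf("  mutation share ~ %.4f, selection share ~ %.4f\n",
                x$slope, 1 - x$slope))
  }
  invisible(x)
}

#' @export
coef.neutrality_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
plot.neutrality_fit <- function(x, ...) {
  if (is.null(x$fit)) stop("degenerate fit: nothing to plot")
  d <- x$fit$model
  plot(d$gc3, d$gc12, xlab = "GC3", ylab = "GC12",
       main = paste("Neutrality plot:", x$species_id),
       xlim = c(0, 1), ylim = c(0, 1), pch = 19, col = "grey30", ...)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  graphics::abline(x$intercept, x$slope, col = "firebrick")
  invisible(x)
}

#' ENC-ratio classification of genes
#'
#' The ENC ratio (ENCexp - ENCobs)/ENCexp measures how far a gene's
#' observed ENC falls below the mutation-only expectation at its GC3s.
#' Genes with |ratio| <= `band` are consistent with mutation pressure
#' alone; larger ratios indicate selection. Genes are also binned into a
#' histogram of width `band` with edges at multiples of `band`
#' (left-closed intervals).
#'
#' @param stats Per-gene statistics from [gene_stats()].
#' @param band Half-width of the mutation-consistent interval (default
#'   0.05) and histogram bin width.
#' @return List with `records` (gene_id, enc_ratio, bin label,
#'   mutation-consistent flag), `n_within`, `pct_within`, and a `bins`
#'   table of counts per interval.
#' @export
enc_ratio_classify <- function(stats, band = 0.05) {
  ok <- !is.na(stats$enc_ratio)
  d <- stats[ok, , drop = FALSE]
  r <- d$enc_ratio
  lo <- floor(r / band) * band
  bin <- sprintf("[%.2f, %.2f)", lo, lo + band)
  within <- abs(r) <= band
  records <- data.frame(
    gene_id = d$gene_id,
    enc_ratio = r,
    bin = bin,
    mutation_consistent = within,
    stringsAsFactors = FALSE
  )
  bins <- as.data.frame(table(bin = bin), stringsAsFactors = FALSE)
  names(bins)[2L] <- "n_genes"
  list(
    records = records,
    n_genes = nrow(records),
    n_within = sum(within),
    pct_within = 100 * mean(within),
    bins = bins[order(bins$bin), , drop = FALSE]
  )
}

#' Parity rule 2 (PR2) bias coordinates
#'
#' Per gene, x = G3/(G3 + C3) and y = A3/(A3 + T3) over third positions
#' of sense codons. Under mutational equilibrium both ratios are 0.5;
#' the vector from (0.5, 0.5) to a gene's point shows the direction and
#' magnitude of its departure.
#'
#' @param stats Per-gene statistics from [gene_stats()] (needs `a3`,
#'   `t3`, `g3`, `c3`).
#' @return data.frame with `gene_id`, `x`, `y`, `quadrant`
#'   (`"lower-left"` etc., `"center"` on the axes) and `defined`
#'   (FALSE when a denominator is zero; coordinates NA).
#' @export
pr2_points <- function(stats) {
  gc_den <- stats$g3 + stats$c3
  at_den <- stats$a3 + stats$t3
  defined <- gc_den > 0 & at_den > 0
  x <- ifelse(gc_den > 0, stats$g3 / gc_den, NA_real_)
  y <- ifelse(at_den > 0, stats$a3 / at_den, NA_real_)
  quadrant <- rep(NA_character_, length(x))
  quadrant[defined] <- paste0(
    ifelse(y[defined] > 0.5, "upper", ifelse(y[defined] < 0.5, "lower", "mid")),
    "-",
    ifelse(x[defined] > 0.5, "right", ifelse(x[defined] < 0.5, "left", "mid"))
  )
  data.frame(
    gene_id = stats$gene_id,
    x = x, y = y,
    quadrant = quadrant,
    defined = defined,
    stringsAsFactors = FALSE
  )
}

#' Pearson correlations among codon usage parameters
#'
#' All pairwise Pearson correlations among GC1, GC2, GC3, GCall, ENC and
#' the codon number across the genes of one species, with two-sided
#' p-values from the t distribution on n - 2 degrees of freedom and the
#' conventional star annotation (`**` p < 0.01, `*` p < 0.05).
#'
#' @param stats Per-gene statistics from [gene_stats()].
#' @param vars Columns to correlate; defaults to the six standard
#'   parameters.
#' @return Long-format data.frame: `species_id`, `var1`, `var2`, `r`,
#'   `p`, `n`, `stars`. Pairs involving a zero-variance variable get
#'   `r = NA`.
#' @export
correlation_matrix <- function(stats,
                               vars = c("gc1", "gc2", "gc3", "gc_all",
                                        "enc_obs", "n_codons")) {
  stopifnot(all(vars %in% names(stats)))
  species <- if ("species_id" %in% names(stats))
    paste(unique(stats$species_id), collapse = "+") else "unknown"
  pairs <- utils::combn(vars, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    v1 <- pairs[1L, j]; v2 <- pairs[2L, j]
    x <- stats[[v1]]; y <- stats[[v2]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L || stats::var(x) == 0 || stats::var(y) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(x, y, method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(species_id = species, var1 = v1, var2 = v2,
               r = r, p = p, n = n,
               stars = if (is.na(p)) "" else if (p < 0.01) "**"
                       else if (p < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
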