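# Independent brute-force oracles for the codon statistics. These are
# deliberately written from the defining formulas over the raw genetic
# code table (Biostrings::GENETIC_CODE), not via the package's family
# structures, so that agreement is a genuine dual-route check.

.GC_TABLE <- Biostrings::GENETIC_CODE

oracle_synonyms <- function(codon) {
  aa <- .GC_TABLE[[codon]]
  names(.GC_TABLE)[.GC_TABLE == aa & .GC_TABLE != "*"]
}

oracle_rscu <- function(counts) {
  sense <- names(.GC_TABLE)[.GC_TABLE != "*"]
  out <- stats::setNames(numeric(length(sense)), sense)
  for (cd in sense) {
    syn <- oracle_synonyms(cd)
    tot <- sum(counts[syn])
    out[cd] <- if (tot == 0) 0 else counts[[cd]] * length(syn) / tot
  }
  out
}

oracle_enc <- function(counts) {
  aas <- setdiff(unique(.GC_TABLE), "*")
  Fvals <- list()
  for (aa in aas) {
    syn <- names(.GC_TABLE)[.GC_TABLE == aa]
    x <- counts[syn]
    n <- sum(x)
    if (n >= 2) {
      Fa <- (n * sum((x / n)^2) - 1) / (n - 1)
      if (Fa > 0)
        Fvals[[aa]] <- c(k = length(syn), F = Fa)
    }
  }
  if (length(Fvals) == 0) return(NA_real_)
  tab <- do.call(rbind, Fvals)
  mean_k <- function(k) {
    v <- tab[tab[, "k"] == k, "F"]
    if (length(v)) mean(v) else NA_real_
  }
  F2 <- mean_k(2); F3 <- mean_k(3); F4 <- mean_k(4); F6 <- mean_k(6)
  if (is.na(F3) && !is.na(F2) && !is.na(F4)) F3 <- (F2 + F4) / 2
  if (anyNA(c(F2, F3, F4, F6))) return(NA_real_)
  min(61, 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6)
}

# composition by literally expanding counts into a base string
oracle_composition <- function(counts) {
  sense <- names(.GC_TABLE)[.GC_TABLE != "*"]
  codvec <- rep(names(counts), counts)
  codvec <- codvec[codvec %in% sense]
  bases <- strsplit(paste(codvec, collapse = ""), "")[[1]]
  pos <- rep(1:3, length.out = length(bases))
  gc <- bases %in% c("G", "C")
  gc1 <- mean(gc[pos == 1]); gc2 <- mean(gc[pos == 2]); gc3 <- mean(gc[pos == 3])
  syn_cod <- codvec[vapply(codvec, function(cd) length(oracle_synonyms(cd)) >= 2,
                           logical(1))]
  b3 <- substr(codvec, 3, 3)
  list(
    n_codons = length(codvec),
    gc1 = gc1, gc2 = gc2, gc3 = gc3,
    gc12 = (gc1 + gc2) / 2, gc_all = (gc1 + gc2 + gc3) / 3,
    gc3s = mean(substr(syn_cod, 3, 3) %in% c("G", "C")),
    a3 = sum(b3 == "A"), t3 = sum(b3 == "T"),
    g3 = sum(b3 == "G"), c3 = sum(b3 == "C")
  )
}

# closed-form two-parameter OLS
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  c(intercept = a, slope = b, r_squared = r2)
}

oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# random sparse-ish codon count vector over all 64 codons
random_counts <- function(max_total = 400) {
  repeat {
    n <- sample.int(max_total, 1)
    cods <- sample(names(.GC_TABLE), n, replace = TRUE,
                   prob = stats::runif(64, 0.2, 1.8))
    counts <- stats::setNames(integer(64), names(.GC_TABLE))
    tab <- table(cods)
    counts[names(tab)] <- as.integer(tab)
    if (sum(counts[.GC_TABLE[names(counts)] != "*"]) > 0) return(counts)
  }
}
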