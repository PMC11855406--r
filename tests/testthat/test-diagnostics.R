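make_stats <- function(gc3, gc12, species = "sp") {
  data.frame(gene_id = sprintf("g%02d", seq_along(gc3)),
             species_id = species, gc3 = gc3, gc12 = gc12,
             stringsAsFactors = FALSE)
}

test_that("neutrality regression recovers exact linear relations", {
  gc3 <- seq(0.2, 0.6, length.out = 10)
  f1 <- neutrality_fit(make_stats(gc3, gc3))
  expect_equal(f1$slope, 1, tolerance = 1e-12)
  expect_equal(f1$r_squared, 1, tolerance = 1e-12)

  f0 <- neutrality_fit(make_stats(gc3, rep(0.4, 10)))
  expect_equal(f0$slope, 0, tolerance = 1e-12)

  expect_error(neutrality_fit(make_stats(c(0.1, 0.2), c(0.1, 0.2))),
               "at least 3")
  fdeg <- neutrality_fit(make_stats(rep(0.3, 5), runif(5)))
  expect_true(fdeg$degenerate)
  expect_true(is.na(fdeg$slope))
})

test_that("neutrality fit agrees with the closed-form OLS solution to 1e-10", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      gc3 <- runif(30, 0.2, 0.5)
      gc12 <- 0.1 * gc3 + 0.35 + rnorm(30, 0, 0.02)
      f <- neutrality_fit(make_stats(gc3, gc12))
      o <- oracle_ols(gc3, gc12)
      expect_equal(f$slope, unname(o["slope"]), tolerance = 1e-10)
      expect_equal(f$intercept, unname(o["intercept"]), tolerance = 1e-10)
      expect_equal(f$r_squared, unname(o["r_squared"]), tolerance = 1e-10)
      expect_equal(unname(coef(f)), unname(o[c("intercept", "slope")]),
                   tolerance = 1e-10)
    }
  })
})

test_that("ENC ratio formula, band classification and binning", {
  st <- data.frame(gene_id = c("a", "b", "c"),
                   enc_ratio = c(0, (60.5 - 45) / 60.5, -0.049),
                   stringsAsFactors = FALSE)
  cls <- enc_ratio_classify(st)
  expect_equal(cls$records$enc_ratio[2], 0.2562, tolerance = 1e-4)
  expect_equal(cls$records$mutation_consistent, c(TRUE, FALSE, TRUE))
  expect_equal(cls$n_within, 2)
  expect_equal(cls$pct_within, 200 / 3, tolerance = 1e-9)
  expect_equal(cls$records$bin, c("[0.00, 0.05)", "[0.25, 0.30)",
                                  "[-0.05, 0.00)"))
  expect_equal(sum(cls$bins$n_genes), 3)
})

test_that("PR2 coordinates and their symmetry under strand exchange", {
  st <- data.frame(gene_id = c("g1", "g2", "g3"),
                   a3 = c(30, 10, 0), t3 = c(30, 30, 0),
                   g3 = c(20, 30, 5), c3 = c(20, 10, 5),
                   stringsAsFactors = FALSE)
  p <- pr2_points(st)
  expect_equal(p$x[1:2], c(0.5, 0.75))
  expect_equal(p$y[1:2], c(0.5, 0.25))
  expect_false(p$defined[3])
  expect_true(is.na(p$y[3]))
  expect_equal(p$quadrant[2], "lower-right")

  # swapping A<->T and G<->C maps (x, y) to (1-x, 1-y)
  withr::with_seed(32, {
    st2 <- data.frame(gene_id = "g", a3 = rpois(1, 50) + 1,
                      t3 = rpois(1, 50) + 1, g3 = rpois(1, 30) + 1,
                      c3 = rpois(1, 30) + 1)
    swapped <- within(st2, {tmp <- a3; a3 <- t3; t3 <- tmp
                            tmp <- g3; g3 <- c3; c3 <- tmp})
    expect_equal(pr2_points(swapped)$x, 1 - pr2_points(st2)$x)
    expect_equal(pr2_points(swapped)$y, 1 - pr2_points(st2)$y)
  })
})

test_that("Pearson correlations match closed forms, stars and affine invariance", {
  withr::with_seed(33, {
    st <- data.frame(gene_id = sprintf("g%02d", 1:25), species_id = "sp",
                     gc1 = runif(25), gc2 = runif(25), gc3 = runif(25),
                     gc_all = runif(25), enc_obs = runif(25, 30, 60),
                     n_codons = sample(100:500, 25))
    cm <- correlation_matrix(st)
    expect_equal(nrow(cm), choose(6, 2))
    for (i in seq_len(nrow(cm))) {
      r_oracle <- oracle_pearson(st[[cm$var1[i]]], st[[cm$var2[i]]])
      expect_equal(cm$r[i], r_oracle, tolerance = 1e-10)
      # two-sided p from the t distribution on n - 2 df
      tt <- r_oracle * sqrt((cm$n[i] - 2) / (1 - r_oracle^2))
      expect_equal(cm$p[i], 2 * pt(-abs(tt), cm$n[i] - 2), tolerance = 1e-10)
    }
    expect_true(all(cm$stars[cm$p < 0.01] == "**"))
    expect_true(all(cm$stars[cm$p >= 0.05] == ""))

    # degenerate pairs: self-correlation 1, sign flip -1, affine invariance
    x <- runif(20)
    st2 <- data.frame(gene_id = as.character(1:20), species_id = "sp",
                      a = x, b = -x, c = 3 * x + 2, d = runif(20))
    cm2 <- correlation_matrix(st2, vars = c("a", "b", "c", "d"))
    get <- function(v1, v2) cm2$r[cm2$var1 == v1 & cm2$var2 == v2]
    expect_equal(get("a", "b"), -1, tolerance = 1e-12)
    expect_equal(get("a", "c"), 1, tolerance = 1e-12)
    expect_equal(get("a", "d"), -get("b", "d"), tolerance = 1e-12)

    stz <- data.frame(gene_id = as.character(1:5), species_id = "sp",
                      a = rep(1, 5), b = runif(5))
    expect_true(is.na(correlation_matrix(stz, vars = c("a", "b"))$r))
  })
})
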