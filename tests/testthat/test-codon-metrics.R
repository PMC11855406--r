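test_that("codon counting matches direct enumeration", {
  cc <- count_codons("ATGAAATAA")
  expect_equal(unname(cc[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))
  expect_equal(sum(cc[sense_codons()]), 2)   # terminal stop carried apart
  cc2 <- count_codons("ATGTTATTGTAA")
  expect_equal(unname(cc2[c("ATG", "TTA", "TTG")]), c(1L, 1L, 1L))

  # random clean gene of 999 nt: sense total = length/3 - 1
  withr::with_seed(11, {
    g <- make_cds(331)   # ATG + 331 + stop = 333 codons = 999 nt
    expect_equal(nchar(g), 999)
    expect_equal(sum(count_codons(g)[sense_codons()]), 332)
  })
  expect_error(count_codons("ATGAA"), "not a multiple of 3")
  expect_error(count_codons("ATGNNNTAA"), "non-ACGT")
})

test_that("RSCU follows the x * k / total formula and flags unobserved families", {
  # equal counts in every family -> RSCU identically 1
  eq <- setNames(rep(7, 61), sense_codons())
  expect_true(all(abs(rscu(eq) - 1) < 1e-12))

  r <- rscu(c(TTA = 6, TTG = 3, CTT = 2, CTC = 1, CTA = 0, CTG = 0))
  expect_equal(unname(r[c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")]),
               c(3.0, 1.5, 1.0, 0.5, 0, 0))
  # only Leu observed: every other family zero and flagged
  expect_true(all(r[setdiff(sense_codons(), aa_families()[["L"]])] == 0))
  expect_true("K" %in% attr(r, "unobserved"))
  expect_false("L" %in% attr(r, "unobserved"))
})

test_that("RSCU family sums equal family size and survive count scaling", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      counts <- random_counts()
      r <- rscu(counts)
      for (aa in names(aa_families())) {
        fam <- aa_families()[[aa]]
        if (sum(counts[fam]) > 0)
          expect_equal(sum(r[fam]), length(fam), tolerance = 1e-12)
      }
      expect_equal(as.numeric(rscu(counts * 13L)), as.numeric(r),
                   tolerance = 1e-12)
    }
  })
})

test_that("composition matches hand counts and the base-string definition", {
  cmp <- composition(count_codons(c("ATG", "GAA")))
  expect_equal(cmp$gc1, 0.5)
  expect_equal(cmp$gc2, 0)
  expect_equal(cmp$gc3, 0.5)
  expect_equal(cmp$gc_all, 1 / 3)   # 2 G/C among the 6 bases
  expect_equal(cmp$gc12, 0.25)

  allgcg <- composition(count_codons(c("GCG", "GCG", "GCG")))
  expect_equal(c(allgcg$gc1, allgcg$gc2, allgcg$gc3), c(1, 1, 1))

  withr::with_seed(6, {
    counts <- random_counts()
    cmp <- composition(counts)
    orc <- oracle_composition(counts)
    for (f in names(orc))
      expect_equal(cmp[[f]], orc[[f]], tolerance = 1e-12, label = f)
    expect_equal(cmp$a3 + cmp$t3 + cmp$g3 + cmp$c3, cmp$n_codons)
  })
  expect_error(composition(setNames(integer(64), codons())), "no sense codons")
})

test_that("ENC attains its analytic extremes and the Wright F formula", {
  uniform <- setNames(rep(10, 61), sense_codons())
  expect_equal(enc_observed(uniform), 61)

  single <- setNames(numeric(61), sense_codons())
  for (fam in aa_families()) single[fam[1]] <- 40
  expect_equal(enc_observed(single), 20)

  # one 2-fold family with counts (3,1): F = (4*0.625 - 1)/3 = 0.5;
  # embed in an otherwise uniform gene and check against the oracle
  counts <- uniform
  counts[aa_families()[["K"]]] <- c(3, 1)
  expect_equal(enc_observed(counts), oracle_enc(counts), tolerance = 1e-12)
  n <- 4; p <- c(3, 1) / 4
  expect_equal((n * sum(p^2) - 1) / (n - 1), 0.5)
})

test_that("larger samples move ENC toward its large-n limit monotonically", {
  withr::with_seed(9, {
    base <- random_counts(300)
    encs <- vapply(c(1L, 4L, 16L, 64L), function(m) enc_observed(base * m),
                   numeric(1))
    encs <- encs[!is.na(encs)]
    # multiplying counts shrinks the finite-sample 1/n correction: the
    # sequence approaches the infinite-n value from one side
    expect_true(all(diff(encs) >= -1e-9) || all(diff(encs) <= 1e-9))
  })
})

test_that("expected ENC follows the mutation-only curve exactly", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  expect_equal(enc_expected(0.302), 52.44, tolerance = 1e-4)
  expect_error(enc_expected(1.2), "\\[0, 1\\]")
  expect_error(enc_expected(-0.1), "\\[0, 1\\]")
})

test_that("gene_stats assembles consistent per-gene rows", {
  withr::with_seed(21, {
    x <- cds_set(c("g1", "g2"), c(make_cds(150), make_cds(200)), "sp")
    st <- gene_stats(x)
    expect_equal(st$n_codons, c(151L, 201L))
    expect_equal(st$gc12, (st$gc1 + st$gc2) / 2)
    expect_equal(st$gc_all, (st$gc1 + st$gc2 + st$gc3) / 3)
    expect_equal(st$a3 + st$t3 + st$g3 + st$c3, st$n_codons)
    expect_equal(st$enc_ratio, (st$enc_exp - st$enc_obs) / st$enc_exp)
    expect_true(all(st$enc_obs >= 20 & st$enc_obs <= 61))
  })
})

test_that("species summary pools counts and reports both ENC variants", {
  withr::with_seed(22, {
    g <- make_cds(180)
    one <- cds_set("g1", g, "solo")
    st <- gene_stats(one)
    sm <- species_summary(one)
    expect_equal(sm$n_codons, st$n_codons)
    expect_equal(sm$gc_all, st$gc_all)
    expect_equal(sm$enc_pooled, st$enc_obs)
    expect_equal(sm$enc_mean, st$enc_obs)

    # two genes with identical counts: pooled composition equals either's
    two <- cds_set(c("a", "b"), c(g, g), "dup")
    sm2 <- species_summary(two)
    expect_equal(sm2$gc1, st$gc1)
    expect_equal(sm2$gc3s, st$gc3s)
    expect_equal(sm2$n_codons, 2L * st$n_codons)
  })
})
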