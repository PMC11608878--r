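POL <- site_filter_policy()

test_that("usable sites equal a brute-force column scan", {
  m <- rbind(strsplit("ACGTACGTAC", "")[[1]], strsplit("ACGNACGTAC", "")[[1]])
  expect_identical(usable_sites(m, POL), setdiff(1:10, 4L))
  set.seed(41)
  for (rep in 1:100) {
    m <- random_alignment(sample(2:8, 1), sample(10:60, 1))
    expect_identical(usable_sites(m, POL), oracle_usable(m))
  }
  # pairwise deletion keeps every site
  expect_identical(usable_sites(m, site_filter_policy("pairwise_deletion")),
                   seq_len(ncol(m)))
})

test_that("pi matches worked examples and pair enumeration", {
  expect_equal(nucleotide_diversity(rep("ACGTACGTAC", 4)), 0)
  expect_equal(nucleotide_diversity(c("AAAAAAAAAA", "AAAAAAAAAT")), 0.1)
  # 4 seqs, one site of 10 with alleles A,A,T,T: (4/6)/10
  seqs <- c("AAAAAAAAAA", "AAAAAAAAAA", "TAAAAAAAAA", "TAAAAAAAAA")
  expect_equal(nucleotide_diversity(seqs), (4 / 6) / 10)
})

test_that("Watterson constants and theta: a1 = 11/6 at n = 4", {
  m <- rbind(strsplit("AAAA", "")[[1]], strsplit("AAAT", "")[[1]],
             strsplit("AAAA", "")[[1]], strsplit("AAAA", "")[[1]])
  # S = 1, sites = 4: theta = 1 / (11/6 * 4)
  expect_equal(wattersons_theta(m), 1 / ((11 / 6) * 4))
  expect_equal(segregating_sites(m), 1L)
})

test_that("Tajima's D is negative for singleton-heavy data and NA when undefined", {
  expect_true(is.na(tajimas_d(rep("ACGT", 6))))          # S = 0
  expect_true(is.na(tajimas_d(c("ACGT", "ACGA", "ACGT")))) # n < 4
  # all variants singletons on a larger sample -> D < 0
  n <- 12; L <- 100
  m <- matrix("A", n, L)
  for (i in 1:n) m[i, i] <- "T"
  expect_lt(tajimas_d(m), 0)
  expect_warning(
    expect_true(is.na(tajimas_d(m, site_filter_policy("pairwise_deletion")))),
    "complete-deletion")
})

test_that("dxy and fst match worked examples", {
  a <- c("AAAAAAAAAA", "AAAAAAAAAA")
  b <- c("TAAAAAAAAA", "TAAAAAAAAA")
  expect_equal(dxy(a, b), 0.1)
  expect_equal(dxy(a, a), 0)
  expect_equal(fst(a, b), 1)          # reciprocally fixed: Hw = 0
  # two groups with identical allele composition: Fst ~ 0 (the Hudson
  # estimator carries a finite-sample bias of exactly -1/(n-1))
  g <- c(rep("AAAAAAAAAA", 25), rep("TAAAAAAAAA", 25))
  expect_lt(abs(fst(g, g)), 0.05)
  expect_equal(fst(g, g), -1 / 49, tolerance = 1e-12)
})

test_that("all six statistics equal their brute-force oracles on random data", {
  set.seed(42)
  for (rep in 1:150) {
    n <- sample(4:10, 1); L <- sample(20:80, 1)
    m <- random_alignment(n, L)
    expect_equal(nucleotide_diversity(m, POL), oracle_pi(m),
                 tolerance = 1e-12)
    expect_equal(segregating_sites(m, POL), oracle_S(m))
    expect_equal(wattersons_theta(m, POL), oracle_theta(m),
                 tolerance = 1e-12)
    td <- tajimas_d(m, POL); tdo <- oracle_tajima(m)
    if (is.na(tdo)) expect_true(is.na(td)) else {
      expect_equal(td, tdo, tolerance = 1e-12)
    }
    na <- sample(2:5, 1)
    ma <- random_alignment(na, L); mb <- random_alignment(sample(2:5, 1), L)
    expect_equal(dxy(ma, mb, POL), oracle_dxy(ma, mb), tolerance = 1e-12)
    fo <- oracle_fst(ma, mb)
    ff <- fst(ma, mb, POL)
    if (is.na(fo)) expect_true(is.na(ff)) else {
      expect_equal(ff, fo, tolerance = 1e-12)
    }
  }
})

test_that("statistics are invariant to sequence order", {
  set.seed(43)
  m <- random_alignment(8, 60)
  p <- sample(8)
  expect_equal(nucleotide_diversity(m), nucleotide_diversity(m[p, ]))
  expect_equal(tajimas_d(m), tajimas_d(m[p, ]))
  ma <- random_alignment(4, 60); mb <- random_alignment(4, 60)
  expect_equal(dxy(ma, mb), dxy(ma[sample(4), ], mb[sample(4), ]))
  expect_equal(fst(ma, mb), fst(ma[sample(4), ], mb[sample(4), ]))
})

test_that("Hudson identity Hb = Hw/(1 - Fst) holds by construction", {
  set.seed(44)
  for (rep in 1:50) {
    ma <- random_alignment(4, 50); mb <- random_alignment(4, 50)
    f <- fst(ma, mb)
    if (is.na(f) || f == 1) next
    comb <- rbind(ma, mb)
    use <- usable_sites(comb, POL)
    hw <- (nucleotide_diversity(ma[, use, drop = FALSE]) +
             nucleotide_diversity(mb[, use, drop = FALSE])) / 2
    hb <- dxy(ma[, use, drop = FALSE], mb[, use, drop = FALSE])
    expect_equal(hb, hw / (1 - f), tolerance = 1e-10)
    expect_gte(hb + 1e-12, max(0, hw))
  }
})

test_that("per-locus stats rows handle one-species and undefined cases", {
  one <- make_aln(c("ACGTAC", "ACGTAT", "ACGTAC"), species = rep("firmus", 3))
  st <- compute_locus_stats(one)
  expect_true(is.na(st$dxy) && is.na(st$fst))
  expect_false(is.na(st$pi_a))
  two <- make_aln(c("ACGTAC", "ACGTAT", "TCGTAC", "TCGTAT"),
                  species = rep(c("firmus", "pennsylvanicus"), each = 2))
  st2 <- compute_locus_stats(two)
  expect_true(all(is.finite(c(st2$pi_a, st2$pi_b, st2$dxy, st2$fst))))
  expect_equal(st2$species_a, "firmus")
  # row matches the per-statistic functions
  a <- two$seqs[1:2, ]; b <- two$seqs[3:4, ]
  expect_equal(st2$dxy, dxy(a, b))
  expect_equal(st2$fst, fst(a, b))
  expect_equal(st2$pi_a, nucleotide_diversity(a))
})

test_that("pooled-total Fst variant differs from Hudson and stays <= it in expectation", {
  set.seed(45)
  ma <- matrix(sample(c("A", "T"), 200, TRUE, prob = c(0.9, 0.1)), 4)
  mb <- matrix(sample(c("A", "T"), 200, TRUE, prob = c(0.1, 0.9)), 4)
  fh <- fst(ma, mb, variant = "hudson")
  fn <- fst(ma, mb, variant = "pooled_total")
  expect_true(is.finite(fh) && is.finite(fn))
  expect_false(isTRUE(all.equal(fh, fn)))
})
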