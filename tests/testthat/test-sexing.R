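test_that("sex classification follows the homozygosity rule with error allowance", {
  five <- stats::setNames(rep("ACGTACGTAC", 5), paste0("X", 1:5))
  r <- infer_sex(five)
  expect_identical(r$inferred_sex, "male")
  expect_equal(r$het_site_count, 0)
  # 3 het sites still male under the default allowance; 4 is female
  g3 <- five; g3[["X1"]] <- "AMGTRYGTAC"   # 3 het sites on one locus
  expect_identical(infer_sex(g3)$inferred_sex, "male")
  g4 <- five; g4[["X1"]] <- "AMGTRYGTAM"
  expect_identical(infer_sex(g4)$inferred_sex, "female")
  # many het sites -> female
  gf <- stats::setNames(rep("RMRMRMRMRM", 5), paste0("X", 1:5))
  expect_identical(infer_sex(gf)$inferred_sex, "female")
  # too few loci -> unknown
  expect_identical(infer_sex(five[1:3])$inferred_sex, "unknown")
  expect_warning(r0 <- infer_sex(stats::setNames(character(0), character(0))),
                 "no X-linked loci")
  expect_identical(r0$inferred_sex, "unknown")
})

test_that("weakly supported het sites are discounted when pileups are given", {
  g <- stats::setNames(rep("AAAA", 5), paste0("X", 1:5))
  g[["X1"]] <- "MMMM"   # 4 het sites -> female without quality check
  expect_identical(infer_sex(g)$inferred_sex, "female")
  # pileups say those het calls ride on sub-threshold support
  weak <- matrix(c(9, 1, 0, 0), 4, 4,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  pl <- list(X1 = pileup_counts("i", "X1", weak))
  expect_identical(infer_sex(g, pileups = pl)$inferred_sex, "male")
})

test_that("male X collapsing keeps one copy per male and is a no-op on autosomes", {
  seqs <- c("ACGT", "ACGT", "AAGT", "AAGT", "ACGA", "ACGT", "ACCT", "ACCT")
  aln <- make_aln(seqs, species = rep("firmus", 8),
                  individual = rep(c("m1", "m2", "f1", "f2"), each = 2),
                  copy = rep(1:2, 4))
  sexes <- c(m1 = "male", m2 = "male", f1 = "female", f2 = "female")
  xc <- collapse_male_x(aln, sexes, "X")
  expect_equal(nrow(xc$seqs), 2 * 2 + 2)       # 2 females x2 + 2 males x1
  expect_true(all(table(xc$labels$individual[xc$labels$individual
                                             %in% c("m1", "m2")]) == 1))
  auto <- collapse_male_x(aln, sexes, "autosomal")
  expect_identical(auto$seqs, aln$seqs)
  expect_identical(auto$labels, aln$labels)
})

test_that("discordant male haplotypes at an X locus warn and keep copy 1", {
  aln <- make_aln(c("ACGT", "ATGT"), species = "firmus",
                  individual = c("m1", "m1"), copy = 1:2)
  expect_warning(xc <- collapse_male_x(aln, c(m1 = "male"), "X"),
                 "discordant")
  expect_identical(paste(xc$seqs[1, ], collapse = ""), "ACGT")
})

test_that("sexes are recovered from simulated data (exact and with errors)", {
  # error-free: diploid consensus from the true haplotype pairs
  # (study-design locus size ~5 kb keeps female het counts well above the
  # male error allowance)
  cfg <- sim_config(length = 5000, linkage = "X", mu = 4e-9,
                    n_male = c(4, 4), n_female = c(4, 4), seed = 77)
  inds <- make_individuals(cfg)
  n_loci <- 5
  genotypes <- list()
  ok <- TRUE
  for (k in seq_len(n_loci)) {
    cfg$seed <- 77 + k
    aln <- simulate_locus(cfg)$alignment
    if (nucleotide_diversity(aln$seqs) == 0) ok <- FALSE  # needs X pi > 0
    dip <- consensus_genotypes(aln)
    for (ind in names(dip)) genotypes[[ind]][[paste0("X", k)]] <- dip[[ind]]
  }
  expect_true(ok)
  inferred <- infer_sexes(genotypes)
  truth <- stats::setNames(inds$sex, inds$individual)
  expect_identical(unname(truth[inferred$individual]),
                   inferred$inferred_sex)   # 100% with zero error
  # collapsed male haplotype equals the true simulated haplotype
  cfg$seed <- 99
  sim <- simulate_locus(cfg)
  truth_aln <- simulate_locus(cfg, duplicate_male_x = FALSE)$alignment
  collapsed <- collapse_male_x(sim$alignment, truth, "X")
  males <- collapsed$labels$sex == "male"
  tm <- truth_aln$labels$sex == "male"
  expect_identical(collapsed$seqs[males, , drop = FALSE],
                   truth_aln$seqs[tm, , drop = FALSE])

  # with 0.2% sequencing error through the pileup caller: > 95% accuracy
  set.seed(101)
  correct <- 0; total <- 0
  for (k in seq_len(n_loci)) {
    cfg$seed <- 200 + k
    aln <- simulate_locus(cfg)$alignment
    lab <- aln$labels
    for (ind in unique(lab$individual)) {
      idx <- which(lab$individual == ind)
      h1 <- paste(aln$seqs[idx[1], ], collapse = "")
      h2 <- paste(aln$seqs[idx[length(idx)], ], collapse = "")
      pl <- simulate_pileup(h1, h2, mean_coverage = 30, error_rate = 0.002,
                            seed = 1000 + 37 * k + idx[1])
      genotypes[[ind]][[paste0("E", k)]] <-
        call_consensus_sequence(pl)$sequence
    }
  }
  noisy <- lapply(genotypes, function(g) g[paste0("E", seq_len(n_loci))])
  inferred2 <- infer_sexes(noisy)
  acc <- mean(truth[inferred2$individual] == inferred2$inferred_sex)
  expect_gt(acc, 0.95)
})
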