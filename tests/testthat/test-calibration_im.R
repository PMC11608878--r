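test_that("species consensus takes the majority and flags ties", {
  expect_identical(species_consensus("ACGT"), "ACGT")
  m <- rbind(strsplit("AAT", "")[[1]], strsplit("AAT", "")[[1]],
             strsplit("ATT", "")[[1]])
  expect_identical(species_consensus(m), "AAT")
  tie <- rbind(strsplit("AT", "")[[1]], strsplit("AT", "")[[1]],
               strsplit("TT", "")[[1]], strsplit("TA", "")[[1]])
  # site 1 ties A/A vs T/T -> W, excluded from divergence counting
  cons <- species_consensus(tie)
  expect_identical(substr(cons, 1, 1), "W")
  d <- consensus_divergence(cons, "AT")
  expect_equal(d$sites_compared, 1L)
})

test_that("consensus divergence and JC correction are exact", {
  expect_equal(consensus_divergence("ACGT", "ACGT")$d, 0)
  one <- paste(c("T", rep("A", 99)), collapse = "")
  ref <- strrep("A", 100)
  expect_equal(consensus_divergence(ref, one)$d, 0.01)
  p <- 0.0736
  expect_equal(-0.75 * log(1 - 4 * p / 3), 0.0774664421, tolerance = 1e-8)
  # build sequences with exactly 736 differences in 10000 sites
  a <- strrep("A", 10000)
  b <- paste(c(rep("T", 736), rep("A", 9264)), collapse = "")
  expect_equal(consensus_divergence(a, b, model = "JC")$d,
               -0.75 * log(1 - 4 * 0.0736 / 3))
})

test_that("D = 2*mu*t arithmetic reproduces the calibration worked values", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.0736, 0.0115), 3.2e6)
  expect_equal(divergence_time(0.0046, 0.0115), 0.2e6)
  r <- locus_mutation_rate(0.026, 3.2e6)
  expect_equal(r$mu, 0.026 / (2 * 3.2e6))
  expect_equal(r$mu, 4.0625e-9, tolerance = 1e-4)
  expect_equal(locus_mutation_rate(c(4e-9, 4.2e-9) * 2 * 1e6, c(1e6, 1e6))$mu,
               4.1e-9)
  expect_warning(locus_mutation_rate(0, 1e6), "implausible")
  expect_error(locus_mutation_rate(0.01, 0), "positive")
})

test_that("divergence_time and locus_mutation_rate are mutual inverses", {
  set.seed(61)
  for (rep in 1:50) {
    mu_my <- runif(1, 0.001, 0.05)       # per site per My
    d <- runif(1, 0.001, 0.2)
    t_years <- divergence_time(d, mu_my)
    back <- locus_mutation_rate(d, t_years)$mu   # per site per year
    expect_equal(back * 1e6, mu_my, tolerance = 1e-12)
  }
})

test_that("longest compatible block matches the worked four-gamete example", {
  # all four gametes at (1-based) sites 3 and 8 of a 10-site locus
  base <- strrep("A", 10)
  hap <- function(s3, s8) {
    ch <- strsplit(base, "")[[1]]; ch[3] <- s3; ch[8] <- s8
    paste(ch, collapse = "")
  }
  m <- c(hap("A", "A"), hap("A", "T"), hap("T", "A"), hap("T", "T"))
  b <- longest_compatible_block(m)
  expect_equal(b$end - b$start, 7)
  expect_equal(b$start, 0)              # leftmost of the two length-7 ties
  expect_equal(b$end, 7)
  expect_equal(b$n_segregating_inside, 1)
  # no segregating sites -> whole locus
  b0 <- longest_compatible_block(rep("ACGTACGTAC", 3))
  expect_equal(c(b0$start, b0$end), c(0, 10))
  expect_error(longest_compatible_block("AMGT"), "phased")
})

test_that("block finder equals exhaustive window enumeration on random data", {
  set.seed(62)
  for (rep in 1:120) {
    m <- random_haplotypes(sample(4:8, 1), sample(12:25, 1),
                           n_seg = sample(3:8, 1),
                           miss_rate = sample(c(0, 0.05), 1))
    got <- longest_compatible_block(m)
    want <- oracle_block(m)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_segregating_inside, want$n_segregating_inside)
    # direct pair-compatibility scan of the returned block
    sub <- m[, (got$start + 1):got$end, drop = FALSE]
    seg <- which(vapply(seq_len(ncol(sub)), function(j) {
      all(sub[, j] %in% c("A", "C", "G", "T")) &&
        length(unique(sub[, j])) == 2
    }, logical(1)))
    if (length(seg) >= 2) {
      for (i in 1:(length(seg) - 1)) for (j in (i + 1):length(seg)) {
        expect_lt(length(unique(paste(sub[, seg[i]], sub[, seg[j]]))), 4)
      }
    }
  }
})

test_that("block length shrinks as recombination (tree concatenation) increases", {
  # concatenating independent gene trees creates four-gamete conflicts
  set.seed(63)
  len_of <- function(n_trees) {
    lens <- vapply(1:30, function(r) {
      parts <- lapply(seq_len(n_trees), function(k) {
        cfg <- sim_config(length = 60, mu = 2e-8, n_male = c(0, 0),
                          n_female = c(3, 3), seed = 1000 * n_trees + r * 7 + k)
        simulate_locus(cfg)$alignment$seqs
      })
      m <- do.call(cbind, parts)
      b <- longest_compatible_block(m)
      b$end - b$start
    }, numeric(1))
    mean(lens)
  }
  l1 <- len_of(1); l3 <- len_of(3)
  expect_gte(l1, 60)           # a single tree never conflicts
  expect_lt(l3, 180)           # concatenation loses some span
})

test_that("IM-format files carry scalars and rates and round-trip", {
  loci <- list(
    list(name = "auto1",
         seqs_a = c(i1_1 = "ACGTACGTAC", i1_2 = "ACGTACGTAT"),
         seqs_b = c(j1_1 = "ACGAACGTAC", j1_2 = "ACGAACGTAC"),
         scalar = 1.0, mu = 4.05e-9),
    list(name = "xlocus",
         seqs_a = c(i1_1 = "ACGTACGTAC"),
         seqs_b = c(j1_1 = "ACGAACGTAC"),
         scalar = 0.75))
  f <- tempfile()
  write_im_input(loci, f, species_names = c("firmus", "pennsylvanicus"))
  txt <- readLines(f)
  expect_true(any(grepl("^auto1 2 2 10 I 1 4.05e-09$", txt)))
  expect_true(any(grepl("^xlocus 1 1 10 I 0.75$", txt)))
  back <- read_im_input(f)
  expect_equal(back$species_names, c("firmus", "pennsylvanicus"))
  expect_equal(back$loci[[1]]$seqs_a, loci[[1]]$seqs_a)
  expect_equal(back$loci[[1]]$mu, 4.05e-9)
  expect_equal(back$loci[[2]]$scalar, 0.75)
  expect_null(back$loci[[2]]$mu)
  # missing scalar for unknown linkage is an error unless defaulted
  expect_error(inheritance_scalar("unknown"), "default")
  expect_equal(inheritance_scalar("unknown", 1.0), 1.0)
  expect_equal(inheritance_scalar("X"), 0.75)
  bad <- list(list(name = "x", seqs_a = c(a = "AC"), seqs_b = c(b = "AC"),
                   scalar = NULL))
  expect_error(write_im_input(bad, tempfile()), "scalar")
  unlink(f)
})

test_that("calibrate_locus averages over available outgroups and handles none", {
  aln <- make_aln(c(strrep("A", 100), strrep("A", 100)),
                  species = c("firmus", "pennsylvanicus"))
  og <- list(bimaculatus = paste(c(rep("T", 8), rep("A", 92)), collapse = ""),
             rubens = paste(c(rep("T", 6), rep("A", 94)), collapse = ""))
  tt <- c(bimaculatus = 3.2e6, rubens = 2.7e6)
  r <- calibrate_locus(aln, og, tt)
  expect_equal(r$outgroups_used, 2L)
  expect_equal(r$mu, mean(c(0.08 / (2 * 3.2e6), 0.06 / (2 * 2.7e6))))
  r0 <- calibrate_locus(aln, list(), tt)
  expect_true(is.na(r0$mu))
  expect_equal(r0$outgroups_used, 0L)
})
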