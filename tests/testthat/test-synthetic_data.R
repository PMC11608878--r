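test_that("simulation is deterministic for a fixed seed", {
  cfg <- sim_config(length = 300, n_male = c(2, 2), n_female = c(2, 2),
                    seed = 7)
  a <- simulate_locus(cfg)$alignment
  b <- simulate_locus(cfg)$alignment
  expect_identical(a$seqs, b$seqs)
  expect_identical(a$labels, b$labels)
  spec <- scenario_semi_permeable(n_per_cell = 1L, seed = 3)
  d1 <- simulate_dataset(spec); d2 <- simulate_dataset(spec)
  expect_identical(d1$alignments[["L001"]]$seqs,
                   d2$alignments[["L001"]]$seqs)
})

test_that("panmixia limit: no split, no migration gives Fst about zero", {
  cfgs <- function(s) sim_config(ne1 = 5e4, ne2 = 5e4, ne_anc = 5e4,
                                 t_split = 0, mu = 2e-8, length = 300,
                                 n_male = c(0, 0), n_female = c(3, 3),
                                 seed = s)
  fsts <- vapply(1:200, function(s) {
    a <- simulate_locus(cfgs(s))$alignment
    f <- fst(a$seqs[a$labels$species == "firmus", ],
             a$seqs[a$labels$species == "pennsylvanicus", ])
    if (is.na(f)) 0 else f
  }, numeric(1))
  se <- stats::sd(fsts) / sqrt(length(fsts))
  expect_lt(abs(mean(fsts)), 3 * se + 0.01)
})

test_that("X loci give males one lineage and optional duplicated copies", {
  cfg <- sim_config(length = 200, linkage = "X", n_male = c(2, 2),
                    n_female = c(2, 2), seed = 11)
  single <- simulate_locus(cfg, duplicate_male_x = FALSE)$alignment
  lab <- single$labels
  expect_true(all(table(lab$individual[lab$sex == "male"]) == 1))
  expect_true(all(table(lab$individual[lab$sex == "female"]) == 2))
  dup <- simulate_locus(cfg, duplicate_male_x = TRUE)$alignment
  lab2 <- dup$labels
  expect_true(all(table(lab2$individual) == 2))
  for (ind in unique(lab2$individual[lab2$sex == "male"])) {
    idx <- which(lab2$individual == ind)
    expect_identical(dup$seqs[idx[1], ], dup$seqs[idx[2], ])
  }
})

test_that("more mutations than sites triggers the multi-hit fallback", {
  cfg <- sim_config(ne1 = 1e5, ne2 = 1e5, ne_anc = 1e5, mu = 1e-5,
                    length = 20, n_male = c(0, 0), n_female = c(2, 2),
                    seed = 5)
  expect_warning(sim <- simulate_locus(cfg), "multi-hit")
  expect_true(sim$genealogy$multi_hit)
})

test_that("scenario datasets echo their configuration", {
  spec <- scenario_no_flow_sweeps(n_per_cell = 2L, seed = 9)
  ds <- simulate_dataset(spec)
  expect_equal(length(ds$alignments), 8)
  expect_equal(sum(ds$locus_metadata$linkage == "X"), 4)
  tr <- ds$locus_truth
  expect_true(all(tr$true_m12 == 0))
  expect_true(all(tr$true_ne_mult[tr$category == "barrier"] == 0.25))
  expect_true(all(tr$true_ne_mult[tr$category == "background"] == 1))
  sp <- scenario_semi_permeable(n_per_cell = 2L, seed = 9)
  tr2 <- simulate_dataset(sp)$locus_truth
  expect_true(all(tr2$true_m12[tr2$category == "barrier"] == 0))
  expect_true(all(tr2$true_m12[tr2$category == "background"] > 0))
  # study-scale preset matches the targeted-resequencing design
  ss <- scenario_study_scale(seed = 1)
  expect_equal(sum(ss$cells$n_loci), 48)
  expect_equal(sum(ss$cells$n_loci[ss$cells$linkage == "X"]), 27)
  expect_equal(sum(ss$cells$n_loci[ss$cells$linkage == "autosomal"]), 21)
  n_ind <- sum(ss$base$n_male + ss$base$n_female)
  expect_equal(n_ind, 96)
})

test_that("written datasets are readable by the pipeline input layer", {
  spec <- scenario_semi_permeable(n_per_cell = 1L, seed = 21)
  ds <- simulate_dataset(spec)
  dir <- tempfile()
  write_dataset(ds, dir)
  st <- read_sample_table(file.path(dir, "sample_table.tsv"))
  expect_true(all(st$sex == "unknown"))    # sexes withheld from the pipeline
  md <- read_locus_metadata(file.path(dir, "locus_metadata.tsv"))
  expect_equal(sort(md$locus_id), sort(names(ds$alignments)))
  aln <- read_locus_fasta(file.path(dir, "L001.fasta"), sample_table = st)
  expect_identical(aln$seqs, ds$alignments[["L001"]]$seqs)
  truth <- utils::read.delim(file.path(dir, "sample_truth.tsv"))
  expect_true(all(truth$sex %in% c("male", "female")))
  unlink(dir, recursive = TRUE)
})

test_that("pileup simulation hits coverage and splits haplotypes evenly", {
  pl <- simulate_pileup(strrep("A", 400), strrep("C", 400),
                        mean_coverage = 40, error_rate = 0, seed = 2)
  tot <- colSums(pl$counts)
  expect_equal(mean(tot), 40, tolerance = 0.1 * 40)
  frac_a <- sum(pl$counts["A", ]) / sum(tot)
  expect_equal(frac_a, 0.5, tolerance = 0.05)
  expect_true(all(pl$counts[c("G", "T"), ] == 0))
  # zero coverage -> all N downstream
  pl0 <- simulate_pileup("ACGT", "ACGT", mean_coverage = 0, seed = 1)
  expect_identical(call_consensus_sequence(pl0)$sequence, "NNNN")
})

test_that("caller recovers simulated genotypes at high coverage", {
  set.seed(71)
  cfg <- sim_config(length = 400, mu = 8e-9, n_male = c(0, 0),
                    n_female = c(5, 5), seed = 81)
  aln <- simulate_locus(cfg)$alignment
  lab <- aln$labels
  n_sites <- 0; n_correct <- 0
  for (ind in unique(lab$individual)) {
    idx <- which(lab$individual == ind)
    h1 <- paste(aln$seqs[idx[1], ], collapse = "")
    h2 <- paste(aln$seqs[idx[2], ], collapse = "")
    pl <- simulate_pileup(h1, h2, mean_coverage = 30, error_rate = 0.002,
                          seed = idx[1])
    called <- call_consensus_sequence(pl)$sequence
    truth <- vapply(seq_len(nchar(h1)), function(j) {
      a <- substr(h1, j, j); b <- substr(h2, j, j)
      if (a == b) a else iupac_code(a, b)
    }, character(1))
    cc <- strsplit(called, "")[[1]]
    n_sites <- n_sites + length(truth)
    n_correct <- n_correct + sum(cc == truth)
  }
  expect_gt(n_correct / n_sites, 0.99)
})
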