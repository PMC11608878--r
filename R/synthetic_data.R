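# Two-population isolation-with-migration coalescent simulator with
# autosomal and X-linked loci (X0 males are hemizygous), per-locus migration
# barriers, sweep-like local diversity reduction, and read-pileup
# simulation. Continuous-time structured coalescent with exponential
# waiting times; infinite-sites mutations mapped onto finite locus
# coordinates (with a multi-hit fallback when mutations outnumber sites).

#' Simulation configuration for one locus
#'
#' @param ne1,ne2,ne_anc diploid effective sizes of species 1, species 2 and
#'   the ancestral population.
#' @param t_split split time in generations (backwards from the present).
#' @param m12,m21 per-lineage per-generation migration probabilities
#'   (backwards in time: `m12` moves a lineage currently in deme 1 to
#'   deme 2).
#' @param mu substitutions per site per generation.
#' @param length locus length in bp.
#' @param linkage `"autosomal"` or `"X"`; X-linked loci use an effective
#'   size of `x_ne_factor * Ne` and one lineage per sampled male.
#' @param n_male,n_female length-2 integer vectors: sampled males/females
#'   per species.
#' @param species length-2 character vector of species names.
#' @param n_pops populations (labels only; species are panmictic unless
#'   sub-structure is added upstream).
#' @param x_ne_factor X-to-autosome effective-size ratio (default 3/4).
#' @param individuals optional pre-built individual table (individual,
#'   species, population, sex) shared across loci of a dataset.
#' @param seed RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(ne1 = 2e5, ne2 = 2e5, ne_anc = 2e5,
                       t_split = 8e5, m12 = 0, m21 = 0,
                       mu = 4e-9, length = 3000L,
                       linkage = c("autosomal", "X"),
                       n_male = c(6L, 6L), n_female = c(6L, 6L),
                       species = c("firmus", "pennsylvanicus"),
                       n_pops = 4L, x_ne_factor = 0.75,
                       individuals = NULL, seed = 1L) {
  linkage <- match.arg(linkage)
  stopifnot(ne1 > 0, ne2 > 0, ne_anc > 0, t_split >= 0,
            m12 >= 0, m12 < 1, m21 >= 0, m21 < 1,
            mu >= 0, length >= 1)
  cfg <- list(ne1 = ne1, ne2 = ne2, ne_anc = ne_anc, t_split = t_split,
              m12 = m12, m21 = m21, mu = mu, length = as.integer(length),
              linkage = linkage, n_male = n_male, n_female = n_female,
              species = species, n_pops = n_pops,
              x_ne_factor = x_ne_factor,
              individuals = individuals, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Build the shared individual table for a configuration
#'
#' Individuals are spread round-robin over the populations of their species;
#' sexes alternate male-first up to the configured counts.
#'
#' @param config a [sim_config()].
#' @return data.frame (individual, species, population, sex).
#' @export
make_individuals <- function(config) {
  rows <- list()
  for (s in 1:2) {
    nm <- config$n_male[s]; nf <- config$n_female[s]
    n <- nm + nf
    sp <- config$species[s]
    pops <- sprintf("%s_p%d", sp, seq_len(config$n_pops))
    sexes <- c(rep("male", nm), rep("female", nf))
    for (i in seq_len(n)) {
      rows[[length(rows) + 1L]] <- data.frame(
        individual = sprintf("%s_%03d", sp, i),
        species = sp,
        population = pops[(i - 1L) %% config$n_pops + 1L],
        sex = sexes[i], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate one locus under the two-population IM coalescent
#'
#' Lineages coalesce within demes at rate `choose(k,2) / (2 Ne_scaled)`,
#' migrate between demes at the per-lineage backwards rates, and merge into
#' the ancestral deme at `t_split`. Mutations are Poisson with mean
#' `mu * L * total_branch_length` and are placed on distinct sites (infinite
#' sites) unless they outnumber the sites, in which case sites are drawn
#' with replacement and a multi-hit warning is raised.
#'
#' At X-linked loci males contribute one lineage (they are hemizygous);
#' `duplicate_male_x = TRUE` (the default) emits the male haplotype twice so
#' that the alignment has two copies per individual, mimicking a phased
#' diploid consensus before male-X collapsing.
#'
#' @param config a [sim_config()].
#' @param duplicate_male_x emit male X haplotypes as two identical copies.
#' @return List: `alignment` (a `locus_alignment`), `genealogy`
#'   (tmrca, total_branch_length, n_mutations, multi_hit), `individuals`.
#' @export
simulate_locus <- function(config, duplicate_male_x = TRUE) {
  old <- .hold_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  inds <- config$individuals
  if (is.null(inds)) inds <- make_individuals(config)
  is_x <- config$linkage == "X"
  scale <- if (is_x) config$x_ne_factor else 1
  # tip bookkeeping: one row per sampled lineage
  tip_rows <- list()
  for (i in seq_len(nrow(inds))) {
    ncopy <- if (is_x && inds$sex[i] == "male") 1L else 2L
    for (k in seq_len(ncopy)) {
      tip_rows[[length(tip_rows) + 1L]] <-
        cbind(inds[i, , drop = FALSE], copy = k)
    }
  }
  tips <- do.call(rbind, tip_rows)
  K <- nrow(tips)
  deme <- match(tips$species, config$species)
  tree <- .sim_genealogy(K, deme, config, scale)
  L <- config$length
  n_mut <- stats::rpois(1, config$mu * L * tree$total_len)
  multi_hit <- FALSE
  anc <- sample(.BASES, L, replace = TRUE)
  seqs <- matrix(rep(anc, each = K), nrow = K)
  if (n_mut > 0) {
    if (n_mut <= L) {
      sites <- sample.int(L, n_mut)
    } else {
      sites <- sample.int(L, n_mut, replace = TRUE)
      multi_hit <- TRUE
      warning("locus has more mutations (", n_mut, ") than sites (", L,
              "): multi-hit sites present")
    }
    edge_of <- sample.int(length(tree$edge_len), n_mut, replace = TRUE,
                          prob = tree$edge_len)
    for (j in seq_len(n_mut)) {
      node <- tree$edge_child[edge_of[j]]
      rows <- tree$desc[[node]]
      cur <- seqs[rows[1], sites[j]]
      seqs[rows, sites[j]] <- sample(setdiff(.BASES, cur), 1)
    }
  }
  if (is_x && duplicate_male_x) {
    male1 <- which(tips$sex == "male" & tips$copy == 1L)
    if (length(male1)) {
      extra <- tips[male1, , drop = FALSE]
      extra$copy <- 2L
      seqs <- rbind(seqs, seqs[male1, , drop = FALSE])
      tips <- rbind(tips, extra)
    }
  }
  ord <- order(tips$individual, tips$copy)
  aln <- locus_alignment(paste0("locus_", config$seed),
                         seqs[ord, , drop = FALSE],
                         tips[ord, c("individual", "species", "population",
                                     "copy", "sex")])
  list(alignment = aln,
       genealogy = list(tmrca = tree$tmrca,
                        total_branch_length = tree$total_len,
                        n_mutations = n_mut, multi_hit = multi_hit),
       individuals = inds)
}

# structured-coalescent genealogy; returns edge list + descendant tip sets
.sim_genealogy <- function(K, deme, config, scale) {
  n_nodes <- 2L * K - 1L
  parent <- integer(n_nodes); time <- numeric(n_nodes)
  active <- seq_len(K)
  act_deme <- deme
  t <- 0
  next_node <- K + 1L
  merged <- config$t_split <= 0
  if (merged) act_deme <- rep(0L, length(act_deme))
  repeat {
    k <- length(active)
    if (k <= 1L) break
    if (!merged) {
      k1 <- sum(act_deme == 1L); k2 <- k - k1
      r_c1 <- k1 * (k1 - 1) / 2 / (2 * config$ne1 * scale)
      r_c2 <- k2 * (k2 - 1) / 2 / (2 * config$ne2 * scale)
      r_m1 <- k1 * config$m12
      r_m2 <- k2 * config$m21
      total <- r_c1 + r_c2 + r_m1 + r_m2
      if (total <= 0) {
        t <- config$t_split
        merged <- TRUE
        act_deme <- rep(0L, k)
        next
      }
      dt <- stats::rexp(1, total)
      if (t + dt >= config$t_split) {
        t <- config$t_split
        merged <- TRUE
        act_deme <- rep(0L, k)
        next
      }
      t <- t + dt
      ev <- sample.int(4L, 1L, prob = c(r_c1, r_c2, r_m1, r_m2))
      if (ev <= 2L) {
        d <- ev
        idx <- which(act_deme == d)
        pick <- idx[sample.int(length(idx), 2L)]
      } else {
        d_from <- ev - 2L
        idx <- which(act_deme == d_from)
        act_deme[idx[sample.int(length(idx), 1L)]] <- 3L - d_from
        next
      }
    } else {
      rate <- k * (k - 1) / 2 / (2 * config$ne_anc * scale)
      t <- t + stats::rexp(1, rate)
      pick <- sample.int(k, 2L)
      pick <- seq_along(active)[pick]
    }
    ch <- active[pick]
    parent[ch] <- next_node
    time[next_node] <- t
    active <- c(active[-pick], next_node)
    act_deme <- c(act_deme[-pick], if (merged) 0L else d)
    next_node <- next_node + 1L
  }
  root <- active[1]
  edge_child <- setdiff(seq_len(root), root)
  edge_len <- time[parent[edge_child]] - time[edge_child]
  desc <- vector("list", root)
  for (v in seq_len(K)) desc[[v]] <- v
  for (v in (K + 1L):root) {
    kids <- which(parent == v)
    desc[[v]] <- unlist(desc[kids])
  }
  list(edge_child = edge_child, edge_len = edge_len, desc = desc,
       tmrca = time[root], total_len = sum(edge_len))
}

#' Scenario specification for a multi-locus dataset
#'
#' @param base a [sim_config()] giving the shared demography.
#' @param cells data.frame with columns `linkage` ("autosomal"/"X"),
#'   `category` ("background"/"barrier") and `n_loci`.
#' @param effects named list of per-category overrides; each entry may set
#'   `m_mult` (multiplies both migration rates) and/or `ne_mult`
#'   (multiplies the two daughter-species sizes, emulating a local sweep;
#'   the ancestral size is untouched).
#' @param seed master seed for the dataset.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(base, cells, effects = list(), seed = 1L) {
  stopifnot(inherits(base, "sim_config"),
            all(c("linkage", "category", "n_loci") %in% names(cells)),
            all(cells$category %in% c("background", "barrier")),
            all(cells$n_loci >= 1L))
  structure(list(base = base, cells = cells, effects = effects,
                 seed = seed),
            class = "scenario_spec")
}

#' Semi-permeable barrier scenario (restricted-introgression islands)
#'
#' Background loci exchange migrants between the species; barrier loci have
#' migration shut off. Under this regime barrier loci accumulate BOTH higher
#' relative (Fst) and higher absolute (Dxy) divergence -- the genomic-islands
#' signature.
#'
#' The default background migration rate gives `4*Ne*m = 2`, the regime in
#' which interspecific gene flow substantially homogenizes unprotected loci
#' while barrier loci keep diverging -- the textbook islands configuration.
#'
#' @param n_per_cell loci per (linkage x category) cell.
#' @param m background migration rate (per lineage per generation).
#' @param base optional [sim_config()] override.
#' @param seed master seed.
#' @return A [scenario_spec()].
#' @export
scenario_semi_permeable <- function(n_per_cell = 12L, m = 2.5e-6,
                                    base = NULL, seed = 1L) {
  if (is.null(base)) base <- sim_config(m12 = m, m21 = m)
  base$m12 <- m; base$m21 <- m
  cells <- expand.grid(linkage = c("autosomal", "X"),
                       category = c("background", "barrier"),
                       stringsAsFactors = FALSE)
  cells$n_loci <- n_per_cell
  scenario_spec(base, cells,
                effects = list(barrier = list(m_mult = 0)),
                seed = seed)
}

#' No-gene-flow sweep scenario (incidental islands)
#'
#' Migration is zero everywhere; "barrier"-category loci instead carry a
#' sweep-like local reduction of the daughter-species effective sizes
#' (default multiplier 0.25). This elevates Fst (through reduced
#' within-species diversity) without elevating Dxy -- high relative but not
#' absolute divergence.
#'
#' @param n_per_cell loci per (linkage x category) cell.
#' @param sweep_ne_mult local Ne multiplier on sweep loci.
#' @param base optional [sim_config()] override.
#' @param seed master seed.
#' @return A [scenario_spec()].
#' @export
scenario_no_flow_sweeps <- function(n_per_cell = 12L, sweep_ne_mult = 0.25,
                                    base = NULL, seed = 1L) {
  if (is.null(base)) base <- sim_config(m12 = 0, m21 = 0)
  base$m12 <- 0; base$m21 <- 0
  cells <- expand.grid(linkage = c("autosomal", "X"),
                       category = c("background", "barrier"),
                       stringsAsFactors = FALSE)
  cells$n_loci <- n_per_cell
  scenario_spec(base, cells,
                effects = list(barrier = list(ne_mult = sweep_ne_mult)),
                seed = seed)
}

#' Study-scale scenario preset
#'
#' 48 loci (27 X-linked, 21 autosomal) over 96 individuals (two species of
#' four populations with 12 individuals each) at ~5 kb per locus, matching
#' the targeted-resequencing design the pipeline is built for; barrier loci
#' are placed preferentially on the X, as in the empirical locus panel.
#'
#' @param m background migration rate.
#' @param length locus length (bp).
#' @param seed master seed.
#' @return A [scenario_spec()].
#' @export
scenario_study_scale <- function(m = 5e-7, length = 5000L, seed = 1L) {
  base <- sim_config(m12 = m, m21 = m, length = length,
                     n_male = c(24L, 24L), n_female = c(24L, 24L))
  cells <- data.frame(
    linkage = c("autosomal", "autosomal", "X", "X"),
    category = c("background", "barrier", "background", "barrier"),
    n_loci = c(8L, 13L, 4L, 23L),
    stringsAsFactors = FALSE)
  scenario_spec(base, cells,
                effects = list(barrier = list(m_mult = 0)),
                seed = seed)
}

#' Simulate a full multi-locus dataset
#'
#' Generates every locus of a scenario with one shared individual table,
#' records per-locus truth (category, true migration, true Ne multiplier)
#' and per-individual truth (sex), and maps categories onto introgression
#' classes (background -> introgressing, barrier -> non_introgressing).
#'
#' @param spec a [scenario_spec()].
#' @param duplicate_male_x passed to [simulate_locus()].
#' @return List: `alignments` (named list of `locus_alignment`),
#'   `locus_metadata`, `sample_table`, `locus_truth`.
#' @export
simulate_dataset <- function(spec, duplicate_male_x = TRUE) {
  base <- spec$base
  inds <- make_individuals(base)
  n_total <- sum(spec$cells$n_loci)
  seeds <- derive_seeds(spec$seed, n_total)
  alignments <- list()
  meta <- list(); truth <- list()
  li <- 0L
  for (ci in seq_len(nrow(spec$cells))) {
    cell <- spec$cells[ci, ]
    eff <- spec$effects[[cell$category]]
    for (r in seq_len(cell$n_loci)) {
      li <- li + 1L
      cfg <- base
      cfg$linkage <- cell$linkage
      cfg$individuals <- inds
      cfg$seed <- seeds[li]
      m_mult <- if (!is.null(eff$m_mult)) eff$m_mult else 1
      ne_mult <- if (!is.null(eff$ne_mult)) eff$ne_mult else 1
      cfg$m12 <- base$m12 * m_mult
      cfg$m21 <- base$m21 * m_mult
      cfg$ne1 <- base$ne1 * ne_mult
      cfg$ne2 <- base$ne2 * ne_mult
      sim <- simulate_locus(cfg, duplicate_male_x = duplicate_male_x)
      id <- sprintf("L%03d", li)
      sim$alignment$locus_id <- id
      alignments[[id]] <- sim$alignment
      meta[[li]] <- data.frame(
        locus_id = id, linkage = cell$linkage,
        class = if (cell$category == "barrier") "non_introgressing"
                else "introgressing",
        stringsAsFactors = FALSE)
      truth[[li]] <- data.frame(
        locus_id = id, category = cell$category,
        linkage = cell$linkage,
        true_m12 = cfg$m12, true_m21 = cfg$m21, true_ne_mult = ne_mult,
        seed = cfg$seed, n_mutations = sim$genealogy$n_mutations,
        stringsAsFactors = FALSE)
    }
  }
  list(alignments = alignments,
       locus_metadata = do.call(rbind, meta),
       sample_table = inds,
       locus_truth = do.call(rbind, truth))
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' One FASTA per locus plus `locus_metadata.tsv`, `sample_table.tsv` (sexes
#' withheld as "unknown" so the pipeline must infer them) and the truth
#' tables `locus_truth.tsv` / `sample_truth.tsv`.
#'
#' @param dataset output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (aln in dataset$alignments) {
    write_locus_fasta(aln, file.path(dir, paste0(aln$locus_id, ".fasta")))
  }
  utils::write.table(dataset$locus_metadata,
                     file.path(dir, "locus_metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  st <- dataset$sample_table
  truth_st <- st
  st$sex <- "unknown"
  utils::write.table(st, file.path(dir, "sample_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(truth_st, file.path(dir, "sample_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$locus_truth,
                     file.path(dir, "locus_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Simulate a read pileup for a haplotype pair
#'
#' Per site the read count is Poisson(`mean_coverage`); each read comes from
#' either haplotype with probability 1/2 and is flipped to a uniformly
#' chosen different base with probability `error_rate`. Sites where a
#' haplotype carries N or a gap contribute no reads from that haplotype.
#'
#' @param hap1,hap2 sequence strings of equal length.
#' @param mean_coverage mean read depth per site.
#' @param error_rate per-read per-site error probability.
#' @param seed RNG seed.
#' @param individual,locus_id identifiers for the container.
#' @return A [pileup_counts()].
#' @export
simulate_pileup <- function(hap1, hap2, mean_coverage, error_rate = 0,
                            seed = 1L, individual = "ind",
                            locus_id = "locus") {
  stopifnot(mean_coverage >= 0, error_rate >= 0, error_rate < 1)
  h1 <- .seq_to_chars(hap1); h2 <- .seq_to_chars(hap2)
  if (length(h1) != length(h2)) stop("haplotypes differ in length")
  old <- .hold_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  L <- length(h1)
  counts <- matrix(0L, nrow = 4, ncol = L, dimnames = list(.BASES, NULL))
  n_reads <- stats::rpois(L, mean_coverage)
  from1 <- stats::rbinom(L, n_reads, 0.5)
  for (j in seq_len(L)) {
    for (src in 1:2) {
      base <- if (src == 1L) h1[j] else h2[j]
      n <- if (src == 1L) from1[j] else n_reads[j] - from1[j]
      if (n == 0L || !(base %in% .BASES)) next
      n_err <- stats::rbinom(1, n, error_rate)
      counts[base, j] <- counts[base, j] + (n - n_err)
      if (n_err > 0) {
        err_bases <- sample(setdiff(.BASES, base), n_err, replace = TRUE)
        for (eb in err_bases) counts[eb, j] <- counts[eb, j] + 1L
      }
    }
  }
  pileup_counts(individual, locus_id, counts)
}
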