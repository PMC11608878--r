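# End-to-end orchestration: simulate or read inputs, call genotypes, infer
# sexes, collapse male X copies, compute per-locus statistics, compare
# locus categories, calibrate mutation rates, trim to non-recombining
# blocks and write IM-format inputs, with a machine-readable run manifest.

#' Reconstruct diploid consensus genotypes from a two-copy alignment
#'
#' Site-wise combination of an individual's two copies: equal called bases
#' give the base, two different called bases give the two-base IUPAC code,
#' anything else gives `N`.
#'
#' @param aln a `locus_alignment` with up to two copies per individual.
#' @return Named character vector (individual -> diploid sequence).
#' @export
consensus_genotypes <- function(aln) {
  lab <- aln$labels
  out <- character(0)
  for (ind in unique(lab$individual)) {
    idx <- which(lab$individual == ind)
    if (length(idx) == 1L) {
      out[ind] <- .chars_to_seq(aln$seqs[idx, ])
      next
    }
    a <- aln$seqs[idx[1], ]; b <- aln$seqs[idx[2], ]
    g <- character(length(a))
    for (j in seq_along(a)) {
      ca <- a[j] %in% .BASES; cb <- b[j] %in% .BASES
      g[j] <- if (ca && cb) {
        if (a[j] == b[j]) a[j] else iupac_code(a[j], b[j])
      } else if (ca) a[j] else if (cb) b[j] else "N"
    }
    out[ind] <- .chars_to_seq(g)
  }
  out
}

#' Default pipeline configuration
#'
#' @param input_dir directory with per-locus FASTAs, `sample_table.tsv` and
#'   `locus_metadata.tsv` (ignored when `simulate` is set).
#' @param output_dir where stage outputs and the manifest are written.
#' @param simulate `NULL`, or a list like
#'   `list(scenario = "semi_permeable", n_per_cell = 12)`; scenarios:
#'   `"semi_permeable"`, `"no_flow_sweeps"`, `"study_scale"`.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param min_cov,het_frac consensus-calling thresholds.
#' @param min_loci,max_het_sites sex-inference thresholds.
#' @param n_perm permutations for category tests.
#' @param policy_mode,treat_gap_as_missing site filter policy.
#' @param fst_variant `"hudson"` or `"pooled_total"`.
#' @param outgroup_times named numeric vector (outgroup species ->
#'   divergence time in years); sequences of these species found in the
#'   alignments are used for calibration and excluded from the focal
#'   statistics. `NULL` disables calibration.
#' @param distance_model `"p"` or `"JC"` for outgroup divergence.
#' @param write_im write the IM-format input file.
#' @return Config list (class `hzscan_config`).
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = "hzscan_out",
                            simulate = NULL, seed = 1L,
                            min_cov = 8L, het_frac = 0.25,
                            min_loci = 5L, max_het_sites = 3L,
                            n_perm = 10000L,
                            policy_mode = "complete_deletion",
                            treat_gap_as_missing = TRUE,
                            fst_variant = "hudson",
                            outgroup_times = NULL,
                            distance_model = "p",
                            write_im = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "hzscan_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(y$outgroup_times)) y$outgroup_times <- unlist(y$outgroup_times)
  do.call(pipeline_config, y)
}

.validate_config <- function(config) {
  if (is.null(config$simulate)) {
    if (is.null(config$input_dir)) {
      stop("config must provide input_dir or a simulate block")
    }
    for (f in c("sample_table.tsv", "locus_metadata.tsv")) {
      if (!file.exists(file.path(config$input_dir, f))) {
        stop("missing required input file: ",
             file.path(config$input_dir, f))
      }
    }
  }
  invisible(config)
}

#' Run the full divergence-scan pipeline
#'
#' Stages (each skipped cleanly when its inputs are absent): simulation or
#' input reading -> sex inference from X-linked homozygosity -> male-X
#' collapsing -> per-locus statistics -> category comparisons -> outgroup
#' calibration -> four-gamete trimming -> IM-input writing. Every stage
#' seed derives from the master seed; warnings are collected into the
#' manifest.
#'
#' @param config a [pipeline_config()] list or path to a YAML file.
#' @return A `run_manifest` (list), invisibly written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  .validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  seeds <- derive_seeds(config$seed, 4L)
  outputs <- list()
  withCallingHandlers({
    # --- stage: inputs -----------------------------------------------------
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      spec <- switch(sim$scenario,
        semi_permeable = scenario_semi_permeable(
          n_per_cell = if (is.null(sim$n_per_cell)) 12L else sim$n_per_cell,
          seed = seeds[1]),
        no_flow_sweeps = scenario_no_flow_sweeps(
          n_per_cell = if (is.null(sim$n_per_cell)) 12L else sim$n_per_cell,
          seed = seeds[1]),
        study_scale = scenario_study_scale(seed = seeds[1]),
        stop("unknown scenario: ", sim$scenario))
      dataset <- simulate_dataset(spec)
      sim_dir <- file.path(config$output_dir, "simulated")
      write_dataset(dataset, sim_dir)
      input_dir <- sim_dir
      alignments <- dataset$alignments
      sample_table <- dataset$sample_table
      sample_table$sex <- "unknown"   # pipeline must infer sexes itself
      metadata <- dataset$locus_metadata
    } else {
      input_dir <- config$input_dir
      sample_table <- read_sample_table(
        file.path(input_dir, "sample_table.tsv"))
      metadata <- read_locus_metadata(
        file.path(input_dir, "locus_metadata.tsv"))
      fastas <- list.files(input_dir, "\\.(fa|fasta|fas)$",
                           full.names = TRUE)
      alignments <- lapply(fastas, read_locus_fasta,
                           sample_table = sample_table)
      names(alignments) <- vapply(alignments, `[[`, "", "locus_id")
    }
    policy <- site_filter_policy(config$policy_mode,
                                 config$treat_gap_as_missing)
    focal_species <- NULL
    if (!is.null(config$outgroup_times)) {
      outgroup_sp <- names(config$outgroup_times)
      all_sp <- unique(unlist(lapply(alignments,
                                     function(a) a$labels$species)))
      focal_species <- setdiff(all_sp, outgroup_sp)
    }
    # --- stage: sex inference ---------------------------------------------
    x_loci <- metadata$locus_id[metadata$linkage == "X"]
    x_loci <- intersect(x_loci, names(alignments))
    sexes <- NULL
    if (length(x_loci) > 0L) {
      called_frac <- vapply(x_loci, function(id) {
        mean(alignments[[id]]$seqs %in% .BASES)
      }, numeric(1))
      panel <- choose_screening_loci(called_frac, config$min_loci)
      genotypes <- list()
      for (id in panel) {
        aln <- alignments[[id]]
        if (!is.null(focal_species)) {
          keep <- aln$labels$species %in% focal_species
          aln <- locus_alignment(aln$locus_id,
                                 aln$seqs[keep, , drop = FALSE],
                                 aln$labels[keep, , drop = FALSE])
        }
        dip <- consensus_genotypes(aln)
        for (ind in names(dip)) genotypes[[ind]][[id]] <- dip[[ind]]
      }
      known <- stats::setNames(sample_table$sex, sample_table$individual)
      sexes <- infer_sexes(genotypes, min_loci = config$min_loci,
                           max_het_sites = config$max_het_sites,
                           known_sexes = known)
      outputs$sexes <- file.path(config$output_dir, "sexes.tsv")
      write_sex_table(sexes, outputs$sexes)
    }
    # --- stage: male-X collapsing -----------------------------------------
    collapsed <- alignments
    if (!is.null(sexes)) {
      for (id in x_loci) {
        collapsed[[id]] <- collapse_male_x(collapsed[[id]], sexes, "X")
      }
    }
    # --- stage: calibration (outgroups inside the alignments) -------------
    calib <- NULL
    if (!is.null(config$outgroup_times)) {
      rows <- lapply(collapsed, function(aln) {
        lab <- aln$labels
        outs <- list()
        for (sp in names(config$outgroup_times)) {
          sel <- lab$species == sp
          if (any(sel)) outs[[sp]] <- aln$seqs[sel, , drop = FALSE]
        }
        keep <- lab$species %in% focal_species
        ingroup <- locus_alignment(aln$locus_id,
                                   aln$seqs[keep, , drop = FALSE],
                                   lab[keep, , drop = FALSE])
        calibrate_locus(ingroup, outs, config$outgroup_times,
                        model = config$distance_model)
      })
      calib <- do.call(rbind, rows)
      rownames(calib) <- NULL
      outputs$calibration <- file.path(config$output_dir,
                                       "calibration.tsv")
      utils::write.table(calib, outputs$calibration, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      # restrict downstream stats to the focal species
      collapsed <- lapply(collapsed, function(aln) {
        keep <- aln$labels$species %in% focal_species
        locus_alignment(aln$locus_id, aln$seqs[keep, , drop = FALSE],
                        aln$labels[keep, , drop = FALSE])
      })
    }
    # --- stage: per-locus statistics --------------------------------------
    stats_table <- compute_stats_table(collapsed, policy = policy,
                                       fst_variant = config$fst_variant)
    outputs$stats <- file.path(config$output_dir, "stats.tsv")
    write_stats_table(stats_table, outputs$stats)
    # --- stage: category comparisons --------------------------------------
    comparison <- compare_categories(stats_table, metadata,
                                     n_perm = config$n_perm,
                                     seed = seeds[2])
    outputs$comparison <- file.path(config$output_dir, "comparison.tsv")
    utils::write.table(comparison, outputs$comparison, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    summary_tab <- summarize_fst_dxy(comparison)
    outputs$summary <- file.path(config$output_dir, "summary.tsv")
    utils::write.table(summary_tab, outputs$summary, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    # --- stage: four-gamete trimming + IM input ---------------------------
    blocks <- lapply(collapsed, longest_compatible_block)
    block_tab <- data.frame(
      locus_id = names(blocks),
      start = vapply(blocks, `[[`, 0L, "start") + 1L,
      end = vapply(blocks, `[[`, 0L, "end"),
      n_segregating_inside = vapply(blocks, `[[`, 0L,
                                    "n_segregating_inside"),
      stringsAsFactors = FALSE)
    outputs$blocks <- file.path(config$output_dir, "blocks.tsv")
    utils::write.table(block_tab, outputs$blocks, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (isTRUE(config$write_im)) {
      im_loci <- list()
      for (id in names(collapsed)) {
        aln <- trim_to_block(collapsed[[id]], blocks[[id]])
        lab <- aln$labels
        sp <- sort(unique(lab$species))
        if (length(sp) < 2L) next
        linkage <- metadata$linkage[metadata$locus_id == id]
        if (length(linkage) == 0L) linkage <- "unknown"
        mu <- if (!is.null(calib)) {
          calib$mu[calib$locus_id == id]
        } else NULL
        seq_of <- function(s) {
          sel <- lab$species == s
          stats::setNames(apply(aln$seqs[sel, , drop = FALSE], 1,
                                paste, collapse = ""),
                          paste0(lab$individual[sel], "_", lab$copy[sel]))
        }
        im_loci[[id]] <- list(
          name = id, seqs_a = seq_of(sp[1]), seqs_b = seq_of(sp[2]),
          scalar = inheritance_scalar(linkage, default_unknown = 1.0),
          mu = if (!is.null(mu) && length(mu) == 1L && is.finite(mu)) mu
               else NULL)
      }
      outputs$im_input <- file.path(config$output_dir, "im_input.txt")
      write_im_input(im_loci, outputs$im_input,
                     species_names = c(stats_table$species_a[1],
                                       stats_table$species_b[1]))
    }
  }, warning = note)
  input_files <- list.files(input_dir, full.names = TRUE)
  manifest <- list(
    config = config[setdiff(names(config), "")],
    seed = config$seed,
    stage_seeds = as.list(seeds),
    input_dir = input_dir,
    input_digests = as.list(tools::md5sum(
      input_files[!file.info(input_files)$isdir])),
    outputs = outputs,
    warnings = warnings_log,
    n_loci = length(alignments),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("hzscan run manifest\n")
  cat("  loci:", x$n_loci, " seed:", x$seed, "\n")
  cat("  outputs:\n")
  for (nm in names(x$outputs)) cat("    ", nm, ": ", x$outputs[[nm]],
                                   "\n", sep = "")
  if (length(x$warnings)) {
    cat("  warnings:", length(x$warnings), "\n")
  }
  invisible(x)
}
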