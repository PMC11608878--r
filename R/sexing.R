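# Sex inference from X-linked homozygosity (X0 system: males are hemizygous,
# so genuine heterozygous calls at X-linked loci indicate a female), and
# collapsing of male X genotypes to single haplotypes.

#' Choose X-linked screening loci for sex inference
#'
#' The screening panel is the `min_loci` X-linked loci with the highest mean
#' called (non-N) fraction across individuals.
#'
#' @param called_fractions named numeric vector (locus -> mean called
#'   fraction), restricted by the caller to X-linked loci.
#' @param min_loci panel size.
#' @return Character vector of locus ids.
#' @export
choose_screening_loci <- function(called_fractions, min_loci = 5L) {
  if (length(called_fractions) < min_loci) return(names(called_fractions))
  names(sort(called_fractions, decreasing = TRUE))[seq_len(min_loci)]
}

#' Infer the sex of one individual from X-linked consensus genotypes
#'
#' Counts heterozygous (two-base IUPAC) sites across the supplied X-linked
#' diploid consensus sequences: `male` if the count is at most
#' `max_het_sites`, `female` otherwise, `unknown` when fewer than `min_loci`
#' loci are available. When pileups are supplied, heterozygous sites whose
#' read support falls below the calling thresholds (coverage under `min_cov`
#' or minor fraction under `het_frac`) are discounted before counting --
#' the mechanical analogue of checking low-count polymorphisms for allele
#' quality and frequency before assigning a sex.
#'
#' @param x_genotypes character vector of diploid consensus sequences at
#'   X-linked loci, named by locus.
#' @param min_loci minimum number of screened loci for a confident call.
#' @param max_het_sites heterozygous-site budget under which an individual
#'   is still classified male (sequencing-error allowance).
#' @param pileups optional named list of [pileup_counts()] (same locus
#'   names) used to discount weakly supported heterozygous sites.
#' @param min_cov,het_frac thresholds used for discounting.
#' @return List: `inferred_sex`, `het_site_count`, `loci_screened`.
#' @export
infer_sex <- function(x_genotypes, min_loci = 5L, max_het_sites = 3L,
                      pileups = NULL, min_cov = 8L, het_frac = 0.25) {
  if (length(x_genotypes) == 0L) {
    warning("no X-linked loci supplied; sex unknown")
    return(list(inferred_sex = "unknown", het_site_count = 0L,
                loci_screened = 0L))
  }
  het <- 0L
  for (locus in names(x_genotypes)) {
    ch <- .seq_to_chars(x_genotypes[[locus]])
    sites <- which(.is_het_code(ch))
    if (!is.null(pileups) && locus %in% names(pileups)) {
      cnt <- pileups[[locus]]$counts
      keep <- vapply(sites, function(j) {
        tot <- sum(cnt[, j])
        if (tot < min_cov) return(FALSE)
        sorted <- sort(cnt[, j], decreasing = TRUE)
        sorted[2] / tot >= het_frac
      }, logical(1))
      sites <- sites[keep]
    }
    het <- het + length(sites)
  }
  n <- length(x_genotypes)
  if (n < min_loci) {
    sex <- "unknown"
  } else {
    sex <- if (het <= max_het_sites) "male" else "female"
  }
  list(inferred_sex = sex, het_site_count = het, loci_screened = n)
}

#' Infer sexes for all individuals from X-linked consensus genotypes
#'
#' @param genotypes list keyed by individual, each a named character vector
#'   of X-linked diploid consensus sequences (locus -> sequence).
#' @inheritParams infer_sex
#' @param known_sexes optional named character vector of known sexes that
#'   override inference.
#' @return data.frame (individual, inferred_sex, het_site_count,
#'   loci_screened).
#' @export
infer_sexes <- function(genotypes, min_loci = 5L, max_het_sites = 3L,
                        pileups = NULL, known_sexes = NULL,
                        min_cov = 8L, het_frac = 0.25) {
  rows <- lapply(names(genotypes), function(ind) {
    r <- infer_sex(genotypes[[ind]], min_loci, max_het_sites,
                   pileups = pileups[[ind]], min_cov = min_cov,
                   het_frac = het_frac)
    if (!is.null(known_sexes) && ind %in% names(known_sexes) &&
        known_sexes[[ind]] %in% c("male", "female")) {
      r$inferred_sex <- known_sexes[[ind]]
    }
    data.frame(individual = ind, inferred_sex = r$inferred_sex,
               het_site_count = r$het_site_count,
               loci_screened = r$loci_screened,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Collapse male X genotypes to single haplotypes
#'
#' At X-linked loci males are hemizygous, so their two phased copies should
#' be identical; only copy 1 is retained. A male whose two copies disagree at
#' any called site triggers a warning (copy 1 is kept). Autosomal loci are
#' returned unchanged.
#'
#' @param aln a `locus_alignment` with two copies per individual.
#' @param sexes data.frame from [infer_sexes()] or a named character vector
#'   individual -> sex.
#' @param linkage `"autosomal"`, `"X"` or `"unknown"` for this locus
#'   (unknown is treated as autosomal, i.e. not collapsed).
#' @return A `locus_alignment`; at X loci the sequence count is
#'   `2 * n_female + n_male` (individuals of unknown sex keep both copies).
#' @export
collapse_male_x <- function(aln, sexes, linkage) {
  if (linkage != "X") return(aln)
  if (is.data.frame(sexes)) {
    sx <- stats::setNames(sexes$inferred_sex, sexes$individual)
  } else sx <- sexes
  lab <- aln$labels
  keep <- rep(TRUE, nrow(lab))
  for (ind in unique(lab$individual)) {
    if (!identical(unname(sx[ind]), "male")) next
    idx <- which(lab$individual == ind)
    if (length(idx) == 2L) {
      a <- aln$seqs[idx[1], ]; b <- aln$seqs[idx[2], ]
      called <- !(a %in% c("N", "-")) & !(b %in% c("N", "-"))
      if (any(a[called] != b[called])) {
        warning("male '", ind, "' has discordant haplotypes at X locus '",
                aln$locus_id, "' (", sum(a[called] != b[called]),
                " sites); keeping copy 1")
      }
      keep[idx[lab$copy[idx] == 2L]] <- FALSE
    }
  }
  locus_alignment(aln$locus_id, aln$seqs[keep, , drop = FALSE],
                  lab[keep, , drop = FALSE])
}

#' Write sex assignments as TSV
#' @param sexes data.frame from [infer_sexes()].
#' @param path output TSV.
#' @return Invisibly, `path`.
#' @export
write_sex_table <- function(sexes, path) {
  utils::write.table(sexes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
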