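# Outgroup-calibrated divergence times and per-locus mutation rates via
# D = 2*mu*t; four-gamete extraction of the longest non-recombining block;
# IM-format input preparation.

#' Site-wise majority consensus of a set of sequences
#'
#' Majority base over called (A/C/G/T) characters per column; a two-way tie
#' yields the two-base IUPAC code (which downstream divergence counting
#' excludes), any deeper tie or an uncalled column yields `N`.
#'
#' @param x alignment, matrix or character vector of sequences.
#' @return A single sequence string.
#' @export
species_consensus <- function(x) {
  m <- .as_seqmat(x)
  out <- vapply(seq_len(ncol(m)), function(j) {
    cnt <- table(factor(m[, j], levels = .BASES))
    if (sum(cnt) == 0L) return("N")
    mx <- max(cnt)
    top <- names(cnt)[cnt == mx]
    if (length(top) == 1L) return(top)
    if (length(top) == 2L) return(iupac_code(top[1], top[2]))
    "N"
  }, character(1))
  .chars_to_seq(out)
}

#' Divergence between two consensus sequences
#'
#' Proportion of differing sites among columns where both sequences carry a
#' called base (A/C/G/T; ambiguity codes and `N`/gaps are excluded), under
#' the uncorrected p-distance (`model = "p"`) or its Jukes--Cantor
#' correction `-(3/4) * log(1 - 4p/3)` (`model = "JC"`).
#'
#' @param cons_a,cons_b equal-length sequence strings.
#' @param model `"p"` or `"JC"`.
#' @return List with `d` (per site) and `sites_compared`; `d` is `NA` when
#'   no site is comparable.
#' @export
consensus_divergence <- function(cons_a, cons_b, model = c("p", "JC")) {
  model <- match.arg(model)
  a <- .seq_to_chars(cons_a); b <- .seq_to_chars(cons_b)
  if (length(a) != length(b)) stop("consensus sequences differ in length")
  ok <- a %in% .BASES & b %in% .BASES
  if (!any(ok)) return(list(d = NA_real_, sites_compared = 0L))
  p <- mean(a[ok] != b[ok])
  d <- if (model == "JC") {
    if (p >= 0.75) stop("p-distance >= 0.75: JC correction undefined")
    -0.75 * log(1 - 4 * p / 3)
  } else p
  list(d = d, sites_compared = sum(ok))
}

#' Divergence time from D = 2*mu*t
#'
#' @param d per-site divergence between two lineages.
#' @param mu_per_site_per_my per-site mutation rate per million years
#'   (default 0.0115, the standard arthropod mitochondrial COI rate).
#' @return Time in years.
#' @examples
#' divergence_time(0.0736)  # 3.2 million years
#' @export
divergence_time <- function(d, mu_per_site_per_my = 0.0115) {
  stopifnot(d >= 0, mu_per_site_per_my > 0)
  d / (2 * mu_per_site_per_my) * 1e6
}

#' Per-locus mutation rate from outgroup divergence
#'
#' Inverts D = 2*mu*t for each outgroup and averages the per-outgroup rates.
#' A zero rate (identical consensus sequences) is flagged with a warning as
#' implausible.
#'
#' @param d_locus per-site divergence(s) between the ingroup and each
#'   outgroup consensus (vector, one per outgroup).
#' @param t_years divergence time(s) in years for the same outgroups.
#' @return List: `mu` (mean substitutions/site/year), `mu_by_outgroup`,
#'   `outgroups_used`.
#' @export
locus_mutation_rate <- function(d_locus, t_years) {
  if (length(d_locus) != length(t_years)) {
    stop("one divergence per outgroup time required")
  }
  if (any(t_years <= 0)) stop("divergence time must be positive")
  mus <- d_locus / (2 * t_years)
  if (any(mus == 0)) warning("zero mutation rate estimated: implausible")
  list(mu = mean(mus), mu_by_outgroup = mus,
       outgroups_used = length(mus))
}

#' Calibrate one locus against outgroup sequences
#'
#' Ingroup consensus is taken over all ingroup sequences; per-outgroup
#' divergence and mutation rate are computed and averaged. Loci with no
#' outgroup sequence get no rate (`mu = NA`).
#'
#' @param aln ingroup `locus_alignment`.
#' @param outgroups named list (outgroup name -> sequence string or matrix
#'   of sequences, aligned to the locus); may be empty.
#' @param t_years named numeric vector of outgroup split times in years.
#' @param model distance model for [consensus_divergence()].
#' @return One-row data.frame: locus_id, per-outgroup d and mu, mean mu,
#'   outgroups_used.
#' @export
calibrate_locus <- function(aln, outgroups, t_years, model = "p") {
  cons_in <- species_consensus(aln$seqs)
  used <- intersect(names(outgroups), names(t_years))
  if (length(used) == 0L) {
    return(data.frame(locus_id = aln$locus_id, d_mean = NA_real_,
                      mu = NA_real_, outgroups_used = 0L,
                      stringsAsFactors = FALSE))
  }
  ds <- vapply(used, function(o) {
    cons_out <- if (is.character(outgroups[[o]]) &&
                    length(outgroups[[o]]) == 1L) {
      outgroups[[o]]
    } else species_consensus(outgroups[[o]])
    consensus_divergence(cons_in, cons_out, model = model)$d
  }, numeric(1))
  rate <- locus_mutation_rate(ds, t_years[used])
  data.frame(locus_id = aln$locus_id, d_mean = mean(ds), mu = rate$mu,
             outgroups_used = length(used), stringsAsFactors = FALSE)
}

#' Longest four-gamete-compatible block
#'
#' Finds the longest contiguous site window in which no pair of biallelic
#' segregating sites exhibits all four gametes (the classical signature of
#' recombination between the pair). Sites with missing data (N, gaps) or
#' more than two alleles are ignored when testing pair compatibility. Ties
#' are broken leftmost; with no segregating sites the whole locus is
#' returned.
#'
#' @param x phased haplotype alignment (matrix, `locus_alignment`, or
#'   character vector) over A/C/G/T/N/-.
#' @return Object of class `compatible_block`: `start`, `end` (0-based
#'   half-open), `n_segregating_inside`.
#' @export
longest_compatible_block <- function(x) {
  m <- .as_seqmat(x)
  if (any(.is_het_code(m))) {
    stop("four-gamete test needs phased haplotypes, not diploid consensus")
  }
  L <- ncol(m)
  seg <- .biallelic_complete_sites(m)
  pairs <- .incompatible_pairs(m, seg)
  if (nrow(pairs) == 0L) {
    blk <- list(start = 0L, end = L, n_segregating_inside = length(seg))
    class(blk) <- "compatible_block"
    return(blk)
  }
  ord <- order(pairs[, 2])
  pq <- pairs[ord, , drop = FALSE]
  best_len <- -1L; best_start <- 0L; best_end <- 0L
  a_min <- 0L; ptr <- 1L
  for (b in seq_len(L)) {
    while (ptr <= nrow(pq) && pq[ptr, 2] <= b) {
      a_min <- max(a_min, pq[ptr, 1])   # window start must be >= p
      ptr <- ptr + 1L
    }
    len <- b - a_min
    if (len > best_len) {
      best_len <- len; best_start <- a_min; best_end <- b
    }
  }
  blk <- list(start = best_start, end = best_end,
              n_segregating_inside = sum(seg > best_start &
                                           seg <= best_end))
  class(blk) <- "compatible_block"
  blk
}

#' @export
print.compatible_block <- function(x, ...) {
  cat(sprintf(
    "Compatible block: sites %d-%d (1-based inclusive), %d segregating\n",
    x$start + 1L, x$end, x$n_segregating_inside))
  invisible(x)
}

# biallelic sites with no missing data (1-based column indices)
.biallelic_complete_sites <- function(m) {
  which(vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (any(!(col %in% .BASES))) return(FALSE)
    length(unique(col)) == 2L
  }, logical(1)))
}

# pairs of segregating sites showing all four gametes; matrix cols (p, q)
.incompatible_pairs <- function(m, seg) {
  out <- list()
  if (length(seg) >= 2L) {
    for (i in 1:(length(seg) - 1L)) {
      for (j in (i + 1L):length(seg)) {
        p <- seg[i]; q <- seg[j]
        if (length(unique(paste(m[, p], m[, q]))) == 4L) {
          out[[length(out) + 1L]] <- c(p, q)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(matrix(integer(0), ncol = 2))
  }
  do.call(rbind, out)
}

#' Extract the block sub-alignment
#'
#' @param aln a `locus_alignment`.
#' @param block a `compatible_block` for the same locus.
#' @return A `locus_alignment` restricted to the block's sites.
#' @export
trim_to_block <- function(aln, block) {
  locus_alignment(aln$locus_id,
                  aln$seqs[, (block$start + 1L):block$end, drop = FALSE],
                  aln$labels)
}

#' Write an IM/IMa-style input file
#'
#' Produces a two-population locus-block text file: title line, number of
#' populations, population names, population tree, number of loci, then per
#' locus a header line `name n1 n2 length model inheritance_scalar [mu]`
#' followed by the sequences (name field padded to 10 characters). The
#' mutation-rate token is omitted for loci without a calibrated rate. The
#' model token is `I` (infinite sites). A matching parser,
#' [read_im_input()], is provided for round-trip checking.
#'
#' @param loci list of locus entries; each entry is a list with `name`,
#'   `seqs_a`, `seqs_b` (named character vectors of equal-length sequence
#'   strings per species), `scalar` (1.0 autosomal, 0.75 X-linked), and
#'   optional `mu` (substitutions/site/year).
#' @param path output path.
#' @param species_names length-2 character vector.
#' @param title first line of the file.
#' @return Invisibly, `path`.
#' @export
write_im_input <- function(loci, path,
                           species_names = c("species1", "species2"),
                           title = "hzscan IM input") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, "2", paste(species_names, collapse = " "),
               "(0,1):2", as.character(length(loci))), con)
  for (lc in loci) {
    if (is.null(lc$scalar)) {
      stop("locus '", lc$name, "': inheritance scalar missing ",
           "(unknown linkage needs an explicit default)")
    }
    L <- nchar(lc$seqs_a[1])
    head <- paste(lc$name, length(lc$seqs_a), length(lc$seqs_b), L, "I",
                  format(lc$scalar, trim = TRUE))
    if (!is.null(lc$mu) && is.finite(lc$mu)) {
      head <- paste(head, format(lc$mu, digits = 10, scientific = TRUE,
                                 trim = TRUE))
    }
    writeLines(head, con)
    nm <- c(names(lc$seqs_a), names(lc$seqs_b))
    sq <- c(unname(lc$seqs_a), unname(lc$seqs_b))
    nm <- formatC(substr(nm, 1, 10), width = 10, flag = "-")
    writeLines(paste0(nm, sq), con)
  }
  invisible(path)
}

#' Parse an IM/IMa-style input file written by [write_im_input()]
#'
#' @param path input file.
#' @return List with `title`, `species_names`, `loci` (same structure as the
#'   input to [write_im_input()]).
#' @export
read_im_input <- function(path) {
  lines <- readLines(path)
  title <- lines[1]
  npop <- as.integer(lines[2])
  if (npop != 2L) stop("only two-population files are supported")
  species_names <- strsplit(lines[3], " +")[[1]]
  nloci <- as.integer(lines[5])
  loci <- list()
  k <- 6L
  for (i in seq_len(nloci)) {
    tok <- strsplit(trimws(lines[k]), " +")[[1]]
    n1 <- as.integer(tok[2]); n2 <- as.integer(tok[3])
    entry <- list(name = tok[1],
                  scalar = as.numeric(tok[6]),
                  mu = if (length(tok) >= 7L) as.numeric(tok[7]) else NULL,
                  model = tok[5], length = as.integer(tok[4]))
    k <- k + 1L
    nm <- trimws(substr(lines[k:(k + n1 + n2 - 1L)], 1, 10))
    sq <- substring(lines[k:(k + n1 + n2 - 1L)], 11)
    entry$seqs_a <- stats::setNames(sq[seq_len(n1)], nm[seq_len(n1)])
    entry$seqs_b <- stats::setNames(sq[n1 + seq_len(n2)], nm[n1 + seq_len(n2)])
    k <- k + n1 + n2
    loci[[i]] <- entry
  }
  list(title = title, species_names = species_names, loci = loci)
}

#' Inheritance scalar for a linkage class
#'
#' 1.0 for autosomal loci, 0.75 for X-linked loci (X0 males carry one X).
#'
#' @param linkage `"autosomal"`, `"X"` or `"unknown"`.
#' @param default_unknown scalar for unknown linkage; error if `NULL`.
#' @return Numeric scalar.
#' @export
inheritance_scalar <- function(linkage, default_unknown = NULL) {
  if (linkage == "autosomal") return(1.0)
  if (linkage == "X") return(0.75)
  if (is.null(default_unknown)) {
    stop("unknown linkage: supply default_unknown")
  }
  default_unknown
}
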