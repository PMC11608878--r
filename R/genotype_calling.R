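# Consensus genotype reconstruction from per-site read pileups.
#
# Calling rule: a site is called only when total coverage reaches min_cov
# (default 8, inclusive); it is called heterozygous when the second most
# frequent base reaches a fraction het_frac (default 0.25, inclusive) of the
# reads, otherwise the modal base is called. Ties for the modal base are
# broken by the fixed order A < C < G < T; a minor base exactly at het_frac
# counts as heterozygous.

#' Call a single consensus base from site read counts
#'
#' @param site_counts numeric vector of read counts, named or ordered
#'   A, C, G, T.
#' @param min_cov minimum total coverage to call (inclusive).
#' @param het_frac minor-allele fraction at or above which the site is called
#'   heterozygous.
#' @return Single character: a base, a two-base IUPAC code, or `N`.
#' @examples
#' call_consensus_base(c(A = 6, C = 2))  # "M"
#' call_consensus_base(c(A = 7))         # "N" (coverage below 8)
#' @export
call_consensus_base <- function(site_counts, min_cov = 8L, het_frac = 0.25) {
  cnt <- .norm_counts(site_counts)
  tot <- sum(cnt)
  if (tot < min_cov || tot == 0) return("N")
  ord <- order(-cnt, seq_along(cnt))   # ties by A<C<G<T
  top <- .BASES[ord[1]]
  second <- cnt[ord[2]]
  if (second / tot >= het_frac) return(iupac_code(top, .BASES[ord[2]]))
  top
}

.norm_counts <- function(x) {
  if (!is.null(names(x))) {
    out <- numeric(4); names(out) <- .BASES
    out[intersect(names(x), .BASES)] <- x[intersect(names(x), .BASES)]
    x <- out
  }
  if (length(x) != 4L) stop("site counts must be length 4 (A, C, G, T)")
  if (any(x < 0)) stop("negative read count")
  unname(x)
}

#' Pileup counts container
#'
#' @param individual,locus_id identifiers.
#' @param counts numeric matrix 4 x L (rows A, C, G, T) of read counts.
#' @return Object of class `pileup_counts`.
#' @export
pileup_counts <- function(individual, locus_id, counts) {
  if (nrow(counts) != 4L) stop("counts must be a 4 x L matrix (A,C,G,T rows)")
  if (any(counts < 0)) stop("negative read count")
  rownames(counts) <- .BASES
  structure(list(individual = individual, locus_id = locus_id,
                 counts = counts),
            class = "pileup_counts")
}

#' Call a diploid consensus sequence from a pileup
#'
#' Applies [call_consensus_base()] site by site and reports the fraction of
#' sites that received a non-`N` call. Individuals/loci whose called fraction
#' falls below `min_called_frac` are flagged for exclusion (the flag is
#' advisory; exclusion itself is a pipeline decision).
#'
#' @param pileup a [pileup_counts()] object.
#' @inheritParams call_consensus_base
#' @param min_called_frac called-fraction floor below which the record is
#'   flagged.
#' @return List with `sequence` (string), `called_fraction`, `flagged`.
#' @export
call_consensus_sequence <- function(pileup, min_cov = 8L, het_frac = 0.25,
                                    min_called_frac = 0.5) {
  cnt <- pileup$counts
  L <- ncol(cnt)
  out <- character(L)
  tot <- colSums(cnt)
  low <- tot < min_cov
  out[low] <- "N"
  for (j in which(!low)) {
    out[j] <- call_consensus_base(cnt[, j], min_cov, het_frac)
  }
  called <- mean(out != "N")
  list(sequence = .chars_to_seq(out),
       called_fraction = called,
       flagged = called < min_called_frac)
}

#' Read pileups from TSV (individual, locus, site, A, C, G, T)
#'
#' Sites are 1-based in the file; a full 4 x L matrix is assembled per
#' (individual, locus), with uncovered sites at zero.
#'
#' @param path TSV file.
#' @param locus_lengths optional named integer vector giving each locus
#'   length; defaults to the maximum site index seen.
#' @return Named list of [pileup_counts()] keyed `individual:locus`.
#' @export
read_pileup_tsv <- function(path, locus_lengths = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "locus", "site", "A", "C", "G", "T")
  if (!all(need %in% names(df))) {
    stop("pileup TSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (key in unique(paste(df$individual, df$locus, sep = ":"))) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    sub <- df[df$individual == parts[1] & df$locus == parts[2], ]
    L <- if (!is.null(locus_lengths) && parts[2] %in% names(locus_lengths)) {
      locus_lengths[[parts[2]]]
    } else max(sub$site)
    m <- matrix(0, nrow = 4, ncol = L, dimnames = list(.BASES, NULL))
    for (b in .BASES) m[b, sub$site] <- sub[[b]]
    out[[key]] <- pileup_counts(parts[1], parts[2], m)
  }
  out
}

#' Write pileups to TSV
#' @param pileups list of [pileup_counts()].
#' @param path output TSV.
#' @return Invisibly, `path`.
#' @export
write_pileup_tsv <- function(pileups, path) {
  rows <- lapply(pileups, function(p) {
    data.frame(individual = p$individual, locus = p$locus_id,
               site = seq_len(ncol(p$counts)),
               A = p$counts["A", ], C = p$counts["C", ],
               G = p$counts["G", ], T = p$counts["T", ])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
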