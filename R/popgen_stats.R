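# Per-locus diversity and divergence statistics on haplotype alignments.
#
# All statistics operate on character matrices (rows = sequences, columns =
# sites) with alphabet {A,C,G,T,N,-}. Anything other than A/C/G/T is treated
# as missing when the policy says so; the default policy is complete
# deletion with gaps counted as missing, which is the site-exclusion
# behaviour of the standard sequence-analysis software this package mirrors.

#' Site filter policy
#'
#' @param mode `"complete_deletion"` (drop any column with missing data in
#'   any retained sequence) or `"pairwise_deletion"` (keep all columns,
#'   handle missingness per sequence pair).
#' @param treat_gap_as_missing should `-` count as missing data? If `FALSE`
#'   a gap is treated as a fifth character state.
#' @return Object of class `site_filter_policy`.
#' @export
site_filter_policy <- function(mode = c("complete_deletion",
                                        "pairwise_deletion"),
                               treat_gap_as_missing = TRUE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, treat_gap_as_missing = treat_gap_as_missing),
            class = "site_filter_policy")
}

.missing_chars <- function(policy) {
  if (policy$treat_gap_as_missing) c("N", "-") else "N"
}

.as_seqmat <- function(x) {
  if (inherits(x, "locus_alignment")) return(x$seqs)
  if (is.character(x) && !is.matrix(x)) {
    return(do.call(rbind, strsplit(toupper(x), "")))
  }
  x
}

#' Usable site indices under a filter policy
#'
#' @param x locus alignment, character matrix or vector of sequences.
#' @param policy a [site_filter_policy()].
#' @return Integer vector of usable column indices (1-based). Under
#'   pairwise deletion every column is usable.
#' @export
usable_sites <- function(x, policy = site_filter_policy()) {
  m <- .as_seqmat(x)
  if (policy$mode == "pairwise_deletion") return(seq_len(ncol(m)))
  miss <- .missing_chars(policy)
  which(colSums(matrix(m %in% miss, nrow = nrow(m))) == 0L)
}

# per-column allele counts over the states relevant under the policy
.col_counts <- function(m, policy) {
  states <- if (policy$treat_gap_as_missing) .BASES else c(.BASES, "-")
  out <- vapply(states, function(b) colSums(m == b),
                numeric(ncol(m)))
  if (ncol(m) == 1L) out <- matrix(out, nrow = 1L,
                                   dimnames = list(NULL, states))
  t(out)   # states x L
}

# pairwise difference proportion between two rows, pairwise deletion
.pair_prop <- function(a, b, miss) {
  ok <- !(a %in% miss) & !(b %in% miss)
  if (!any(ok)) return(NA_real_)
  mean(a[ok] != b[ok])
}

#' Nucleotide diversity (pi) per site
#'
#' Mean pairwise difference proportion between sequences. Under complete
#' deletion this is the total pairwise difference count over usable sites
#' divided by `choose(n,2) * sites_used`; under pairwise deletion it is the
#' mean of per-pair difference proportions.
#'
#' @inheritParams usable_sites
#' @return Numeric scalar; `NA` when fewer than 2 sequences or no usable
#'   sites.
#' @export
nucleotide_diversity <- function(x, policy = site_filter_policy()) {
  m <- .as_seqmat(x)
  n <- nrow(m)
  if (n < 2L) return(NA_real_)
  if (policy$mode == "pairwise_deletion") {
    miss <- .missing_chars(policy)
    props <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      props <- c(props, .pair_prop(m[i, ], m[j, ], miss))
    }
    return(mean(props, na.rm = TRUE))
  }
  use <- usable_sites(m, policy)
  if (length(use) == 0L) return(NA_real_)
  cc <- .col_counts(m[, use, drop = FALSE], policy)
  npairs <- n * (n - 1) / 2
  diffs <- npairs - colSums(cc * (cc - 1) / 2)
  sum(diffs) / (npairs * length(use))
}

#' Segregating sites
#'
#' @inheritParams usable_sites
#' @return Integer count of polymorphic usable columns (under pairwise
#'   deletion, columns with two or more distinct called states).
#' @export
segregating_sites <- function(x, policy = site_filter_policy()) {
  m <- .as_seqmat(x)
  if (policy$mode == "complete_deletion") {
    use <- usable_sites(m, policy)
    if (length(use) == 0L) return(0L)
    m <- m[, use, drop = FALSE]
  }
  cc <- .col_counts(m, policy)
  sum(colSums(cc > 0) >= 2L)
}

#' Watterson's theta per site
#'
#' `theta_W = S / (a1 * sites_used)` with `a1 = sum(1/i, i = 1..n-1)`.
#'
#' @inheritParams usable_sites
#' @return Numeric scalar; `NA` when undefined.
#' @export
wattersons_theta <- function(x, policy = site_filter_policy()) {
  m <- .as_seqmat(x)
  n <- nrow(m)
  if (n < 2L) return(NA_real_)
  use <- usable_sites(m, policy)
  if (length(use) == 0L) return(NA_real_)
  S <- segregating_sites(m, policy)
  a1 <- sum(1 / seq_len(n - 1))
  S / (a1 * length(use))
}

#' Tajima's D
#'
#' Standardized difference between the pairwise (pi-based) and
#' segregating-sites estimates of theta, using the classical constants:
#' `a1 = sum 1/i`, `a2 = sum 1/i^2` (i = 1..n-1), `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2+a2)`,
#' `D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S-1))` where `pi_total` is the
#' mean pairwise difference *count* over usable sites.
#'
#' Undefined (returns `NA`) when `S = 0`, `n < 4`, or the policy is not
#' complete deletion.
#'
#' @inheritParams usable_sites
#' @return Numeric scalar or `NA`.
#' @export
tajimas_d <- function(x, policy = site_filter_policy()) {
  m <- .as_seqmat(x)
  n <- nrow(m)
  if (n < 4L) return(NA_real_)
  if (policy$mode != "complete_deletion") {
    warning("Tajima's D requires the complete-deletion site policy")
    return(NA_real_)
  }
  use <- usable_sites(m, policy)
  if (length(use) == 0L) return(NA_real_)
  mm <- m[, use, drop = FALSE]
  cc <- .col_counts(mm, policy)
  npairs <- n * (n - 1) / 2
  S <- sum(colSums(cc > 0) >= 2L)
  if (S == 0L) return(NA_real_)
  pi_total <- sum(npairs - colSums(cc * (cc - 1) / 2)) / npairs
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Absolute divergence Dxy per site
#'
#' Mean per-site difference proportion over all between-group sequence
#' pairs. Under complete deletion, usable sites are columns complete in both
#' groups jointly.
#'
#' @param x_a,x_b alignments/matrices for the two groups.
#' @param policy a [site_filter_policy()].
#' @return Numeric scalar; `NA` when a group is empty or no sites usable.
#' @export
dxy <- function(x_a, x_b, policy = site_filter_policy()) {
  a <- .as_seqmat(x_a); b <- .as_seqmat(x_b)
  if (nrow(a) < 1L || nrow(b) < 1L) return(NA_real_)
  if (ncol(a) != ncol(b)) stop("groups have different alignment lengths")
  if (policy$mode == "pairwise_deletion") {
    miss <- .missing_chars(policy)
    props <- c()
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      props <- c(props, .pair_prop(a[i, ], b[j, ], miss))
    }
    return(mean(props, na.rm = TRUE))
  }
  comb <- rbind(a, b)
  use <- usable_sites(comb, policy)
  if (length(use) == 0L) return(NA_real_)
  ca <- .col_counts(a[, use, drop = FALSE], policy)
  cb <- .col_counts(b[, use, drop = FALSE], policy)
  between <- nrow(a) * nrow(b) - colSums(ca * cb)
  sum(between) / (nrow(a) * nrow(b) * length(use))
}

#' Fst between two groups of sequences
#'
#' Default is the Hudson--Slatkin--Maddison form `1 - Hw/Hb` with
#' `Hw = (pi_A + pi_B)/2` and `Hb = Dxy`, the estimator in which the
#' relative-vs-absolute divergence contrast is usually stated. The
#' `"pooled_total"` variant uses `1 - Hw/Ht` with `Ht` the diversity of the
#' pooled sample (a Gst/Nst-style denominator). Within-group diversities are
#' computed on the jointly usable site set so numerator and denominator see
#' the same sites. Negative values are reported as-is, never clipped.
#'
#' @inheritParams dxy
#' @param variant `"hudson"` (default) or `"pooled_total"`.
#' @return Numeric scalar; `NA` when the denominator is zero or a group has
#'   fewer than 2 sequences.
#' @export
fst <- function(x_a, x_b, policy = site_filter_policy(),
                variant = c("hudson", "pooled_total")) {
  variant <- match.arg(variant)
  a <- .as_seqmat(x_a); b <- .as_seqmat(x_b)
  if (nrow(a) < 2L || nrow(b) < 2L) return(NA_real_)
  comb <- rbind(a, b)
  use <- usable_sites(comb, policy)
  if (length(use) == 0L) return(NA_real_)
  sub <- site_filter_policy("complete_deletion", policy$treat_gap_as_missing)
  aa <- a[, use, drop = FALSE]; bb <- b[, use, drop = FALSE]
  hw <- (nucleotide_diversity(aa, sub) + nucleotide_diversity(bb, sub)) / 2
  denom <- if (variant == "hudson") {
    dxy(aa, bb, sub)
  } else {
    nucleotide_diversity(comb[, use, drop = FALSE], sub)
  }
  if (is.na(denom) || denom == 0) return(NA_real_)
  1 - hw / denom
}

#' Per-locus statistics table row
#'
#' Computes within-species diversity (n, S, pi, theta_W, Tajima's D, each
#' with complete deletion within the species) and between-species divergence
#' (Dxy, Fst on the jointly usable sites) for one locus. Species A/B are the
#' first/second species in sorted order unless `species_order` is given.
#'
#' @param aln a `locus_alignment` (already sex-collapsed if X-linked).
#' @param policy a [site_filter_policy()].
#' @param species_order optional length-2 character vector.
#' @param fst_variant passed to [fst()].
#' @return One-row data.frame (class `locus_stats`).
#' @export
compute_locus_stats <- function(aln, policy = site_filter_policy(),
                                species_order = NULL,
                                fst_variant = "hudson") {
  sp <- sort(unique(aln$labels$species))
  if (!is.null(species_order)) sp <- species_order
  get <- function(s) aln$seqs[aln$labels$species == s, , drop = FALSE]
  one <- function(m) {
    if (nrow(m) < 2L) {
      return(list(n = nrow(m), S = NA_integer_, pi = NA_real_,
                  theta_w = NA_real_, tajimas_d = NA_real_))
    }
    list(n = nrow(m),
         S = segregating_sites(m, policy),
         pi = nucleotide_diversity(m, policy),
         theta_w = wattersons_theta(m, policy),
         tajimas_d = tajimas_d(m, policy))
  }
  a <- one(get(sp[1]))
  if (length(sp) >= 2L) {
    mb <- get(sp[2])
    b <- one(mb)
    ma <- get(sp[1])
    d <- dxy(ma, mb, policy)
    f <- fst(ma, mb, policy, variant = fst_variant)
    su <- length(usable_sites(rbind(ma, mb), policy))
  } else {
    b <- list(n = 0L, S = NA_integer_, pi = NA_real_, theta_w = NA_real_,
              tajimas_d = NA_real_)
    d <- NA_real_; f <- NA_real_
    su <- length(usable_sites(aln$seqs, policy))
  }
  out <- data.frame(
    locus_id = aln$locus_id,
    species_a = sp[1],
    species_b = if (length(sp) >= 2L) sp[2] else NA_character_,
    n_a = a$n, S_a = a$S, pi_a = a$pi, theta_a = a$theta_w,
    tajimas_d_a = a$tajimas_d,
    n_b = b$n, S_b = b$S, pi_b = b$pi, theta_b = b$theta_w,
    tajimas_d_b = b$tajimas_d,
    dxy = d, fst = f, sites_used = su,
    stringsAsFactors = FALSE)
  class(out) <- c("locus_stats", class(out))
  out
}

#' Statistics table for a list of loci
#'
#' @param alignments list of `locus_alignment` objects.
#' @inheritParams compute_locus_stats
#' @return data.frame, one row per locus.
#' @export
compute_stats_table <- function(alignments, policy = site_filter_policy(),
                                species_order = NULL,
                                fst_variant = "hudson") {
  rows <- lapply(alignments, compute_locus_stats, policy = policy,
                 species_order = species_order, fst_variant = fst_variant)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read the per-locus statistics TSV
#' @param stats data.frame from [compute_stats_table()].
#' @param path TSV path.
#' @return Invisibly `path` / the data.frame.
#' @export
write_stats_table <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_stats_table
#' @export
read_stats_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
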