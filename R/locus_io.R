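# Per-locus FASTA alignments and metadata tables.
#
# Internal representation: a `locus_alignment` is a list with
#   locus_id : character scalar
#   seqs     : character matrix, one row per haplotype/consensus sequence,
#              one column per alignment site, upper case
#   labels   : data.frame(individual, species, population, copy, sex),
#              one row per sequence, rows aligned with seqs
# Coordinates are 0-based half-open internally; reports are 1-based.

#' Construct a locus alignment
#'
#' @param locus_id character scalar.
#' @param seqs character vector of equal-length sequences, or a character
#'   matrix of single characters (rows = sequences).
#' @param labels data.frame with columns `individual`, `species`,
#'   `population`, `copy`, `sex` (missing columns are filled with defaults).
#' @return An object of class `locus_alignment`.
#' @export
locus_alignment <- function(locus_id, seqs, labels) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- which(lens != lens[1])[1]
      stop("ragged alignment in locus '", locus_id, "': record ", bad,
           " has length ", lens[bad], ", expected ", lens[1])
    }
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
  } else {
    seqs <- toupper(seqs)
  }
  if (nrow(seqs) < 1L) stop("alignment must contain at least one sequence")
  dimnames(seqs) <- NULL
  labels <- .complete_labels(labels, nrow(seqs))
  bad <- !(seqs %in% .IUPAC_ALL)
  if (any(bad)) {
    stop("non-IUPAC character(s) in locus '", locus_id, "': ",
         paste(unique(seqs[bad]), collapse = " "))
  }
  key <- paste(labels$individual, labels$copy)
  if (anyDuplicated(key)) {
    stop("duplicate (individual, copy) in locus '", locus_id, "': ",
         key[duplicated(key)][1])
  }
  structure(list(locus_id = locus_id, seqs = seqs, labels = labels),
            class = "locus_alignment")
}

.complete_labels <- function(labels, n) {
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  if (nrow(labels) != n) stop("labels must have one row per sequence")
  if (is.null(labels$copy)) labels$copy <- 1L
  if (is.null(labels$sex)) labels$sex <- "unknown"
  if (is.null(labels$population)) labels$population <- "pop1"
  for (col in c("individual", "species")) {
    if (is.null(labels[[col]])) stop("labels must contain column '", col, "'")
  }
  labels$copy <- as.integer(labels$copy)
  if (!all(labels$copy %in% c(1L, 2L))) stop("copy index must be 1 or 2")
  if (!all(labels$sex %in% c("male", "female", "unknown"))) {
    stop("sex must be male/female/unknown")
  }
  rownames(labels) <- NULL
  labels[c("individual", "species", "population", "copy", "sex")]
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("Locus alignment '", x$locus_id, "': ", nrow(x$seqs), " sequences x ",
      ncol(x$seqs), " sites\n", sep = "")
  tab <- table(x$labels$species)
  cat("  species: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of sites in a locus alignment
#' @param aln a `locus_alignment`.
#' @return Integer number of alignment columns.
#' @export
n_sites <- function(aln) ncol(aln$seqs)

# Header dialect: canonical is individual|species|population|copy, with an
# optional fifth |sex field.  Anything else is resolved via the sample table,
# after stripping a trailing _1/_2 (or /1, .1) copy suffix.
.parse_header <- function(header, sample_table) {
  if (grepl("|", header, fixed = TRUE)) {
    parts <- strsplit(header, "|", fixed = TRUE)[[1]]
    if (length(parts) < 4L) {
      stop("cannot resolve FASTA header '", header,
           "': expected individual|species|population|copy")
    }
    sex <- if (length(parts) >= 5L) parts[5] else "unknown"
    return(list(individual = parts[1], species = parts[2],
                population = parts[3], copy = as.integer(parts[4]),
                sex = sex))
  }
  m <- regmatches(header, regexec("^(.*)[._/]([12])$", header))[[1]]
  if (length(m) == 3L) {
    ind <- m[2]; copy <- as.integer(m[3])
  } else {
    ind <- header; copy <- NA_integer_
  }
  if (is.null(sample_table)) {
    stop("cannot resolve FASTA header '", header,
         "': not canonical and no sample table supplied")
  }
  row <- sample_table[sample_table$individual == ind, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("cannot resolve FASTA header '", header,
         "': individual '", ind, "' not found in sample table")
  }
  list(individual = ind, species = row$species, population = row$population,
       copy = copy, sex = if (is.null(row$sex)) "unknown" else row$sex)
}

#' Read a per-locus FASTA alignment
#'
#' Headers are resolved to sample labels either through the canonical
#' `individual|species|population|copy` dialect or through `sample_table`
#' (a data.frame with columns individual, species, population and optionally
#' sex). Sequences are upper-cased and validated against the IUPAC alphabet.
#'
#' @param path FASTA file, one locus per file.
#' @param sample_table optional data.frame used to resolve non-canonical
#'   headers.
#' @param locus_id defaults to the file name without extension.
#' @return A [locus_alignment()].
#' @export
read_locus_fasta <- function(path, sample_table = NULL, locus_id = NULL) {
  if (is.null(locus_id)) {
    locus_id <- sub("\\.(fa|fasta|fas)$", "", basename(path),
                    ignore.case = TRUE)
  }
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty FASTA file: ", path)
  chars <- lapply(as.character(dna), toupper)
  lens <- lengths(chars)
  if (length(unique(lens)) > 1L) {
    bad <- names(dna)[which(lens != lens[1])[1]]
    stop("ragged alignment in '", path, "': record '", bad, "'")
  }
  parsed <- lapply(names(dna), .parse_header, sample_table = sample_table)
  labels <- do.call(rbind, lapply(parsed, as.data.frame,
                                  stringsAsFactors = FALSE))
  if (anyNA(labels$copy)) {
    # headers without explicit copy index: assign by order of appearance
    for (ind in unique(labels$individual[is.na(labels$copy)])) {
      idx <- which(labels$individual == ind)
      labels$copy[idx] <- seq_along(idx)
    }
  }
  locus_alignment(locus_id, do.call(rbind, chars), labels)
}

#' Write a locus alignment as FASTA
#'
#' Headers use the canonical `individual|species|population|copy` dialect so
#' that [read_locus_fasta()] round-trips without a sample table.
#'
#' @param aln a `locus_alignment`.
#' @param path output file.
#' @param width line-wrap width in bases.
#' @return Invisibly, `path`.
#' @export
write_locus_fasta <- function(aln, path, width = 70L) {
  lab <- aln$labels
  headers <- paste(lab$individual, lab$species, lab$population, lab$copy,
                   sep = "|")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln$seqs))) {
    s <- .chars_to_seq(aln$seqs[i, ])
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", headers[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

#' Mask poor-quality triple ambiguity codes
#'
#' Converts the three-base ambiguity codes `D`, `H`, `V`, `B` to `N`
#' (missing), leaving the heterozygote two-base codes (R, Y, S, W, K, M),
#' plain bases, `N` and gaps untouched.
#'
#' @param seq a sequence string, or a character vector of them.
#' @return Same shape as the input, masked.
#' @export
mask_ambiguity <- function(seq) {
  out <- vapply(seq, function(s) {
    ch <- toupper(.seq_to_chars(s))
    bad <- !(ch %in% .IUPAC_ALL)
    if (any(bad)) {
      stop("non-IUPAC character '", ch[bad][1], "' in sequence")
    }
    ch[ch %in% names(.IUPAC_THREE)] <- "N"
    .chars_to_seq(ch)
  }, character(1))
  unname(out)
}

#' Expand a diploid consensus sequence into two pseudo-haplotypes
#'
#' Each heterozygous (two-base IUPAC) site is split into its two bases with
#' the phase of each site assigned independently at random from the seeded
#' RNG; homozygous, missing and gap sites are copied to both haplotypes. All
#' site-frequency statistics downstream are invariant to the phase seed; only
#' four-gamete trimming can depend on it, which is why the seed is carried in
#' run manifests.
#'
#' @param diploid_seq sequence string over bases, `N`, `-` and two-base
#'   IUPAC codes (three-base codes must be masked first).
#' @param seed integer RNG seed for phase assignment.
#' @return Character vector `c(hap1, hap2)`.
#' @export
expand_to_haplotypes <- function(diploid_seq, seed = 1L) {
  ch <- toupper(.seq_to_chars(diploid_seq))
  if (any(ch %in% names(.IUPAC_THREE))) {
    stop("three-base ambiguity codes present; run mask_ambiguity() first")
  }
  bad <- !(ch %in% .IUPAC_ALL)
  if (any(bad)) stop("non-IUPAC character '", ch[bad][1], "' in sequence")
  h1 <- ch
  h2 <- ch
  het <- which(.is_het_code(ch))
  if (length(het)) {
    flip <- withr_seed_logical(seed, length(het))
    for (k in seq_along(het)) {
      pair <- iupac_expand(ch[het[k]])
      if (flip[k]) pair <- rev(pair)
      h1[het[k]] <- pair[1]
      h2[het[k]] <- pair[2]
    }
  }
  c(.chars_to_seq(h1), .chars_to_seq(h2))
}

# seeded coin flips that do not disturb the caller's RNG state
withr_seed_logical <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n) < 0.5
}

#' Expand every diploid consensus row of an alignment into haplotype pairs
#'
#' @param aln `locus_alignment` of one consensus row per individual.
#' @param seed phase seed; each individual gets an independent derived seed.
#' @return A `locus_alignment` with two rows (copy 1 and 2) per individual.
#' @export
expand_alignment <- function(aln, seed = 1L) {
  lab <- aln$labels
  seqs <- list(); rows <- list()
  child <- derive_seeds(seed, nrow(aln$seqs))
  for (i in seq_len(nrow(aln$seqs))) {
    haps <- expand_to_haplotypes(.chars_to_seq(aln$seqs[i, ]), child[i])
    for (k in 1:2) {
      seqs[[length(seqs) + 1L]] <- haps[k]
      r <- lab[i, ]; r$copy <- k
      rows[[length(rows) + 1L]] <- r
    }
  }
  locus_alignment(aln$locus_id, unlist(seqs), do.call(rbind, rows))
}

#' Read a sample table TSV (individual, species, population, sex)
#' @param path TSV file.
#' @return data.frame.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "species", "population")
  if (!all(need %in% names(df))) {
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$sex)) df$sex <- "unknown"
  df
}

#' Read a locus metadata TSV (locus_id, linkage, class[, linkage_group, cM])
#' @param path TSV file.
#' @return data.frame with validated enumerations.
#' @export
read_locus_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("locus_id", "linkage", "class") %in% names(df))) {
    stop("locus metadata must have columns locus_id, linkage, class")
  }
  if (anyDuplicated(df$locus_id)) stop("duplicate locus_id in metadata")
  if (!all(df$linkage %in% c("autosomal", "X", "unknown"))) {
    stop("linkage must be autosomal/X/unknown")
  }
  ok <- c("introgressing", "non_introgressing", "unclassified")
  if (!all(df$class %in% ok)) {
    stop("class must be one of: ", paste(ok, collapse = ", "))
  }
  df
}

#' Derive independent child seeds from one master seed
#'
#' One global seed governs all stage seeds: the master seed initializes the
#' RNG once and `n` child seeds are drawn uniformly from 1..2^31-2. The same
#' master seed therefore reproduces every stochastic stage of a run.
#'
#' @param seed master seed.
#' @param n number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(2147483646L, n, replace = FALSE)
}
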