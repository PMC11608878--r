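# Independent brute-force oracles, coded from the definitions and kept
# deliberately naive; the package implementations are checked against these.

# random alignment: per column, monomorphic w.p. mono_p, otherwise two
# alleles at a random frequency; missing characters sprinkled at miss_rate
random_alignment <- function(n, L, miss_rate = 0.05, mono_p = 0.5,
                             gap_rate = 0.02) {
  m <- matrix("", n, L)
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(L)) {
    if (stats::runif(1) < mono_p) {
      m[, j] <- sample(bases, 1)
    } else {
      ab <- sample(bases, 2)
      m[, j] <- sample(ab, n, replace = TRUE,
                       prob = c(p <- stats::runif(1, 0.1, 0.9), 1 - p))
    }
  }
  miss <- stats::runif(n * L) < miss_rate
  m[miss] <- "N"
  gap <- stats::runif(n * L) < gap_rate
  m[gap] <- "-"
  m
}

oracle_usable <- function(m) {
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    keep[j] <- all(m[, j] %in% c("A", "C", "G", "T"))
  }
  which(keep)
}

oracle_pi <- function(m) {
  use <- oracle_usable(m)
  if (length(use) == 0 || nrow(m) < 2) return(NA_real_)
  mm <- m[, use, drop = FALSE]
  n <- nrow(mm)
  total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + sum(mm[i, ] != mm[j, ])
  }
  total / (choose(n, 2) * length(use))
}

oracle_S <- function(m) {
  use <- oracle_usable(m)
  if (length(use) == 0) return(0L)
  s <- 0L
  for (j in use) if (length(unique(m[, j])) > 1) s <- s + 1L
  s
}

oracle_theta <- function(m) {
  use <- oracle_usable(m)
  n <- nrow(m)
  if (n < 2 || length(use) == 0) return(NA_real_)
  a1 <- 0
  for (i in 1:(n - 1)) a1 <- a1 + 1 / i
  oracle_S(m) / (a1 * length(use))
}

# Tajima 1989, re-derived independently of the package path
oracle_tajima <- function(m) {
  n <- nrow(m)
  use <- oracle_usable(m)
  if (n < 4 || length(use) == 0) return(NA_real_)
  mm <- m[, use, drop = FALSE]
  S <- oracle_S(m)
  if (S == 0) return(NA_real_)
  khat <- 0   # mean pairwise difference count
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    khat <- khat + sum(mm[i, ] != mm[j, ])
  }
  khat <- khat / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracle_dxy <- function(ma, mb) {
  comb <- rbind(ma, mb)
  use <- oracle_usable(comb)
  if (length(use) == 0) return(NA_real_)
  total <- 0
  for (i in seq_len(nrow(ma))) for (j in seq_len(nrow(mb))) {
    total <- total + sum(ma[i, use] != mb[j, use])
  }
  total / (nrow(ma) * nrow(mb) * length(use))
}

oracle_fst <- function(ma, mb) {
  comb <- rbind(ma, mb)
  use <- oracle_usable(comb)
  if (length(use) == 0) return(NA_real_)
  hw <- (oracle_pi(ma[, use, drop = FALSE]) +
           oracle_pi(mb[, use, drop = FALSE])) / 2
  hb <- oracle_dxy(ma[, use, drop = FALSE], mb[, use, drop = FALSE])
  if (is.na(hb) || hb == 0) return(NA_real_)
  1 - hw / hb
}

# exhaustive longest compatible window: check every window against every
# incompatible pair of biallelic complete sites
oracle_block <- function(m) {
  L <- ncol(m)
  bases <- c("A", "C", "G", "T")
  seg <- c()
  for (j in seq_len(L)) {
    col <- m[, j]
    if (all(col %in% bases) && length(unique(col)) == 2) seg <- c(seg, j)
  }
  pairs <- matrix(0L, 0, 2)
  if (length(seg) >= 2) {
    for (i in 1:(length(seg) - 1)) for (j in (i + 1):length(seg)) {
      p <- seg[i]; q <- seg[j]
      if (length(unique(paste(m[, p], m[, q]))) == 4) {
        pairs <- rbind(pairs, c(p, q))
      }
    }
  }
  best <- c(start = 0L, end = 0L); best_len <- -1L
  for (a in 0:(L - 1)) for (b in (a + 1):L) {
    ok <- TRUE
    if (nrow(pairs) > 0) {
      inside <- pairs[, 1] > a & pairs[, 2] <= b
      ok <- !any(inside)
    }
    if (ok && (b - a) > best_len) {
      best <- c(start = a, end = b); best_len <- b - a
    }
  }
  list(start = unname(best["start"]), end = unname(best["end"]),
       n_segregating_inside = sum(seg > best["start"] & seg <= best["end"]))
}

# random phased haplotype alignment with controllable recombination signal:
# two underlying "trees" (left/right halves) generate correlated columns
random_haplotypes <- function(n, L, n_seg = 6, miss_rate = 0) {
  m <- matrix(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              n, L, byrow = TRUE)
  sites <- sample(L, min(n_seg, L))
  for (j in sites) {
    ab <- sample(c("A", "C", "G", "T"), 2)
    m[, j] <- sample(ab, n, replace = TRUE)
  }
  if (miss_rate > 0) m[stats::runif(n * L) < miss_rate] <- "N"
  m
}

# textbook BCa, written independently (quantile type 1 on sorted bootstrap
# statistics, explicit jackknife) for the dual-implementation check
oracle_bca <- function(values, statistic, n_boot, alpha, seed) {
  set.seed(seed)
  n <- length(values)
  hat <- statistic(values)
  boots <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    boots[b] <- statistic(sample(values, n, replace = TRUE))
  }
  z0 <- stats::qnorm(sum(boots < hat) / n_boot)
  jack <- numeric(n)
  for (i in seq_len(n)) jack[i] <- statistic(values[-i])
  d <- mean(jack) - jack
  a <- sum(d^3) / (6 * sum(d^2)^1.5)
  zl <- stats::qnorm(alpha / 2); zu <- stats::qnorm(1 - alpha / 2)
  a1 <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  a2 <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  sorted <- sort(boots)
  pick <- function(p) sorted[max(1L, min(n_boot, ceiling(p * n_boot)))]
  c(lower = pick(a1), upper = pick(a2))
}

# small labelled alignment builder for unit tests
make_aln <- function(seqs, species, individual = NULL, copy = NULL,
                     sex = NULL, locus_id = "test") {
  n <- length(seqs)
  if (is.null(individual)) individual <- paste0("ind", seq_len(n))
  if (is.null(copy)) copy <- rep(1L, n)
  if (is.null(sex)) sex <- rep("unknown", n)
  locus_alignment(locus_id, seqs,
                  data.frame(individual = individual, species = species,
                             population = "p1", copy = copy, sex = sex,
                             stringsAsFactors = FALSE))
}
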