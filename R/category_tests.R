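# Locus-category comparisons: permutation tests on group medians, BCa
# bootstrap intervals, and rank correlation with bootstrap p-values.

#' Permutation test for a difference in group medians
#'
#' The statistic is `median(A) - median(B)` (optionally means). Labels are
#' permuted across the pooled values. When the number of distinct
#' reallocations `choose(nA+nB, nA)` is at most `exhaustive_limit` the full
#' enumeration is used and the p-value is the exact proportion of
#' reallocations at least as extreme as the observed one (the identity
#' reallocation always counts, so p is never 0). Otherwise `n_perm` random
#' reallocations are drawn and the add-one Monte-Carlo estimate
#' `p = (1 + #extreme) / (n_perm + 1)` is reported.
#'
#' @param values_a,values_b numeric vectors (finite, non-empty).
#' @param n_perm number of random reallocations in Monte-Carlo mode.
#' @param seed RNG seed for Monte-Carlo mode.
#' @param statistic `"median"` or `"mean"`.
#' @param alternative `"two.sided"` (default), `"greater"` (A > B) or
#'   `"less"`.
#' @param exhaustive `"auto"` (default), `"always"` or `"never"`.
#' @param exhaustive_limit enumeration cutoff for `"auto"`.
#' @return Object of class `permutation_result`.
#' @export
permutation_test_median_diff <- function(values_a, values_b,
                                         n_perm = 10000L, seed = 1L,
                                         statistic = c("median", "mean"),
                                         alternative = c("two.sided",
                                                         "greater", "less"),
                                         exhaustive = c("auto", "always",
                                                        "never"),
                                         exhaustive_limit = 20000) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  exhaustive <- match.arg(exhaustive)
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (!all(is.finite(c(values_a, values_b)))) {
    stop("values must be finite (drop undefined loci first)")
  }
  fun <- if (statistic == "median") stats::median else mean
  obs <- fun(values_a) - fun(values_b)
  pool <- c(values_a, values_b)
  na <- length(values_a); n <- length(pool)
  n_comb <- choose(n, na)
  use_exhaustive <- exhaustive == "always" ||
    (exhaustive == "auto" && n_comb <= exhaustive_limit)
  tol <- 1e-12 * max(1, abs(obs))
  extreme <- function(t) {
    switch(alternative,
           two.sided = abs(t) >= abs(obs) - tol,
           greater = t >= obs - tol,
           less = t <= obs + tol)
  }
  if (use_exhaustive) {
    idx <- utils::combn(n, na)
    perm_stats <- apply(idx, 2, function(k) fun(pool[k]) - fun(pool[-k]))
    p <- mean(extreme(perm_stats))
    method <- "exhaustive"
    n_used <- ncol(idx)
  } else {
    old <- .hold_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
    perm_stats <- vapply(seq_len(n_perm), function(i) {
      k <- sample.int(n, na)
      fun(pool[k]) - fun(pool[-k])
    }, numeric(1))
    p <- (1 + sum(extreme(perm_stats))) / (n_perm + 1)
    method <- "monte_carlo"
    n_used <- n_perm
  }
  structure(list(statistic_name = paste0("diff_of_", statistic, "s"),
                 observed = obs,
                 median_a = stats::median(values_a),
                 median_b = stats::median(values_b),
                 n_a = na, n_b = length(values_b),
                 p_value = p, n_permutations = n_used,
                 method = method, alternative = alternative, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test (", x$statistic_name, ", ", x$method, ", ",
      x$alternative, ")\n", sep = "")
  cat(sprintf("  observed = %.6g (medians %.6g vs %.6g; n = %d/%d)\n",
              x$observed, x$median_a, x$median_b, x$n_a, x$n_b))
  cat(sprintf("  p = %.4g  (%d reallocations)\n", x$p_value,
              x$n_permutations))
  invisible(x)
}

.hold_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' BCa bootstrap confidence interval
#'
#' Efron's bias-corrected and accelerated interval: the bias correction is
#' `z0 = qnorm(#{theta* < theta_hat} / B)`, the acceleration `a` comes from
#' the skewness of the jackknife values, and the interval endpoints are the
#' bootstrap quantiles at the adjusted levels
#' `alpha_k = pnorm(z0 + (z0 + z_k) / (1 - a (z0 + z_k)))`.
#'
#' @param values numeric vector (length >= 8).
#' @param statistic function of a numeric vector, default [stats::median()].
#' @param n_boot bootstrap replicates.
#' @param alpha two-sided miss probability (0.05 gives a 95% interval).
#' @param seed RNG seed.
#' @return Object of class `bca_interval` with fields `point`, `lower`,
#'   `upper`, `alpha`, `z0`, `acceleration`, `n_boot`, `seed`, `degenerate`.
#' @export
bca_interval <- function(values, statistic = stats::median,
                         n_boot = 10000L, alpha = 0.05, seed = 1L) {
  n <- length(values)
  if (n < 8L) stop("need at least 8 values for a BCa interval")
  point <- statistic(values)
  old <- .hold_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    statistic(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  if (all(boot == point)) {
    return(structure(list(point = point, lower = point, upper = point,
                          alpha = alpha, z0 = 0, acceleration = 0,
                          n_boot = n_boot, seed = seed, degenerate = TRUE),
                     class = "bca_interval"))
  }
  prop <- sum(boot < point) / n_boot
  prop <- min(max(prop, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
  z0 <- stats::qnorm(prop)
  jack <- vapply(seq_len(n), function(i) statistic(values[-i]), numeric(1))
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  a <- if (denom == 0) 0 else sum((jm - jack)^3) / (6 * denom)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  lo <- stats::quantile(boot, adj(stats::qnorm(alpha / 2)), names = FALSE)
  hi <- stats::quantile(boot, adj(stats::qnorm(1 - alpha / 2)),
                        names = FALSE)
  structure(list(point = point, lower = lo, upper = hi, alpha = alpha,
                 z0 = z0, acceleration = a, n_boot = n_boot, seed = seed,
                 degenerate = FALSE),
            class = "bca_interval")
}

#' @export
print.bca_interval <- function(x, ...) {
  cat(sprintf("BCa %g%% interval: %.6g (%.6g, %.6g)%s\n",
              100 * (1 - x$alpha), x$point, x$lower, x$upper,
              if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  z0 = %.4f, acceleration = %.4f, B = %d\n",
              x$z0, x$acceleration, x$n_boot))
  invisible(x)
}

#' Spearman rank correlation with a case-resampling bootstrap p-value
#'
#' `rho` uses mid-ranks for ties. The bootstrap p-value is
#' `2 * min(P(rho* <= 0), P(rho* >= 0))` over case-resampled pairs, floored
#' at `1/(n_boot+1)` and capped at 1.
#'
#' @param x,y paired numeric vectors, length >= 5.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return List with `rho`, `p_bootstrap`, `n_boot`, `seed`.
#' @export
spearman_bootstrap <- function(x, y, n_boot = 10000L, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 5L) stop("need at least 5 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: rho undefined")
  }
  rho <- stats::cor(x, y, method = "spearman")
  old <- .hold_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  n <- length(x)
  boot <- vapply(seq_len(n_boot), function(i) {
    k <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[k]) == 0 || stats::sd(y[k]) == 0) return(NA_real_)
    stats::cor(x[k], y[k], method = "spearman")
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  p <- min(max(p, 1 / (n_boot + 1)), 1)
  list(rho = rho, p_bootstrap = p, n_boot = n_boot, seed = seed)
}

#' Compare locus categories (the machine-readable category-summary table)
#'
#' Runs the four standard contrasts -- introgression class over all loci,
#' autosomal vs X-linked, and introgression class within each linkage
#' class -- for each requested per-locus statistic, with a permutation test
#' per (contrast, statistic). Loci whose statistic is undefined (`NA`) are
#' dropped from that test; an empty cell skips the contrast with a warning.
#'
#' @param stats_table data.frame from [compute_stats_table()] (or read back
#'   from its TSV).
#' @param metadata locus metadata data.frame (locus_id, linkage, class).
#' @param statistics columns of `stats_table` to compare.
#' @param n_perm,seed,alternative passed to
#'   [permutation_test_median_diff()].
#' @return Long data.frame: contrast, group_a, group_b, statistic,
#'   median_a, median_b, n_a, n_b, p_value, method.
#' @export
compare_categories <- function(stats_table, metadata,
                               statistics = c("fst", "dxy", "pi_a", "pi_b",
                                              "tajimas_d_a", "tajimas_d_b"),
                               n_perm = 10000L, seed = 1L,
                               alternative = "two.sided") {
  df <- merge(stats_table, metadata, by = "locus_id")
  contrasts <- list(
    list(name = "class_all", split = df$class,
         a = "non_introgressing", b = "introgressing", subset = TRUE),
    list(name = "linkage", split = df$linkage,
         a = "autosomal", b = "X", subset = TRUE),
    list(name = "class_autosomal", split = df$class,
         a = "non_introgressing", b = "introgressing",
         subset = df$linkage == "autosomal"),
    list(name = "class_X", split = df$class,
         a = "non_introgressing", b = "introgressing",
         subset = df$linkage == "X"))
  seeds <- derive_seeds(seed, length(contrasts) * length(statistics))
  k <- 0L
  rows <- list()
  for (ct in contrasts) {
    for (st in statistics) {
      k <- k + 1L
      vals <- df[[st]]
      sel_a <- ct$subset & ct$split == ct$a & is.finite(vals)
      sel_b <- ct$subset & ct$split == ct$b & is.finite(vals)
      if (sum(sel_a) == 0L || sum(sel_b) == 0L) {
        warning("contrast '", ct$name, "' for '", st,
                "' skipped: empty cell")
        next
      }
      pr <- permutation_test_median_diff(vals[sel_a], vals[sel_b],
                                         n_perm = n_perm, seed = seeds[k],
                                         alternative = alternative)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = ct$name, group_a = ct$a, group_b = ct$b,
        statistic = st, median_a = pr$median_a, median_b = pr$median_b,
        n_a = pr$n_a, n_b = pr$n_b, p_value = pr$p_value,
        method = pr$method, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reshape a category comparison into the compact Fst/Dxy summary
#'
#' One row per contrast with Fst and Dxy medians, cell sizes and
#' permutation p-values -- the compact summary-table layout.
#'
#' @param comparison output of [compare_categories()].
#' @return data.frame with one row per contrast.
#' @export
summarize_fst_dxy <- function(comparison) {
  cts <- unique(comparison$contrast)
  rows <- lapply(cts, function(ct) {
    f <- comparison[comparison$contrast == ct &
                      comparison$statistic == "fst", ]
    d <- comparison[comparison$contrast == ct &
                      comparison$statistic == "dxy", ]
    if (nrow(f) == 0L && nrow(d) == 0L) return(NULL)
    g <- if (nrow(f)) f else d
    data.frame(contrast = ct,
               group_a = g$group_a[1], group_b = g$group_b[1],
               fst_median_a = if (nrow(f)) f$median_a else NA_real_,
               fst_median_b = if (nrow(f)) f$median_b else NA_real_,
               dxy_median_a = if (nrow(d)) d$median_a else NA_real_,
               dxy_median_b = if (nrow(d)) d$median_b else NA_real_,
               n_a = g$n_a[1], n_b = g$n_b[1],
               p_fst = if (nrow(f)) f$p_value else NA_real_,
               p_dxy = if (nrow(d)) d$p_value else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
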