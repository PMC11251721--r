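# Directional statistics.
#
# Mean resultant vectors, a rotation-invariant two-sample Kuiper test with
# permutation p-values, the Watson-Williams test for equality of mean
# directions (with the concentration-based applicability gate at average
# mean vector length 0.45, after Batschelet), plus the scalar
# within-subject tests used by the comparison workflow: the Wilcoxon
# signed-rank test and one-way repeated-measures ANOVA with
# Greenhouse-Geisser correction and Bonferroni post hoc tests.

#' Mean resultant vector of a circular sample
#'
#' Average of the unit vectors of the sample angles. The vector length
#' (0-1) measures concentration; the direction is the circular mean in the
#' arena convention. The direction is `NA` when the length is numerically
#' zero.
#'
#' @param angles numeric vector of angles in degrees.
#' @return object of class `mean_vector`: list with `direction` (deg),
#'   `length` (0-1) and `n`.
#' @examples
#' mean_vector(c(170, 190))$length # cos(10 deg)
#' @export
mean_vector <- function(angles) {
  if (!length(angles)) stop("mean_vector() needs at least one angle")
  r <- deg2rad(angles)
  C <- mean(cos(r)); S <- mean(sin(r))
  len <- sqrt(C^2 + S^2)
  dir <- if (len < 1e-12) NA_real_ else wrap360(rad2deg(atan2(S, C)))
  structure(list(direction = dir, length = len, n = length(angles)),
            class = "mean_vector")
}

#' @export
print.mean_vector <- function(x, ...) {
  cat(sprintf("<mean_vector: direction %s deg, length %.4f, n = %d>\n",
              if (is.na(x$direction)) "NA" else sprintf("%.2f", x$direction),
              x$length, x$n))
  invisible(x)
}

new_circ_test <- function(statistic, df, p_value, applicable, method,
                          n_per_group, extra = list()) {
  structure(c(list(statistic = statistic, df = df, p_value = p_value,
                   applicable = applicable, method = method,
                   n_per_group = n_per_group), extra),
            class = "circ_test")
}

#' @export
print.circ_test <- function(x, ...) {
  cat(sprintf("<%s: statistic %.4f, p = %.4g%s>\n", x$method, x$statistic,
              x$p_value,
              if (!isTRUE(x$applicable)) " [NOT APPLICABLE]" else ""))
  invisible(x)
}

# Kuiper V between two label vectors over a shared tie-group structure:
# the cumulative walk of +1/n1 (group a) / -1/n2 (group b) steps over the
# pooled sorted angles, aggregated within tied values; V = max - min of the
# walk including its 0 baseline. V is invariant under a common rotation.
kuiper_V <- function(is_a, grp, n1, n2) {
  step <- ifelse(is_a, 1 / n1, -1 / n2)
  d <- cumsum(rowsum(step, grp))
  max(d, 0) - min(d, 0)
}

#' Kuiper two-sample test for circular data (permutation p-value)
#'
#' Rotation-invariant circular analogue of the two-sample
#' Kolmogorov-Smirnov test: the statistic is
#' `V = max(F_a - F_b) + max(F_b - F_a)` over the circular empirical
#' distribution functions, which does not depend on the choice of origin.
#' The p-value is obtained by random permutation of the pooled sample
#' labels, giving exact small-sample behaviour.
#'
#' @param a,b numeric vectors of angles in degrees.
#' @param n_perm number of label permutations (default 10000).
#' @param seed optional integer seed making the p-value reproducible.
#' @return a `circ_test` with `statistic` (V), `p_value`, `n_per_group`.
#' @export
kuiper_two_sample <- function(a, b, n_perm = 10000, seed = NULL) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  n1 <- length(a); n2 <- length(b)
  pool <- wrap360(c(a, b))
  ord <- order(pool)
  v <- pool[ord]
  grp <- cumsum(!duplicated(v))           # tie groups of sorted values
  lab <- c(rep(TRUE, n1), rep(FALSE, n2))[ord]
  no_ties <- grp[length(grp)] == n1 + n2
  vfun <- if (no_ties) {
    cst <- 1 / n1 + 1 / n2
    function(l) {            # fast path: no tied angles, plain cumsum
      d <- cumsum(l * cst - 1 / n2)
      max(d, 0) - min(d, 0)
    }
  } else {
    function(l) kuiper_V(l, grp, n1, n2)
  }
  V <- vfun(lab)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (vfun(sample(lab)) >= V - 1e-12) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (n_perm + 1)
  new_circ_test(V, NA, p, TRUE, "kuiper_two_sample_permutation", c(n1, n2),
                extra = list(n_perm = n_perm))
}

# maximum-likelihood von Mises concentration from a mean resultant length
# (Fisher's approximation)
a1inv <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams test for equality of mean directions
#'
#' One-way parametric test that `k` circular samples share a mean
#' direction, with the standard concentration correction factor
#' `1 + 3/(8 kappa)`. The test assumes reasonably concentrated von Mises
#' samples; following the field convention the result is flagged as not
#' applicable (but still reported) when the average of the groups' mean
#' resultant vector lengths is below 0.45.
#'
#' @param samples list of numeric vectors of angles in degrees (>= 2
#'   groups, each with >= 2 observations).
#' @param applicability_threshold minimum average mean vector length for
#'   the test to be considered interpretable (default 0.45).
#' @return a `circ_test` with `statistic` (F), `df = c(k - 1, N - k)`,
#'   `p_value`, `applicable`, and the per-group mean vectors.
#' @export
watson_williams <- function(samples, applicability_threshold = 0.45) {
  if (!is.list(samples) || length(samples) < 2)
    stop("watson_williams() needs a list of at least two groups")
  ns <- lengths(samples)
  if (any(ns < 2)) stop("every group needs at least two observations")
  k <- length(samples)
  N <- sum(ns)
  mvs <- lapply(samples, mean_vector)
  Ri <- vapply(seq_len(k), function(i) mvs[[i]]$length * ns[i], numeric(1))
  all_r <- deg2rad(unlist(samples))
  R <- sqrt(sum(cos(all_r))^2 + sum(sin(all_r))^2)
  rw <- sum(Ri) / N
  kappa <- a1inv(rw)
  K <- 1 + 3 / (8 * kappa)
  Fstat <- K * ((N - k) * (sum(Ri) - R)) / ((k - 1) * (N - sum(Ri)))
  p <- pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  applicable <- mean(vapply(mvs, `[[`, numeric(1), "length")) >=
    applicability_threshold
  if (!applicable)
    warning("Watson-Williams test not applicable: average mean vector length < ",
            applicability_threshold, call. = FALSE)
  new_circ_test(Fstat, c(k - 1, N - k), p, applicable, "watson_williams",
                ns, extra = list(mean_vectors = mvs, kappa = kappa,
                                 correction = K))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences. Zero differences are dropped; the
#' exact signed-rank distribution is used for `n <= 25` when the absolute
#' differences are free of ties, otherwise a normal approximation with tie
#' correction. If every difference is zero the result is flagged as
#' degenerate with `p_value = NA`.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n` (non-zero differences), `exact`, and `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0L,
                exact = FALSE, degenerate = TRUE,
                method = "wilcoxon_signed_rank"))
  }
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !has_ties) {
    p_less <- psignrank(W, n)
    p_greater <- psignrank(W - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_less, p_greater))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    exact <- FALSE
  }
  list(statistic = W, p_value = p, n = n, exact = exact, degenerate = FALSE,
       method = "wilcoxon_signed_rank")
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject F test for a complete subjects-by-conditions matrix.
#' Reports the uncorrected F with `df = (k - 1, (k - 1)(n - 1))`, the
#' Greenhouse-Geisser epsilon estimated from the double-centred covariance
#' of the condition scores, the corrected degrees of freedom and p-value,
#' and Bonferroni-corrected pairwise paired t-tests (multiplier = number of
#' pairs).
#'
#' @param mat numeric matrix, rows = subjects, columns = conditions.
#' @return list with `F`, `df`, `p_value`, `gg_epsilon`, `df_gg`,
#'   `p_value_gg`, and a `posthoc` data.frame.
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("rm_anova() requires a complete matrix (no missing cells)")
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2 || n < 2) stop("need at least 2 conditions and 2 subjects")
  grand <- mean(mat)
  col_m <- colMeans(mat); row_m <- rowMeans(mat)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  Fstat <- if (ms_err > 0) ms_cond / ms_err else if (ms_cond == 0) 0 else Inf
  p <- if (is.finite(Fstat)) pf(Fstat, df1, df2, lower.tail = FALSE) else 0
  if (Fstat == 0) p <- 1

  S <- cov(mat)
  A <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  denom <- (k - 1) * sum(A^2)
  eps <- if (denom < 1e-24) 1 else (sum(diag(A)))^2 / denom
  eps <- min(1, max(1 / (k - 1), eps))
  p_gg <- if (is.finite(Fstat)) {
    if (Fstat == 0) 1 else pf(Fstat, df1 * eps, df2 * eps, lower.tail = FALSE)
  } else 0

  cols <- colnames(mat) %||% paste0("c", seq_len(k))
  colnames(mat) <- cols
  pairs <- utils::combn(k, 2)
  npairs <- ncol(pairs)
  posthoc <- do.call(rbind, lapply(seq_len(npairs), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    dd <- mat[, i1] - mat[, i2]
    sdd <- stats::sd(dd)
    if (sdd < 1e-15) {
      tt <- 0; pr <- 1
    } else {
      tt <- mean(dd) / (sdd / sqrt(n))
      pr <- 2 * pt(-abs(tt), n - 1)
    }
    data.frame(pair = paste(cols[i1], cols[i2], sep = " vs "),
               t = tt, df = n - 1, p_raw = pr,
               p_bonferroni = min(1, pr * npairs),
               stringsAsFactors = FALSE)
  }))
  list(F = Fstat, df = c(df1, df2), p_value = p,
       gg_epsilon = eps, df_gg = c(df1 * eps, df2 * eps), p_value_gg = p_gg,
       ss = c(condition = ss_cond, subject = ss_subj, error = ss_err),
       n = n, k = k, posthoc = posthoc, method = "rm_anova_gg")
}
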