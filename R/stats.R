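# Group-level inference: t maps, repeated-measures ANOVA with post-hocs,
# covariate regression, and Benjamini-Hochberg FDR. All tests are
# vectorized over targets (voxels or network edges) and use the classical
# closed forms; permutation cluster-level FWE lives in cluster.R.

#' One-sample t-test per target
#'
#' `t = (mean - null_mean) / (sd / sqrt(n))`, df = n - 1, two-tailed p.
#' Zero-variance targets yield `NA` with a flag instead of a value.
#'
#' @param values Subjects x targets matrix (a vector is one target).
#' @param null_mean Null mean (default 0).
#' @return A tibble with `target`, `n`, `estimate` (mean), `t`, `df`, `p`,
#'   `flagged`.
#' @export
one_sample_t <- function(values, null_mean = 0) {
  x <- as.matrix(values)
  tn <- colnames(x)
  if (is.null(tn)) tn <- as.character(seq_len(ncol(x)))
  n <- unname(colSums(!is.na(x)))
  m <- unname(colMeans(x, na.rm = TRUE))
  s <- unname(apply(x, 2, stats::sd, na.rm = TRUE))
  tt <- (m - null_mean) / (s / sqrt(n))
  df <- n - 1
  bad <- n < 3 | s == 0 | is.na(s)
  tt[bad] <- NA_real_
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  tibble::tibble(
    target = tn, n = as.integer(n), estimate = m, t = tt,
    df = as.integer(df), p = p, flagged = bad
  )
}

#' Paired t-test per target
#'
#' One-sample t-test on within-subject differences `a - b`; df = n - 1.
#'
#' @param values_a,values_b Subjects x targets matrices with matching
#'   dimensions (rows = the same subjects).
#' @return As [one_sample_t()], with `estimate` the mean difference.
#' @export
paired_t <- function(values_a, values_b) {
  a <- as.matrix(values_a)
  b <- as.matrix(values_b)
  if (!all(dim(a) == dim(b))) {
    abort_bh("Paired inputs have mismatched subjects or targets.", "data_error")
  }
  d <- a - b
  colnames(d) <- colnames(a)
  one_sample_t(d)
}

#' One-way repeated-measures ANOVA per target
#'
#' Within-subject F test across conditions with the subject effect removed:
#' `F = MS_condition / MS_error` with df `(C - 1, (C - 1)(n - 1))` - for
#' three conditions, `(2, 2(n - 1))`. No sphericity correction by default
#' (`gg = TRUE` applies Greenhouse-Geisser).
#'
#' @param values Subjects x conditions matrix (one target), or a 3D array
#'   subjects x conditions x targets.
#' @param gg Apply the Greenhouse-Geisser sphericity correction to the
#'   degrees of freedom? Default `FALSE`.
#' @return A tibble with `target`, `F`, `df1`, `df2`, `p` (and `epsilon`
#'   when `gg = TRUE`).
#' @export
rm_anova <- function(values, gg = FALSE) {
  arr <- if (length(dim(values)) == 3L) values else array(as.matrix(values), c(dim(as.matrix(values)), 1L))
  n <- dim(arr)[1]; cc <- dim(arr)[2]; nt <- dim(arr)[3]
  if (anyNA(arr)) abort_bh("Repeated-measures design has missing cells.", "data_error")
  if (n < 3) abort_bh("Need at least 3 subjects.", "data_error")
  dn <- dimnames(values)
  tn <- if (length(dn) >= 3) dn[[3]] else NULL
  if (is.null(tn)) tn <- as.character(seq_len(nt))
  out <- vector("list", nt)
  for (k in seq_len(nt)) {
    y <- arr[, , k]
    gm <- mean(y)
    ss_cond <- n * sum((colMeans(y) - gm)^2)
    ss_subj <- cc * sum((rowMeans(y) - gm)^2)
    ss_tot <- sum((y - gm)^2)
    ss_err <- ss_tot - ss_cond - ss_subj
    df1 <- cc - 1
    df2 <- (cc - 1) * (n - 1)
    ms_cond <- ss_cond / df1
    ms_err <- ss_err / df2
    f <- if (ms_err <= 0) {
      if (ms_cond <= 1e-24) 0 else Inf
    } else {
      ms_cond / ms_err
    }
    eps <- 1
    if (gg) {
      # Greenhouse-Geisser epsilon from the double-centered covariance
      s <- stats::cov(y)
      sc <- sweep(sweep(s, 1, rowMeans(s)), 2, colMeans(s)) + mean(s)
      eps <- sum(diag(sc))^2 / ((cc - 1) * sum(sc^2))
      eps <- min(max(eps, 1 / (cc - 1)), 1)
    }
    p <- stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
    out[[k]] <- tibble::tibble(
      target = tn[k], F = f, df1 = df1 * eps, df2 = df2 * eps, p = p,
      epsilon = eps
    )
  }
  res <- dplyr::bind_rows(out)
  if (!gg) res$epsilon <- NULL
  res
}

#' Bonferroni-corrected pairwise post-hoc tests
#'
#' Paired t-tests on every condition pair, with p multiplied by the number
#' of pairs (3 for three conditions) and capped at 1. Run after a
#' significant repeated-measures ANOVA to identify the direction of the
#' differences.
#'
#' @param values Subjects x conditions matrix, or 3D array
#'   subjects x conditions x targets.
#' @param targets Optional target names/indices to restrict to (e.g. the
#'   ANOVA-significant ones).
#' @return A tibble with `target`, `pair`, `estimate`, `t`, `df`, `p`,
#'   `p_bonf`.
#' @export
posthoc_pairwise <- function(values, targets = NULL) {
  arr <- if (length(dim(values)) == 3L) values else array(as.matrix(values), c(dim(as.matrix(values)), 1L))
  nt <- dim(arr)[3]
  cn <- dimnames(arr)[[2]]
  if (is.null(cn)) cn <- paste0("cond", seq_len(dim(arr)[2]))
  dn <- dimnames(values)
  tn <- if (length(dn) >= 3) dn[[3]] else NULL
  if (is.null(tn)) tn <- as.character(seq_len(nt))
  kidx <- seq_len(nt)
  if (!is.null(targets)) {
    kidx <- if (is.character(targets)) match(targets, tn) else as.integer(targets)
  }
  pairs <- utils::combn(dim(arr)[2], 2)
  n_pairs <- ncol(pairs)
  res <- purrr::map_dfr(kidx, function(k) {
    purrr::map_dfr(seq_len(n_pairs), function(j) {
      a <- arr[, pairs[1, j], k]
      b <- arr[, pairs[2, j], k]
      tt <- one_sample_t(matrix(a - b, ncol = 1))
      tibble::tibble(
        target = tn[k],
        pair = paste(cn[pairs[1, j]], "vs", cn[pairs[2, j]]),
        estimate = tt$estimate, t = tt$t, df = tt$df, p = tt$p,
        p_bonf = pmin(tt$p * n_pairs, 1)
      )
    })
  })
  res
}

#' Per-target regression on a behavioural covariate
#'
#' Ordinary least squares of each target's values on a score plus an
#' intercept; reports the slope t statistic with df = n - 2. A perfect fit
#' is reported with `p = 0` and flagged (the t statistic is at machine
#' limits).
#'
#' @param maps Subjects x targets matrix.
#' @param score Numeric covariate, one value per subject.
#' @return A tibble with `target`, `slope`, `t`, `df`, `p`, `flagged`.
#' @export
regress_covariate <- function(maps, score) {
  x <- as.matrix(maps)
  tn <- colnames(x)
  if (is.null(tn)) tn <- as.character(seq_len(ncol(x)))
  n <- nrow(x)
  if (n < 4) abort_bh("Need at least 4 subjects.", "data_error")
  if (length(score) != n) abort_bh("Score length must equal subjects.", "data_error")
  if (stats::sd(score) == 0) abort_bh("Covariate is constant.", "data_error")
  sc <- score - mean(score)
  sxx <- sum(sc^2)
  xc <- sweep(x, 2, colMeans(x))
  slope <- as.vector(crossprod(sc, xc)) / sxx
  fitted <- outer(sc, slope)
  rss <- colSums((xc - fitted)^2)
  df <- n - 2
  se <- sqrt(rss / df / sxx)
  tt <- slope / se
  flagged <- se == 0
  tt[flagged] <- sign(slope[flagged]) * Inf
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  tibble::tibble(
    target = tn, slope = slope, t = tt, df = as.integer(df), p = p,
    flagged = flagged
  )
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR control across a family of tests (e.g. the 10 network
#' edges). Adjusted p-values are monotone non-decreasing in rank.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed,
#'   passed through).
#' @param q FDR level (default 0.05).
#' @return A tibble with `p`, `p_adjusted`, `significant`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) abort_bh("Empty p-value vector.", "data_error")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort_bh("p-values must lie in [0, 1].", "data_error")
  }
  adj <- rep(NA_real_, length(p_values))
  adj[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  tibble::tibble(
    p = p_values,
    p_adjusted = adj,
    significant = !is.na(adj) & adj <= q
  )
}
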