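#' Fisher r-to-z transformation
#'
#' Variance-stabilizing transform `z = atanh(r)` applied to correlation
#' coefficients before parametric testing. Correlations are clipped to
#' `(-1 + 1e-7, 1 - 1e-7)` so that perfect correlations map to a finite
#' ceiling instead of `Inf`.
#'
#' @param r Numeric vector of correlation coefficients in `[-1, 1]`.
#' @return Numeric vector of Fisher z values; strictly increasing in `r`,
#'   odd (`fisher_z(-r) == -fisher_z(r)`).
#' @examples
#' fisher_z(c(-0.5, 0, 0.5))
#' @export
fisher_z <- function(r) {
  stopifnot(is.numeric(r))
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

#' Derive a child RNG seed from a master seed
#'
#' Deterministic integer mixing so that every stochastic stage draws from
#' its own stream while the whole run is reproducible from one master seed.
#' Results stay below 2^31 - 1.
#'
#' @param seed Master seed (integer).
#' @param index Stream index (integer >= 0).
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647)
  x <- (s * 48271 + as.double(index) * 30269 + 11213) %% 2147483629
  as.integer(x %% 2147483399 + 1)
}

# Evaluate an expression with a locally-set RNG seed, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Pearson correlation of one reference series against the columns of a
# matrix, vectorized. Zero-variance columns give NA.
cor_vs_matrix <- function(ref, mat) {
  stopifnot(length(ref) == nrow(mat))
  rc <- ref - mean(ref)
  mc <- sweep(mat, 2, colMeans(mat))
  num <- as.vector(crossprod(rc, mc))
  den <- sqrt(sum(rc^2) * colSums(mc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

abort_bh <- function(msg, class) {
  rlang::abort(msg, class = paste0("brainheart_", class))
}
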