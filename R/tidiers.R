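# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an inter-network FC matrix into an edge table
#'
#' @param x An `fc_matrix`.
#' @param ... Unused.
#' @return A tibble with `net_a`, `net_b`, `r`, `z` (one row per edge).
#' @method tidy fc_matrix
#' @export
tidy.fc_matrix <- function(x, ...) {
  out <- x$edges
  if (!is.null(x$session_label)) out$session <- x$session_label
  out
}

#' Tidy a cluster table (drops map attributes, keeps the records)
#'
#' @param x A `cluster_table` from [cluster_inference()].
#' @param ... Unused.
#' @return A plain tibble of cluster records.
#' @method tidy cluster_table
#' @export
tidy.cluster_table <- function(x, ...) {
  out <- x
  attributes(out)[c("cdt_p", "cdt_t", "n_perm", "connectivity",
                    "stat_map", "null_max")] <- NULL
  class(out) <- setdiff(class(out), "cluster_table")
  tibble::as_tibble(out)
}

#' One-row summary of a cluster inference
#'
#' @param x A `cluster_table`.
#' @param ... Unused.
#' @return A tibble with the CDT, permutation count, cluster counts and the
#'   smallest attainable p.
#' @method glance cluster_table
#' @export
glance.cluster_table <- function(x, ...) {
  tibble::tibble(
    cdt_p = attr(x, "cdt_p"),
    cdt_t = attr(x, "cdt_t"),
    n_perm = attr(x, "n_perm"),
    connectivity = attr(x, "connectivity"),
    n_clusters = nrow(x),
    n_significant = sum(x$significant),
    p_floor = 1 / (attr(x, "n_perm") + 1)
  )
}

#' One-row summary of an ICA decomposition
#'
#' @param x An `ic_decomposition`.
#' @param ... Unused.
#' @return A tibble with component count, iterations, convergence and
#'   kurtosis range.
#' @method glance ic_decomposition
#' @export
glance.ic_decomposition <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$sources),
    n_iter = x$n_iter,
    converged = x$converged,
    final_change = x$final_change,
    min_abs_kurtosis = min(abs(x$kurtosis)),
    low_kurtosis = x$low_kurtosis
  )
}
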