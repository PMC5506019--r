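# Temporal-concatenation group ICA (TC-GICA) with dual regression.
#
# Pipeline: per-subject temporal PCA of the concatenated sessions (750
# volumes -> 30 components), temporal concatenation across subjects
# (30 x N rows), group PCA/whitening to 20 dimensions, extended-infomax
# unmixing into 20 spatial components, dual regression back to
# subject-specific time courses and maps, and template matching to pick the
# five networks of interest.

#' Per-subject temporal PCA
#'
#' Reduces a subject's concatenated preprocessed sessions (time x voxels)
#' to the top `n_pcs` temporal principal components. Components (left
#' singular vectors) are mutually orthonormal; the reduced data are the
#' corresponding voxel loadings, one row per component.
#'
#' @param sessions List of preprocessed `ts_img`s (or time x voxel
#'   matrices) to concatenate in time.
#' @param n_pcs Number of components (default 30).
#' @return A `subject_pcs`: list with `components` (time x n_pcs,
#'   orthonormal), `reduced` (n_pcs x voxels), `variance_explained`,
#'   `n_volumes`.
#' @export
subject_pca <- function(sessions, n_pcs = 30L) {
  mats <- lapply(sessions, function(s) {
    if (inherits(s, "ts_img")) t(as_voxel_matrix(s)) else as.matrix(s)
  })
  x <- do.call(rbind, mats)
  if (n_pcs >= min(dim(x))) {
    abort_bh(
      sprintf("n_pcs (%d) must be below min(volumes, voxels) = %d.",
              n_pcs, min(dim(x))),
      "config_error"
    )
  }
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x, nu = n_pcs, nv = 0)
  d2 <- sv$d^2
  structure(
    list(
      components = sv$u,
      reduced = t(sv$u) %*% x,
      variance_explained = sum(d2[seq_len(n_pcs)]) / sum(d2),
      n_volumes = nrow(x)
    ),
    class = "subject_pcs"
  )
}

#' Temporally concatenate subject components
#'
#' @param all_subjects List of `subject_pcs`.
#' @return Matrix with `sum(n_pcs)` rows (e.g. 30 components x 32 subjects
#'   = 960) and one column per voxel.
#' @export
concatenate_pcs <- function(all_subjects) {
  ncols <- vapply(all_subjects, function(s) ncol(s$reduced), integer(1))
  nrows <- vapply(all_subjects, function(s) nrow(s$reduced), integer(1))
  if (length(unique(ncols)) != 1L || length(unique(nrows)) != 1L) {
    abort_bh("Subjects have mismatched component dimensions.", "data_error")
  }
  do.call(rbind, lapply(all_subjects, function(s) s$reduced))
}

#' Group PCA and whitening
#'
#' Projects the concatenated matrix onto its top `n_dims` principal
#' directions and rescales so the output rows have identity covariance
#' across voxels. Returns the unwhitening transform for reconstruction.
#'
#' @param group_matrix Rows x voxels matrix from [concatenate_pcs()].
#' @param n_dims Retained dimensions (default 20).
#' @return List with `whitened` (n_dims x voxels, identity covariance),
#'   `unwhiten` (rows x n_dims), `row_means`, `sdev`.
#' @export
group_pca_whiten <- function(group_matrix, n_dims = 20L) {
  x <- as.matrix(group_matrix)
  if (n_dims > nrow(x)) {
    abort_bh("n_dims exceeds the number of rows.", "config_error")
  }
  mu <- rowMeans(x)
  xc <- x - mu
  sv <- svd(xc, nu = n_dims, nv = n_dims)
  if (sv$d[n_dims] < max(sv$d) * 1e-10) {
    abort_bh(
      sprintf("Covariance is degenerate at %d dimensions (rank < n_dims).", n_dims),
      "data_error"
    )
  }
  nv <- ncol(x)
  whitened <- sqrt(nv - 1) * t(sv$v[, seq_len(n_dims), drop = FALSE])
  unwhiten <- sv$u[, seq_len(n_dims), drop = FALSE] %*%
    diag(sv$d[seq_len(n_dims)] / sqrt(nv - 1), n_dims)
  list(whitened = whitened, unwhiten = unwhiten, row_means = mu, sdev = sv$d)
}

#' Extended infomax independent component analysis
#'
#' Unmixes whitened data into independent spatial sources by infomax with
#' natural-gradient updates and an annealed learning rate:
#' `W <- W + lr * (I - phi(u) u'/V) W`, with the hyperbolic-tangent score
#' `phi(u) = tanh(u)` for super-Gaussian sources, switching to the
#' sub-Gaussian score `phi(u) = u - tanh(u)` for sources whose running
#' kurtosis estimate is negative (the extended sub/super switch). Deterministic for a fixed seed (random orthogonal
#' initialization). Components are reported with unit variance and
#' non-negative skewness; an all-Gaussian input (non-identifiable) is
#' surfaced as a `low_kurtosis` flag with a warning rather than silent
#' success.
#'
#' Infomax, like any ICA, has local optima; `n_restarts` runs are started
#' from different seeded random orthogonal matrices and the solution with
#' the highest infomax objective (`log|det W|` plus the mean source
#' log-density) is kept, which makes the decomposition robust to an
#' occasional bad basin.
#'
#' @param whitened n_components x voxels matrix from [group_pca_whiten()].
#' @param seed Integer seed (restart seeds derive from it).
#' @param max_iter Maximum iterations (default 2048).
#' @param tol Convergence tolerance on the weight-change Frobenius norm
#'   (default 1e-6).
#' @param lr Initial learning rate.
#' @param n_restarts Independent restarts (default 4).
#' @return An `ic_decomposition`: list with `sources` (components x voxels,
#'   unit variance, skew >= 0), `unmixing` (W), `mixing` (for the whitened
#'   space), `kurtosis`, `low_kurtosis`, `n_iter`, `converged`,
#'   `final_change`, `objective`, `restart_objectives`.
#' @export
infomax_ica <- function(whitened, seed = 1L, max_iter = 2048L, tol = 1e-6,
                        lr = 0.3, n_restarts = 4L) {
  x <- as.matrix(whitened)
  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    runs[[r]] <- tryCatch(
      infomax_once(x, derive_seed(seed, r), max_iter, tol, lr),
      brainheart_non_convergence = function(e) e
    )
  }
  ok <- !vapply(runs, inherits, logical(1), "condition")
  if (!any(ok)) stop(runs[[1]])
  objs <- vapply(runs[ok], `[[`, numeric(1), "objective")
  best <- runs[ok][[which.max(objs)]]
  best$restart_objectives <- objs
  if (best$low_kurtosis) {
    warning(
      "All sources have near-zero kurtosis: Gaussian sources are not ",
      "identifiable by ICA.",
      call. = FALSE
    )
  }
  best$seed <- as.integer(seed)
  best
}

infomax_once <- function(x, seed, max_iter, tol, lr) {
  n <- nrow(x)
  v <- ncol(x)
  W <- with_seed(seed, {
    m <- matrix(stats::rnorm(n * n), n, n)
    qr.Q(qr(m))
  })
  I_n <- diag(n)
  K <- rep(1, n)
  change <- Inf
  last_dw <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    u <- W %*% x
    # re-estimate each source's sub/super-Gaussianity every few iterations;
    # the sub-Gaussian branch engages only for decisively negative excess
    # kurtosis so that transient mixtures keep the super-Gaussian score
    if (it %% 5L == 1L) {
      m2 <- rowMeans(u^2)
      K <- ifelse(rowMeans(u^4) / (m2^2) - 3 < -0.5, -1, 1)
    }
    phi <- tanh(u)
    if (any(K < 0)) {
      sub <- which(K < 0)
      phi[sub, ] <- u[sub, , drop = FALSE] - tanh(u[sub, , drop = FALSE])
    }
    grad <- (I_n - tcrossprod(phi, u) / v) %*% W
    dW <- lr * grad
    change <- sqrt(sum(dW^2))
    if (!is.finite(change)) {
      abort_bh("Infomax diverged; lower the learning rate.", "non_convergence")
    }
    # anneal: sharply when the update direction swings by more than 60
    # degrees, and on a slow schedule after a warmup so the weights freeze
    # once the sources have stabilized
    if (!is.null(last_dw)) {
      cosang <- sum(dW * last_dw) / sqrt(sum(dW^2) * sum(last_dw^2) + 1e-30)
      if (cosang < 0.5) lr <- lr * 0.9
    }
    if (it > 512L) lr <- lr * 0.99
    last_dw <- dW
    W <- W + dW
    if (change < tol) break
  }
  if (change >= tol) {
    abort_bh(
      sprintf("Infomax did not converge in %d iterations (last update norm %.3g).",
              max_iter, change),
      "non_convergence"
    )
  }
  s <- W %*% x
  # infomax objective of the converged solution: log|det W| plus each
  # source's mean log-density under the better of the two normalized source
  # models (sech density for super-Gaussian, two-Gaussian mixture
  # exp(-u^2/2)cosh(u) for sub-Gaussian); normalization constants make the
  # two branches comparable across solutions
  obj_terms <- vapply(seq_len(n), function(i) {
    z <- s[i, ]
    sup <- -mean(log(cosh(z))) - log(pi)
    sub <- mean(-z^2 / 2 + log(cosh(z))) - 0.5 * log(2 * pi) - 0.5
    max(sup, sub)
  }, numeric(1))
  objective <- as.numeric(determinant(W, logarithm = TRUE)$modulus) +
    sum(obj_terms)
  # fixed reporting convention: unit variance, non-negative skewness
  sdv <- apply(s, 1, stats::sd)
  s <- s / sdv
  sk <- apply(s, 1, function(z) mean((z - mean(z))^3))
  flip <- ifelse(sk < 0, -1, 1)
  s <- s * flip
  W <- diag(flip / sdv) %*% W
  kur <- apply(s, 1, function(z) mean((z - mean(z))^4) / stats::var(z)^2 - 3)
  structure(
    list(
      sources = s, unmixing = W, mixing = solve(W), kurtosis = kur,
      low_kurtosis = all(abs(kur) < 0.5), n_iter = it, converged = TRUE,
      final_change = change, objective = objective, seed = as.integer(seed)
    ),
    class = "ic_decomposition"
  )
}

#' @export
print.ic_decomposition <- function(x, ...) {
  cat(sprintf(
    "<ic_decomposition> %d components over %d voxels; converged in %d iterations%s\n",
    nrow(x$sources), ncol(x$sources), x$n_iter,
    if (x$low_kurtosis) " [low kurtosis]" else ""
  ))
  invisible(x)
}

#' Dual regression
#'
#' Stage 1 regresses each volume on the (variance-normalized) group spatial
#' maps across voxels, giving per-component subject time courses. Stage 2
#' regresses each voxel's series on those time courses across time, giving
#' subject-specific spatial maps. Exact (machine precision) when the data
#' are a noiseless mixture of orthogonal maps.
#'
#' @param img A subject-session `ts_img` (or a time x voxels matrix).
#' @param group_maps Components x voxels matrix.
#' @return List with `timecourses` (time x components) and `maps`
#'   (components x voxels).
#' @export
dual_regression <- function(img, group_maps) {
  x <- if (inherits(img, "ts_img")) t(as_voxel_matrix(img)) else as.matrix(img)
  m <- as.matrix(group_maps)
  if (ncol(x) != ncol(m)) {
    abort_bh("Image and group maps disagree on the number of voxels.", "data_error")
  }
  m_norm <- m / apply(m, 1, stats::sd)
  d1 <- t(m_norm)
  q1 <- qr(d1)
  if (q1$rank < ncol(d1)) {
    abort_bh("Group maps are rank deficient over the mask.", "data_error")
  }
  tc <- t(qr.coef(q1, t(x)))          # time x components
  q2 <- qr(tc)
  if (q2$rank < ncol(tc)) {
    abort_bh("Stage-1 time courses are rank deficient.", "data_error")
  }
  maps <- qr.coef(q2, x)              # components x voxels
  list(timecourses = tc, maps = maps)
}

#' Match components to network templates
#'
#' Finds the injective assignment of templates to components that maximizes
#' the total absolute spatial correlation (exact search with branch-and-
#' bound pruning; trivial at 5 templates x 20 components). The correlation
#' sign is recorded so anti-correlated matches can be flipped downstream.
#'
#' @param ic_maps Components x voxels matrix.
#' @param templates Named list or matrix (templates x voxels) of template
#'   maps; on synthetic data, the atlas network masks.
#' @param floor Minimum acceptable |correlation| per template (default
#'   0.2); an assignment below the floor is an error.
#' @return A tibble with `template`, `component`, `correlation` (signed),
#'   `abs_correlation`.
#' @export
match_templates <- function(ic_maps, templates, floor = 0.2) {
  tm <- if (is.list(templates)) {
    do.call(rbind, lapply(templates, as.numeric))
  } else {
    as.matrix(templates)
  }
  tnames <- if (!is.null(rownames(tm))) rownames(tm) else paste0("template", seq_len(nrow(tm)))
  if (nrow(ic_maps) < nrow(tm)) {
    abort_bh("Fewer components than templates.", "data_error")
  }
  cmat <- stats::cor(t(tm), t(ic_maps)) # templates x components
  acm <- abs(cmat)
  nt <- nrow(acm); nc <- ncol(acm)
  best <- list(score = -Inf, assign = NULL)
  row_max <- apply(acm, 1, max)
  search <- function(row, used, score, assign) {
    if (row > nt) {
      if (score > best$score) best <<- list(score = score, assign = assign)
      return(invisible(NULL))
    }
    if (score + sum(row_max[row:nt]) <= best$score) return(invisible(NULL))
    ord <- order(acm[row, ], decreasing = TRUE)
    for (j in ord) {
      if (used[j]) next
      used[j] <- TRUE
      search(row + 1L, used, score + acm[row, j], c(assign, j))
      used[j] <- FALSE
    }
  }
  search(1L, rep(FALSE, nc), 0, integer(0))
  sel <- best$assign
  out <- tibble::tibble(
    template = tnames,
    component = sel,
    correlation = cmat[cbind(seq_len(nt), sel)],
    abs_correlation = acm[cbind(seq_len(nt), sel)]
  )
  if (any(out$abs_correlation < floor)) {
    bad <- out$template[out$abs_correlation < floor]
    abort_bh(
      sprintf("Unmatched network(s) below the correlation floor: %s.",
              paste(bad, collapse = ", ")),
      "unmatched_network"
    )
  }
  out
}

#' Inter-network functional connectivity matrix
#'
#' Pairwise Pearson correlations between matched network time courses,
#' Fisher z transformed, as a symmetric matrix plus a tidy edge table.
#'
#' @param timecourses Time x networks matrix (stage-1 dual-regression time
#'   courses for the matched components).
#' @param labels Network names (default column names).
#' @param session_label Optional label stored on the result.
#' @return An `fc_matrix`: list with `z` (symmetric matrix, `NA` diagonal),
#'   `edges` (tibble `net_a`, `net_b`, `r`, `z`), `labels`,
#'   `session_label`.
#' @export
internetwork_fc <- function(timecourses, labels = colnames(timecourses),
                            session_label = NULL) {
  tc <- as.matrix(timecourses)
  if (nrow(tc) < 3) abort_bh("Need at least 3 time points.", "data_error")
  if (is.null(labels)) labels <- paste0("net", seq_len(ncol(tc)))
  sds <- apply(tc, 2, stats::sd)
  if (any(sds == 0)) {
    abort_bh(
      sprintf("Constant time course for network(s): %s.",
              paste(labels[sds == 0], collapse = ", ")),
      "data_error"
    )
  }
  r <- stats::cor(tc)
  z <- fisher_z(r)
  diag(z) <- NA_real_
  dimnames(z) <- list(labels, labels)
  pairs <- utils::combn(seq_along(labels), 2)
  edges <- tibble::tibble(
    net_a = labels[pairs[1, ]],
    net_b = labels[pairs[2, ]],
    r = r[t(pairs)],
    z = z[t(pairs)]
  )
  structure(
    list(z = z, edges = edges, labels = labels, session_label = session_label),
    class = "fc_matrix"
  )
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf(
    "<fc_matrix> %d networks%s\n", length(x$labels),
    if (is.null(x$session_label)) "" else paste0(" [", x$session_label, "]")
  ))
  print(round(x$z, 3))
  invisible(x)
}

#' Run temporal-concatenation group ICA on a cohort of preprocessed images
#'
#' @param subject_sessions List (one element per subject) of lists of
#'   preprocessed `ts_img`s (or time x voxel matrices).
#' @param n_pcs First-level components per subject (default 30).
#' @param n_ics Group components (default 20).
#' @param seed Integer seed for the infomax initialization.
#' @param ... Passed to [infomax_ica()].
#' @return List with `subject_pcs`, `whitening`, `ica`, `group_maps`
#'   (n_ics x voxels), and `dual` (per subject: stage-1 time courses per
#'   session and stage-2 maps).
#' @export
run_group_ica <- function(subject_sessions, n_pcs = 30L, n_ics = 20L,
                          seed = 1L, ...) {
  pcs <- lapply(subject_sessions, subject_pca, n_pcs = n_pcs)
  grp <- concatenate_pcs(pcs)
  wh <- group_pca_whiten(grp, n_dims = n_ics)
  ica <- infomax_ica(wh$whitened, seed = seed, ...)
  dual <- lapply(subject_sessions, function(sessions) {
    per_session <- lapply(sessions, dual_regression, group_maps = ica$sources)
    all_tc <- do.call(rbind, lapply(per_session, `[[`, "timecourses"))
    maps <- dual_regression(
      do.call(rbind, lapply(sessions, function(s) {
        if (inherits(s, "ts_img")) t(as_voxel_matrix(s)) else as.matrix(s)
      })),
      ica$sources
    )$maps
    list(session_timecourses = lapply(per_session, `[[`, "timecourses"),
         timecourses = all_tc, maps = maps)
  })
  list(
    subject_pcs = pcs, whitening = wh, ica = ica,
    group_maps = ica$sources, dual = dual
  )
}
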