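test_that("subject PCA captures exact low rank and returns orthonormal components", {
  set.seed(2)
  base <- matrix(rnorm(3 * 60), 60, 3) %*% matrix(rnorm(3 * 40), 3, 40)
  pcs <- subject_pca(list(base), n_pcs = 3)
  expect_equal(pcs$variance_explained, 1, tolerance = 1e-10)
  gram <- crossprod(pcs$components)
  expect_equal(gram, diag(3), tolerance = 1e-8)
  expect_error(
    subject_pca(list(base), n_pcs = 45),
    class = "brainheart_config_error"
  )
})

test_that("temporal concatenation stacks subject components", {
  set.seed(3)
  mk <- function() subject_pca(list(matrix(rnorm(50 * 30), 50)), n_pcs = 3)
  subs <- replicate(2, mk(), simplify = FALSE)
  expect_equal(nrow(concatenate_pcs(subs)), 6L)
  bad <- c(subs, list(subject_pca(list(matrix(rnorm(50 * 30), 50)), n_pcs = 4)))
  expect_error(concatenate_pcs(bad), class = "brainheart_data_error")
})

test_that("whitening yields identity covariance and an exact round trip", {
  set.seed(4)
  x <- matrix(rnorm(40 * 500), 40)
  wh <- group_pca_whiten(x, 20)
  cv <- tcrossprod(wh$whitened) / (ncol(x) - 1)
  expect_equal(cv, diag(20), tolerance = 1e-6)
  # reconstruction equals the projection of x onto the top-20 subspace
  xc <- x - rowMeans(x)
  sv <- svd(xc)
  proj <- sv$u[, 1:20] %*% diag(sv$d[1:20]) %*% t(sv$v[, 1:20])
  expect_equal(wh$unwhiten %*% wh$whitened, proj, tolerance = 1e-8)
  lowrank <- matrix(rnorm(5 * 500), 5)
  expect_error(
    group_pca_whiten(rbind(lowrank, lowrank, lowrank, lowrank), 20),
    class = "brainheart_data_error"
  )
})

test_that("infomax recovers super-Gaussian sources up to sign and order", {
  set.seed(9)
  S <- matrix(sign(rnorm(3 * 2000)) * rexp(3 * 2000), 3)
  X <- matrix(rnorm(9), 3) %*% S
  ic <- infomax_ica(group_pca_whiten(X, 3)$whitened, seed = 2)
  cm <- abs(cor(t(ic$sources), t(S)))
  # assignment by maximum absolute correlation
  expect_true(all(apply(cm, 2, max) > 0.95))
  expect_false(ic$low_kurtosis)
  # determinism under a fixed seed
  ic2 <- infomax_ica(group_pca_whiten(X, 3)$whitened, seed = 2)
  expect_identical(ic$sources, ic2$sources)
  # sign convention: non-negative skewness per source
  sk <- apply(ic$sources, 1, function(z) mean((z - mean(z))^3))
  expect_true(all(sk >= 0))
})

test_that("Gaussian-only inputs surface non-identifiability, not silence", {
  set.seed(12)
  G <- matrix(rnorm(3 * 2000), 3)
  expect_warning(
    ic <- infomax_ica(group_pca_whiten(G, 3)$whitened, seed = 1),
    "kurtosis"
  )
  expect_true(ic$low_kurtosis)
})

test_that("dual regression is exact for noiseless orthogonal mixtures", {
  set.seed(6)
  maps <- matrix(0, 3, 300)
  maps[1, 1:100] <- rnorm(100)
  maps[2, 101:200] <- rnorm(100)
  maps[3, 201:300] <- rnorm(100)
  tc <- matrix(rnorm(150 * 3), 150)
  x <- tc %*% maps
  dr <- dual_regression(x, maps)
  # stage 1 recovers the time courses in the normalized-map scale
  sc <- apply(maps, 1, sd)
  expect_equal(sweep(dr$timecourses, 2, sc, `/`), tc, tolerance = 1e-10)
  # stage 2 returns the maps in that same scale
  expect_equal(dr$maps, maps / sc, tolerance = 1e-10)
  # with noise, time courses stay highly correlated with the truth
  xn <- x + matrix(rnorm(length(x), sd = 0.1), nrow(x))
  drn <- dual_regression(xn, maps)
  for (k in 1:3) expect_gt(cor(drn$timecourses[, k], tc[, k]), 0.95)
  # permutation equivariance
  drp <- dual_regression(x, maps[c(2, 3, 1), ])
  expect_equal(drp$timecourses, dr$timecourses[, c(2, 3, 1)], tolerance = 1e-10)
  expect_equal(drp$maps, dr$maps[c(2, 3, 1), ], tolerance = 1e-10)
})

test_that("template matching is exact, sign-aware and floor-guarded", {
  set.seed(8)
  maps <- matrix(rnorm(20 * 400), 20)
  templates <- maps[c(3, 7, 11, 15, 19), ]
  rownames(templates) <- paste0("net", 1:5)
  m <- match_templates(maps, templates)
  expect_equal(m$component, c(3L, 7L, 11L, 15L, 19L))
  expect_equal(m$correlation, rep(1, 5), tolerance = 1e-12)
  # sign flips keep the assignment and record the negative correlation
  mf <- match_templates(maps, -templates)
  expect_equal(mf$component, c(3L, 7L, 11L, 15L, 19L))
  expect_equal(mf$correlation, rep(-1, 5), tolerance = 1e-12)
  expect_true(all(!duplicated(m$component)))
  expect_error(
    match_templates(maps, matrix(rnorm(5 * 400), 5), floor = 0.9),
    class = "brainheart_unmatched_network"
  )
})

test_that("inter-network FC is a symmetric Fisher-z edge table", {
  set.seed(10)
  tc <- matrix(rnorm(150 * 3), 150)
  tc[, 2] <- tc[, 1] # identical pair -> clip ceiling
  fc <- internetwork_fc(tc, labels = c("a", "b", "c"))
  expect_equal(fc$z["a", "b"], fisher_z(1))
  expect_equal(fc$z, t(fc$z))
  expect_equal(nrow(fc$edges), 3L)
  expect_true(all(is.na(diag(fc$z))))
  tc[, 3] <- 5
  expect_error(
    internetwork_fc(tc, labels = c("a", "b", "c")),
    class = "brainheart_data_error"
  )
  expect_error(
    internetwork_fc(tc, labels = c("a", "b", "c")),
    regexp = "c"
  )
})

test_that("independent network time courses give null inter-network z", {
  set.seed(14)
  z <- replicate(500, {
    fc <- internetwork_fc(matrix(rnorm(150 * 2), 150), labels = c("a", "b"))
    fc$edges$z
  })
  expect_gte(mean(abs(z) < 0.3), 0.99)
})
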