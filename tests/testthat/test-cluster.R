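test_that("cluster labelling matches a brute-force flood fill", {
  # two separated blobs of 5 and 3 voxels
  mask <- array(FALSE, c(6, 6, 4))
  mask[1:5, 1, 1] <- TRUE
  mask[4:6, 6, 4] <- TRUE
  lab <- label_clusters(mask, 18)
  expect_equal(sort(tabulate(lab[lab > 0])), c(3L, 5L))
  expect_equal(max(lab), 2L)
  # random masks against the igraph oracle, all three connectivity rules
  set.seed(50)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:3) {
      m <- array(runif(5 * 5 * 5) < 0.3, c(5, 5, 5))
      lab <- label_clusters(m, conn)
      sizes <- sort(tabulate(lab[lab > 0]))
      oracle <- sort(igraph_components(m, conn))
      expect_equal(sizes, as.integer(oracle))
    }
  }
  expect_equal(max(label_clusters(array(FALSE, c(3, 3, 3)))), 0L)
})

test_that("stronger connectivity rules merge diagonal neighbours", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE
  m[2, 2, 1] <- TRUE # face-diagonal: 18 and 26 connect, 6 does not
  expect_equal(max(label_clusters(m, 6)), 2L)
  expect_equal(max(label_clusters(m, 18)), 1L)
  m2 <- array(FALSE, c(3, 3, 3))
  m2[1, 1, 1] <- TRUE
  m2[2, 2, 2] <- TRUE # full diagonal: only 26 connects
  expect_equal(max(label_clusters(m2, 18)), 2L)
  expect_equal(max(label_clusters(m2, 26)), 1L)
})

test_that("permutation p-values respect the floor and detect real clusters", {
  set.seed(51)
  # n = 40 subjects: partial sign flips wash the effect out, so no
  # permutation can reproduce the 8-voxel cluster
  dat <- matrix(rnorm(40 * 216), 40, 216)
  dat[, 1:8] <- dat[, 1:8] + 2.5 # one 8-voxel effect (a 2x2x2 corner block)
  ct <- cluster_inference(
    dat, c(6, 6, 6),
    scheme = "sign_flip", cdt_p = 0.01, n_perm = 99, seed = 5
  )
  expect_gte(nrow(ct), 1L)
  top <- ct[1, ]
  expect_equal(top$n_voxels, 8L)
  expect_true(top$significant)
  # observed max larger than every permutation max -> p at the floor
  expect_lt(max(attr(ct, "null_max")), 8)
  expect_equal(top$p_fwe, 1 / 100)
  expect_true(all(ct$p_fwe >= 1 / 100))
  # the reported p matches the permutation formula for every cluster
  expect_equal(
    ct$p_fwe,
    vapply(ct$n_voxels, function(s) {
      (1 + sum(attr(ct, "null_max") >= s)) / 100
    }, numeric(1))
  )
})

test_that("permutation inference is invariant to subject relabelling", {
  set.seed(52)
  dat <- matrix(rnorm(10 * 125), 10, 125)
  dat[, 1:5] <- dat[, 1:5] + 1.5
  a <- cluster_inference(dat, c(5, 5, 5), "sign_flip", cdt_p = 0.01,
                         n_perm = 99, seed = 7)
  b <- cluster_inference(dat[sample(10), ], c(5, 5, 5), "sign_flip",
                         cdt_p = 0.01, n_perm = 99, seed = 7)
  expect_equal(a$n_voxels, b$n_voxels)
  expect_equal(attr(a, "stat_map"), attr(b, "stat_map"), tolerance = 1e-10)
})

test_that("condition swaps and score permutation schemes run their designs", {
  set.seed(53)
  a <- matrix(rnorm(10 * 125), 10, 125)
  b <- a + matrix(rnorm(10 * 125, sd = 0.2), 10, 125)
  b[, 1:6] <- b[, 1:6] - 1.5
  ct <- cluster_inference(a, c(5, 5, 5), "condition_swap", data_b = b,
                          cdt_p = 0.01, n_perm = 99, seed = 9)
  expect_gte(sum(ct$significant), 1L)
  expect_error(
    cluster_inference(a, c(5, 5, 5), "condition_swap", cdt_p = 0.01,
                      n_perm = 99),
    class = "brainheart_config_error"
  )
  score <- rnorm(10)
  maps <- matrix(rnorm(10 * 125), 10, 125)
  maps[, 1:6] <- maps[, 1:6] + 2 * score
  cs <- cluster_inference(maps, c(5, 5, 5), "score_permute", score = score,
                          cdt_p = 0.01, n_perm = 99, seed = 11)
  expect_gte(sum(cs$significant), 1L)
  expect_error(
    cluster_inference(maps, c(5, 5, 5), "score_permute", cdt_p = 0.01,
                      n_perm = 99),
    class = "brainheart_config_error"
  )
  expect_error(
    cluster_inference(maps, c(5, 5, 5), "sign_flip", n_perm = 50),
    class = "brainheart_config_error"
  )
})

test_that("negative effects form negative-sign clusters", {
  set.seed(54)
  dat <- matrix(rnorm(12 * 125), 12, 125)
  dat[, 20:27] <- dat[, 20:27] - 2.5
  ct <- cluster_inference(dat, c(5, 5, 5), "sign_flip", cdt_p = 0.01,
                          n_perm = 99, seed = 13)
  expect_true(any(ct$sign == "negative" & ct$significant))
})
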