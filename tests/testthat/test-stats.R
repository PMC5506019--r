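test_that("one-sample t matches the closed form and stats::t.test", {
  r <- one_sample_t(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$t, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2L)
  tt <- t.test(c(1, 2, 3))
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  # symmetric values about zero
  expect_equal(one_sample_t(matrix(c(-2, -1, 1, 2), ncol = 1))$t, 0)
  # zero variance flags instead of inventing a value
  zv <- one_sample_t(matrix(c(5, 5, 5), ncol = 1))
  expect_true(zv$flagged)
  expect_true(is.na(zv$t))
})

test_that("paired t is the one-sample t on differences", {
  a <- matrix(c(4, 5, 6), ncol = 1)
  b <- matrix(c(3, 3, 3), ncol = 1)
  r <- paired_t(a, b)
  expect_equal(r$t, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2L)
  tt <- t.test(a[, 1], b[, 1], paired = TRUE)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-10)
  same <- paired_t(a, a)
  expect_true(is.na(same$t) || same$t == 0) # zero-variance differences flagged
  expect_error(paired_t(a, b[1:2, , drop = FALSE]), class = "brainheart_data_error")
})

test_that("repeated-measures ANOVA matches the sum-of-squares oracle and aov", {
  y <- matrix(
    c(
      5.1, 6.0, 5.5,
      4.2, 5.1, 4.9,
      6.3, 7.2, 6.4,
      5.0, 5.8, 5.9
    ),
    nrow = 4, byrow = TRUE
  )
  r <- rm_anova(y)
  # independent oracle: explicit sum-of-squares decomposition
  gm <- mean(y)
  ss_cond <- 4 * sum((colMeans(y) - gm)^2)
  ss_subj <- 3 * sum((rowMeans(y) - gm)^2)
  ss_err <- sum((y - gm)^2) - ss_cond - ss_subj
  f_oracle <- (ss_cond / 2) / (ss_err / 6)
  expect_equal(r$F, f_oracle, tolerance = 1e-10)
  expect_equal(r$df1, 2)
  expect_equal(r$df2, 6)
  # cross-check against stats::aov
  d <- data.frame(
    y = as.vector(y),
    subj = factor(rep(1:4, 3)),
    cond = factor(rep(1:3, each = 4))
  )
  a <- summary(aov(y ~ cond + Error(subj / cond), data = d))
  f_aov <- a[["Error: subj:cond"]][[1]]$`F value`[1]
  expect_equal(r$F, f_aov, tolerance = 1e-10)
  # identical condition means per subject -> F = 0
  flat <- matrix(rep(c(1, 2, 3, 4), 3), 4)
  expect_equal(rm_anova(flat)$F, 0)
  # adding a constant to one subject's conditions leaves F unchanged
  y2 <- y; y2[2, ] <- y2[2, ] + 10
  expect_equal(rm_anova(y2)$F, r$F, tolerance = 1e-10)
  y_na <- y; y_na[1, 1] <- NA
  expect_error(rm_anova(y_na), class = "brainheart_data_error")
})

test_that("post-hoc pairwise tests apply the Bonferroni factor of three", {
  set.seed(40)
  y <- matrix(rnorm(30), 10, 3)
  ph <- posthoc_pairwise(y)
  expect_equal(nrow(ph), 3L)
  expect_equal(ph$p_bonf, pmin(ph$p * 3, 1))
  expect_true(all(ph$p_bonf <= 1))
  # raw p of 0.01 -> 0.03; raw 0.5 -> capped at 1
  expect_equal(min(ph$p * 3, 1), ph$p_bonf[which.min(ph$p)])
})

test_that("covariate regression matches lm and flags perfect fits", {
  set.seed(41)
  score <- rnorm(12)
  maps <- cbind(2 * score, 2 * score + rnorm(12, sd = 0.3))
  r <- regress_covariate(maps, score)
  expect_equal(r$slope[1], 2, tolerance = 1e-12)
  expect_true(r$flagged[1])
  expect_equal(r$p[1], 0)
  lf <- summary(lm(maps[, 2] ~ score))
  expect_equal(r$slope[2], coef(lf)[2, 1], tolerance = 1e-10)
  expect_equal(r$t[2], coef(lf)[2, 3], tolerance = 1e-10)
  expect_equal(r$df[2], 10L)
  expect_error(
    regress_covariate(maps, rep(1, 12)),
    class = "brainheart_data_error"
  )
  # permuted scores give slopes centred on zero
  set.seed(42)
  tvals <- replicate(200, {
    regress_covariate(maps[, 2, drop = FALSE], sample(score))$t
  })
  expect_lt(abs(mean(tvals)), 0.3)
})

test_that("Benjamini-Hochberg matches hand step-up enumeration", {
  # step-up: reject all i <= max{ i : p(i) <= i q / m }
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  r <- fdr_bh(p, q = 0.05)
  expect_true(all(r$significant)) # p(i) <= 0.01 i for all i at the max rank
  expect_equal(r$p_adjusted, c(0.05, 0.05, 0.05, 0.05, 0.05))
  r2 <- fdr_bh(c(0.5, 0.6, 0.7), q = 0.05)
  expect_false(any(r2$significant))
  r3 <- fdr_bh(0.04, q = 0.05)
  expect_true(r3$significant)
  expect_equal(r3$p_adjusted, 0.04)
  # adjusted p is monotone non-decreasing in rank
  set.seed(43)
  p4 <- runif(50)
  r4 <- fdr_bh(p4)
  ord <- order(p4)
  expect_true(all(diff(r4$p_adjusted[ord]) >= -1e-15))
  expect_error(fdr_bh(numeric(0)), class = "brainheart_data_error")
  expect_error(fdr_bh(c(0.5, 1.2)), class = "brainheart_data_error")
})

test_that("type-I error of the one-sample t is nominal at n = 29", {
  set.seed(44)
  x <- matrix(rnorm(29 * 1000), 29)
  r <- one_sample_t(x)
  rate <- mean(r$p < 0.05)
  # binomial 99.9% band around 0.05 with 1000 targets
  expect_lt(abs(rate - 0.05), 3.3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("post-hocs localize an after-gratitude-only edge change", {
  # injected connectivity change in the post-gratitude rest only: the two
  # pairs involving that session separate, the baseline vs post-resentment
  # pair does not (checked on the generated latents, the brute-force path)
  atl <- tiny_atlas()
  spec <- coupling_spec(
    fc_effects = tibble::tibble(
      condition = "rest_post_gratitude",
      net_a = "dmn", net_b = "salience", delta_r = 0.3
    ),
    behavior_effects = tibble::tibble(
      score = character(), condition = character(), net_a = character(),
      net_b = character(), slope = numeric()
    )
  )
  rests <- c("rest_baseline", "rest_post_gratitude", "rest_post_resentment")
  n_rep <- 20L
  ok <- vapply(seq_len(n_rep), function(rep) {
    coh <- simulate_cohort(16, spec, atl, seed = 7000 + rep)
    z <- sapply(rests, function(cond) {
      vapply(coh$subjects, function(sub) {
        lat <- sub$sessions[[cond]]$truth$latents
        fisher_z(cor(lat[, 1], lat[, 3]))
      }, numeric(1))
    })
    ph <- posthoc_pairwise(array(z, c(dim(z), 1L),
                                 dimnames = list(NULL, rests, "edge")))
    sig <- ph$p_bonf < 0.05
    grat <- grepl("rest_post_gratitude", ph$pair)
    all(sig[grat]) && !any(sig[!grat])
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})
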