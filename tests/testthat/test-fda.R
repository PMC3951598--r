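test_that("pixel pooling conserves pixels and inherits cookie labels", {
  wl <- c(450, 525, 630)
  mk_img <- function(level) {
    spectral_image(array(level, c(10, 10, 3)), wl,
                   mask = matrix(TRUE, 10, 10))
  }
  pool <- build_pixel_dataset(list(mk_img(0.2), mk_img(0.8)),
                              class_labels = c("overbaked", "underbaked"))
  expect_equal(nrow(pool$pixels), 200)
  expect_equal(as.vector(table(pool$groups)), c(100, 100))
  expect_equal(levels(pool$groups), c("underbaked", "overbaked"))
  expect_true(all(pool$pixels[pool$groups == "underbaked", ] == 0.8))

  empty <- mk_img(0.5)
  empty$mask <- matrix(FALSE, 10, 10)
  expect_warning(
    pool2 <- build_pixel_dataset(list(mk_img(0.2), empty, mk_img(0.8)),
                                 class_labels = c("overbaked", "adequately_baked",
                                                  "underbaked")),
    "empty mask"
  )
  expect_equal(nrow(pool2$pixels), 200)
})

test_that("two-class FDA matches the closed-form LDA direction", {
  for (seed in 1:5) {
    dat <- withr::with_seed(seed, {
      n <- 300; p <- 4
      mu1 <- rnorm(p); mu2 <- rnorm(p)
      A <- matrix(rnorm(p * p), p)
      x1 <- matrix(rnorm(n * p), n) %*% A + rep(mu1, each = n)
      x2 <- matrix(rnorm(n * p), n) %*% A + rep(mu2, each = n)
      list(x = rbind(x1, x2),
           g = factor(rep(c("a", "b"), each = n)))
    })
    m <- fit_fda(dat$x, dat$g, ridge = 0)
    # classic oracle: w  propto  S_W^{-1} (mu1 - mu2)
    centered <- dat$x - rowsum(dat$x, dat$g)[as.integer(dat$g), ] / 300
    s_w <- crossprod(centered)
    w_oracle <- solve(s_w, colMeans(dat$x[dat$g == "a", ]) -
                        colMeans(dat$x[dat$g == "b", ]))
    w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
    cosine <- abs(sum(m$loadings[1, ] * w_oracle))
    expect_equal(cosine, 1, tolerance = 1e-8)
  }
})

test_that("FDA agrees with MASS::lda on a three-class problem", {
  dat <- withr::with_seed(42, {
    n <- 200; p <- 5
    centers <- matrix(rnorm(3 * p, sd = 2), 3)
    x <- do.call(rbind, lapply(1:3, function(k) {
      matrix(rnorm(n * p), n) + rep(centers[k, ], each = n)
    }))
    list(x = x, g = factor(rep(letters[1:3], each = n)))
  })
  m <- fit_fda(dat$x, dat$g, ridge = 0)
  ld <- MASS::lda(dat$x, dat$g)
  ref <- ld$scaling[, 1] / sqrt(sum(ld$scaling[, 1]^2))
  expect_equal(abs(sum(m$loadings[1, ] * ref)), 1, tolerance = 1e-6)
})

test_that("FDA degenerate inputs raise informative errors", {
  x <- withr::with_seed(1, matrix(rnorm(60), 20, 3))
  g <- factor(rep(c("a", "b"), 10))
  same_mean <- rbind(x, x)
  expect_error(fit_fda(same_mean, factor(rep(c("a", "b"), each = 20))),
               "no separation")
  # rank-deficient within-scatter without ridge
  x2 <- cbind(x[, 1], x[, 1], x[, 2])
  x2 <- x2 + rep(c(0, 1), 10)  # separate the groups
  expect_error(fit_fda(x2, g, ridge = 0), "singular|ridge")
  expect_s3_class(fit_fda(x2, g), "fda_model")  # default ridge handles it
})

test_that("S_B rank never exceeds n_groups - 1 and duplication leaves the fit unchanged", {
  dat <- withr::with_seed(3, {
    x <- matrix(rnorm(900), 300, 3) + rep(c(0, 1.5, 3), each = 100)
    list(x = x, g = factor(rep(c("u", "a", "o"), each = 100), levels = c("u", "a", "o")))
  })
  m <- fit_fda(dat$x, dat$g)
  expect_equal(sum(eigen(m$between_scatter, symmetric = TRUE,
                         only.values = TRUE)$values > 1e-6), 2)
  m2 <- fit_fda(rbind(dat$x, dat$x), factor(rep(dat$g, 2), levels(dat$g)))
  expect_equal(m2$orientation_sign * m2$loadings[1, ],
               m$orientation_sign * m$loadings[1, ], tolerance = 1e-8)
})

test_that("browning score is anchored at zero and decreases with browning", {
  s1 <- fixture_set1()
  model <- fixture_browning_model()
  # anchored: the lightest (underbaked) class mean pixel score is 0
  expect_equal(unname(model$class_mean_scores["underbaked"]), 0, tolerance = 1e-9)
  expect_true(all(diff(model$class_mean_scores) < 0))

  # pixel scoring: constant image -> constant map; browner -> lower
  wl <- s1$images[[1]]$wavelengths_nm
  light <- spectral_image(array(0.6, c(8, 8, length(wl))), wl,
                          mask = matrix(TRUE, 8, 8))
  dark <- spectral_image(array(0.3, c(8, 8, length(wl))), wl,
                         mask = matrix(TRUE, 8, 8))
  sl <- score_pixels(light, model = model)
  sd_ <- score_pixels(dark, model = model)
  expect_equal(max(sl, na.rm = TRUE), min(sl, na.rm = TRUE))
  expect_lt(mean(sd_, na.rm = TRUE), mean(sl, na.rm = TRUE))

  short <- spectral_image(array(0.5, c(8, 8, 3)), wl[1:3],
                          mask = matrix(TRUE, 8, 8))
  expect_error(score_pixels(short, model = model), "grid|bands")
})

test_that("mean browning score averages the masked pixels only", {
  sm <- matrix(NA_real_, 4, 4)
  mask <- matrix(FALSE, 4, 4)
  mask[1:2, 1:2] <- TRUE
  sm[1:2, 1] <- 0; sm[1:2, 2] <- -2
  expect_equal(mean_browning_score(sm, mask), -1)
  expect_equal(mean_browning_score(matrix(-3, 2, 2)), -3)
  expect_error(mean_browning_score(sm, matrix(FALSE, 4, 4)), "empty")
  # invariant under mask-preserving permutation
  perm <- withr::with_seed(1, sample(4))
  expect_equal(mean_browning_score(sm[1:2, perm[perm <= 2], drop = FALSE],
                                   matrix(TRUE, 2, 2)),
               mean_browning_score(sm, mask))
})

test_that("class limits are midpoints of the transition-time group means", {
  expect_equal(
    unname(compute_class_limits(c(`4` = -1, `6` = -3, `10` = -6, `12` = -8))),
    c(-2, -7)
  )
  expect_error(compute_class_limits(c(`4` = -1, `6` = -3, `10` = -6)),
               "12")
  model <- fixture_browning_model()
  expect_gt(model$limit_under_adequate, model$limit_adequate_over)
})

test_that("cookie classification thresholds the mean score with ties to the more-baked class", {
  lim <- c(limit_under_adequate = -1, limit_adequate_over = -4)
  expect_equal(classify_cookie(-0.2, lim), "underbaked")
  expect_equal(classify_cookie(-1, lim), "adequately_baked")
  expect_equal(classify_cookie(-4, lim), "overbaked")
  expect_equal(classify_cookie(-2.5, lim), "adequately_baked")
})

test_that("pixel classification smooths away salt-and-pepper islands", {
  lim <- c(limit_under_adequate = -0.5, limit_adequate_over = -2)
  mask <- matrix(TRUE, 20, 20)
  sm <- matrix(-1, 20, 20)
  islands <- withr::with_seed(5, cbind(sample(3:18, 5), sample(3:18, 5)))
  sm[islands] <- -6
  raw <- classify_pixels(sm, mask, lim, gaussian_sigma = 0)
  expect_equal(sum(raw == "overbaked"), 5)
  smoothed <- classify_pixels(sm, mask, lim, gaussian_sigma = 1.5)
  expect_equal(sum(smoothed == "overbaked"), 0)
  # uniform map above the upper limit is all underbaked, any sigma
  expect_true(all(classify_pixels(matrix(0, 8, 8), matrix(TRUE, 8, 8), lim,
                                  gaussian_sigma = 0) == "underbaked"))
  expect_error(classify_pixels(sm, mask, lim, gaussian_sigma = -1), ">= 0")
})
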