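test_that("noise-free 4PL data are recovered to six significant digits", {
  doses <- 10^seq(-2, 3, length.out = 10)
  truth <- c(bottom = 0.1, top = 1.0, ic50 = 10, hill = 1.5)
  d <- simulate_dose_response(doses, truth["bottom"], truth["top"],
                              truth["ic50"], truth["hill"], cv = 0,
                              replicates = 2)
  f <- fit_4pl(d)
  expect_lt(abs(f$bottom - truth["bottom"]) / truth["bottom"], 1e-6)
  expect_lt(abs(f$top - truth["top"]) / truth["top"], 1e-6)
  expect_lt(abs(f$ic50 - truth["ic50"]) / truth["ic50"], 1e-6)
  expect_lt(abs(f$hill - truth["hill"]) / truth["hill"], 1e-6)
  expect_lt(f$rss, 1e-12)
  # degenerate profile: the IC50 CI collapses onto the estimate
  expect_equal(unname(f$ic50_ci), rep(f$ic50, 2), tolerance = 1e-6)
})

test_that("steep curves localize the IC50 to within one dose step", {
  doses <- 2^seq(-4, 4)      # two-fold ladder around ic50 = 1
  d <- simulate_dose_response(doses, 0, 1, ic50 = 1.3, hill = 20, cv = 0,
                              replicates = 2)
  f <- fit_4pl(d)
  expect_gt(f$ic50, 1.3 / 2)
  expect_lt(f$ic50, 1.3 * 2)
})

test_that("non-identifiable and invalid dose-response inputs error", {
  flat <- data.frame(dose = 10^(0:5), response = 1)
  expect_error(fit_4pl(flat), "non-identifiable")
  expect_error(fit_4pl(data.frame(dose = c(1, 2, 3), response = c(1, 0.5, 0))),
               "4 distinct doses")
  expect_error(fit_4pl(data.frame(dose = c(0, 1, 2, 3, 4),
                                  response = c(1, 0.9, 0.5, 0.2, 0.1))),
               "strictly positive")
})

test_that("the profile-likelihood IC50 interval brackets the estimate and the truth on noisy data", {
  d <- simulate_dose_response(10^seq(-2, 2, length.out = 9), ic50 = 1,
                              hill = 1.5, cv = 0.05, replicates = 3,
                              seed = 11)
  f <- fit_4pl(d)
  expect_true(f$ic50_ci[1] < f$ic50 && f$ic50 < f$ic50_ci[2])
  expect_true(f$ic50_ci[1] < 1 && 1 < f$ic50_ci[2])
})

test_that("Dunnett reduces to the pooled t-test with two groups and is calibrated against Monte Carlo", {
  set.seed(3)
  x <- rnorm(6, 10); y <- rnorm(6, 11)
  res <- compare_ic50_anova_dunnett(list(ctrl = x, ko = y), control = "ctrl")
  oracle <- t.test(y, x, var.equal = TRUE)$p.value   # analytic equivalence
  expect_equal(res$comparisons$p_adj, oracle, tolerance = 1e-4)
  expect_equal(res$comparisons$estimate, mean(y) - mean(x))

  # identical groups: nothing to detect
  z <- rnorm(5)
  res0 <- compare_ic50_anova_dunnett(list(a = z, b = z, c = z), control = "a")
  expect_true(all(res0$comparisons$p_adj > 0.99))
  expect_error(compare_ic50_anova_dunnett(list(a = z, b = 1), control = "a"),
               "2 replicates")

  # Monte-Carlo oracle for the many-to-one adjusted p-value (k = 4 groups)
  set.seed(5)
  groups <- list(ctrl = rnorm(5, 0), g1 = rnorm(5, 0.6), g2 = rnorm(5, 0),
                 g3 = rnorm(5, -0.4))
  res4 <- compare_ic50_anova_dunnett(groups, control = "ctrl", seed = 6)
  n <- 5; k <- 4; df <- k * (n - 1)
  y_obs <- unlist(groups)
  g <- factor(rep(names(groups), each = n), levels = names(groups))
  s2 <- sum(tapply(y_obs, g, function(v) sum((v - mean(v))^2))) / df
  means <- tapply(y_obs, g, mean)
  t_obs <- (means[-1] - means[1]) / sqrt(2 * s2 / n)
  nmc <- 40000
  set.seed(7)
  ymc <- matrix(rnorm(nmc * k * n), ncol = k * n)
  gm <- vapply(1:k, function(j)
    rowMeans(ymc[, ((j - 1) * n + 1):(j * n), drop = FALSE]), numeric(nmc))
  s2mc <- (rowSums(ymc^2) - n * rowSums(gm^2)) / df
  tmax <- apply(abs((gm[, -1] - gm[, 1]) / sqrt(2 * s2mc / n)), 1, max)
  for (j in seq_along(t_obs)) {
    p_mc <- mean(tmax >= abs(t_obs[j]))
    se <- sqrt(p_mc * (1 - p_mc) / nmc)
    expect_lt(abs(res4$comparisons$p_adj[j] - p_mc), 4 * se + 0.003)
  }
})

test_that("bliss_expected obeys its algebra", {
  expect_equal(bliss_expected(0, 0.4), 0.4)
  expect_equal(bliss_expected(1, 1), 1)
  expect_equal(bliss_expected(0.3, 0.5), 0.65)
  expect_error(bliss_expected(-0.1, 0.5), "\\[0, 1\\]")
  set.seed(8)
  fx <- runif(50); fy <- runif(50)
  expect_equal(bliss_expected(fx, fy), bliss_expected(fy, fx))  # symmetric
  expect_true(all(bliss_expected(fx, fy) >= pmax(fx, fy) - 1e-12))
  expect_true(all(bliss_expected(fx, fy) <= 1))
  expect_true(all(diff(bliss_expected(sort(fx), 0.3)) >= 0))    # monotone
})

test_that("synergy volumes are zero on an exact Bliss surface and recover planted deviations exactly", {
  b <- null_board()
  sv <- synergy_volumes(b)
  expect_equal(sv$synergy_volume, 0, tolerance = 1e-9)
  expect_equal(sv$antagonism_volume, 0, tolerance = 1e-9)
  expect_equal(max(abs(sv$deviation)), 0, tolerance = 1e-9)

  dx <- equipotency_doses(1)
  dy <- equipotency_doses(1, c(0.03125, 0.0625, 0.125, 0.25, 0.5, 1, 2, 4, 8))
  bump <- data.frame(dose_x = dx[2], dose_y = dy[4], dev = 0.10)
  b2 <- simulate_checkerboard(dx, dy, synergy_bump = bump, noise_sd = 0,
                              replicates = 3, seed = 2)
  sv2 <- synergy_volumes(b2, dose_scale = "unit")
  # hand computation: a +10% deviation at one unit-weight cell
  expect_equal(sv2$synergy_volume, 10, tolerance = 1e-9)
  expect_equal(sv2$antagonism_volume, 0, tolerance = 1e-9)
  expect_equal(sv2$deviation[as.character(dx[2]), as.character(dy[4])], 10,
               tolerance = 1e-9)
  # linear weighting scales the same cell by its dose-interval area
  sv2l <- synergy_volumes(b2, dose_scale = "linear")
  w_x <- (dx[3] - dx[1]) / 2
  w_y <- (dy[5] - dy[3]) / 2
  expect_equal(sv2l$synergy_volume, 10 * w_x * w_y, tolerance = 1e-9)

  # negating the planted deviation swaps synergy and antagonism exactly
  bump_neg <- transform(bump, dev = -dev)
  b3 <- simulate_checkerboard(dx, dy, synergy_bump = bump_neg, noise_sd = 0,
                              replicates = 3, seed = 2)
  sv3 <- synergy_volumes(b3, dose_scale = "unit")
  expect_equal(sv3$antagonism_volume, -sv2$synergy_volume, tolerance = 1e-9)
  expect_equal(sv3$synergy_volume, 0, tolerance = 1e-9)
})

test_that("synergy volume grows with the planted deviation and shrinks with confidence", {
  dx <- equipotency_doses(1)
  dy <- equipotency_doses(1, c(0.25, 0.5, 1, 2))
  res <- lapply(c(0.05, 0.1, 0.2), function(dev) {
    b <- simulate_checkerboard(dx, dy,
                               synergy_bump = data.frame(dose_x = dx[3],
                                                         dose_y = dy[2],
                                                         dev = dev),
                               noise_sd = 0.02, replicates = 4, seed = 5)
    synergy_volumes(b, dose_scale = "unit")
  })
  # CI-thresholded volumes are non-decreasing (small bumps may be censored
  # to zero); raw deviation volumes grow strictly
  expect_true(all(diff(vapply(res, `[[`, numeric(1),
                              "synergy_volume")) >= 0))
  expect_gt(res[[3]]$synergy_volume, 0)
  expect_true(all(diff(vapply(res, `[[`, numeric(1),
                              "raw_synergy_volume")) > 0))
  b <- simulate_checkerboard(dx, dy,
                             synergy_bump = data.frame(dose_x = dx[3],
                                                       dose_y = dy[2],
                                                       dev = 0.2),
                             noise_sd = 0.02, replicates = 4, seed = 5)
  v95 <- synergy_volumes(b, confidence = 0.95, dose_scale = "unit")
  v999 <- synergy_volumes(b, confidence = 0.999, dose_scale = "unit")
  expect_gte(v95$synergy_volume, v999$synergy_volume)
})

test_that("synergy analysis demands complete boards", {
  b <- null_board()
  expect_error(synergy_volumes(b[!(b$dose_x == 0 & b$dose_y == 0), ]),
               "untreated")
  expect_error(synergy_volumes(b[!(b$dose_x > 0 & b$dose_y == 0), ]),
               "monotherapy")
})
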