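test_that("hertz force follows the closed form and its monotonicities", {
  expect_equal(hertz_force(0, 3e9, 1.5e-6), 0)
  # direct evaluation, cross-checked against an independent rewriting
  E <- 3e9; nu <- 0.33; R <- 1.5e-6; d <- 5e-9
  expect_equal(hertz_force(d, E, R, nu),
               4 / 3 * E / (1 - nu^2) * sqrt(R * d^2 * d))
  expect_equal(hertz_force(d, 2 * E, R, nu), 2 * hertz_force(d, E, R, nu))
  expect_lt(hertz_force(d, E, R, nu), hertz_force(2 * d, E, R, nu))
  expect_lt(hertz_force(d, E, R, nu), hertz_force(d, E, 2 * R, nu))
  expect_error(hertz_force(-1e-9, E, R), ">= 0")
})

test_that("hertz fits recover planted parameters", {
  noiseless <- gen_force_curves(E = 3e9, noise_sd = 0, n_curves = 1,
                                seed = 1)$curves[[1]]
  fit <- fit_hertz(noiseless)
  expect_equal(fit$E, 3e9, tolerance = 1e-6)
  expect_lt(abs(fit$delta0), 1e-12)

  noisy <- gen_force_curves(E = 3e9, noise_sd = 0.01, n_curves = 20,
                            seed = 2)$curves
  Es <- vapply(noisy, function(cu) fit_hertz(cu)$E, numeric(1))
  expect_true(all(abs(Es - 3e9) / 3e9 < 0.02))

  shifted <- gen_force_curves(E = 3e9, noise_sd = 0.005, delta0_nm = 2,
                              n_curves = 10, seed = 3)$curves
  d0s <- vapply(shifted, function(cu) fit_hertz(cu)$delta0, numeric(1))
  expect_true(all(abs(d0s - 2e-9) < 0.2e-9))

  pinned <- fit_hertz(shifted[[1]], fix_delta0 = 2e-9)
  expect_equal(pinned$delta0, 2e-9)
  expect_lt(abs(pinned$E - 3e9) / 3e9, 0.02)
})

test_that("hertz fitting is scale-consistent in force", {
  cu <- gen_force_curves(E = 1e9, noise_sd = 0.01, seed = 7)$curves[[1]]
  scaled <- suppressMessages(
    force_curve(cu$delta * 1e9, cu$force * 1e9 * 3.5, cu$R * 1e9, cu$nu))
  expect_equal(fit_hertz(scaled)$E, 3.5 * fit_hertz(cu)$E,
               tolerance = 1e-6)
})

test_that("exact spearman reproduces small-sample permutation probabilities", {
  res <- spearman_exact(1:5, c(2, 3, 7, 8, 11))
  expect_equal(res$r, 1)
  expect_equal(res$p_one_sided, 1 / 120)
  expect_equal(round(res$p_one_sided, 4), 0.0083)
  expect_equal(res$p_two_sided, 2 / 120)

  anti <- spearman_exact(1:5, 5:1)
  expect_equal(anti$r, -1)
  expect_equal(anti$p_one_sided, 1)   # upper tail contains everything

  expect_error(spearman_exact(1:2, 2:1), "at least 3")
  expect_error(spearman_exact(c(1, 1, 2, 3, 4), 1:5, exact = TRUE),
               "untied")
})

# local 5! enumeration for the oracles below, independent of the package's
# recursion
permn5 <- function() {
  out <- NULL
  for (a in 1:5) for (b in 1:5) for (cc in 1:5) for (d in 1:5) for (e in 1:5) {
    p <- c(a, b, cc, d, e)
    if (!anyDuplicated(p)) out <- rbind(out, p)
  }
  out
}

test_that("exact p matches a brute-force enumeration on random data", {
  brute_p <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    r_obs <- cor(rx, ry)
    perms <- permn5()
    r_all <- apply(perms, 1, function(p) cor(rx, ry[p]))
    c(one = mean(r_all >= r_obs - 1e-12),
      two = mean(abs(r_all) >= abs(r_obs) - 1e-12))
  }
  withr::with_seed(55, {
    for (k in 1:10) {
      x <- sample(100, 5); y <- sample(100, 5)
      res <- spearman_exact(x, y)
      want <- brute_p(x, y)
      expect_equal(res$p_one_sided, unname(want["one"]))
      expect_equal(res$p_two_sided, unname(want["two"]))
      # agreement with the standard estimator for r
      expect_equal(res$r, cor(x, y, method = "spearman"))
      # and with the distribution-based exact test
      ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                      alternative = "greater",
                                      exact = TRUE))
      expect_equal(res$p_one_sided, unname(ct$p.value))
    }
  })
})

test_that("permutation p-values are calibrated and invariances hold", {
  # exactness: under the uniform permutation null, P(p_one <= u) = u for
  # every achievable level u, and the largest level is 1
  perms <- permn5()
  x <- 1:5
  ps <- apply(perms, 1, function(p) spearman_exact(x, p)$p_one_sided)
  for (u in unique(ps))
    expect_equal(mean(ps <= u + 1e-12), u)
  expect_equal(max(ps), 1)
  # monotone-transform invariance
  res <- spearman_exact(c(3, 1, 4, 1.5, 9), c(2, 7, 1, 8, 2.8))
  res2 <- spearman_exact(exp(c(3, 1, 4, 1.5, 9)),
                         log(c(2, 7, 1, 8, 2.8)))
  expect_equal(res$r, res2$r)
  expect_equal(res$p_one_sided, res2$p_one_sided)
})

test_that("large samples fall back to the t approximation with notice", {
  withr::with_seed(77, {
    x <- rnorm(20); y <- x + rnorm(20)
  })
  expect_message(res <- spearman_exact(x, y), "approximation")
  expect_equal(res$method, "t approximation")
  expect_gt(res$r, 0)
})

test_that("bead geometry totals follow the sphere formulas", {
  expect_equal(internalized_geometry(2, 0),
               list(volume_um3 = 0, surface_um2 = 0))
  one <- internalized_geometry(2, 1)                    # unit radius
  expect_equal(one$volume_um3, 4 * pi / 3)
  expect_equal(one$surface_um2, 4 * pi)
  six <- internalized_geometry(6, 2)                    # r = 3, two beads
  expect_equal(six$volume_um3, 2 * 4 / 3 * pi * 27)
  expect_equal(six$surface_um2, 2 * 4 * pi * 9)
  expect_error(internalized_geometry(0, 1), "positive")
})

test_that("phagocytosis summaries report both efficiency readouts", {
  none <- phagocytosis_efficiency(c(0, 0, 0))
  expect_equal(none$fraction_engulfing, 0)
  expect_equal(none$mean_internalized, 0)

  mix <- phagocytosis_efficiency(c(2, 0, 1), surface_bound = c(1, 2, 0))
  expect_equal(mix$fraction_engulfing, 2 / 3)
  expect_equal(mix$mean_internalized, 1)
  expect_equal(mix$mean_surface_bound, 1)
  expect_error(phagocytosis_efficiency(integer()), "empty")

  withr::with_seed(9, counts <- rpois(50, 1.4))
  s <- phagocytosis_efficiency(counts)
  expect_equal(s$fraction_engulfing, mean(counts > 0))
  expect_equal(s$mean_internalized, mean(counts))
  expect_equal(sum(s$distribution), 50)
})
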