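# noiseless construction following the bias model exactly: individuals carry
# loadings t in {+1, -1}; scores X[i, j] = t_i * sqrt(b * (1 + c1 * 2 * u_j))
# so that every point-wise product is b * tau * (1 + c1 * (u_i + u_j)) with
# tau = t_i * t_j and a shared per-variant fuzziness u_j.
noiseless_case <- function(b, c1, n_pos = 4, n_neg = 3, m = 60) {
  u <- seq(0.05, 0.95, length.out = m)
  t_load <- c(rep(1, n_pos), rep(-1, n_neg))
  X <- outer(t_load, sqrt(b * (1 + c1 * 2 * u)))
  U <- matrix(u, length(t_load), m, byrow = TRUE)
  list(X = X, U = U, raw = accumulate_grm(X), tau = outer(t_load, t_load))
}

test_that("pair regression extrapolates noiseless linear data exactly", {
  set.seed(41)
  u1 <- stats::runif(50)
  u2 <- stats::runif(50)
  y <- 3 + 2 * (u1 + u2) - 1.5 * u1 * u2 + 0.7 * (u1^2 + u2^2)
  fit <- pair_regression(y, u1, u2)
  expect_false(fit$fallback)
  expect_equal(fit$intercept, 3, tolerance = 1e-9)
  # mean-zero noise keeps the intercept close
  set.seed(2)
  fitn <- pair_regression(y + stats::rnorm(50, 0, 0.01), u1, u2)
  expect_equal(fitn$intercept, 3, tolerance = 0.02)
})

test_that("degenerate regressions fall back to the plain mean", {
  y <- c(0.3, 0.5, 0.1, 0.7)
  fit <- pair_regression(y, rep(0, 4), rep(0, 4))
  expect_true(fit$fallback)
  expect_equal(fit$intercept, mean(y))
  expect_equal(fit$coef, c(0, 0, 0))
  fit2 <- pair_regression(y[1:2], c(0.1, 0.2), c(0.1, 0.2))
  expect_true(fit2$fallback)
})

test_that("pair selection returns extremes, random block and diagonal", {
  K <- matrix(0, 5, 5)
  K[1, 2] <- K[2, 1] <- 0.9
  K[3, 4] <- K[4, 3] <- -0.5
  sel <- select_pairs(K, n_top = 1, n_bottom = 1, n_random = 0)
  off <- sel[sel[, 1] != sel[, 2], , drop = FALSE]
  expect_equal(nrow(off), 2L)
  expect_true(any(off[, 1] == 1 & off[, 2] == 2))
  expect_true(any(off[, 1] == 3 & off[, 2] == 4))
  expect_equal(sum(sel[, 1] == sel[, 2]), 5L)   # all diagonal elements

  sel_all <- select_pairs(K, 0, 0, n_random = 5, seed = 1)
  expect_equal(nrow(sel_all), choose(5, 2) + 5)
  expect_error(select_pairs(K, 0, 0, 0), "degenerate")

  # deterministic tie-breaking: constant matrix, top pairs by pair order
  sel_tie <- select_pairs(matrix(1, 4, 4), 2, 0, 0)
  off_tie <- sel_tie[sel_tie[, 1] != sel_tie[, 2], , drop = FALSE]
  expect_equal(off_tie, rbind(c(1L, 2L), c(1L, 3L)), ignore_attr = TRUE)
})

test_that("the multiplicative bias is recovered exactly on noiseless data", {
  # flat fuzziness response: beta equals the constructed bias b
  cs <- noiseless_case(b = 0.62, c1 = 0)
  adj <- adjust_grm(cs$raw, cs$X, cs$U, n_top = 3, n_bottom = 3,
                    n_random = 7, quartile_shift = FALSE, seed = 1)
  expect_equal(adj$beta, 0.62, tolerance = 1e-6)
  expect_equal(unname(adj$adjusted), unname(cs$tau), tolerance = 1e-6,
               ignore_attr = TRUE)

  # fuzziness-dependent bias: the full pipeline still recovers tau exactly
  cs2 <- noiseless_case(b = 0.4, c1 = 0.8)
  adj2 <- adjust_grm(cs2$raw, cs2$X, cs2$U, n_top = 3, n_bottom = 3,
                     n_random = 7, quartile_shift = FALSE, seed = 1)
  expect_equal(unname(adj2$adjusted), unname(cs2$tau), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_gt(adj2$beta, 0.4)   # absorbs the mean fuzziness inflation
})

test_that("beta calibration algebra matches its contract", {
  # synthetic pairs: intercepts proportional to tau, raw = bias * tau
  tau <- c(1, 1, 1, 0.5, 0.25, 0, 0, 0)
  is_diag <- c(TRUE, TRUE, TRUE, rep(FALSE, 5))
  s_scale <- 0.8; bias <- 0.55
  cal <- calibrate_beta(values = bias * tau, intercepts = s_scale * tau,
                        is_diag = is_diag)
  expect_equal(cal$c_bar, s_scale)
  expect_equal(cal$beta, bias, tolerance = 1e-9)
  expect_equal(cal$beta_diag, bias, tolerance = 1e-9)
  # too few pairs: calibration refuses
  expect_true(is.na(calibrate_beta(1, 1, TRUE)$beta))
})

test_that("the quartile shift zeroes the first quartile off the diagonal", {
  cs <- noiseless_case(b = 0.5, c1 = 0.3)
  adj <- adjust_grm(cs$raw, cs$X, cs$U, n_top = 3, n_bottom = 3, n_random = 7,
                    quartile_shift = TRUE, seed = 1)
  off <- adj$adjusted[upper.tri(adj$adjusted)]
  expect_equal(unname(stats::quantile(off, 0.25)), 0, tolerance = 1e-9)
  expect_equal(diag(adj$adjusted), diag(cs$tau) / 1, tolerance = 1e-6)
  # shift equals the documented linear-interpolation quartile
  vals <- c(-0.02, -0.01, 0, 0.5)
  expect_equal(unname(stats::quantile(vals, 0.25, type = 7)), -0.0125)
})

test_that("adjustment with unit bias and zero fuzziness is the identity", {
  set.seed(12)
  X <- matrix(stats::rnorm(10 * 80), 10, 80)
  U <- matrix(0, 10, 80)
  raw <- accumulate_grm(X)
  adj <- adjust_grm(raw, X, U, n_top = 2, n_bottom = 2, n_random = 6,
                    quartile_shift = FALSE, seed = 3)
  # with zero fuzziness every pair regression falls back to the raw mean,
  # so the calibration line is the identity and beta the mean diagonal
  expect_equal(adj$beta, mean(diag(raw)), tolerance = 1e-9)
  expect_equal(unname(adj$adjusted), unname(raw / adj$beta), tolerance = 1e-9)
})

test_that("adjustment preserves the ranking of related pairs", {
  st <- pipeline_study()
  fit <- glkin(st, adjust_par = c(4, 4, 12), snp_subsample = 4000, seed = 2)
  rk_raw <- order(fit$K_raw[upper.tri(fit$K_raw)])
  rk_adj <- order(fit$K[upper.tri(fit$K)])
  expect_identical(rk_raw, rk_adj)
})

test_that("adjustment moves low-depth estimates toward the truth", {
  st <- pipeline_study()
  sib <- sib_index(st)
  fit <- glkin(st, adjust_par = c(8, 8, 16), snp_subsample = 4000, seed = 2)
  truth <- mean(st$truth$phi_true)
  raw_err <- abs(mean(fit$K_raw[sib]) / 2 - truth)
  adj_err <- abs(mean(fit$K[sib]) / 2 - truth)
  expect_lt(adj_err, raw_err)
  expect_true(all(fit$beta < 1))           # downward bias at 2.5x
  expect_gt(min(fit$beta, na.rm = TRUE), 0)
})
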