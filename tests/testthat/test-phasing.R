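test_that("per-base twist SD follows the torsional-elasticity formula", {
  # plug-in: h_r = 10.5, ell = 3.4e-8 cm, T = 298 K, C_app = 2.4e-19 erg cm
  p <- phasing_params(h_r = 10.5, C_app = 2.4e-19)
  expect_equal(sigma_bp(p), 0.127583068088, tolerance = 1e-10)
  # linear in h_r
  p2 <- phasing_params(h_r = 21, C_app = 2.4e-19)
  expect_equal(sigma_bp(p2), 2 * sigma_bp(p))
  # rigid-DNA limit: C_app -> large makes sigma_bp -> 0
  expect_lt(sigma_bp(phasing_params(h_r = 10.5, C_app = 1e-10)), 1e-5)
  # round trip: params built from sigma_bp reproduce it
  p3 <- phasing_params(h_r = 5.46, sigma_bp = 0.15)
  expect_equal(sigma_bp(p3), 0.15)
})

test_that("twist SD grows with the square root of spacing", {
  p <- phasing_params()
  expect_equal(sigma_tw(0, p), 0)
  expect_equal(sigma_tw(4, p), 2 * sigma_bp(p))
  s <- seq(0, 40, by = 0.5)
  expect_true(!is.unsorted(sigma_tw(s, p)))
  expect_error(sigma_tw(-1, p), "non-negative")
})

test_that("predicted fluorescence matches a brute-force term-by-term sum", {
  p <- phasing_params(h_r = 5.46, K_min = 1, s_min = 1, sigma_bp = 0.15,
                      N = 96)
  # independent 193-term summation, frozen
  expect_equal(predict_F(3.73, p), 9.6067494358e+18, tolerance = 1e-8)
  # F at a minimum equals K_min when torsional broadening is negligible
  expect_equal(predict_F(p$s_min, p), p$K_min, tolerance = 1e-12)
  p5 <- phasing_params(h_r = 5.46, K_min = 2.5, s_min = 1, sigma_bp = 0.15)
  expect_equal(predict_F(1, p5), 2.5, tolerance = 1e-9)
  # neighbouring Gaussian tails can only deepen the minimum
  expect_lte(predict_F(p$s_min + p$h_r, p), p$K_min + 1e-9)
})

test_that("noise-free curves have minima separated by exactly h_r", {
  p <- phasing_params(h_r = 5.46, K_min = 1, s_min = 1, sigma_bp = 0.15)
  s <- seq(4, 30, by = 0.01)
  lf <- log_predict_F(s, p)
  minima <- s[which(diff(sign(diff(lf))) == 2) + 1]
  expect_gte(length(minima), 4)
  expect_true(all(abs(diff(minima) - p$h_r) <= 0.02))
})

test_that("truncation at N = 96 is numerically converged", {
  p96 <- phasing_params()
  p10k <- phasing_params(N = 10000L)
  s <- seq(0.5, 40, by = 0.5)
  rel <- abs(log_predict_F(s, p96) - log_predict_F(s, p10k))
  expect_lt(max(rel), 1e-12)
})

test_that("stiffer DNA gives stronger peak-to-trough contrast", {
  contrast <- function(C_app) {
    p <- phasing_params(h_r = 5.46, K_min = 1, s_min = 1, C_app = C_app)
    diff(range(log_predict_F(c(20, 20 + p$h_r / 2), p)))
  }
  cs <- c(1e-20, 5e-20, 2e-19)
  expect_true(!is.unsorted(vapply(cs, contrast, numeric(1))))
})

test_that("phase and helix projection follow the fitted geometry", {
  p <- phasing_params(h_r = 5.46, s_min = 1)
  expect_equal(phase_of(1, p), 0)
  expect_equal(phase_of(1 + 5.46 / 2, p), 0.5)
  expect_equal(phase_of(1 + 3 * 5.46, p), 0)
  expect_equal(helix_projection(10.5), 0)
  expect_equal(helix_projection(5.25), pi)
  expect_equal(helix_projection(21), 0)
})

test_that("least-squares fit recovers parameters from exact curves", {
  truth <- phasing_params(h_r = 5.46, K_min = 1, s_min = 1, sigma_bp = 0.15)
  s <- 1:32
  f <- predict_F(s, truth)
  fit <- suppressMessages(fit_phasing(s, f))
  expect_lt(abs(fit$params$h_r - truth$h_r), 1e-3)
  expect_lt(abs(fit$params$s_min %% fit$params$h_r -
                  truth$s_min %% truth$h_r), 1e-2)
  expect_equal(fit$params$K_min, 1, tolerance = 0.01)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  # phases of the fitted model at the minima are 0
  expect_lt(min(fit$phase[s == 23]), 0.05)  # 23 = 1 + ~4 periods
})

test_that("constant intensities yield a flagged degenerate fit", {
  fit <- suppressMessages(fit_phasing(1:20, rep(3, 20)))
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_true(is.na(fit$params$h_r))
})
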