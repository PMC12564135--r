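# A cheap standard pull setup reused across estimator tests: small domain,
# modest speed, so each trace takes a fraction of a second.
pull_setup <- function(pot, v = 0.5, k = 10, D = 100, temperature = 300) {
  dyn <- langevin_params(D, temperature,
                         suggest_dt(pot, D, temperature, k_extra = k))
  list(pot = pot, dyn = dyn, v = v, k = k)
}

test_that("bin_work interpolates linearly and idempotently", {
  # trace with analytic quadratic work, ascending
  lam <- seq(0, 4, by = 0.25)
  tr <- tibble::tibble(t = lam, lambda = lam, z = lam, f = 2 * lam,
                       W = 0.7 * lam^2)
  attr(tr, "protocol") <- pull_protocol("F", v = 1, z_start = 0, z_end = 4)
  hits <- seq(0, 4, by = 0.5) # nodes on the sample positions
  expect_equal(bin_work(tr, hits)$W, 0.7 * hits^2, tolerance = 1e-12)
  # refining x2 and coarsening back leaves node values unchanged
  fine <- bin_work(tr, seq(0, 4, by = 0.125))
  tr_fine <- tibble::tibble(t = fine$z, lambda = fine$z, z = fine$z,
                            f = 0, W = fine$W)
  attr(tr_fine, "protocol") <- attr(tr, "protocol")
  back <- bin_work(tr_fine, hits)
  expect_equal(back$W, bin_work(tr, hits)$W, tolerance = 1e-12)
  expect_error(bin_work(tr, seq(0, 5, 0.5)), "outside")
})

test_that("descending traces are re-indexed onto the shared axis", {
  # reverse pull over [0, 4]: cumulative work from the top
  lam <- seq(4, 0, by = -0.25)
  W <- 0.3 * (4 - lam) # linear accumulation on the way down
  tr <- tibble::tibble(t = seq_along(lam), lambda = lam, z = lam, f = 0.3,
                       W = W)
  attr(tr, "protocol") <- pull_protocol("R", v = 1, z_start = 4, z_end = 0)
  got <- bin_work(tr, seq(0, 4, by = 1))
  # W_tot - W_cum(z): work spent between passing z and finishing at 0
  expect_equal(got$W, 0.3 * seq(0, 4, by = 1), tolerance = 1e-12)
})

test_that("average_works handles single, duplicated and mixed traces", {
  st <- pull_setup(potential("flat", 0, domain = c(0, 4)))
  pf <- pull_protocol("F", v = st$v, k_spring = st$k, z_start = 0, z_end = 4)
  pr <- pull_protocol("R", v = st$v, k_spring = st$k, z_start = 4, z_end = 0)
  f1 <- simulate_smd_pull(st$pot, st$dyn, pf, seed = 1)
  r1 <- simulate_smd_pull(st$pot, st$dyn, pr, seed = 2)
  grid <- seq(0, 4, by = 0.5)
  mw <- average_works(list(f1, r1), grid)
  expect_equal(mw$W_F, bin_work(f1, grid)$W)
  expect_true(all(is.na(mw$se_F))) # single pull: SE undefined
  mw2 <- average_works(list(f1, f1, f1, r1, r1), grid)
  expect_equal(mw2$se_F, rep(0, length(grid))) # duplicated trace: SE = 0
  pf_bad <- pull_protocol("F", v = 1, k_spring = st$k, z_start = 0,
                          z_end = 3)
  f_bad <- simulate_smd_pull(st$pot, st$dyn, pf_bad, seed = 3)
  expect_error(average_works(list(f_bad, r1), grid), "mixed")
  expect_error(average_works(list(f1, f1), grid), "per direction")
})

test_that("flat-potential null: mean work stays within 3 SE of zero", {
  st <- pull_setup(potential("flat", 0, domain = c(0, 6)), v = 1)
  traces <- fr_pull_set(st$pot, st$dyn, v = st$v, k_spring = st$k,
                        z_start = 0, z_end = 6, n_pulls = 100, seed = 4)
  grid <- seq(0, 6, by = 0.5)
  mw <- average_works(traces, grid)
  est <- estimate_pmf(mw, anchor = 0)
  ok <- abs(est$dU) <= 3 * pmax(est$se, 1e-12) | est$se == 0
  expect_true(all(ok[-1])) # anchor node is exactly zero by construction
  # dissipation is nonnegative within 3 SE and its mean slope is gamma*v
  wd <- estimate_dissipation(mw)
  expect_true(all(wd$Wd >= -3 * wd$se, na.rm = TRUE))
})

test_that("symmetric mean works give an identically zero PMF", {
  grid <- seq(0, 5, by = 0.5)
  mw <- structure(
    tibble::tibble(z = grid, W_F = sin(grid), se_F = 0.1,
                   W_R = sin(grid), se_R = 0.1),
    class = c("fr_meanworks", class(tibble::tibble())),
    n_F = 10L, n_R = 10L, v = 1
  )
  est <- estimate_pmf(mw, anchor = 2.5)
  expect_equal(est$dU, rep(0, length(grid)))
  expect_equal(est$se, rep(0.5 * sqrt(0.02), length(grid)))
  expect_error(estimate_pmf(mw, anchor = 9), "anchor")
})

test_that("swapping the direction labels negates the estimate exactly", {
  st <- pull_setup(potential("double_well", c(1.5, 1, 5),
                             domain = c(0, 6)), v = 1)
  traces <- fr_pull_set(st$pot, st$dyn, v = st$v, k_spring = st$k,
                        z_start = 0, z_end = 6, n_pulls = 5, seed = 9)
  grid <- seq(0, 6, by = 0.5)
  est <- estimate_pmf(average_works(traces, grid), anchor = 3)
  swapped <- lapply(traces, function(tr) {
    attr(tr, "direction") <- if (attr(tr, "direction") == "F") "R" else "F"
    tr
  })
  est_sw <- estimate_pmf(average_works(swapped, grid), anchor = 3)
  expect_equal(est_sw$dU, -est$dU, tolerance = 1e-12)
  expect_equal(est_sw$se, est$se, tolerance = 1e-12)
})

test_that("two anchors differ by a constant shift only", {
  st <- pull_setup(potential("linear", c(0, 0.5), domain = c(0, 6)), v = 1)
  traces <- fr_pull_set(st$pot, st$dyn, v = st$v, k_spring = st$k,
                        z_start = 0, z_end = 6, n_pulls = 4, seed = 31)
  grid <- seq(0, 6, by = 0.5)
  mw <- average_works(traces, grid)
  a <- estimate_pmf(mw, anchor = 0)
  b <- estimate_pmf(mw, anchor = 6)
  shift <- a$dU - b$dU
  expect_lt(diff(range(shift)), 1e-12)
  expect_equal(a$dU[1], 0)
  expect_equal(b$dU[length(grid)], 0)
})

test_that("the estimator recovers a linear ramp slope in the slow limit", {
  slope <- 0.5
  st <- pull_setup(potential("linear", c(0, slope), domain = c(0, 6)),
                   v = 0.05)
  traces <- fr_pull_set(st$pot, st$dyn, v = st$v, k_spring = st$k,
                        z_start = 0, z_end = 6, n_pulls = 6, seed = 12)
  est <- estimate_pmf(average_works(traces, seq(0, 6, 0.5)), anchor = 0)
  fit <- stats::lm(dU ~ z, data = est)
  expect_equal(unname(stats::coef(fit)[2]), slope, tolerance = 0.02)
})

test_that("mean works respect the second-law bounds around the PMF", {
  st <- pull_setup(potential("double_well", c(1.5, 1, 5),
                             domain = c(0, 6)), v = 1)
  traces <- fr_pull_set(st$pot, st$dyn, v = st$v, k_spring = st$k,
                        z_start = 0, z_end = 6, n_pulls = 15, seed = 8)
  grid <- seq(0, 6, by = 0.5)
  mw <- average_works(traces, grid)
  est <- estimate_pmf(mw, anchor = 0)
  se_w <- pmax(mw$se_F, mw$se_R, na.rm = TRUE)
  expect_true(all(mw$W_F >= est$dU - 3 * se_w))
  expect_true(all(mw$W_R >= -est$dU - 3 * se_w))
  wd <- estimate_dissipation(mw)
  expect_true(all(wd$Wd >= -3 * wd$se))
})

test_that("RMSE against the true potential shrinks with more pulls", {
  # a stiff guide (k = 40) keeps the spring-convolution bias well below the
  # sampling noise, so the error is dominated by the 1/sqrt(n) statistics
  pot <- potential("double_well", c(1.5, 1, 5), domain = c(0, 6))
  st <- pull_setup(pot, v = 2, k = 40)
  grid <- seq(0, 6, by = 0.5)
  truth <- pot_energy(pot, grid)
  truth <- truth - truth[1]
  rmse <- vapply(c(5, 20, 80), function(n) {
    traces <- fr_pull_set(pot, st$dyn, v = st$v, k_spring = st$k,
                          z_start = 0, z_end = 6, n_pulls = n, seed = 44)
    est <- estimate_pmf(average_works(traces, grid), anchor = 0)
    sqrt(mean((est$dU - truth)^2))
  }, numeric(1))
  expect_lt(rmse[3], rmse[1])
  expect_lt(rmse[2], rmse[1])
})

test_that("known generator diffusivity is recovered from dissipation", {
  D <- 50
  v <- 2
  pot <- potential("flat", 0, domain = c(0, 10))
  dyn <- langevin_params(D, 300, suggest_dt(pot, D, 300, k_extra = 10))
  traces <- fr_pull_set(pot, dyn, v = v, k_spring = 10, z_start = 0,
                        z_end = 10, n_pulls = 60, seed = 77)
  mw <- average_works(traces, seq(0, 10, by = 0.5))
  wd <- estimate_dissipation(mw)
  fit <- stats::lm(Wd ~ z, data = wd)
  d_hat <- kB * 300 * v / unname(stats::coef(fit)[2])
  expect_equal(d_hat, D, tolerance = 0.2)
  # the per-node profile agrees where significant
  dprof <- estimate_friction_diffusion(wd, v = v, temperature = 300)
  expect_true(all(dprof$D > 0, na.rm = TRUE))
})

test_that("dissipation slope doubles with the pull speed", {
  pot <- potential("flat", 0, domain = c(0, 8))
  D <- 50
  dyn <- langevin_params(D, 300, suggest_dt(pot, D, 300, k_extra = 10))
  slope_at <- function(v, seed) {
    traces <- fr_pull_set(pot, dyn, v = v, k_spring = 10, z_start = 0,
                          z_end = 8, n_pulls = 50, seed = seed)
    wd <- estimate_dissipation(average_works(traces, seq(0, 8, 0.5)))
    unname(stats::coef(stats::lm(Wd ~ z, data = wd))[2])
  }
  s1 <- slope_at(1, 61)
  s2 <- slope_at(2, 62)
  expect_equal(s2 / s1, 2, tolerance = 0.25)
})
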