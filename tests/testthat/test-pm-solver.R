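test_that("diffusivity families match their closed forms", {
  expect_equal(diffusivity(0, 0.1), 1)
  expect_equal(diffusivity(0, 0.1, "exponential"), 1)
  expect_equal(diffusivity(0.1, 0.1), 0.5)
  expect_equal(diffusivity(0.1, 0.1, "exponential"), exp(-1))
  expect_equal(diffusivity(c(1, 2), 2), c(1 / 1.25, 0.5))
  expect_error(diffusivity(-1, 0.1), "gradient")
  # c'(g)/g stays finite at g = 0 (rational: -2/k^2, exponential: -2/k^2)
  expect_equal(pmwave:::cprime_over_g(0, 0.5, "rational"), -8)
  expect_equal(pmwave:::cprime_over_g(0, 0.5, "exponential"), -8)
})

test_that("the right-hand side vanishes for constants and gives the Laplacian limit", {
  ctl <- pm_control(k = Inf, j0 = 2, threshold = 0, t_end = 2e-5)
  g <- multilevel_grid(2, 5)
  co <- sg_decompose(matrix(0.3, g$N, g$N), g, ctl$spec, L = 4)
  expect_lt(max(abs(pm_rhs(co, ctl))), 1e-10)
  xs <- pmwave:::grid_xs(g); ys <- pmwave:::grid_ys(g)
  U <- outer(ys, xs, function(y, x) x^2 + y^2)
  cu <- sg_decompose(U, g, ctl$spec, L = 4)
  F <- pm_rhs(cu, ctl)
  expect_lt(max(abs(F - 4)), 1e-3)
})

test_that("the wavelet right-hand side converges to the FD divergence form at rate ~h^2", {
  ctl <- pm_control(k = 1, j0 = 2)
  diffs <- vapply(6:8, function(J) {
    g <- multilevel_grid(2, J); N <- g$N; h <- 1 / (N - 1)
    xs <- pmwave:::grid_xs(g); ys <- pmwave:::grid_ys(g)
    U <- outer(ys, xs, function(y, x)
      0.5 + 0.3 * sin(2 * pi * x) * cos(pi * y) + 0.1 * x * y)
    co <- sg_decompose(U, g, ctl$spec, L = 4)
    Fw <- pm_rhs(co, ctl)
    mir <- function(m) rbind(m[1, ], m, m[N, ])[, c(1, 1:N, N)]
    um <- mir(U); ci <- 2:(N + 1)
    ux <- (um[ci, ci + 1] - um[ci, ci - 1]) / (2 * h)
    uy <- (um[ci + 1, ci] - um[ci - 1, ci]) / (2 * h)
    cv <- diffusivity(sqrt(ux^2 + uy^2), ctl$k, ctl$c_type)
    cm <- mir(cv)
    Ffd <- ((cm[ci, ci + 1] + cv) / 2 * (um[ci, ci + 1] - U) -
              (cm[ci, ci - 1] + cv) / 2 * (U - um[ci, ci - 1])) / h^2 +
           ((cm[ci + 1, ci] + cv) / 2 * (um[ci + 1, ci] - U) -
              (cm[ci - 1, ci] + cv) / 2 * (U - um[ci - 1, ci])) / h^2
    int <- 8:(N - 7)
    max(abs((Fw - Ffd)[int, int]))
  }, numeric(1))
  rates <- diffs[-3] / diffs[-1]           # successive halvings of h
  expect_true(all(rates > 2))              # -> 4 as the O(h^2) gap dominates
  expect_gt(rates[2], 2.5)
})

test_that("the homotopy parameter is the affine map of the step", {
  expect_equal(homotopy_parameter(0.2, 0.2, 0.4), 0)
  expect_equal(homotopy_parameter(0.4, 0.2, 0.4), 1)
  expect_equal(homotopy_parameter(0.3, 0.2, 0.4), 0.5)
  expect_error(homotopy_parameter(0.5, 0.2, 0.4), "step")
})

test_that("one step reduces to the quadratic growth polynomial on a scalar surrogate", {
  lam <- -2.5; dt <- 0.1; phi <- 1.7
  st <- pmwave:::hpm_step_core(phi, function(p) lam * p, dt)
  expect_equal(st$phi, phi * (1 + lam * dt + (lam * dt)^2 / 2))
  # F == 0 leaves the state untouched
  g <- multilevel_grid(2, 4)
  ctl <- pm_control(j0 = 2, t_end = 2e-5)
  state <- hpm_state(matrix(0.25, g$N, g$N), g, ctl)
  s2 <- hpm_step(state, ctl)
  expect_equal(s2$values, state$values)
  expect_equal(s2$t, ctl$tau)
})

test_that("time stepping is second order against a Crank-Nicolson oracle on the heat equation", {
  g <- multilevel_grid(2, 4); N <- g$N
  xs <- pmwave:::grid_xs(g); ys <- pmwave:::grid_ys(g)
  U0 <- 0.5 + 0.25 * outer(ys, xs, function(y, x) cos(pi * x) * cos(pi * y))
  spec <- scaling_spec("daub_autocorr", M = 3)
  # assemble the linear spatial operator column by column
  nv <- N * N
  A <- matrix(0, nv, nv)
  for (i in seq_len(nv)) {
    e <- matrix(0, N, N); e[i] <- 1
    co <- sg_decompose(e, g, spec, L = 4)
    A[, i] <- as.vector(pmwave:::sg_eval_grid(co, xs, ys, 2, 0) +
                          pmwave:::sg_eval_grid(co, xs, ys, 0, 2))
  }
  t_end <- 8e-4
  taus <- c(4e-5, 2e-5, 1e-5)
  errs <- vapply(taus, function(tau) {
    ctl <- pm_control(k = Inf, tau = tau, t_end = t_end, j0 = 2,
                      threshold = 0, L = 4)
    rh <- pmwave:::pm_solve_single(U0, ctl, grid = g)
    Mcn <- solve(diag(nv) - tau / 2 * A, diag(nv) + tau / 2 * A)
    v <- as.vector(U0)
    for (s in seq_len(round(t_end / tau))) v <- Mcn %*% v
    max(abs(as.vector(rh$values) - v))
  }, numeric(1))
  slope <- coef(lm(log(errs) ~ log(taus)))[2]
  expect_gt(slope, 1.7)
  expect_lt(slope, 2.3)
  # and both tracks follow the analytic decay of the single Fourier mode
  ctl <- pm_control(k = Inf, tau = 1e-5, t_end = t_end, j0 = 2,
                    threshold = 0, L = 4)
  rh <- pmwave:::pm_solve_single(U0, ctl, grid = g)
  exact <- 0.5 + 0.25 * exp(-2 * pi^2 * t_end) *
    outer(ys, xs, function(y, x) cos(pi * x) * cos(pi * y))
  expect_lt(max(abs(rh$values - exact)), 1e-3)
  fd <- fd_reference_solve(U0, ctl)
  expect_lt(max(abs(fd$values - exact)), 5e-3)
})

test_that("a zero-noise constant image passes through the solver unchanged", {
  ctl <- pm_control(t_end = 3e-5, j0 = 2)
  fit <- pm_denoise(matrix(0.4, 33, 33), ctl)
  expect_lt(max(abs(fit$output - 0.4)), 1e-12)
  expect_equal(length(unique(fit$diagnostics$active)), 1L)
})

test_that("denoising a seeded phantom improves PSNR and shrinks the active set", {
  ph <- generate_phantom(65, "disks", noise_sigma = 0.05, seed = 42)
  fit <- pm_denoise(ph$noisy, pm_control(j0 = 3), clean = ph$clean)
  expect_gt(fit$psnr[["output"]], fit$psnr[["input"]])
  a <- fit$diagnostics$active
  expect_lte(a[length(a)], a[1])
  # approximate maximum principle
  expect_gte(min(fit$output), min(ph$noisy) - 0.01)
  expect_lte(max(fit$output), max(ph$noisy) + 0.01)
})

test_that("threshold-0 solve equals the uncompressed multilevel solve", {
  ph <- generate_phantom(33, "disks", noise_sigma = 0.05, seed = 7)
  ctl <- pm_control(threshold = 0, j0 = 2, t_end = 3e-5)
  fit <- pm_denoise(ph$noisy, ctl)
  # manual full-grid stepping without any compress/masking in the loop
  g <- multilevel_grid(2, 5)
  U <- ph$noisy
  for (s in 1:3) {
    rhs <- function(v) pm_rhs(sg_decompose(v, g, ctl$spec, ctl$L), ctl)
    st <- pmwave:::hpm_step_core(U, rhs, ctl$tau)
    U <- st$phi
  }
  expect_lt(max(abs(fit$output - U)), 1e-8)
})

test_that("the stepper reports instability instead of returning nonfinite fields", {
  g <- multilevel_grid(2, 4)
  set.seed(1)
  ctl <- pm_control(k = Inf, tau = 0.5, t_end = 10, j0 = 2, threshold = 0, L = 4)
  U <- matrix(runif(g$N^2), g$N, g$N)
  expect_error(pmwave:::pm_solve_single(U, ctl, grid = g), "instability")
})

test_that("the FD reference scheme conserves gray level and matches stencil algebra", {
  set.seed(9)
  U <- matrix(runif(33 * 33), 33, 33)
  ctl <- pm_control(k = 0.5, tau = 1e-5, t_end = 5e-5)
  r <- fd_reference_solve(U, ctl)
  expect_lt(abs(sum(r$values) - sum(U)), 1e-10)
  # constant unchanged
  rc <- fd_reference_solve(matrix(0.7, 17, 17), ctl)
  expect_equal(rc$values, matrix(0.7, 17, 17))
  # one heat step of x^2 + y^2 adds tau * 4 in the interior
  xs <- seq(0, 1, length.out = 33)
  U2 <- outer(xs, xs, function(y, x) x^2 + y^2)
  ctl1 <- pm_control(k = Inf, tau = 1e-5, t_end = 1e-5)
  r2 <- fd_reference_solve(U2, ctl1)
  expect_lt(max(abs(r2$values[3:31, 3:31] - (U2 + 4e-5)[3:31, 3:31])), 1e-12)
  expect_warning(fd_reference_solve(U2, pm_control(tau = 1, t_end = 1)), "stability")
})

test_that("the wavelet solver keeps a step edge at least as sharp as the FD solver", {
  # qualitative edge-preservation ordering on the seeded step phantom;
  # logged (not load-bearing for the numerics above)
  ph <- generate_phantom(65, "step_edge", noise_sigma = 0.05, seed = 42)
  ctl <- pm_control(j0 = 3)
  fw <- pm_denoise(ph$noisy, ctl)
  fd <- fd_reference_solve(ph$noisy, ctl)
  egrad <- function(m) mean(abs(m[, 34] - m[, 32])) * (64 / 2)
  gw <- egrad(fw$output); gf <- egrad(fd$values)
  if (gw < gf)
    message("edge-preservation ordering violated: wavelet ", gw, " < fd ", gf)
  expect_gte(gw, gf * 0.98)
})
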