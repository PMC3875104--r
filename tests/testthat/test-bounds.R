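test_that("power-kernel Beta integral matches its closed form and quadrature", {
  # hand-computable cases
  expect_equal(beta_integral(1, 1, 1, 2), 2)          # int_0^2 ds
  expect_equal(beta_integral(1, 1, 2, 1), 0.5)        # int_0^1 s ds
  # randomized sweep against adaptive quadrature
  set.seed(17)
  for (i in 1:30) {
    p <- runif(1, 0.5, 3)
    b <- runif(1, 0.2, 2)
    g <- runif(1, 0.2, 2)
    # keep the endpoint singularities mild enough for adaptive quadrature
    if (p * (b - 1) + 1 <= 0.3 || p * (g - 1) + 1 <= 0.3) next
    t_up <- runif(1, 0.5, 3)
    cf <- beta_integral(p, b, g, t_up)
    qd <- integrate(function(s) (t_up - s)^(p * (b - 1)) * s^(p * (g - 1)),
                    0, t_up, rel.tol = 1e-10)$value
    expect_equal(cf, qd, tolerance = 1e-8)
  }
  expect_error(beta_integral(3, 0.2, 1, 1), "non-integrable")
})

test_that("Hoelder exponents satisfy the conjugacy and positivity identities", {
  e <- holder_exponents(0.8)
  expect_equal(e$p, 21 / 17, tolerance = 1e-15)
  expect_equal(e$q, 5.25, tolerance = 1e-15)
  expect_equal(e$q * 0.8 - 1, 4 * 0.8, tolerance = 1e-12)
  set.seed(29)
  for (alpha in runif(200, 0.001, 0.999)) {
    ex <- holder_exponents(alpha)
    expect_equal(1 / ex$p + 1 / ex$q, 1, tolerance = 1e-14)
    expect_equal(ex$q * alpha - 1, 4 * alpha, tolerance = 1e-12)
    expect_lt(abs(ex$p * (alpha - 1) + 1 - 4 * alpha^2 / (1 + 3 * alpha)),
              1e-14)
    # Beta argument stays positive and finite
    barg <- ex$p * (alpha - 1) + 1
    expect_gt(barg, 0)
    expect_true(is.finite(beta(barg, barg)))
  }
  expect_error(holder_exponents(1))
  expect_error(holder_exponents(0))
})

test_that("the kernel k*(t) vanishes at zero, grows monotonically, matches direct arithmetic", {
  expect_identical(kstar(0, 0.8), 0)
  set.seed(41)
  grid <- seq(0.05, 4, length.out = 60)
  for (alpha in runif(20, 0.05, 0.95)) {
    expect_true(all(diff(kstar(grid, alpha)) >= 0))
  }
  # direct (non-log) special-function arithmetic as oracle at alpha = 0.8
  e <- 1.235294117647059 * (0.8 - 1) + 1
  oracle <- beta(e, e)^(5.25 / 1.235294117647059) / gamma(0.8)^5.25
  expect_equal(kstar(1, 0.8), oracle, tolerance = 1e-10)
})

test_that("decoupled Gronwall bound collapses to the classical single-function form", {
  gi <- gronwall_inputs(const_fun(1), const_fun(2),
                        phi11 = const_kernel(0.3), phi12 = const_kernel(0),
                        phi21 = const_kernel(0), phi22 = const_kernel(0.2))
  grid <- seq(0, 2, length.out = 41)
  gb <- coupled_gronwall_bound(gi, grid)
  expect_equal(gb$u_bound, 1 * exp(0.3 * grid), tolerance = 1e-10)
  expect_equal(gb$v_bound, 2 * exp(0.2 * grid), tolerance = 1e-10)
})

test_that("constant-kernel Gronwall bound matches the closed form", {
  cc <- 0.5
  gi <- gronwall_inputs(const_fun(1), const_fun(1),
                        phi11 = const_kernel(cc), phi12 = const_kernel(cc),
                        phi21 = const_kernel(cc), phi22 = const_kernel(cc))
  grid <- seq(0, 1, length.out = 81)
  gb <- coupled_gronwall_bound(gi, grid, refine = 2)
  # with phi = c and f = 1: Phi_i = e^{ct}, the cross integral is e^{ct} - 1,
  # the nested term is (e^{2ct} - 1)/2 - (e^{ct} - 1)
  closed <- exp(cc * grid) *
    exp(cc * grid + (exp(2 * cc * grid) - 1) / 2 - (exp(cc * grid) - 1))
  expect_equal(gb$u_bound, closed, tolerance = 1e-4)
  expect_equal(gb$v_bound, closed, tolerance = 1e-4)
})

test_that("Gronwall bounds dominate Picard fixed points of the equality system", {
  # The Picard oracle is run on an 8x finer grid so its own O(h^2)
  # discretization error stays below the comparison slack: in the decoupled
  # family the bound is *attained* by the equality solution, so the margin
  # there is purely numerical.
  grid <- seq(0, 1.5, length.out = 61)
  fine <- seq(0, 1.5, length.out = 481)
  at <- match(grid, fine)
  slack <- 1e-6
  check_family <- function(f1, f2, ph) {
    gi <- gronwall_inputs(f1, f2, ph[[1]], ph[[2]], ph[[3]], ph[[4]])
    gb <- coupled_gronwall_bound(gi, grid, refine = 2)
    fp <- picard_fixed_point(f1, f2, ph[[1]], ph[[2]], ph[[3]], ph[[4]], fine)
    expect_true(all(gb$u_bound >= fp$u[at] - slack))
    expect_true(all(gb$v_bound >= fp$v[at] - slack))
  }
  # decoupled (classical single-function Gronwall, bound attained)
  check_family(const_fun(1), const_fun(0.5),
               lapply(c(0.4, 0, 0, 0.3), const_kernel))
  # constant coupled kernels
  check_family(const_fun(1), const_fun(1),
               lapply(c(0.3, 0.2, 0.25, 0.35), const_kernel))
  # nondecreasing time-varying kernels
  check_family(function(t) 0.5 + 0.1 * t, function(t) 1 + t^2,
               list(function(t, s) rep(0.2 * (1 + t), length(s)),
                    function(t, s) 0.1 * (t + s),
                    function(t, s) rep(0.15 * sqrt(t), length(s)),
                    function(t, s) 0.25 * t * (1 + s)))
})

test_that("non-monotone or negative Gronwall inputs are rejected with an index", {
  gi_bad <- gronwall_inputs(function(t) 1 - t, const_fun(1),
                            const_kernel(0.1), const_kernel(0),
                            const_kernel(0), const_kernel(0.1))
  expect_error(coupled_gronwall_bound(gi_bad, seq(0, 1, 0.1)),
               "decreasing at grid index")
  gi_neg <- gronwall_inputs(const_fun(1), const_fun(1),
                            const_kernel(-0.1), const_kernel(0),
                            const_kernel(0), const_kernel(0.1))
  expect_error(coupled_gronwall_bound(gi_neg, seq(0, 1, 0.1)), "negative")
})

test_that("trajectory envelopes reduce, refine, and respond monotonically", {
  zero <- const_fun(0)
  grid <- seq(0.1, 2, length.out = 20)
  # all coefficients zero: the bare singular prefactor remains
  cur0 <- theorem9_bounds(list(a1_t = zero, a2_t = zero,
                               b1_t = zero, b2_t = zero), 0.8, grid)
  expect_equal(cur0$bound_x1, grid^(0.8 - 1), tolerance = 1e-14)
  expect_equal(cur0$bound_x2, grid^(0.8 - 1), tolerance = 1e-14)

  # constant coefficients: values stable under a 10x finer quadrature grid
  coeffs <- list(a1_t = const_fun(0.2), a2_t = const_fun(0.15),
                 b1_t = const_fun(0.1), b2_t = const_fun(0.12))
  coarse <- theorem9_bounds(coeffs, 0.8, grid)
  dense_grid <- sort(unique(c(seq(0.1, 2, length.out = 191), grid)))
  dense <- theorem9_bounds(coeffs, 0.8, dense_grid)
  at <- match(grid, dense_grid)
  expect_equal(coarse$bound_x1, dense$bound_x1[at], tolerance = 1e-4)
  expect_equal(coarse$bound_x2, dense$bound_x2[at], tolerance = 1e-4)

  # enlarging any coefficient never decreases either envelope
  for (nm in c("a1_t", "a2_t", "b1_t", "b2_t")) {
    bigger <- coeffs
    bigger[[nm]] <- const_fun(0.4)
    cb <- theorem9_bounds(bigger, 0.8, grid)
    expect_true(all(cb$bound_x1 >= coarse$bound_x1 - 1e-12))
    expect_true(all(cb$bound_x2 >= coarse$bound_x2 - 1e-12))
  }

  expect_error(theorem9_bounds(coeffs, 0.8, c(0, 1)), "strictly positive")
})

test_that("power-law rescaling of trajectories is elementwise exact", {
  sys <- fde_system(0.8, 2, function(t, y) c(-y[1], -0.5 * y[2]), c(1, 2))
  tr <- caputo_pece_solve(sys, solver_config(0.05, 1))
  st <- scaled_trajectory(tr, 0.8)
  expect_equal(st$grid, tr$times[-1])
  expect_equal(st$beta_t, abs(tr$states[-1, 1]) * tr$times[-1]^0.2)
  expect_equal(st$gamma_t, abs(tr$states[-1, 2]) * tr$times[-1]^0.2)
  # alpha = 1: no rescaling
  st1 <- scaled_trajectory(tr, 1)
  expect_equal(st1$beta_t, abs(tr$states[-1, 1]))
  # zero trajectory stays zero
  trz <- caputo_pece_solve(fde_system(0.8, 2, function(t, y) 0 * y, c(0, 0)),
                           solver_config(0.05, 1))
  stz <- scaled_trajectory(trz, 0.8)
  expect_true(all(stz$beta_t == 0 & stz$gamma_t == 0))
})

test_that("bound verification counts violations correctly", {
  grid <- seq(0.1, 1, by = 0.1)
  zero <- const_fun(0)
  curve <- theorem9_bounds(list(a1_t = zero, a2_t = zero,
                                b1_t = zero, b2_t = zero), 0.8, grid)
  mk_traj <- function(states) {
    structure(list(times = c(0, grid),
                   states = rbind(c(0, 0), states),
                   order = 0.8, step = 0.1), class = "fde_trajectory")
  }
  # zero trajectory: every point below the envelope
  rep0 <- verify_bound(mk_traj(matrix(0, 10, 2)), curve)
  expect_identical(rep0$fraction, 1)
  # one exceeding point out of m: fraction 1 - 1/m
  st <- matrix(0.1, 10, 2)
  st[4, 1] <- 10   # above t^(alpha-1) everywhere on this grid
  rep1 <- verify_bound(mk_traj(st), curve)
  expect_equal(rep1$fraction, 1 - 1 / 10)
  expect_gt(rep1$worst_ratio, 1)
  # mismatched grids are rejected
  bad <- mk_traj(matrix(0, 10, 2))
  bad$times <- bad$times + 0.01
  expect_error(verify_bound(bad, curve), "do not match")
})

test_that("a non-Lipschitz system inside the linear envelope respects its bound", {
  # f_i = c sqrt(|x1 x2|) satisfies |f_i| <= (c/2)|x1| + (c/2)|x2| (AM-GM)
  # but is not Lipschitz at the origin; a tiny positive start approximates a
  # nontrivial branch of the non-unique zero-start problem.
  cc <- 0.5
  alpha <- 0.8
  rhs <- function(t, y) rep(cc * sqrt(abs(y[1] * y[2])), 2)
  sys <- fde_system(alpha, 2, rhs, c(1e-8, 1e-8))
  tr <- caputo_pece_solve(sys, solver_config(0.01, 2))
  expect_gt(max(tr$states), 1e-8)   # the branch actually grows
  coeffs <- list(a1_t = const_fun(cc / 2), a2_t = const_fun(cc / 2),
                 b1_t = const_fun(cc / 2), b2_t = const_fun(cc / 2))
  curve <- theorem9_bounds(coeffs, alpha, tr$times[-1])
  rep <- verify_bound(tr, curve)
  expect_identical(rep$fraction, 1)
})

test_that("couple-model envelope helper enforces its domain of validity", {
  p0 <- couple_params(0.2, 0.3, 0.1, -0.05, 0.01, 0, 0, nu = 0.8)
  cf <- couple_bound_coefficients(p0, M = 2)
  expect_equal(cf$a1_t(c(0, 1)), c(0.2, 0.2))
  expect_equal(cf$b1_t(1), 0.1 * (1 + 0.01 * 4))
  expect_equal(cf$b2_t(1), 0.05 * (1 + 0.01 * 4))
  # attraction constants cannot be absorbed into a homogeneous envelope
  expect_error(couple_bound_coefficients(section5_params(), M = 2),
               "A1 = A2 = 0")
})

test_that("bound curves serialize with the documented columns", {
  grid <- seq(0.2, 1, length.out = 5)
  curve <- theorem9_bounds(list(a1_t = const_fun(0.1), a2_t = const_fun(0.1),
                                b1_t = const_fun(0.1), b2_t = const_fun(0.1)),
                           0.7, grid)
  path <- withr::local_tempfile(fileext = ".csv")
  write_bound_curve_csv(curve, path)
  df <- read.csv(path)
  expect_identical(names(df),
                   c("t", "bound_x1", "bound_x2", "kstar", "Psi1", "Psi2"))
  expect_equal(df$bound_x1, curve$bound_x1)
})
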