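# Quadrature helpers.  All running integrals in this module are cumulative
# composite trapezoid sums on a once-refined (midpoint-inserted) grid; the
# kernels are smooth away from t = 0, so one refinement level recovers the
# accuracy a composite Simpson rule would give while keeping every grid point
# available as an upper limit.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(numeric(n))
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}
refine_grid <- function(x, levels = 1L) {
  for (i in seq_len(levels)) {
    mid <- (x[-1] + x[-length(x)]) / 2
    x <- sort(c(x, mid))
  }
  x
}

#' Closed-form power-kernel Beta integral
#'
#' Evaluates
#' \deqn{\int_0^t (t-s)^{p(\beta-1)} s^{p(\gamma-1)}\,ds
#'   = t^{\theta} B[p(\gamma-1)+1,\ p(\beta-1)+1],}
#' with `theta = p(beta + gamma - 2) + 1`, valid whenever both Beta arguments
#' are positive (integrability at the endpoints).  This identity converts the
#' Hölder remainder of the singular Caputo kernel into the explicit
#' [kstar()] factor.
#'
#' @param p,beta,gamma Positive constants.
#' @param t Positive upper limit (vectorized).
#' @return The integral value(s).
#' @export
beta_integral <- function(p, beta, gamma, t) {
  stopifnot(p > 0, beta > 0, gamma > 0, all(t >= 0))
  e1 <- p * (gamma - 1) + 1
  e2 <- p * (beta - 1) + 1
  if (e1 <= 0 || e2 <= 0)
    stop("beta_integral: non-integrable exponents (need p*(beta-1)+1 > 0 and p*(gamma-1)+1 > 0)")
  theta <- p * (beta + gamma - 2) + 1
  t^theta * exp(lbeta(e1, e2))
}

#' Hölder conjugate exponents of the a priori bound
#'
#' The bound derivation applies Hölder's inequality with the specific
#' conjugate pair
#' `p = (1 + 4 alpha) / (1 + 3 alpha)`, `q = (1 + 4 alpha) / alpha`,
#' chosen so that both kernel exponents stay integrable:
#' `p (alpha - 1) + 1 = 4 alpha^2 / (1 + 3 alpha) > 0` and
#' `q alpha - 1 = 4 alpha > 0`.
#'
#' @param alpha Fractional order in (0, 1).
#' @return An object of class `bound_exponents`: list with `p`, `q`, `alpha`.
#' @examples
#' e <- holder_exponents(0.8)
#' 1 / e$p + 1 / e$q   # 1
#' @export
holder_exponents <- function(alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1)
  if (alpha <= 0 || alpha >= 1)
    stop("holder_exponents: alpha must lie strictly in (0, 1)")
  structure(list(p = (1 + 4 * alpha) / (1 + 3 * alpha),
                 q = (1 + 4 * alpha) / alpha,
                 alpha = alpha),
            class = "bound_exponents")
}

#' The kernel factor k*(t) of the a priori bound
#'
#' \deqn{k^*(t) = t^{q\alpha - 1}\,
#'   B^{q/p}[p(\alpha-1)+1,\ p(\alpha-1)+1] \,/\, \Gamma^q(\alpha),}
#' with `p, q` from [holder_exponents()].  Since `q alpha - 1 = 4 alpha > 0`,
#' `k*(0) = 0` and `k*` is nondecreasing in `t`.  The Beta and Gamma powers
#' are computed in log space to avoid overflow at small `alpha` (where `q` is
#' large).
#'
#' @param t Nonnegative time(s); vectorized.
#' @param alpha Fractional order in (0, 1).
#' @return `k*(t)`, same length as `t`.
#' @export
kstar <- function(t, alpha) {
  ex <- holder_exponents(alpha)
  stopifnot(all(t >= 0))
  e <- ex$p * (alpha - 1) + 1
  logc <- (ex$q / ex$p) * lbeta(e, e) - ex$q * lgamma(alpha)
  ifelse(t == 0, 0, exp((ex$q * alpha - 1) * log(t) + logc))
}

#' Inputs for the coupled Gronwall bound
#'
#' Packages the data of the two-function Gronwall-type inequality
#' \deqn{u(t) \le f_1(t) + \int_0^t [\varphi_{11}(t,s) u(s)
#'   + \varphi_{12}(t,s) v(s)]\,ds}
#' (and symmetrically for `v`): nondecreasing nonnegative forcing functions
#' `f1`, `f2` and nonnegative kernels `phi_ij(t, s)`, each nondecreasing in
#' `t` for fixed `s`.  Monotonicity is verified on the evaluation grid by
#' [coupled_gronwall_bound()].
#'
#' @param f1,f2 Functions of one variable, vectorized.
#' @param phi11,phi12,phi21,phi22 Functions `(t, s)`, vectorized in `s`.
#' @return An object of class `gronwall_inputs`.
#' @export
gronwall_inputs <- function(f1, f2, phi11, phi12, phi21, phi22) {
  stopifnot(is.function(f1), is.function(f2), is.function(phi11),
            is.function(phi12), is.function(phi21), is.function(phi22))
  structure(list(f1 = f1, f2 = f2,
                 phi = list(phi11 = phi11, phi12 = phi12,
                            phi21 = phi21, phi22 = phi22)),
            class = "gronwall_inputs")
}

#' Explicit bounds of the coupled Gronwall inequality
#'
#' Evaluates the closed-form dominating functions of the two-function
#' Gronwall lemma:
#' \deqn{u(t) \le \Big[f_1(t) + f_2(t)\!\int_0^t \varphi_{12}(t,s)\Phi_2(s)ds\Big]
#'  \exp\Big\{\int_0^t \varphi_{11}(t,s)ds
#'  + \int_0^t \varphi_{12}(t,s)\Phi_2(s)
#'    \Big(\int_0^s \varphi_{21}(s,\tau)\Phi_1(\tau)d\tau\Big)ds\Big\},}
#' with `Phi_i(t) = exp(int_0^t phi_ii(t, s) ds)`, and symmetrically for `v`.
#' All running integrals (including the nested inner ones, whose kernels
#' depend on the outer variable) are composite trapezoid sums on a refined
#' copy of the evaluation grid.
#'
#' @param inputs A [gronwall_inputs].
#' @param grid Nondecreasing time grid starting at a value >= 0 (0 is
#'   prepended internally if absent).
#' @param refine Number of midpoint-refinement levels for the quadrature.
#' @return List with `grid`, `u_bound`, `v_bound`, `Phi1`, `Phi2` evaluated
#'   at the supplied grid points.
#' @export
coupled_gronwall_bound <- function(inputs, grid, refine = 1L) {
  stopifnot(inherits(inputs, "gronwall_inputs"))
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = FALSE) || any(grid < 0))
    stop("coupled_gronwall_bound: grid must be nondecreasing and nonnegative")
  ext <- if (grid[1] > 0) c(0, grid) else grid
  g <- refine_grid(ext, refine)
  M <- length(g)

  check_mono <- function(vals, what) {
    bad <- which(diff(vals) < -1e-10 * max(1, max(abs(vals))))
    if (length(bad))
      stop(sprintf("coupled_gronwall_bound: %s is decreasing at grid index %d",
                   what, bad[1]))
  }
  f1v <- inputs$f1(g); f2v <- inputs$f2(g)
  if (any(f1v < 0) || any(f2v < 0))
    stop("coupled_gronwall_bound: forcing functions must be nonnegative")
  check_mono(f1v, "f1"); check_mono(f2v, "f2")
  for (nm in names(inputs$phi)) {
    ph <- inputs$phi[[nm]]
    for (si in seq(1, M, length.out = min(M, 9))) {
      s <- g[round(si)]
      vals <- vapply(g, function(t) ph(t, s), numeric(1))
      if (any(vals < 0))
        stop(sprintf("coupled_gronwall_bound: kernel %s is negative", nm))
      check_mono(vals, sprintf("kernel %s (in t at s = %g)", nm, s))
    }
  }

  phi <- inputs$phi
  row_int <- function(ph, weight) {
    # k -> int_0^{g[k]} ph(g[k], s) * weight(s) ds
    vapply(seq_len(M), function(k) {
      s <- g[1:k]
      trapz(s, ph(g[k], s) * weight[1:k])
    }, numeric(1))
  }
  one <- rep(1, M)
  Phi1 <- exp(row_int(phi$phi11, one))
  Phi2 <- exp(row_int(phi$phi22, one))
  J1 <- row_int(phi$phi21, Phi1)   # s -> int_0^s phi21(s,.) Phi1
  J2 <- row_int(phi$phi12, Phi2)   # s -> int_0^s phi12(s,.) Phi2
  N1 <- row_int(phi$phi12, Phi2 * J1)
  N2 <- row_int(phi$phi21, Phi1 * J2)
  u_bound <- (f1v + f2v * J2) * Phi1 * exp(N1)
  v_bound <- (f2v + f1v * J1) * Phi2 * exp(N2)

  keep <- match(grid, g)
  list(grid = grid, u_bound = u_bound[keep], v_bound = v_bound[keep],
       Phi1 = Phi1[keep], Phi2 = Phi2[keep])
}

#' A priori trajectory envelopes for the 2-D fractional system
#'
#' For a Caputo system `D^alpha x_i = f_i(t, x1, x2)` (order in (0, 1), zero
#' initial data) whose right-hand sides obey the linear envelope
#' `|f1| <= a1(t)|x1| + b1(t)|x2|`, `|f2| <= b2(t)|x1| + a2(t)|x2|` with
#' continuous nonnegative coefficient functions, the solutions satisfy
#' \deqn{|x_1(t)| \le t^{\alpha-1} \exp\Big\{\tfrac{1}{q} k^*(t)
#'   \Big[\int_0^t a_1^q + \int_0^t b_1^q(s)\Psi_2(s)
#'   \Big(k^*(s)\int_0^s b_2^q(\tau)\Psi_1(\tau)d\tau\Big)ds\Big]\Big\},}
#' with `Psi_i(t) = exp(k*(t) int_0^t a_i^q(s) ds)` and symmetrically for
#' `x_2`.  The prefactor `t^{alpha-1}` diverges as `t -> 0+`, so the
#' evaluation grid must be strictly positive; integrals still start at 0.
#'
#' @param coeffs List (or [couple_bound_coefficients()] output) with
#'   vectorized nonnegative functions `a1_t`, `a2_t`, `b1_t`, `b2_t`.
#' @param alpha Fractional order in (0, 1).
#' @param grid Strictly positive, increasing time grid.
#' @param refine Midpoint-refinement levels for the quadrature.
#' @return An object of class `bound_curve`: list with `grid`, `bound_x1`,
#'   `bound_x2`, `kstar_values`, `Psi1`, `Psi2`, `exponents`.
#' @export
theorem9_bounds <- function(coeffs, alpha, grid, refine = 1L) {
  ex <- holder_exponents(alpha)
  grid <- as.numeric(grid)
  if (any(grid <= 0))
    stop("theorem9_bounds: grid must be strictly positive (prefactor t^(alpha-1) is singular at 0)")
  if (is.unsorted(grid, strictly = TRUE))
    stop("theorem9_bounds: grid must be strictly increasing")
  g <- refine_grid(c(0, grid), refine)
  q <- ex$q

  evalf <- function(f) {
    v <- f(g)
    if (length(v) == 1) v <- rep(v, length(g))
    if (any(v < 0)) stop("theorem9_bounds: coefficient functions must be nonnegative")
    v
  }
  a1q <- evalf(coeffs$a1_t)^q
  a2q <- evalf(coeffs$a2_t)^q
  b1q <- evalf(coeffs$b1_t)^q
  b2q <- evalf(coeffs$b2_t)^q

  ks <- kstar(g, alpha)
  A1 <- cumtrapz(g, a1q)
  A2 <- cumtrapz(g, a2q)
  Psi1 <- exp(ks * A1)
  Psi2 <- exp(ks * A2)
  inner1 <- ks * cumtrapz(g, b2q * Psi1)
  inner2 <- ks * cumtrapz(g, b1q * Psi2)
  T1 <- cumtrapz(g, b1q * Psi2 * inner1)
  T2 <- cumtrapz(g, b2q * Psi1 * inner2)
  pref <- c(Inf, g[-1]^(alpha - 1))
  bound1 <- pref * exp((ks / q) * (A1 + T1))
  bound2 <- pref * exp((ks / q) * (A2 + T2))

  keep <- match(grid, g)
  structure(list(grid = grid,
                 bound_x1 = bound1[keep], bound_x2 = bound2[keep],
                 kstar_values = ks[keep],
                 Psi1 = Psi1[keep], Psi2 = Psi2[keep],
                 exponents = ex),
            class = "bound_curve")
}

#' Constant envelope coefficients for the couple model on a box
#'
#' Derives constant coefficient functions for [theorem9_bounds()] from a
#' couple parameter set, valid while the trajectory stays in the box
#' `|x_i| <= M`: there `|beta_i x (1 - eps x^2)| <= |beta_i| (1 + eps M^2) |x|`.
#' This is a local linearization, not a global envelope.  The attraction
#' constants cannot be absorbed into a homogeneous linear envelope, so the
#' helper requires `A1 = A2 = 0`.
#'
#' @param params A [couple_params] with `A1 = A2 = 0`.
#' @param M Box half-width, positive.
#' @return A list of constant functions `a1_t`, `a2_t`, `b1_t`, `b2_t`.
#' @export
couple_bound_coefficients <- function(params, M) {
  stopifnot(inherits(params, "couple_params"), M > 0)
  if (params$A1 != 0 || params$A2 != 0)
    stop(paste("couple_bound_coefficients: the linear envelope requires",
               "A1 = A2 = 0 (constant appeal cannot be absorbed into a",
               "homogeneous bound)"))
  amp <- 1 + params$eps * M^2
  const_fun <- function(v) { force(v); function(t) rep(v, length(t)) }
  list(a1_t = const_fun(params$alpha1),
       a2_t = const_fun(params$alpha2),
       b1_t = const_fun(abs(params$beta1) * amp),
       b2_t = const_fun(abs(params$beta2) * amp))
}

#' Power-law rescaled trajectory
#'
#' The bound derivation works with the rescaled magnitudes
#' `beta(t) = |x1(t)| t^{1-alpha}` and `gamma(t) = |x2(t)| t^{1-alpha}`,
#' which absorb the singular prefactor.  The `t = 0` row is skipped.
#'
#' @param traj A 2-D `fde_trajectory`.
#' @param alpha Fractional order in (0, 1].
#' @return List with `grid` (positive times), `beta_t`, `gamma_t`.
#' @export
scaled_trajectory <- function(traj, alpha) {
  stopifnot(inherits(traj, "fde_trajectory"), ncol(traj$states) >= 2,
            alpha > 0, alpha <= 1)
  pos <- traj$times > 0
  tt <- traj$times[pos]
  list(grid = tt,
       beta_t = abs(traj$states[pos, 1]) * tt^(1 - alpha),
       gamma_t = abs(traj$states[pos, 2]) * tt^(1 - alpha))
}

#' Empirical verification of an a priori envelope
#'
#' Compares a solved 2-D trajectory against a [theorem9_bounds()] curve on
#' their shared grid and reports the fraction of grid points at which both
#' components sit below their envelopes, together with the worst ratio
#' `|x_i(t)| / bound_i(t)`.
#'
#' @param traj A 2-D `fde_trajectory` whose positive times equal
#'   `curve$grid`.
#' @param curve A `bound_curve`.
#' @return List with `fraction`, `worst_ratio`, `n_points`.
#' @export
verify_bound <- function(traj, curve) {
  stopifnot(inherits(traj, "fde_trajectory"), inherits(curve, "bound_curve"))
  pos <- traj$times > 0
  tt <- traj$times[pos]
  if (length(tt) != length(curve$grid) ||
      max(abs(tt - curve$grid)) > 1e-10 * max(1, max(curve$grid)))
    stop("verify_bound: trajectory and bound curve grids do not match")
  x1 <- abs(traj$states[pos, 1])
  x2 <- abs(traj$states[pos, 2])
  ok <- (x1 <= curve$bound_x1) & (x2 <= curve$bound_x2)
  list(fraction = mean(ok),
       worst_ratio = max(x1 / curve$bound_x1, x2 / curve$bound_x2),
       n_points = length(tt))
}

#' Write a bound curve as CSV
#'
#' Columns `t,bound_x1,bound_x2,kstar,Psi1,Psi2`.
#'
#' @param curve A `bound_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bound_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "bound_curve"))
  df <- data.frame(t = curve$grid, bound_x1 = curve$bound_x1,
                   bound_x2 = curve$bound_x2, kstar = curve$kstar_values,
                   Psi1 = curve$Psi1, Psi2 = curve$Psi2)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
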