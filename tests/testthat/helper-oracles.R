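# Independent oracles used across the suite.  These deliberately avoid the
# package's own quadrature/series helpers.

# plain trapezoid rule, independent of couplefde internals
oracle_trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Picard iteration for the EQUALITY version of the coupled Gronwall system
#   u(t) = f1(t) + int_0^t [phi11(t,s) u(s) + phi12(t,s) v(s)] ds   (and sym.)
# on a grid; returns the fixed point (u, v).
picard_fixed_point <- function(f1, f2, phi11, phi12, phi21, phi22, grid,
                               max_iter = 400, tol = 1e-12) {
  u <- f1(grid); v <- f2(grid)
  for (it in seq_len(max_iter)) {
    u_new <- vapply(seq_along(grid), function(k) {
      s <- grid[1:k]
      f1(grid[k]) + oracle_trapz(s, phi11(grid[k], s) * u[1:k] +
                                    phi12(grid[k], s) * v[1:k])
    }, numeric(1))
    v_new <- vapply(seq_along(grid), function(k) {
      s <- grid[1:k]
      f2(grid[k]) + oracle_trapz(s, phi21(grid[k], s) * u[1:k] +
                                    phi22(grid[k], s) * v[1:k])
    }, numeric(1))
    delta <- max(abs(u_new - u), abs(v_new - v))
    u <- u_new; v <- v_new
    if (delta < tol) break
  }
  list(u = u, v = v)
}

const_fun <- function(v) { force(v); function(t) rep(v, length(t)) }
const_kernel <- function(v) { force(v); function(t, s) rep(v, length(s)) }

# convenience: linear Caputo reference solution y0 * E_alpha(lambda t^alpha)
ml_reference <- function(alpha, lambda, y0 = 1) {
  function(t) y0 * vapply(t, function(ti)
    mittag_leffler(alpha, lambda * ti^alpha), numeric(1))
}
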