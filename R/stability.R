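#' Equilibria of the transformed couple system
#'
#' At an equilibrium of the 4-D transformed system the pass-through rows force
#' `y2* = y4* = 0`, leaving the two algebraic equations
#' `-alpha1 y1 + beta1 y3 (1 - eps y3^2) + A1 = 0` and
#' `-alpha2 y3 + beta2 y1 (1 - eps y1^2) + A2 = 0`.  The first is solved for
#' `y1` as a cubic polynomial in `y3`; substituting into the second yields a
#' univariate polynomial of degree at most 9 in `y3`, assembled symbolically
#' in its coefficients (no floating cancellation during assembly) and solved
#' by the companion-matrix method ([polyroot()]).  Real roots are
#' back-substituted, filtered by the residual of the 2-D rhs, and
#' de-duplicated.
#'
#' With `A1 = A2 = 0` the origin is always an equilibrium; the reference
#' regime has a unique positive equilibrium near (4.38469, 0, 4.92833, 0).
#'
#' @param params A [couple_params].
#' @param tol Residual tolerance: roots whose max-norm rhs residual exceeds
#'   `tol` are dropped.
#' @return A list of equilibria, each a list with `y` (length-4 state, zeros
#'   in positions 2 and 4) and `residual`; ordered by norm.  Empty if no real
#'   root survives the filter.
#' @export
find_equilibria <- function(params, tol = 1e-8) {
  stopifnot(inherits(params, "couple_params"))
  if (params$alpha1 == 0)
    stop("find_equilibria: elimination requires alpha1 != 0")
  a1 <- params$alpha1; a2 <- params$alpha2
  b1 <- params$beta1; b2 <- params$beta2
  eps <- params$eps; A1 <- params$A1; A2 <- params$A2

  # y1(y3) = (b1*y3*(1 - eps*y3^2) + A1)/a1, ascending coefficients in y3
  y1_poly <- c(A1 / a1, b1 / a1, 0, -eps * b1 / a1)
  # g(y3) = -a2*y3 + b2*(y1 - eps*y1^3) + A2
  y1_cubed <- poly_mul(poly_mul(y1_poly, y1_poly), y1_poly)
  g <- poly_add(poly_add(c(A2, -a2), b2 * y1_poly), -b2 * eps * y1_cubed)
  g <- poly_trim(g)

  if (length(g) < 2) return(list())  # constant: no root (or all of R; degenerate)
  roots <- polyroot(g)
  scale <- pmax(1, Mod(roots))
  y3_real <- Re(roots[abs(Im(roots)) <= 1e-8 * scale])

  eqs <- lapply(y3_real, function(y3) {
    y1 <- (b1 * y3 * (1 - eps * y3^2) + A1) / a1
    res <- max(abs(rhs_2d(params, y1, y3)))
    list(y = c(y1, 0, y3, 0), residual = res)
  })
  eqs <- Filter(function(e) e$residual < tol, eqs)
  # de-duplicate clustered roots
  if (length(eqs) > 1) {
    keep <- rep(TRUE, length(eqs))
    for (i in seq_along(eqs)[-1]) for (j in seq_len(i - 1)) {
      if (keep[j] && max(abs(eqs[[i]]$y - eqs[[j]]$y)) <
          1e-7 * max(1, max(abs(eqs[[j]]$y)))) keep[i] <- FALSE
    }
    eqs <- eqs[keep]
  }
  eqs[order(vapply(eqs, function(e) sqrt(sum(e$y^2)), numeric(1)))]
}

# ascending-coefficient polynomial helpers
poly_mul <- function(x, y) {
  n <- length(x) + length(y) - 1L
  r <- numeric(n)
  for (i in seq_along(x)) r[i:(i + length(y) - 1L)] <-
      r[i:(i + length(y) - 1L)] + x[i] * y
  r
}
poly_add <- function(x, y) {
  n <- max(length(x), length(y))
  c(x, numeric(n - length(x))) + c(y, numeric(n - length(y)))
}
poly_trim <- function(x, tol = 0) {
  last <- max(c(1L, which(abs(x) > tol)))
  x[seq_len(last)]
}

#' Jacobian of the transformed system at an equilibrium
#'
#' The linearization has the fixed sparsity pattern
#' rows `(0,1,0,0)`, `(-alpha1, 0, a, 0)`, `(0,0,0,1)`, `(b, 0, -alpha2, 0)`
#' with the cross-coupling slopes
#' `a = beta1 (1 - 3 eps y3*^2)` and `b = beta2 (1 - 3 eps y1*^2)`.
#'
#' @param params A [couple_params].
#' @param eq An equilibrium as returned by [find_equilibria()].
#' @return A list with `a`, `b`, and the 4x4 matrix `J`.
#' @export
jacobian_at <- function(params, eq) {
  stopifnot(inherits(params, "couple_params"), is.list(eq), length(eq$y) == 4)
  a <- params$beta1 * (1 - 3 * params$eps * eq$y[3]^2)
  b <- params$beta2 * (1 - 3 * params$eps * eq$y[1]^2)
  J <- matrix(c(0, 1, 0, 0,
                -params$alpha1, 0, a, 0,
                0, 0, 0, 1,
                b, 0, -params$alpha2, 0),
              4, 4, byrow = TRUE)
  list(a = a, b = b, J = J)
}

#' Reduced characteristic coefficients
#'
#' The characteristic polynomial of the 4x4 Jacobian is biquadratic,
#' `P(lambda) = lambda^4 + a1 lambda^2 + a2`, so with `k = lambda^2` it
#' reduces to `k^2 + a1 k + a2` where
#' `a1 = alpha1 + alpha2` and `a2 = alpha1 alpha2 - a b`.
#'
#' @param params A [couple_params].
#' @param jac Output of [jacobian_at()].
#' @return A list with `a1`, `a2`.
#' @export
characteristic_coefficients <- function(params, jac) {
  list(a1 = params$alpha1 + params$alpha2,
       a2 = params$alpha1 * params$alpha2 - jac$a * jac$b)
}

#' Roots of the reduced quadratic
#'
#' Both roots of `k^2 + a1 k + a2 = 0`, i.e.
#' `k = (-a1 +- sqrt(a1^2 - 4 a2)) / 2`, as complex numbers.
#'
#' @param coeffs Output of [characteristic_coefficients()].
#' @return Complex vector of length 2.
#' @export
reduced_roots <- function(coeffs) {
  disc <- as.complex(coeffs$a1^2 - 4 * coeffs$a2)
  s <- sqrt(disc)
  c((-coeffs$a1 + s) / 2, (-coeffs$a1 - s) / 2)
}

#' Fractional Routh-Hurwitz verdict
#'
#' For the biquadratic reduction the fractional Routh-Hurwitz sufficient
#' conditions are sign conditions on the reduced coefficients: `a1 > 0` and
#' `a2 > 0` imply local asymptotic stability for every order in (0, 1), while
#' `a2 < 0` implies instability (the quartic then has a positive real root).
#' Boundary cases fall outside both conditions and are reported as
#' `"indeterminate"` rather than forced to a side.
#'
#' @param coeffs Output of [characteristic_coefficients()].
#' @param tol Strictness tolerance for the sign tests.
#' @return One of `"stable"`, `"unstable"`, `"indeterminate"`.
#' @export
routh_hurwitz_classify <- function(coeffs, tol = 1e-12) {
  stopifnot(tol > 0)
  if (coeffs$a1 > tol && coeffs$a2 > tol) "stable"
  else if (coeffs$a2 < -tol) "unstable"
  else "indeterminate"
}

#' Eigenvalue-argument verdict
#'
#' The direct asymptotic stability test for a fractional linear system of
#' order `alpha`: stable iff every eigenvalue satisfies
#' `|arg(lambda)| > alpha * pi / 2`.  A zero eigenvalue (argument 0) violates
#' the condition.  Angles within `tol` of the sector boundary are reported
#' `"marginal"`.
#'
#' @param lambdas Complex vector of eigenvalues.
#' @param alpha Fractional order in (0, 1].
#' @param tol Angular strictness tolerance (radians).
#' @return One of `"stable"`, `"unstable"`, `"marginal"`.
#' @export
arg_condition_classify <- function(lambdas, alpha, tol = 1e-12) {
  stopifnot(alpha > 0, alpha <= 1, tol > 0)
  args <- abs(Arg(lambdas))
  args[Mod(lambdas) == 0] <- 0       # zero root: condition violated
  thr <- alpha * pi / 2
  if (min(args) > thr + tol) "stable"
  else if (any(args < thr - tol)) "unstable"
  else "marginal"
}

#' Full stability report at the reported equilibrium
#'
#' Assembles the equilibrium, Jacobian summary, reduced characteristic
#' coefficients, the two `k` roots, the four eigenvalues (both principal
#' square roots of each `k`, so that each `lambda^2` reproduces a `k`), and
#' the two independent stability verdicts.
#'
#' The reported equilibrium is the one with both feeling coordinates positive
#' and smallest norm (the "positive equilibrium"); if none is positive, the
#' smallest-residual one.
#'
#' @param params A [couple_params].
#' @param alpha Fractional order used for the argument test (defaults to
#'   `params$nu / 2` when `nu > 1`, else `params$nu`).
#' @param tol Residual tolerance for equilibrium finding.
#' @return An object of class `stability_report`.
#' @examples
#' rep <- full_stability_report(section5_params())
#' rep$routh_verdict   # "stable"
#' @export
full_stability_report <- function(params, alpha = NULL, tol = 1e-8) {
  stopifnot(inherits(params, "couple_params"))
  if (is.null(alpha)) alpha <- if (params$nu > 1) params$nu / 2 else params$nu
  eqs <- find_equilibria(params, tol = tol)
  if (length(eqs) == 0)
    stop(structure(class = c("couplefde_no_equilibrium", "error", "condition"),
                   list(message = "no equilibrium found within tolerance",
                        call = NULL)))
  pos <- Filter(function(e) e$y[1] > 0 && e$y[3] > 0, eqs)
  eq <- if (length(pos)) {
    pos[[which.min(vapply(pos, function(e) sum(e$y^2), numeric(1)))]]
  } else {
    eqs[[which.min(vapply(eqs, function(e) e$residual, numeric(1)))]]
  }
  jac <- jacobian_at(params, eq)
  coeffs <- characteristic_coefficients(params, jac)
  k <- reduced_roots(coeffs)
  lam <- c(sqrt(k[1]), -sqrt(k[1]), sqrt(k[2]), -sqrt(k[2]))
  routh <- routh_hurwitz_classify(coeffs)
  argv <- arg_condition_classify(lam, alpha)
  structure(list(equilibrium = eq, jac = jac, coeffs = coeffs,
                 k_roots = k, lambda_roots = lam,
                 routh_verdict = routh, arg_verdict = argv,
                 verdicts_agree = identical(routh, argv),
                 alpha = alpha),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability report (order alpha =", format(x$alpha), ")\n")
  cat(sprintf("  equilibrium: (%.5f, %.5f, %.5f, %.5f), residual %.2e\n",
              x$equilibrium$y[1], x$equilibrium$y[2], x$equilibrium$y[3],
              x$equilibrium$y[4], x$equilibrium$residual))
  cat(sprintf("  Jacobian slopes: a = %.6g, b = %.6g\n", x$jac$a, x$jac$b))
  cat(sprintf("  reduced coefficients: a1 = %.6g, a2 = %.6g\n",
              x$coeffs$a1, x$coeffs$a2))
  cat(sprintf("  k roots: %s\n", paste(format(x$k_roots, digits = 6),
                                       collapse = ", ")))
  cat(sprintf("  Routh-Hurwitz verdict: %s\n", x$routh_verdict))
  cat(sprintf("  argument-test verdict: %s (threshold %.4f rad)\n",
              x$arg_verdict, x$alpha * pi / 2))
  cat(sprintf("  verdicts agree: %s\n", x$verdicts_agree))
  invisible(x)
}

#' Serialize a stability report as JSON
#'
#' Complex numbers are written as `{re, im}` pairs.
#'
#' @param report A `stability_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stability_json <- function(report, path) {
  stopifnot(inherits(report, "stability_report"))
  cplx <- function(z) lapply(z, function(zi) list(re = Re(zi), im = Im(zi)))
  obj <- list(
    equilibrium = list(y = report$equilibrium$y,
                       residual = report$equilibrium$residual),
    jacobian = list(a = report$jac$a, b = report$jac$b,
                    J = apply(report$jac$J, 1, as.numeric, simplify = FALSE)),
    coefficients = report$coeffs,
    k_roots = cplx(report$k_roots),
    lambda_roots = cplx(report$lambda_roots),
    routh_verdict = report$routh_verdict,
    arg_verdict = report$arg_verdict,
    verdicts_agree = report$verdicts_agree,
    alpha = report$alpha)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
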