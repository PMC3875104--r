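#' Couple-model parameter set
#'
#' Bundles the seven constants of the nonlinear couple model together with the
#' derivative order.  `alpha1`, `alpha2` are the oblivion (decay) constants and
#' must be positive: each individual's feeling decays in the absence of the
#' partner.  `beta1`, `beta2` are the reaction constants (response to the
#' partner's feeling, either sign), `eps` the shared nonlinearity constant of
#' the cubic saturation term, and `A1`, `A2` the attraction (appeal) constants.
#' `nu` is the order of the Caputo derivative in the model equations: the
#' accelerated model uses `1 < nu <= 2` (solved through its 4-D order-`nu/2`
#' transformation), while the a priori bound machinery addresses
#' `0 < nu < 1`.
#'
#' @param alpha1,alpha2 Positive oblivion constants.
#' @param beta1,beta2 Reaction constants.
#' @param eps Nonnegative nonlinearity constant.
#' @param A1,A2 Attraction constants.
#' @param nu Derivative order, in (0, 2].
#'
#' @return An object of class `couple_params`.
#' @examples
#' p <- couple_params(0.005, 0.006, 4e-4, -1e-4, 1e-3, 0.02, 0.03, nu = 1.6)
#' rhs_2d(p, 0, 0)   # (A1, A2) at the origin
#' @export
couple_params <- function(alpha1, alpha2, beta1, beta2, eps, A1, A2, nu) {
  vals <- c(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
            eps = eps, A1 = A1, A2 = A2, nu = nu)
  if (!all(is.finite(vals)))
    stop("all couple-model parameters must be finite numbers")
  if (alpha1 <= 0 || alpha2 <= 0)
    stop("oblivion constants alpha1, alpha2 must be positive")
  if (eps < 0)
    stop("nonlinearity constant eps must be nonnegative")
  if (nu <= 0 || nu > 2)
    stop("derivative order nu must lie in (0, 2]")
  structure(as.list(vals), class = "couple_params")
}

#' @export
print.couple_params <- function(x, ...) {
  cat("Couple-model parameters (order nu =", format(x$nu), ")\n")
  cat(sprintf("  oblivion   alpha1 = %g, alpha2 = %g\n", x$alpha1, x$alpha2))
  cat(sprintf("  reaction   beta1  = %g, beta2  = %g\n", x$beta1, x$beta2))
  cat(sprintf("  nonlinear  eps    = %g\n", x$eps))
  cat(sprintf("  attraction A1     = %g, A2     = %g\n", x$A1, x$A2))
  invisible(x)
}

#' Reference parameter set of the accelerated couple simulation
#'
#' The parameter regime used throughout the package's worked examples: a
#' secure/cautious lover paired with a hermit, weak reactions relative to
#' attraction, and derivative order 1.6 (so the transformed system has order
#' 0.8).
#'
#' @return A [couple_params] object.
#' @export
section5_params <- function() {
  couple_params(alpha1 = 0.005, alpha2 = 0.006,
                beta1 = 0.0004, beta2 = -0.0001,
                eps = 0.001, A1 = 0.02, A2 = 0.03, nu = 1.6)
}

param_fields <- c("alpha1", "alpha2", "beta1", "beta2", "eps", "A1", "A2", "nu")

#' Read / write parameter sets as JSON
#'
#' Parameter sets are stored as flat JSON objects with keys
#' `alpha1, alpha2, beta1, beta2, eps, A1, A2, nu`.
#'
#' @param path File path.
#' @param params A [couple_params] object.
#' @return `read_params_json` returns a [couple_params]; `write_params_json`
#'   returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(param_fields, names(obj))
  if (length(missing))
    stop("parameter JSON is missing fields: ", paste(missing, collapse = ", "))
  do.call(couple_params, as.list(obj[param_fields]))
}

#' @rdname read_params_json
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "couple_params"))
  jsonlite::write_json(unclass(params)[param_fields], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
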