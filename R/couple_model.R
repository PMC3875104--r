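#' Right-hand side of the two-dimensional couple model
#'
#' The model couples the feelings `x1`, `x2` of two individuals through
#' \deqn{D^\nu x_1 = -\alpha_1 x_1 + \beta_1 x_2 (1 - \varepsilon x_2^2) + A_1,}
#' \deqn{D^\nu x_2 = -\alpha_2 x_2 + \beta_2 x_1 (1 - \varepsilon x_1^2) + A_2.}
#' Feelings decay at rate `alpha_i` in the absence of the partner, respond to
#' the partner with strength `beta_i` saturated by the cubic term, and are
#' driven by the constant appeal `A_i`.
#'
#' @param params A [couple_params].
#' @param x1,x2 Current feelings.
#' @return Numeric vector `c(dx1, dx2)` of the two derivative components.
#' @export
rhs_2d <- function(params, x1, x2) {
  stopifnot(inherits(params, "couple_params"))
  c(-params$alpha1 * x1 + params$beta1 * x2 * (1 - params$eps * x2^2) + params$A1,
    -params$alpha2 * x2 + params$beta2 * x1 * (1 - params$eps * x1^2) + params$A2)
}

#' Order reduction of the accelerated couple model
#'
#' The model of order `nu` in (1, 2] is never integrated directly: with zero
#' initial conditions the Caputo composition identity
#' `D^{nu/2}(D^{nu/2} x) = D^nu x` holds, so the substitution
#' `y1 = x1, y2 = D^{nu/2} x1, y3 = x2, y4 = D^{nu/2} x2` turns it into the
#' 4-D system of order `alpha = nu/2` in (0.5, 1]
#' \deqn{D^\alpha y = (y_2,\; -\alpha_1 y_1 + \beta_1 y_3(1-\varepsilon y_3^2)
#'   + A_1,\; y_4,\; -\alpha_2 y_3 + \beta_2 y_1(1-\varepsilon y_1^2) + A_2),}
#' solvable by [caputo_pece_solve()].  The zero initial state is hard-wired
#' because the composition identity requires it (and the model starts with no
#' feelings); rows 1 and 3 of the rhs are the pass-through components `y2`,
#' `y4`.
#'
#' @param params A [couple_params] with `1 < nu <= 2`.
#' @return An [fde_system] of order `nu / 2`, dimension 4, zero initial state.
#' @examples
#' sys <- transform_to_first_order(section5_params())
#' sys$rhs(0, c(0, 0, 0, 0))   # (0, A1, 0, A2)
#' @export
transform_to_first_order <- function(params) {
  stopifnot(inherits(params, "couple_params"))
  if (params$nu <= 1 || params$nu > 2)
    stop("transform_to_first_order: order reduction requires 1 < nu <= 2")
  a1 <- params$alpha1; a2 <- params$alpha2
  b1 <- params$beta1; b2 <- params$beta2
  eps <- params$eps; A1 <- params$A1; A2 <- params$A2
  fde_system(order = params$nu / 2, dimension = 4L,
             rhs = function(t, y) {
               c(y[2],
                 -a1 * y[1] + b1 * y[3] * (1 - eps * y[3]^2) + A1,
                 y[4],
                 -a2 * y[3] + b2 * y[1] * (1 - eps * y[1]^2) + A2)
             },
             initial_state = c(0, 0, 0, 0))
}

#' The 2-D couple model as an order-nu Caputo problem
#'
#' For `0 < nu <= 1` the model is a plain 2-D Caputo system, the setting of
#' the a priori bound machinery.  Unlike the accelerated path, the initial
#' state is user-settable here.
#'
#' @param params A [couple_params] with `0 < nu <= 1`.
#' @param initial_state Length-2 initial feelings, default `c(0, 0)`.
#' @return An [fde_system] of order `nu`, dimension 2.
#' @export
as_fde_system_2d <- function(params, initial_state = c(0, 0)) {
  stopifnot(inherits(params, "couple_params"))
  if (params$nu > 1)
    stop("as_fde_system_2d: requires 0 < nu <= 1 (use transform_to_first_order for nu > 1)")
  fde_system(order = params$nu, dimension = 2L,
             rhs = function(t, y) rhs_2d(params, y[1], y[2]),
             initial_state = initial_state)
}

# Romantic-style sign patterns.  The named constraints pin the signs that
# define the style; oblivion constants are always stored positive (the decay
# term enters the rhs as -alpha_i * x_i).
#   secure_cautious: individual 1 retreats from own feelings, is encouraged
#                    by the partner's  -> beta1 > 0
#   hermit:          individual 2 retreats from own feelings and from the
#                    partner's         -> beta2 < 0
style_sign_patterns <- list(
  secure_cautious = c(beta1 = 1, beta2 = 0),
  hermit = c(beta1 = 0, beta2 = -1)
)

default_scenario_ranges <- function() {
  ref <- section5_params()
  lapply(unclass(ref)[c("alpha1", "alpha2", "beta1", "beta2", "eps",
                        "A1", "A2")],
         function(v) sort(abs(v) * c(0.1, 10)))
}

#' Seeded romantic-style scenario generation
#'
#' Draws reproducible collections of couple-model parameter sets from named
#' sign regimes ("romantic styles").  Magnitudes are drawn uniformly from
#' per-parameter ranges (default: within one order of magnitude of the
#' reference regime, which keeps the cubic term perturbative), then the
#' style's sign pattern is applied; signs the style does not pin are drawn
#' uniformly at random for the reaction constants and kept positive for the
#' attraction constants.  The pseudo-style `"paper_section5"` returns exactly
#' the reference parameter set, untouched by randomness.
#'
#' @param styles Character vector of style names: `"secure_cautious"`,
#'   `"hermit"`, or `"paper_section5"`.
#' @param n Number of draws per style.
#' @param seed Integer RNG seed; identical `seed` + request reproduce the
#'   draws exactly.
#' @param ranges Named list of `c(lo, hi)` magnitude ranges for
#'   `alpha1, alpha2, beta1, beta2, eps, A1, A2`.
#' @param nu Derivative order assigned to the draws (default 1.6).
#'
#' @return An object of class `scenario_set`: list with `seed`, `styles`, and
#'   `draws` (a list of [couple_params], each with attribute `style`).
#' @examples
#' ss <- sample_scenarios("hermit", n = 3, seed = 42)
#' vapply(ss$draws, function(p) p$beta2, numeric(1))  # all negative
#' @export
sample_scenarios <- function(styles, n, seed,
                             ranges = default_scenario_ranges(), nu = 1.6) {
  stopifnot(n >= 1, length(styles) >= 1)
  unknown <- setdiff(styles, c(names(style_sign_patterns), "paper_section5"))
  if (length(unknown))
    stop("sample_scenarios: unknown style name(s): ",
         paste(unknown, collapse = ", "))
  for (rg in ranges)
    if (length(rg) != 2 || any(rg < 0) || rg[1] > rg[2])
      stop("sample_scenarios: ranges must be nonnegative c(lo, hi) pairs")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  draws <- list()
  for (style in styles) {
    for (i in seq_len(n)) {
      if (style == "paper_section5") {
        p <- section5_params()
      } else {
        mag <- vapply(ranges, function(rg) stats::runif(1, rg[1], rg[2]),
                      numeric(1))
        pat <- style_sign_patterns[[style]]
        sgn_beta <- function(name) {
          if (pat[[name]] != 0) pat[[name]] else sample(c(-1, 1), 1)
        }
        p <- couple_params(alpha1 = mag[["alpha1"]], alpha2 = mag[["alpha2"]],
                           beta1 = sgn_beta("beta1") * mag[["beta1"]],
                           beta2 = sgn_beta("beta2") * mag[["beta2"]],
                           eps = mag[["eps"]],
                           A1 = mag[["A1"]], A2 = mag[["A2"]], nu = nu)
      }
      attr(p, "style") <- style
      draws[[length(draws) + 1L]] <- p
    }
  }
  structure(list(seed = as.integer(seed), styles = styles, draws = draws),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("Scenario set: %d draws (%s), seed %d\n", length(x$draws),
              paste(x$styles, collapse = ", "), x$seed))
  invisible(x)
}

#' Scenario-set JSON round trip
#'
#' Scenario sets are written as a JSON object `{seed, styles, draws}` with
#' each draw a flat parameter object carrying its style.
#'
#' @param scenarios A `scenario_set`.
#' @param path File path.
#' @return The path (write) or a `scenario_set` (read).
#' @export
write_scenarios_json <- function(scenarios, path) {
  stopifnot(inherits(scenarios, "scenario_set"))
  draws <- lapply(scenarios$draws, function(p)
    c(unclass(p)[param_fields], list(style = attr(p, "style"))))
  jsonlite::write_json(list(seed = scenarios$seed, styles = scenarios$styles,
                            draws = draws),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenarios_json
#' @export
read_scenarios_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  draws <- lapply(obj$draws, function(d) {
    p <- do.call(couple_params, d[param_fields])
    attr(p, "style") <- d$style
    p
  })
  structure(list(seed = as.integer(obj$seed),
                 styles = unlist(obj$styles), draws = draws),
            class = "scenario_set")
}
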