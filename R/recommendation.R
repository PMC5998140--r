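#' Market prices for economic fertilization
#'
#' Prices per kg of N, P2O5 and K2O nutrient and per kg of grain. The
#' price ratios `alpha = p_n/p_y`, `beta = p_p/p_y`, `gamma = p_k/p_y`
#' enter the economic-rate equations.
#'
#' @param p_n,p_p,p_k,p_y Positive prices (currency per kg).
#' @return Object of class `price_spec` with elements `p_n`, `p_p`, `p_k`,
#'   `p_y`, `alpha`, `beta`, `gamma`.
#' @export
#' @examples
#' price_spec(p_n = 4.3, p_p = 5.0, p_k = 5.2, p_y = 2.8)
price_spec <- function(p_n, p_p, p_k, p_y) {
  pr <- c(p_n, p_p, p_k, p_y)
  if (!all(is.finite(pr)) || any(pr <= 0)) {
    stop("all prices must be positive and finite", call. = FALSE)
  }
  structure(list(p_n = p_n, p_p = p_p, p_k = p_k, p_y = p_y,
                 alpha = p_n / p_y, beta = p_p / p_y, gamma = p_k / p_y),
            class = "price_spec")
}

# build a price_spec directly from ratios (internal; used where only the
# ratios matter, e.g. property tests and the CLI's --ratios shortcut)
.price_from_ratios <- function(alpha, beta, gamma) {
  price_spec(p_n = alpha, p_p = beta, p_k = gamma, p_y = 1)
}

#' Maximum-yield fertilization rates of the non-structural model
#'
#' Setting the partial derivatives of yield to zero gives the closed form
#' `N_max = 1/c1 - N0`, `P_max = 1/c2 - P0`, `K_max = 1/c3 - K0`.
#' Negative components are returned as-is; interpreting them (extrapolation,
#' wrong signs) is the typicality stage's job.
#'
#' @param params A [tnfm_params()] with `c1, c2, c3 > 0`.
#' @return List with `rates` (named numeric `c(n, p, k)`, kg/hm^2) and
#'   `yield` (kg/hm^2, the model value at those rates).
#' @export
tnfm_max_rates <- function(params) {
  stopifnot(inherits(params, "tnfm_params"))
  p <- unclass(params)
  if (any(p[c("c1", "c2", "c3")] <= 0)) {
    stop("no finite maximum: all of c1, c2, c3 must be positive",
         call. = FALSE)
  }
  rates <- c(n = unname(1 / p["c1"] - p["N0"]),
             p = unname(1 / p["c2"] - p["P0"]),
             k = unname(1 / p["c3"] - p["K0"]))
  list(rates = rates,
       yield = tnfm_predict(params, rates["n"], rates["p"], rates["k"]))
}

#' Economic fertilization rates of the non-structural model
#'
#' Setting each marginal product equal to the fertilizer/grain price ratio
#' gives `N_eco = 1/(c1 + alpha/Y_eco) - N0` (and analogously for P, K),
#' an implicit system because `Y_eco` is the yield at the economic rates.
#' It is solved by fixed-point iteration: `Y_eco` starts at the maximum
#' yield, rates are recomputed, `Y_eco` is re-evaluated at those rates, and
#' the loop stops when no rate moves by more than `tol`. Three to five
#' iterations normally suffice.
#'
#' @param params A [tnfm_params()] with all components positive.
#' @param prices A [price_spec()].
#' @param max_iter Maximum iterations (default 5).
#' @param tol Componentwise rate-change tolerance in kg/hm^2 (default 0.1,
#'   far below agronomic relevance).
#' @return List with `rates`, `yield`, `iterations`, `converged`.
#' @export
tnfm_econ_rates <- function(params, prices, max_iter = 5L, tol = 0.1) {
  stopifnot(inherits(params, "tnfm_params"), inherits(prices, "price_spec"))
  p <- unclass(params)
  if (any(p <= 0)) {
    stop("economic rates require all-positive model parameters", call. = FALSE)
  }
  ratios <- c(prices$alpha, prices$beta, prices$gamma)
  cs <- p[c("c1", "c2", "c3")]
  supply <- p[c("N0", "P0", "K0")]

  y_eco <- tnfm_max_rates(params)$yield
  rates <- rep(NA_real_, 3)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    new_rates <- unname(1 / (cs + ratios / y_eco) - supply)
    y_eco <- tnfm_predict(params, new_rates[1], new_rates[2], new_rates[3])
    if (all(is.finite(rates)) && max(abs(new_rates - rates)) < tol) {
      rates <- new_rates
      converged <- TRUE
      break
    }
    rates <- new_rates
  }
  names(rates) <- c("n", "p", "k")
  list(rates = rates, yield = y_eco, iterations = iterations,
       converged = converged)
}

#' Maximum-yield fertilization rates of the quadratic model
#'
#' The critical point of the quadratic surface, which must exist and have a
#' negative-definite Hessian (leading principal minors G1 < 0, G2 > 0,
#' G3 < 0) to be a global maximum.
#'
#' @param params A [tpfm_params()].
#' @return List with `rates` and `yield`, as in [tnfm_max_rates()].
#' @export
tpfm_max_rates <- function(params) {
  stopifnot(inherits(params, "tpfm_params"))
  cp <- tpfm_critical_point(params)
  if (is.null(cp)) {
    stop("no maximum: the gradient system is singular (no unique critical ",
         "point)", call. = FALSE)
  }
  G <- tpfm_hessian_minors(params)
  bad <- c("G1 >= 0", "G2 <= 0", "G3 >= 0")[
    c(G["G1"] >= 0, G["G2"] <= 0, G["G3"] >= 0)]
  if (length(bad)) {
    stop("no maximum: Hessian not negative-definite (",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  list(rates = cp, yield = tpfm_predict(params, cp["n"], cp["p"], cp["k"]))
}

#' Economic fertilization rates of the quadratic model
#'
#' Solves the linear system `dY/dN = alpha`, `dY/dP = beta`,
#' `dY/dK = gamma` (marginal product equals the price ratio).
#'
#' @param params A [tpfm_params()] admitting a maximum (see
#'   [tpfm_max_rates()]).
#' @param prices A [price_spec()].
#' @return List with `rates` and `yield`.
#' @export
tpfm_econ_rates <- function(params, prices) {
  stopifnot(inherits(params, "tpfm_params"), inherits(prices, "price_spec"))
  H <- tpfm_hessian(params)
  b <- unclass(params)
  scale <- max(abs(H))
  if (scale == 0 || abs(det(H)) < 1e-12 * scale^3) {
    stop("singular gradient system: no unique economic rates", call. = FALSE)
  }
  rhs <- c(prices$alpha - b["b1"], prices$beta - b["b2"],
           prices$gamma - b["b3"])
  x <- solve(H, rhs)
  names(x) <- c("n", "p", "k")
  list(rates = x, yield = tpfm_predict(params, x["n"], x["p"], x["k"]))
}

#' Fertilization recommendation for a fitted model
#'
#' Combines the maximum-yield block and, when prices are supplied, the
#' economic block. Rates and yields are reported at full precision; the
#' print method rounds to whole kg/hm^2 as conventional in published
#' recommendation tables.
#'
#' @param params A [tnfm_params()] or [tpfm_params()] (or a fitted model
#'   object, whose parameters are extracted).
#' @param prices Optional [price_spec()].
#' @param ... Passed to the economic solver (e.g. `max_iter`, `tol`).
#' @return Object of class `recommendation`: list with `family`,
#'   `max_rates`, `max_yield`, and optionally `eco_rates`, `eco_yield`,
#'   `iterations_used`, `converged`.
#' @export
recommend <- function(params, prices = NULL, ...) {
  if (inherits(params, "fert_fit")) params <- params$params
  if (inherits(params, "tnfm_params")) {
    mx <- tnfm_max_rates(params)
    out <- list(family = "tnfm", max_rates = mx$rates, max_yield = mx$yield)
    if (!is.null(prices)) {
      eco <- tnfm_econ_rates(params, prices, ...)
      out <- c(out, list(eco_rates = eco$rates, eco_yield = eco$yield,
                         iterations_used = eco$iterations,
                         converged = eco$converged))
    }
  } else if (inherits(params, "tpfm_params")) {
    mx <- tpfm_max_rates(params)
    out <- list(family = "tpfm", max_rates = mx$rates, max_yield = mx$yield)
    if (!is.null(prices)) {
      eco <- tpfm_econ_rates(params, prices)
      out <- c(out, list(eco_rates = eco$rates, eco_yield = eco$yield))
    }
  } else {
    stop("params must be tnfm_params, tpfm_params or a fitted model",
         call. = FALSE)
  }
  structure(out, class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  fam <- switch(x$family, tnfm = "non-structural", tpfm = "quadratic")
  cat("Fertilization recommendation (", fam, " model), kg/hm^2:\n", sep = "")
  cat(sprintf("  maximum yield: N %.0f, P2O5 %.0f, K2O %.0f -> %.0f kg/hm^2\n",
              x$max_rates["n"], x$max_rates["p"], x$max_rates["k"],
              x$max_yield))
  if (!is.null(x$eco_rates)) {
    cat(sprintf("  economic:      N %.0f, P2O5 %.0f, K2O %.0f -> %.0f kg/hm^2\n",
                x$eco_rates["n"], x$eco_rates["p"], x$eco_rates["k"],
                x$eco_yield))
  }
  invisible(x)
}
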