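#' Parameters of the ternary non-structural fertilizer response model
#'
#' The model is `Y = A (N0+N)(P0+P)(K0+K) exp(-c1 N - c2 P - c3 K)`, with
#' `N`, `P`, `K` the application rates of N, P2O5 and K2O (kg/hm^2). `N0`,
#' `P0`, `K0` are soil nutrient supply equivalents (kg/hm^2), `c1..c3` the
#' yield-increase effect coefficients (1/(kg/hm^2)) and `A` the conversion
#' coefficient of soil fertility to yield. No sign constraints are imposed
#' at construction: negative estimates must be representable because
#' typicality is judged downstream.
#'
#' @param A,N0,P0,K0,c1,c2,c3 Model parameters (finite numerics).
#' @return Named numeric vector of class `tnfm_params`.
#' @export
#' @examples
#' tnfm_params(A = 1.16e-3, N0 = 163, P0 = 171, K0 = 133,
#'             c1 = 3.0e-3, c2 = 3.8e-3, c3 = 4.3e-3)
tnfm_params <- function(A, N0, P0, K0, c1, c2, c3) {
  p <- c(A = A, N0 = N0, P0 = P0, K0 = K0, c1 = c1, c2 = c2, c3 = c3)
  if (!all(is.finite(p))) stop("all parameters must be finite", call. = FALSE)
  structure(p, class = "tnfm_params")
}

#' Parameters of the ternary quadratic polynomial fertilizer response model
#'
#' The model is the full second-order polynomial
#' `Y = b0 + b1 N + b2 P + b3 K + b4 N^2 + b5 P^2 + b6 K^2 +
#'  b7 NP + b8 NK + b9 PK`.
#'
#' @param b0,b1,b2,b3,b4,b5,b6,b7,b8,b9 Regression coefficients.
#' @return Named numeric vector of class `tpfm_params`.
#' @export
tpfm_params <- function(b0, b1, b2, b3, b4, b5, b6, b7, b8, b9) {
  p <- c(b0 = b0, b1 = b1, b2 = b2, b3 = b3, b4 = b4,
         b5 = b5, b6 = b6, b7 = b7, b8 = b8, b9 = b9)
  if (!all(is.finite(p))) stop("all coefficients must be finite", call. = FALSE)
  structure(p, class = "tpfm_params")
}

# largest |exponent| admitted before exp() would over/underflow meaningfully
.exp_guard <- 700

#' Predicted yield under the non-structural model
#'
#' @param params A [tnfm_params()] object.
#' @param n,p,k Application rates in kg/hm^2 (vectorized, recycled).
#' @return Numeric vector of predicted yields (kg/hm^2).
#' @export
tnfm_predict <- function(params, n, p, k) {
  stopifnot(inherits(params, "tnfm_params"))
  pr <- unclass(params)
  ex <- -(pr["c1"] * n + pr["c2"] * p + pr["c3"] * k)
  if (any(!is.finite(ex)) || any(abs(ex) > .exp_guard)) {
    stop("numeric error: exponent |c1*N + c2*P + c3*K| exceeds ", .exp_guard,
         call. = FALSE)
  }
  unname(pr["A"] * (pr["N0"] + n) * (pr["P0"] + p) * (pr["K0"] + k) * exp(ex))
}

#' Predicted yield under the quadratic polynomial model
#'
#' @param params A [tpfm_params()] object.
#' @param n,p,k Application rates in kg/hm^2 (vectorized, recycled).
#' @return Numeric vector of predicted yields (kg/hm^2).
#' @export
tpfm_predict <- function(params, n, p, k) {
  stopifnot(inherits(params, "tpfm_params"))
  b <- unclass(params)
  unname(b["b0"] + b["b1"] * n + b["b2"] * p + b["b3"] * k +
         b["b4"] * n^2 + b["b5"] * p^2 + b["b6"] * k^2 +
         b["b7"] * n * p + b["b8"] * n * k + b["b9"] * p * k)
}

#' Marginal products (gradient) of the quadratic surface
#'
#' @param params A [tpfm_params()] object.
#' @param n,p,k Application rates of a single point.
#' @return Numeric `c(dY/dN, dY/dP, dY/dK)`.
#' @export
tpfm_gradient <- function(params, n, p, k) {
  stopifnot(inherits(params, "tpfm_params"))
  b <- unclass(params)
  unname(c(b["b1"] + 2 * b["b4"] * n + b["b7"] * p + b["b8"] * k,
           b["b2"] + 2 * b["b5"] * p + b["b7"] * n + b["b9"] * k,
           b["b3"] + 2 * b["b6"] * k + b["b8"] * n + b["b9"] * p))
}

#' Hessian matrix of the quadratic surface
#'
#' Constant in the rates: `[[2b4, b7, b8], [b7, 2b5, b9], [b8, b9, 2b6]]`.
#'
#' @param params A [tpfm_params()] object.
#' @return 3x3 symmetric numeric matrix.
#' @export
tpfm_hessian <- function(params) {
  stopifnot(inherits(params, "tpfm_params"))
  b <- unclass(params)
  matrix(c(2 * b["b4"], b["b7"],     b["b8"],
           b["b7"],     2 * b["b5"], b["b9"],
           b["b8"],     b["b9"],     2 * b["b6"]),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("N", "P", "K"), c("N", "P", "K")))
}

#' Leading principal minors of the quadratic surface's Hessian
#'
#' `G1 = 2 b4`, `G2 = 4 b4 b5 - b7^2`,
#' `G3 = 2 (4 b4 b5 b6 + b7 b8 b9 - b4 b9^2 - b5 b8^2 - b6 b7^2)`.
#' The sign pattern (-, +, -) certifies a negative-definite Hessian and so
#' a global maximum of the quadratic surface.
#'
#' @param params A [tpfm_params()] object.
#' @return Named numeric `c(G1, G2, G3)`.
#' @export
tpfm_hessian_minors <- function(params) {
  stopifnot(inherits(params, "tpfm_params"))
  b <- unclass(params)
  c(G1 = unname(2 * b["b4"]),
    G2 = unname(4 * b["b4"] * b["b5"] - b["b7"]^2),
    G3 = unname(2 * (4 * b["b4"] * b["b5"] * b["b6"] +
                     b["b7"] * b["b8"] * b["b9"] -
                     b["b4"] * b["b9"]^2 - b["b5"] * b["b8"]^2 -
                     b["b6"] * b["b7"]^2)))
}

#' Stationary (critical) point of the quadratic surface
#'
#' Solves the 3x3 linear system `grad Y = 0`. A relative determinant below
#' `1e-12` of its scale is treated as structurally singular (no unique
#' critical point) rather than round-off.
#'
#' @param params A [tpfm_params()] object.
#' @return Named numeric `c(n, p, k)`, or `NULL` when the system is
#'   singular.
#' @export
tpfm_critical_point <- function(params) {
  H <- tpfm_hessian(params)
  b <- unclass(params)
  rhs <- -c(b["b1"], b["b2"], b["b3"])
  scale <- max(abs(H))
  if (scale == 0 || abs(det(H)) < 1e-12 * scale^3) return(NULL)
  x <- solve(H, rhs)
  names(x) <- c("n", "p", "k")
  x
}

#' Quadratic (Taylor) reduction of the non-structural model
#'
#' Expanding `exp(x) = 1 + x + O(x^2)` in each nutrient factor and dropping
#' pairwise and triple products of `c1, c2, c3` as well as the N*P*K
#' interaction collapses the non-structural surface onto a full quadratic
#' polynomial: the quadratic model is a simplified special case of the
#' non-structural one. With `B = 1 - N0 c1`, `C = 1 - P0 c2`,
#' `D = 1 - K0 c3`:
#' `b0 = A N0 P0 K0`, `b1 = A B P0 K0`, `b2 = A C N0 K0`, `b3 = A D N0 P0`,
#' `b4 = -A c1 P0 K0`, `b5 = -A c2 N0 K0`, `b6 = -A c3 N0 P0`,
#' `b7 = A B C K0`, `b8 = A B D P0`, `b9 = A C D N0`.
#' The truncation is implemented exactly as stated; no higher-order
#' correction is applied.
#'
#' @param params A [tnfm_params()] object.
#' @return A [tpfm_params()] object.
#' @export
tnfm_to_quadratic <- function(params) {
  stopifnot(inherits(params, "tnfm_params"))
  p <- as.list(unclass(params))
  B <- 1 - p$N0 * p$c1
  C <- 1 - p$P0 * p$c2
  D <- 1 - p$K0 * p$c3
  tpfm_params(b0 = p$A * p$N0 * p$P0 * p$K0,
              b1 = p$A * B * p$P0 * p$K0,
              b2 = p$A * C * p$N0 * p$K0,
              b3 = p$A * D * p$N0 * p$P0,
              b4 = -p$A * p$c1 * p$P0 * p$K0,
              b5 = -p$A * p$c2 * p$N0 * p$K0,
              b6 = -p$A * p$c3 * p$N0 * p$P0,
              b7 = p$A * B * C * p$K0,
              b8 = p$A * B * D * p$P0,
              b9 = p$A * C * D * p$N0)
}

#' @export
print.tnfm_params <- function(x, digits = 5, ...) {
  cat("Non-structural fertilizer response parameters:\n")
  print(signif(unclass(x), digits), ...)
  invisible(x)
}

#' @export
print.tpfm_params <- function(x, digits = 5, ...) {
  cat("Quadratic polynomial fertilizer response coefficients:\n")
  print(signif(unclass(x), digits), ...)
  invisible(x)
}
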