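#' Goodness-of-fit statistics for a fertilizer response model
#'
#' The total sum of squares is taken about the observed mean; R^2 is
#' `1 - SSE/SST` (it can be negative for a fit worse than the mean). The
#' F statistic is `((SST - SSE)/df_reg) / (SSE/df_res)` with
#' `df_res = n - df_reg - 1`, and P its upper tail under F(df_reg, df_res).
#'
#' @param observed,fitted Numeric yield vectors of equal length.
#' @param df_reg Regression degrees of freedom (9 for the quadratic model,
#'   6 for the non-structural model).
#' @return Object of class `fit_stats`: list with `sse`, `sst`, `r2`, `f`,
#'   `df_reg`, `df_res`, `p`.
#' @export
goodness_of_fit <- function(observed, fitted, df_reg) {
  stopifnot(length(observed) == length(fitted), df_reg >= 1)
  n <- length(observed)
  if (n < df_reg + 2) stop("need at least df_reg + 2 observations", call. = FALSE)
  sse <- sum((observed - fitted)^2)
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) stop("zero total sum of squares: constant response", call. = FALSE)
  df_res <- n - df_reg - 1L
  f <- ((sst - sse) / df_reg) / (sse / df_res)
  f <- max(f, 0)
  structure(list(sse = sse, sst = sst, r2 = 1 - sse / sst, f = f,
                 df_reg = as.integer(df_reg), df_res = as.integer(df_res),
                 p = stats::pf(f, df_reg, df_res, lower.tail = FALSE)),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("R^2 = %.3f, F(%d,%d) = %.1f, P = %.3f\n",
              x$r2, x$df_reg, x$df_res, x$f, x$p))
  invisible(x)
}

# observations of a trial as a plain modelling frame
.model_frame <- function(trial) {
  stopifnot(inherits(trial, "trial_record"))
  with(trial$observations,
       data.frame(N = n_rate, P = p_rate, K = k_rate, Y = yield_mean))
}

#' Fit the quadratic polynomial model by ordinary least squares
#'
#' Regresses the 14 treatment yield means on
#' `(1, N, P, K, N^2, P^2, K^2, NP, NK, PK)`. Replicate standard deviations
#' are not used in fitting; the published significance tests are consistent
#' with treatment means (df_res = 4 for 10 coefficients).
#'
#' @param trial A [trial_record()].
#' @return Object of class `c("tpfm_fit", "fert_fit")`: list with `params`
#'   ([tpfm_params()]), `stats` ([goodness_of_fit()]), `fitted`,
#'   `residuals`, `site_id`, `design`, `family`.
#' @export
fit_tpfm <- function(trial) {
  d <- .model_frame(trial)
  X <- with(d, cbind(1, N, P, K, N^2, P^2, K^2, N * P, N * K, P * K))
  colnames(X) <- c("b0", "b1", "b2", "b3", "b4", "b5", "b6", "b7", "b8", "b9")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, d$Y)
  fitted <- drop(X %*% beta)
  structure(list(params = do.call(tpfm_params, as.list(beta)),
                 stats = goodness_of_fit(d$Y, fitted, df_reg = 9L),
                 fitted = fitted, residuals = d$Y - fitted,
                 site_id = trial$site_id, design = trial$design,
                 family = "tpfm", converged = TRUE, n_starts_used = 1L),
            class = c("tpfm_fit", "fert_fit"))
}

#' Default starting values for the non-structural fit
#'
#' Soil supply equivalents start at the level-2 rates; each yield-increase
#' coefficient at `1/(2 * level-2 rate)` (placing the implied optimum at the
#' level-2 rate); `A` at `control yield / (N0 * P0 * K0)` so that the
#' initial surface reproduces the unfertilized control exactly.
#'
#' @param trial A [trial_record()].
#' @return A [tnfm_params()] object.
#' @export
default_init <- function(trial) {
  stopifnot(inherits(trial, "trial_record"))
  des <- trial$design
  control <- trial$observations$yield_mean[
    trial$observations$treatment == "N0P0K0"]
  if (!length(control) || control <= 0) {
    stop("initialization error: control (N0P0K0) yield must be positive",
         call. = FALSE)
  }
  N0 <- des[["n2_rate"]]; P0 <- des[["p2_rate"]]; K0 <- des[["k2_rate"]]
  tnfm_params(A = control / (N0 * P0 * K0), N0 = N0, P0 = P0, K0 = K0,
              c1 = 1 / (2 * N0), c2 = 1 / (2 * P0), c3 = 1 / (2 * K0))
}

# residual vector for the Levenberg-Marquardt solver
.tnfm_residuals <- function(par, d) {
  ex <- -(par[5] * d$N + par[6] * d$P + par[7] * d$K)
  ex <- pmin(pmax(ex, -.exp_guard), .exp_guard)
  d$Y - par[1] * (par[2] + d$N) * (par[3] + d$P) * (par[4] + d$K) * exp(ex)
}

#' Fit the non-structural model by nonlinear least squares
#'
#' Minimizes `Q(a) = sum_i (Y_i - f(X_i, a))^2` over
#' `(A, N0, P0, K0, c1, c2, c3)` without sign constraints, by
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]) from multiple starting
#' points: the [default_init()] start plus `n_starts - 1` perturbed copies
#' (independent log-normal factors, sdlog 0.5, on each component). The
#' start reaching the lowest SSE wins. Results are deterministic given
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param trial A [trial_record()].
#' @param init Optional [tnfm_params()] overriding the default start.
#' @param n_starts Number of starts (>= 1); default 20.
#' @param seed Integer seed for start perturbations.
#' @return Object of class `c("tnfm_fit", "fert_fit")`; see [fit_tpfm()]
#'   for the common fields, plus `n_starts_used` and `converged`.
#' @export
fit_tnfm <- function(trial, init = NULL, n_starts = 20L, seed = 1L) {
  d <- .model_frame(trial)
  if (nrow(d) < 9L) stop("need at least 9 observations for 7 parameters",
                         call. = FALSE)
  start0 <- unclass(if (is.null(init)) default_init(trial) else init)
  stopifnot(length(start0) == 7L, n_starts >= 1L)

  # perturbation factors drawn from a private RNG stream
  starts <- list(start0)
  if (n_starts > 1L) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
    for (i in seq_len(n_starts - 1L)) {
      starts[[i + 1L]] <- start0 * stats::rlnorm(7L, meanlog = 0, sdlog = 0.5)
    }
  }

  best <- NULL
  diagnostics <- character(length(starts))
  for (i in seq_along(starts)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], fn = .tnfm_residuals, d = d,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) e)
    if (inherits(res, "error")) {
      diagnostics[i] <- conditionMessage(res)
      next
    }
    ok <- res$info %in% 1:4
    diagnostics[i] <- res$message
    sse <- sum(res$fvec^2)
    if (is.finite(sse) && (is.null(best) || sse < best$sse)) {
      best <- list(par = res$par, sse = sse, ok = ok)
    }
  }
  if (is.null(best)) {
    stop("nonlinear fit failed for all ", length(starts), " start(s):\n",
         paste(unique(diagnostics), collapse = "\n"), call. = FALSE)
  }

  params <- do.call(tnfm_params, as.list(best$par))
  fitted <- tnfm_predict(params, d$N, d$P, d$K)
  structure(list(params = params,
                 stats = goodness_of_fit(d$Y, fitted, df_reg = 6L),
                 fitted = fitted, residuals = d$Y - fitted,
                 site_id = trial$site_id, design = trial$design,
                 family = "tnfm", converged = best$ok,
                 n_starts_used = length(starts)),
            class = c("tnfm_fit", "fert_fit"))
}

#' @export
print.fert_fit <- function(x, ...) {
  label <- switch(x$family,
                  tnfm = "ternary non-structural model (NLS)",
                  tpfm = "ternary quadratic polynomial model (OLS)")
  cat("Fertilizer response fit: ", label, "\n", sep = "")
  cat("  site: ", x$site_id, "\n", sep = "")
  print(x$params)
  print(x$stats)
  invisible(x)
}

#' @export
coef.fert_fit <- function(object, ...) unclass(object$params)
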