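#' Specification of a synthetic "3414" trial
#'
#' Describes how to generate one trial: the true response surface, the
#' design's level-2 rates, the replicate-level Gaussian noise standard
#' deviation, the number of field replicates, and a seed. The defaults
#' mirror the built-in early-rice trials: replicate noise of 300 kg/hm^2
#' (the mid-range of the printed replicate standard deviations) and 3
#' replicates per treatment.
#'
#' @param truth A [tnfm_params()] or [tpfm_params()] object.
#' @param design A [design_rates()]; default 165-75-105 kg/hm^2.
#' @param noise_sd Replicate-level Gaussian sd in kg/hm^2 (>= 0).
#' @param reps Replicates per treatment (>= 1).
#' @param seed Integer seed.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(truth, design = design_rates(165, 75, 105),
                            noise_sd = 300, reps = 3L, seed = 1L) {
  stopifnot(inherits(truth, "tnfm_params") || inherits(truth, "tpfm_params"),
            inherits(design, "design_rates"),
            is.numeric(noise_sd), noise_sd >= 0, reps >= 1)
  structure(list(truth = truth, design = design, noise_sd = noise_sd,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "simulation_spec")
}

.predict_truth <- function(truth, n, p, k) {
  if (inherits(truth, "tnfm_params")) tnfm_predict(truth, n, p, k)
  else tpfm_predict(truth, n, p, k)
}

#' Generate one synthetic "3414" trial
#'
#' For each of the 14 treatments, draws `reps` replicate yields as the
#' model mean plus Gaussian noise and records their mean and sd. Negative
#' replicate draws are truncated at zero and counted (attribute
#' `n_truncated`). Deterministic given the spec's seed; the caller's RNG
#' state is untouched.
#'
#' @param spec A [simulation_spec()].
#' @param site_id Site identifier for the generated record.
#' @return A [trial_record()]; attribute `n_truncated` counts truncated
#'   replicate draws.
#' @export
generate_trial <- function(spec, site_id = "synthetic") {
  stopifnot(inherits(spec, "simulation_spec"))
  codes <- design_codes_3414()
  rates <- t(vapply(codes, treatment_rates, numeric(3), design = spec$design))
  mu <- .predict_truth(spec$truth, rates[, 1], rates[, 2], rates[, 3])
  if (any(mu <= 0)) {
    stop("generation error: truth predicts non-positive yield at design ",
         "point(s) ", paste(codes[mu <= 0], collapse = ", "), call. = FALSE)
  }

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
  set.seed(spec$seed)

  n_trunc <- 0L
  ym <- ys <- numeric(length(codes))
  for (i in seq_along(codes)) {
    draws <- mu[i] + stats::rnorm(spec$reps, 0, spec$noise_sd)
    n_trunc <- n_trunc + sum(draws < 0)
    draws <- pmax(draws, 0)
    ym[i] <- mean(draws)
    ys[i] <- if (spec$reps > 1L) stats::sd(draws) else NA_real_
  }
  obs <- data.frame(treatment = codes,
                    n_rate = rates[, 1], p_rate = rates[, 2],
                    k_rate = rates[, 3],
                    yield_mean = ym, yield_sd = ys, reps = spec$reps)
  tr <- trial_record(site_id, spec$design, obs)
  attr(tr, "n_truncated") <- n_trunc
  tr
}

#' Parameter-recovery and typicality-rate experiment
#'
#' Desk-scale analogue of a multi-trial success-rate comparison: for each
#' condition (a [simulation_spec()]), simulate `n_reps` trials, fit both
#' model families to each, classify the fits with the condition's own
#' design range, and summarize recovery of the non-structural parameters
#' (bias and RMSE, when the truth is non-structural) together with the
#' percentage of TYPICAL verdicts per family. Replicates use split seed
#' streams derived from `seed`, so conditions are mutually independent and
#' the whole experiment is reproducible.
#'
#' @param conditions A [simulation_spec()] or list of them (each spec's
#'   `seed` field is ignored in favour of the derived stream).
#' @param n_reps Simulated trials per condition (0 gives an empty report).
#' @param seed Integer master seed.
#' @param n_starts Starts for the nonlinear fits (default 5; recovery at
#'   "3414" scale is insensitive to more).
#' @param prices Optional [price_spec()] forwarded to classification.
#' @param alpha Significance level for classification.
#' @return Object of class `recovery_report`: list with `summary` (one row
#'   per condition) and `param_recovery` (per-condition bias/RMSE table, or
#'   NULL for quadratic truths).
#' @export
recovery_experiment <- function(conditions, n_reps, seed = 1L, n_starts = 5L,
                                prices = NULL, alpha = 0.05) {
  if (inherits(conditions, "simulation_spec")) conditions <- list(conditions)
  stopifnot(length(conditions) >= 1L, n_reps >= 0L)
  if (n_reps == 0L) {
    return(structure(list(summary = data.frame(), param_recovery = NULL,
                          n_reps = 0L),
                     class = "recovery_report"))
  }

  par_names <- c("A", "N0", "P0", "K0", "c1", "c2", "c3")
  summaries <- list(); recoveries <- list()
  for (ci in seq_along(conditions)) {
    spec <- conditions[[ci]]
    tnfm_truth <- inherits(spec$truth, "tnfm_params")
    est <- matrix(NA_real_, n_reps, 7L, dimnames = list(NULL, par_names))
    typ <- matrix(FALSE, n_reps, 2L,
                  dimnames = list(NULL, c("tnfm", "tpfm")))
    failures <- 0L
    for (r in seq_len(n_reps)) {
      # split streams: one derived seed per (condition, replicate)
      rep_seed <- (as.integer(seed) * 1000L + ci * 10000L + r) %% .Machine$integer.max
      rspec <- simulation_spec(spec$truth, spec$design, spec$noise_sd,
                               spec$reps, seed = rep_seed)
      tr <- generate_trial(rspec, site_id = sprintf("sim-c%d-r%d", ci, r))
      res <- tryCatch({
        f1 <- fit_tnfm(tr, n_starts = n_starts, seed = rep_seed)
        f2 <- fit_tpfm(tr)
        list(est = unclass(f1$params),
             typ = c(tnfm = as.character(classify_fit(f1, prices = prices,
                                                      alpha = alpha)$klass) ==
                       "TYPICAL",
                     tpfm = as.character(classify_fit(f2, prices = prices,
                                                      alpha = alpha)$klass) ==
                       "TYPICAL"))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- failures + 1L
      } else {
        est[r, ] <- res$est
        typ[r, ] <- res$typ
      }
    }
    ok <- stats::complete.cases(est)
    summaries[[ci]] <- data.frame(
      condition = ci, noise_sd = spec$noise_sd, reps = spec$reps,
      n_reps = n_reps, n_failed = failures,
      typical_pct_tnfm = 100 * mean(typ[, "tnfm"]),
      typical_pct_tpfm = 100 * mean(typ[, "tpfm"]))
    if (tnfm_truth) {
      truth <- unclass(spec$truth)
      err <- sweep(est[ok, , drop = FALSE], 2L, truth)
      recoveries[[ci]] <- data.frame(
        condition = ci, parameter = par_names, truth = unname(truth),
        bias = colMeans(err), rmse = sqrt(colMeans(err^2)),
        row.names = NULL)
    }
  }
  structure(list(summary = do.call(rbind, summaries),
                 param_recovery = if (length(recoveries)) {
                   do.call(rbind, recoveries)
                 },
                 n_reps = n_reps),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter-recovery experiment (", x$n_reps,
      " replicates/condition):\n", sep = "")
  if (nrow(x$summary)) print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
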