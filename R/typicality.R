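#' Fertilization-rate range of a "3414" design
#'
#' The experimental range per nutrient is the closed interval
#' `[0, 1.5 * level-2 rate]`; a recommendation exactly on the boundary
#' counts as inside.
#'
#' @param design A [design_rates()] object.
#' @return Object of class `design_range`: 2x3 matrix of bounds with
#'   columns N, P, K.
#' @export
design_range <- function(design) {
  stopifnot(inherits(design, "design_rates"))
  m <- rbind(lower = c(0, 0, 0), upper = 1.5 * unclass(design))
  colnames(m) <- c("n", "p", "k")
  structure(m, class = c("design_range", class(m)))
}

.in_range <- function(rates, range) {
  all(rates >= range["lower", ] & rates <= range["upper", ])
}

.new_verdict <- function(family, significant, ps_ok = NA, max_ok = NA,
                         rf_ok = NA, klass, price_free = NA,
                         recommendation = NULL, p_value = NA_real_) {
  structure(list(family = family, significant = significant, ps_ok = ps_ok,
                 max_ok = max_ok, rf_ok = rf_ok,
                 klass = factor(klass,
                                levels = c("NRSS", "PS", "MAX", "RF",
                                           "TYPICAL")),
                 price_free = price_free, recommendation = recommendation,
                 p_value = p_value),
            class = "typicality_verdict")
}

#' @export
print.typicality_verdict <- function(x, ...) {
  fam <- switch(x$family, tnfm = "non-structural", tpfm = "quadratic")
  flag <- function(v) if (is.na(v)) "-" else if (v) "Y" else "N"
  cat(sprintf("Typicality (%s model): %s\n", fam, as.character(x$klass)))
  cat(sprintf("  significant %s | signs %s | maximum %s | in-range %s%s\n",
              flag(x$significant), flag(x$ps_ok), flag(x$max_ok),
              flag(x$rf_ok),
              if (isTRUE(x$price_free)) " (price-free: maximum rates only)"
              else ""))
  invisible(x)
}

# shared RF stage: maximum (and, with prices, economic) rates inside the
# design range; returns list(rf_ok, price_free, recommendation)
.rf_stage <- function(params, range, prices, ...) {
  rec <- tryCatch(recommend(params, prices = prices, ...),
                  error = function(e) NULL)
  if (is.null(rec)) return(list(rf_ok = FALSE, price_free = is.null(prices),
                                recommendation = NULL))
  ok <- .in_range(rec$max_rates, range)
  if (!is.null(prices)) ok <- ok && .in_range(rec$eco_rates, range)
  list(rf_ok = ok, price_free = is.null(prices), recommendation = rec)
}

#' Classify a fitted quadratic model as typical or non-typical
#'
#' Stages, stopping at the first failure: (i) NRSS — the regression F test
#' at level `alpha`; (ii) PS — monomial coefficients `b1, b2, b3` positive
#' and quadratic coefficients `b4, b5, b6` negative (interaction signs
#' `b7..b9` are unconstrained); (iii) MAX — a unique critical point with
#' Hessian leading principal minors `G1 < 0, G2 > 0, G3 < 0`; (iv) RF —
#' recommended rates componentwise inside the design range. With prices,
#' RF checks both the maximum and the economic rates; without prices it
#' checks the maximum rates only and the verdict is marked price-free.
#'
#' @param fit A `tpfm_fit` from [fit_tpfm()].
#' @param range Optional [design_range()]; defaults to the fitted trial's.
#' @param prices Optional [price_spec()].
#' @param alpha Significance level for the NRSS stage (default 0.05).
#' @return A `typicality_verdict` with `klass` one of NRSS, PS, MAX, RF,
#'   TYPICAL.
#' @export
classify_tpfm <- function(fit, range = NULL, prices = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "tpfm_fit"))
  if (is.null(range)) range <- design_range(fit$design)
  b <- unclass(fit$params)
  p_value <- fit$stats$p

  if (p_value >= alpha) {
    return(.new_verdict("tpfm", FALSE, klass = "NRSS", p_value = p_value))
  }
  ps_ok <- all(b[c("b1", "b2", "b3")] > 0) && all(b[c("b4", "b5", "b6")] < 0)
  if (!ps_ok) {
    return(.new_verdict("tpfm", TRUE, ps_ok = FALSE, klass = "PS",
                        p_value = p_value))
  }
  cp <- tpfm_critical_point(fit$params)
  G <- tpfm_hessian_minors(fit$params)
  max_ok <- !is.null(cp) && G["G1"] < 0 && G["G2"] > 0 && G["G3"] < 0
  if (!max_ok) {
    return(.new_verdict("tpfm", TRUE, ps_ok = TRUE, max_ok = FALSE,
                        klass = "MAX", p_value = p_value))
  }
  rf <- .rf_stage(fit$params, range, prices)
  .new_verdict("tpfm", TRUE, ps_ok = TRUE, max_ok = TRUE, rf_ok = rf$rf_ok,
               klass = if (rf$rf_ok) "TYPICAL" else "RF",
               price_free = rf$price_free, recommendation = rf$recommendation,
               p_value = p_value)
}

#' Classify a fitted non-structural model as typical or non-typical
#'
#' Stages: (i) NRSS — significance at `alpha`; (ii) PS — all seven
#' parameters `A, N0, P0, K0, c1, c2, c3` strictly positive; (iii) MAX —
#' automatic pass given PS, because the non-structural surface with
#' all-positive parameters always has an interior global maximum (so the
#' no-maximum class cannot occur for this family); (iv) RF — recommended
#' rates inside the design range, as in [classify_tpfm()].
#'
#' @inheritParams classify_tpfm
#' @param fit A `tnfm_fit` from [fit_tnfm()].
#' @return A `typicality_verdict`.
#' @export
classify_tnfm <- function(fit, range = NULL, prices = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "tnfm_fit"))
  if (is.null(range)) range <- design_range(fit$design)
  p_value <- fit$stats$p

  if (p_value >= alpha) {
    return(.new_verdict("tnfm", FALSE, klass = "NRSS", p_value = p_value))
  }
  ps_ok <- all(unclass(fit$params) > 0)
  if (!ps_ok) {
    return(.new_verdict("tnfm", TRUE, ps_ok = FALSE, klass = "PS",
                        p_value = p_value))
  }
  rf <- .rf_stage(fit$params, range, prices)
  .new_verdict("tnfm", TRUE, ps_ok = TRUE, max_ok = TRUE, rf_ok = rf$rf_ok,
               klass = if (rf$rf_ok) "TYPICAL" else "RF",
               price_free = rf$price_free, recommendation = rf$recommendation,
               p_value = p_value)
}

#' Classify a fitted model (family dispatched from the fit)
#'
#' @inheritParams classify_tpfm
#' @param fit A `tnfm_fit` or `tpfm_fit`.
#' @return A `typicality_verdict`.
#' @export
classify_fit <- function(fit, range = NULL, prices = NULL, alpha = 0.05) {
  if (inherits(fit, "tnfm_fit")) classify_tnfm(fit, range, prices, alpha)
  else if (inherits(fit, "tpfm_fit")) classify_tpfm(fit, range, prices, alpha)
  else stop("fit must be a tnfm_fit or tpfm_fit", call. = FALSE)
}

#' Fit and classify a collection of trials, with summary counts
#'
#' Fits the chosen model family to every trial, classifies each fit with
#' its own per-trial design range, and tabulates the verdict classes with
#' percentages. Individual trial failures are recorded, not fatal.
#'
#' @param trials List of [trial_record()] objects (at least one).
#' @param family `"tnfm"` or `"tpfm"`.
#' @param prices Optional [price_spec()] (omitted: price-free RF check).
#' @param alpha Significance level (default 0.05).
#' @param n_starts,seed Passed to [fit_tnfm()] for the non-structural
#'   family.
#' @return Object of class `batch_classification`: list with `verdicts`
#'   (per-trial), `fits`, `failures`, and `summary` (data frame of class
#'   counts and percentages).
#' @export
batch_classify <- function(trials, family = c("tnfm", "tpfm"), prices = NULL,
                           alpha = 0.05, n_starts = 20L, seed = 1L) {
  family <- match.arg(family)
  if (inherits(trials, "trial_record")) trials <- list(trials)
  if (!length(trials)) stop("no trials supplied", call. = FALSE)

  verdicts <- list(); fits <- list(); failures <- character()
  for (tr in trials) {
    res <- tryCatch({
      fit <- if (family == "tnfm") {
        fit_tnfm(tr, n_starts = n_starts, seed = seed)
      } else fit_tpfm(tr)
      list(fit = fit, verdict = classify_fit(fit, prices = prices,
                                             alpha = alpha))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[tr$site_id] <- conditionMessage(res)
    } else {
      fits[[tr$site_id]] <- res$fit
      verdicts[[tr$site_id]] <- res$verdict
    }
  }
  klasses <- factor(vapply(verdicts, function(v) as.character(v$klass), ""),
                    levels = c("NRSS", "PS", "MAX", "RF", "TYPICAL"))
  counts <- table(klasses)
  summary <- data.frame(klass = names(counts),
                        count = as.integer(counts),
                        percent = round(100 * as.integer(counts) /
                                          max(length(verdicts), 1L), 1))
  structure(list(family = family, verdicts = verdicts, fits = fits,
                 failures = failures, summary = summary,
                 n_trials = length(trials)),
            class = "batch_classification")
}

#' @export
print.batch_classification <- function(x, ...) {
  fam <- switch(x$family, tnfm = "non-structural", tpfm = "quadratic")
  cat(sprintf("Batch typicality, %s model, %d trial(s):\n", fam, x$n_trials))
  print(x$summary, row.names = FALSE)
  if (length(x$failures)) {
    cat("  failures:", paste(names(x$failures), collapse = ", "), "\n")
  }
  invisible(x)
}
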