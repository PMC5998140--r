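#' The 14 treatment codes of a "3414" fertilizer trial
#'
#' A "3414" design crosses three nutrients (N, P2O5, K2O) at four coded
#' levels (0, 1, 2, 3), retaining 14 informative combinations. Level 2 is
#' the locally recommended rate; levels 0, 1 and 3 apply 0, 0.5 and 1.5
#' times that rate.
#'
#' @return Character vector of the 14 treatment codes, in conventional
#'   order (`N0P0K0` first, `N2P1K1` last).
#' @export
#' @examples
#' design_codes_3414()
design_codes_3414 <- function() {
  c("N0P0K0", "N0P2K2", "N1P2K2", "N2P0K2", "N2P1K2", "N2P2K2", "N2P3K2",
    "N2P2K0", "N2P2K1", "N2P2K3", "N3P2K2", "N1P1K2", "N1P2K1", "N2P1K1")
}

# coded level -> fraction of the level-2 rate
.level_multipliers <- c("0" = 0, "1" = 0.5, "2" = 1, "3" = 1.5)

#' Parse a treatment code into N/P/K levels
#'
#' @param code Treatment code such as `"N1P2K2"`.
#' @return Integer vector `c(n, p, k)` of coded levels.
#' @keywords internal
parse_treatment_code <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  m <- regmatches(code, regexec("^N([0-3])P([0-3])K([0-3])$", code))[[1]]
  if (length(m) != 4L) {
    stop("malformed treatment code: '", code,
         "' (expected N{i}P{j}K{k} with levels 0-3)", call. = FALSE)
  }
  as.integer(m[2:4])
}

#' Level-2 application rates of a trial design
#'
#' @param n2_rate,p2_rate,k2_rate Level-2 (recommended) application rates of
#'   N, P2O5 and K2O in kg/hm^2. All must be positive.
#' @return An object of class `design_rates`.
#' @export
#' @examples
#' design_rates(165, 75, 105)
design_rates <- function(n2_rate, p2_rate, k2_rate) {
  r <- c(n2_rate = n2_rate, p2_rate = p2_rate, k2_rate = k2_rate)
  if (!all(is.finite(r)) || any(r <= 0)) {
    stop("all level-2 rates must be positive and finite", call. = FALSE)
  }
  structure(r, class = "design_rates")
}

#' Actual application rates for a treatment code
#'
#' Maps coded levels to rates: level 0, 1, 2, 3 apply 0, 0.5, 1 and 1.5
#' times the level-2 rate of the corresponding nutrient.
#'
#' @param code Treatment code, e.g. `"N1P2K2"`.
#' @param design A [design_rates()] object.
#' @return Named numeric `c(n_rate, p_rate, k_rate)` in kg/hm^2.
#' @export
#' @examples
#' treatment_rates("N1P2K2", design_rates(165, 75, 105))
treatment_rates <- function(code, design) {
  stopifnot(inherits(design, "design_rates"))
  lev <- parse_treatment_code(code)
  mult <- .level_multipliers[as.character(lev)]
  c(n_rate = unname(mult[1] * design[["n2_rate"]]),
    p_rate = unname(mult[2] * design[["p2_rate"]]),
    k_rate = unname(mult[3] * design[["k2_rate"]]))
}

#' Construct a single "3414" trial record
#'
#' @param site_id Character site identifier.
#' @param design A [design_rates()] object.
#' @param observations Data frame with one row per treatment and columns
#'   `treatment`, `n_rate`, `p_rate`, `k_rate`, `yield_mean` and optionally
#'   `yield_sd`, `reps`. Exactly the 14 codes of [design_codes_3414()] must
#'   be present, each once, and rates must agree with the design's level
#'   multipliers to within `rate_tol`.
#' @param soil_properties Optional named list of soil assay metadata
#'   (pH, organic matter, alkali-hydrolysable N, Olsen-P, available K).
#' @param rate_tol Tolerance (kg/hm^2) for agreement between stated rates
#'   and design-implied rates; absorbs rounding in published tables.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(site_id, design, observations,
                         soil_properties = NULL, rate_tol = 0.5) {
  stopifnot(is.character(site_id), length(site_id) == 1L,
            inherits(design, "design_rates"), is.data.frame(observations))
  obs <- as.data.frame(observations)
  need <- c("treatment", "n_rate", "p_rate", "k_rate", "yield_mean")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols)) {
    stop("observations missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"yield_sd" %in% names(obs)) obs$yield_sd <- NA_real_
  if (!"reps" %in% names(obs)) obs$reps <- NA_integer_

  codes <- design_codes_3414()
  dup <- unique(obs$treatment[duplicated(obs$treatment)])
  if (length(dup)) {
    stop("site '", site_id, "': duplicate treatment(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(codes, obs$treatment)
  extra <- setdiff(obs$treatment, codes)
  if (length(absent) || length(extra)) {
    msg <- c(if (length(absent)) paste0("missing: ", paste(absent, collapse = ", ")),
             if (length(extra)) paste0("unknown: ", paste(extra, collapse = ", ")))
    stop("site '", site_id, "': invalid treatment set (",
         paste(msg, collapse = "; "), ")", call. = FALSE)
  }
  obs <- obs[match(codes, obs$treatment), , drop = FALSE]
  rownames(obs) <- NULL

  if (any(!is.finite(obs$yield_mean)) || any(obs$yield_mean <= 0)) {
    stop("site '", site_id, "': yield_mean must be positive and finite",
         call. = FALSE)
  }
  if (any(obs[, c("n_rate", "p_rate", "k_rate")] < 0)) {
    stop("site '", site_id, "': application rates must be non-negative",
         call. = FALSE)
  }
  if (any(!is.na(obs$reps) & obs$reps < 1)) {
    stop("site '", site_id, "': reps must be >= 1", call. = FALSE)
  }
  implied <- t(vapply(obs$treatment, treatment_rates, numeric(3),
                      design = design))
  dev <- abs(as.matrix(obs[, c("n_rate", "p_rate", "k_rate")]) - implied)
  if (max(dev) > rate_tol) {
    bad <- obs$treatment[apply(dev, 1L, max) > rate_tol]
    stop("site '", site_id, "': rates disagree with design multipliers for ",
         paste(bad, collapse = ", "), " (tolerance ", rate_tol, " kg/hm^2)",
         call. = FALSE)
  }

  structure(list(site_id = site_id, design = design, observations = obs,
                 soil_properties = soil_properties),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat("\"3414\" trial record: ", x$site_id, "\n", sep = "")
  cat(sprintf("  level-2 rates (N-P2O5-K2O): %g-%g-%g kg/hm^2\n",
              x$design[["n2_rate"]], x$design[["p2_rate"]],
              x$design[["k2_rate"]]))
  cat(sprintf("  yields: %.0f-%.0f kg/hm^2 (control %.0f)\n",
              min(x$observations$yield_mean), max(x$observations$yield_mean),
              x$observations$yield_mean[1]))
  invisible(x)
}

# canonical CSV columns for trial I/O
.trial_columns <- c("site_id", "treatment", "n_rate", "p_rate", "k_rate",
                    "yield_mean", "yield_sd", "reps")

#' Read "3414" trials from a CSV file
#'
#' One row per (site, treatment). Two rate encodings are accepted: explicit
#' per-treatment rates (`n_rate`, `p_rate`, `k_rate`) or the design's
#' level-2 rates (`n2_rate`, `p2_rate`, `k2_rate`) from which per-treatment
#' rates are reconstructed via the treatment code. When explicit rates are
#' given, the design is recovered from the `N2P2K2` row.
#'
#' @param path Path to a UTF-8 CSV file with a header.
#' @param schema Optional named character vector mapping canonical column
#'   names (`site_id`, `treatment`, `yield_mean`, ...) to the file's column
#'   names, e.g. `c(site_id = "location")`.
#' @return Named list of [trial_record()] objects, one per site.
#' @export
load_trials <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) {
      stop("schema error reading '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (nrow(raw) == 0L || ncol(raw) == 0L) {
    stop("schema error: '", path, "' is empty or has no data rows",
         call. = FALSE)
  }
  if (!is.null(schema)) {
    stopifnot(is.character(schema), !is.null(names(schema)))
    for (canon in names(schema)) {
      from <- schema[[canon]]
      if (!from %in% names(raw)) {
        stop("schema error: mapped column '", from, "' (for '", canon,
             "') not present in file", call. = FALSE)
      }
      names(raw)[names(raw) == from] <- canon
    }
  }
  for (col in c("site_id", "treatment", "yield_mean")) {
    if (!col %in% names(raw)) {
      stop("schema error: required column '", col, "' not found", call. = FALSE)
    }
  }
  explicit <- all(c("n_rate", "p_rate", "k_rate") %in% names(raw))
  by_design <- all(c("n2_rate", "p2_rate", "k2_rate") %in% names(raw))
  if (!explicit && !by_design) {
    stop("schema error: need either n_rate/p_rate/k_rate or ",
         "n2_rate/p2_rate/k2_rate columns", call. = FALSE)
  }

  out <- lapply(split(raw, raw$site_id), function(df) {
    dup <- unique(df$treatment[duplicated(df$treatment)])
    if (length(dup)) {
      stop("site '", df$site_id[1], "': duplicate treatment(s): ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
    if (by_design && !explicit) {
      des <- design_rates(df$n2_rate[1], df$p2_rate[1], df$k2_rate[1])
      rates <- t(vapply(df$treatment, treatment_rates, numeric(3),
                        design = des))
      df$n_rate <- rates[, 1]; df$p_rate <- rates[, 2]; df$k_rate <- rates[, 3]
    } else {
      ref <- df[df$treatment == "N2P2K2", , drop = FALSE]
      if (nrow(ref) != 1L) {
        stop("site '", df$site_id[1],
             "': cannot recover design (need exactly one N2P2K2 row)",
             call. = FALSE)
      }
      des <- design_rates(ref$n_rate, ref$p_rate, ref$k_rate)
    }
    trial_record(df$site_id[1], des, df)
  })
  out[unique(raw$site_id)]
}

#' Write trials to CSV in the canonical schema
#'
#' @param trials A `trial_record` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (inherits(trials, "trial_record")) trials <- list(trials)
  rows <- lapply(trials, function(tr) {
    cbind(site_id = tr$site_id, tr$observations)
  })
  df <- do.call(rbind, rows)
  df <- df[, .trial_columns]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' The six built-in early-rice "3414" trials
#'
#' Six field trials of early rice at three soil-fertility levels in each of
#' Pinghe and Xianyou counties (Fujian, China). Yield means and standard
#' deviations over field replicates are shipped as printed; level-2 rates
#' are 165-75-105 kg/hm^2 (N-P2O5-K2O) in Pinghe, 165-56-109 at low/medium
#' and 165-53-112 at high fertility in Xianyou.
#'
#' @return Named list of six [trial_record()] objects.
#' @export
#' @examples
#' builtin_trials()[["Pinghe-low"]]
builtin_trials <- function() {
  path <- system.file("extdata", "early_rice_trials.csv",
                      package = "fertresp", mustWork = TRUE)
  load_trials(path)
}
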