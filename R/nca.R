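# Non-compartmental analysis and the prediction-error validation gate.

#' Non-compartmental analysis of a concentration-time series
#'
#' Cmax/Tmax from the grid maximum; AUC0-t by the linear trapezoidal rule to
#' `t_last`; terminal slope `lambda_z` by log-linear regression over the last
#' `n_terminal` positive-concentration points after Tmax;
#' `AUC0-inf = AUC0-t + C(t_last)/lambda_z`. When fewer than 3 positive
#' terminal points are available the terminal phase is flagged unavailable
#' and `auc_0_inf` is `NA` (never silently equal to `auc_0_t`).
#'
#' @param times_h Strictly increasing time grid (h).
#' @param conc Concentrations (same length, non-negative).
#' @param t_last Truncation time for AUC0-t (default: last time point).
#' @param n_terminal Number of terminal points for the lambda_z fit
#'   (default 5).
#' @param r2_warn Warn if the terminal log-linear fit has R squared below
#'   this value (default 0.99).
#' @return Object of class `nca_result`: `cmax`, `tmax`, `auc_0_t`,
#'   `auc_0_inf`, `lambda_z`, `lambda_z_r2`, `extrapolated_fraction`,
#'   `t_last`.
#' @export
nca <- function(times_h, conc, t_last = max(times_h), n_terminal = 5L,
                r2_warn = 0.99) {
  if (length(times_h) < 3L) stop("need at least 3 time points")
  if (length(conc) != length(times_h)) stop("times and concentrations differ in length")
  if (any(diff(times_h) <= 0)) stop("times must be strictly increasing (no duplicates)")
  if (any(conc < 0)) stop("negative concentrations")
  if (all(conc == 0)) stop("no positive concentrations in profile")

  keep <- times_h <= t_last + 1e-12
  t <- times_h[keep]
  c_ <- conc[keep]
  i_max <- which.max(c_)
  cmax <- c_[i_max]
  tmax <- t[i_max]
  auc_0_t <- trapz_auc(t, c_)

  # terminal phase: last n positive points strictly after tmax
  post <- which(t > tmax & c_ > 0)
  post <- utils::tail(post, n_terminal)
  lambda_z <- NA_real_
  r2 <- NA_real_
  auc_0_inf <- NA_real_
  extrap <- NA_real_
  if (length(post) >= 3L) {
    fit <- stats::lm(log(c_[post]) ~ t[post])
    slope <- -unname(stats::coef(fit)[2])
    y <- log(c_[post])
    ss_tot <- sum((y - mean(y))^2)
    # guard against an exactly collinear terminal tail
    r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
    if (is.finite(slope) && slope > 0) {
      lambda_z <- slope
      if (r2 < r2_warn) {
        warning(sprintf("terminal fit R^2 = %.4f below %.2f", r2, r2_warn))
      }
      tail_area <- c_[length(c_)] / lambda_z
      auc_0_inf <- auc_0_t + tail_area
      extrap <- tail_area / auc_0_inf
    }
  }
  if (!is.finite(auc_0_inf)) {
    warning("terminal phase unavailable (<3 positive points after Tmax or ",
            "non-negative slope); AUC0-inf flagged NA")
  }
  structure(list(cmax = cmax, tmax = tmax, auc_0_t = auc_0_t,
                 auc_0_inf = auc_0_inf, lambda_z = lambda_z,
                 lambda_z_r2 = r2, extrapolated_fraction = extrap,
                 t_last = t[length(t)]),
            class = "nca_result")
}

# linear trapezoid; exact for piecewise-linear profiles
trapz_auc <- function(t, c_) {
  sum(diff(t) * (utils::head(c_, -1) + utils::tail(c_, -1)) / 2)
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA: Cmax %.4g at %.3g h; AUC0-%g %.4g; AUC0-inf %.4g",
              x$cmax, x$tmax, x$t_last, x$auc_0_t, x$auc_0_inf))
  if (is.finite(x$lambda_z)) {
    cat(sprintf(" (lambda_z %.4g 1/h, R^2 %.4f, %.1f%% extrapolated)",
                x$lambda_z, x$lambda_z_r2, 100 * x$extrapolated_fraction))
  }
  cat("\n")
  invisible(x)
}

#' Percentage prediction error
#'
#' `100 * |simulated - observed| / observed`, the metric used to compare a
#' simulated PK parameter with its observed clinical value.
#'
#' @param observed Observed value (> 0).
#' @param simulated Simulated value (> 0).
#' @return Percent prediction error.
#' @export
prediction_error <- function(observed, simulated) {
  if (any(observed <= 0)) stop("observed value must be positive")
  100 * abs(simulated - observed) / observed
}

#' Validate simulated PK metrics against observed values
#'
#' Joins observed and simulated metric tables by API and metric name,
#' computes the percentage prediction error for each, and applies the
#' acceptance gate: the model is considered sufficiently accurate when every
#' prediction error is at or below the threshold (default 20%).
#'
#' @param obs Data frame `api`, `metric`, `observed` (see [observed_pk()]).
#' @param sim Data frame `api`, `metric`, `simulated`.
#' @param threshold_percent Gate threshold (default 20).
#' @return Object of class `validation_report`: the joined `table` with a
#'   `pe_percent` and `pass` column, `overall_pass`, `max_pe_percent`,
#'   `threshold_percent`.
#' @export
validate_model <- function(obs, sim, threshold_percent = 20) {
  stopifnot(all(c("api", "metric", "observed") %in% names(obs)),
            all(c("api", "metric", "simulated") %in% names(sim)))
  tab <- merge(obs, sim, by = c("api", "metric"), all.x = TRUE, sort = FALSE)
  if (anyNA(tab$simulated)) {
    miss <- tab[is.na(tab$simulated), c("api", "metric")]
    stop("missing simulated metric(s): ",
         paste(miss$api, miss$metric, sep = ":", collapse = ", "))
  }
  tab$pe_percent <- prediction_error(tab$observed, tab$simulated)
  tab$pass <- tab$pe_percent <= threshold_percent
  structure(list(table = tab,
                 overall_pass = all(tab$pass),
                 max_pe_percent = max(tab$pe_percent),
                 threshold_percent = threshold_percent),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("PBPK validation gate (threshold %.3g%% prediction error)\n",
              x$threshold_percent))
  tab <- x$table
  tab$observed <- signif(tab$observed, 4)
  tab$simulated <- signif(tab$simulated, 4)
  tab$pe_percent <- round(tab$pe_percent, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("max %%PE %.2f -> overall %s\n", x$max_pe_percent,
              if (x$overall_pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Write a validation report as structured text
#'
#' @param report A `validation_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  writeLines(utils::capture.output(print(report)), path)
  invisible(path)
}
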