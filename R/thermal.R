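#' Daily chilling units from mean temperature
#'
#' Piecewise-linear chilling-unit (CU) accumulation used to quantify cold
#' exposure of dormant material. The function is 0 outside (-3.4, 10.4] degC,
#' rises as `0.159 * t_mean + 0.506` on (-3.4, 3.5] and falls as
#' `-0.159 * t_mean + 1.621` on (3.5, 10.4]. The printed coefficients yield
#' slightly negative values just above -3.4 degC; these are returned as-is
#' rather than clamped.
#'
#' @param t_mean Daily mean air temperature, degC. Vectorised.
#' @return Numeric vector of unitless daily chilling units.
#' @seealso [forcing_units()], [growing_degree_days()], [accumulate_thermal()]
#' @export
#' @examples
#' chilling_units(c(-5, 0, 3.5, 7, 20))
chilling_units <- function(t_mean) {
  if (!is.numeric(t_mean) || any(!is.finite(t_mean))) {
    stop("`t_mean` must be finite numeric", call. = FALSE)
  }
  cu <- numeric(length(t_mean))
  lo <- t_mean > -3.4 & t_mean <= 3.5
  hi <- t_mean > 3.5 & t_mean <= 10.4
  cu[lo] <- 0.159 * t_mean[lo] + 0.506
  cu[hi] <- -0.159 * t_mean[hi] + 1.621
  cu
}

#' Daily forcing units from mean temperature
#'
#' Logistic forcing-unit (FU) accumulation quantifying warm exposure:
#' `FU = 1 / (1 + exp(-0.47 * t_mean + 6.49))`, bounded in (0, 1) with
#' midpoint near 13.81 degC.
#'
#' @inheritParams chilling_units
#' @return Numeric vector of unitless daily forcing units in (0, 1).
#' @export
#' @examples
#' forcing_units(c(0, 13.8085, 25))
forcing_units <- function(t_mean) {
  if (!is.numeric(t_mean) || any(!is.finite(t_mean))) {
    stop("`t_mean` must be finite numeric", call. = FALSE)
  }
  1 / (1 + exp(-0.47 * t_mean + 6.49))
}

#' Daily growing degree days
#'
#' Base-0 growing degree days: the mean of the daily maximum and minimum
#' temperature when positive, otherwise 0.
#'
#' @param t_max Daily maximum temperature, degC. Vectorised.
#' @param t_min Daily minimum temperature, degC.
#' @return Numeric vector of unitless daily GDD, always `>= 0`.
#' @export
#' @examples
#' growing_degree_days(20, 10)
#' growing_degree_days(2, -6)
growing_degree_days <- function(t_max, t_min) {
  if (!is.numeric(t_max) || !is.numeric(t_min) ||
      any(!is.finite(t_max)) || any(!is.finite(t_min))) {
    stop("`t_max` and `t_min` must be finite numeric", call. = FALSE)
  }
  if (any(t_min > t_max)) stop("`t_min` must not exceed `t_max`", call. = FALSE)
  m <- (t_max + t_min) / 2
  ifelse(m > 0, m, 0)
}

#' Cumulative thermal time over a weather series
#'
#' Computes the chosen daily thermal metric for each day from `start_date`
#' onward and its running sum. The weather table must cover every calendar day
#' of the window: silent gaps would corrupt cumulative sums, so a missing day
#' is an error, never interpolated.
#'
#' @param weather Data frame with columns `date` (Date or ISO-8601 character),
#'   `t_mean`, `t_max`, `t_min` (degC).
#' @param start_date First day of accumulation (inside the series).
#' @param metric One of `"CU"`, `"FU"`, `"GDD"`.
#' @return A tibble with columns `date`, `daily` (that day's metric) and
#'   `cumulative` (running sum from `start_date`), one row per day from
#'   `start_date` to the series end.
#' @export
#' @examples
#' w <- synth_weather(30, mean_temp = 8, annual_amplitude = 0, noise_sd = 1,
#'                    seed = 1)
#' accumulate_thermal(w, w$date[1], "GDD")
accumulate_thermal <- function(weather, start_date,
                               metric = c("CU", "FU", "GDD")) {
  metric <- match.arg(metric)
  weather <- as_weather(weather)
  start_date <- as.Date(start_date)
  if (length(start_date) != 1 || is.na(start_date)) {
    stop("`start_date` must be a single date", call. = FALSE)
  }
  keep <- weather$date >= start_date
  if (nrow(weather) > 0 &&
      (start_date < min(weather$date) || start_date > max(weather$date))) {
    stop("`start_date` lies outside the weather series", call. = FALSE)
  }
  w <- weather[keep, , drop = FALSE]
  if (nrow(w) == 0) {
    return(tibble::tibble(date = as.Date(character()), daily = numeric(),
                          cumulative = numeric()))
  }
  gaps <- diff(as.integer(w$date))
  if (any(gaps != 1)) {
    stop("weather series has missing day(s) after ",
         w$date[which(gaps != 1)[1]], call. = FALSE)
  }
  daily <- switch(metric,
    CU  = chilling_units(w$t_mean),
    FU  = forcing_units(w$t_mean),
    GDD = growing_degree_days(w$t_max, w$t_min)
  )
  tibble::tibble(date = w$date, daily = daily, cumulative = cumsum(daily))
}

# validate + coerce a weather data frame
as_weather <- function(weather) {
  need <- c("date", "t_mean", "t_max", "t_min")
  miss <- setdiff(need, names(weather))
  if (length(miss) > 0) {
    stop("weather table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  weather <- tibble::as_tibble(weather)
  weather$date <- as.Date(weather$date)
  if (any(is.na(weather$date))) stop("unparseable dates", call. = FALSE)
  if (is.unsorted(weather$date, strictly = TRUE)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  if (any(weather$t_min > weather$t_max)) {
    stop("t_min > t_max in weather table", call. = FALSE)
  }
  weather
}

#' Estimate T50, the time to 50% adventitious rooting, for a cohort
#'
#' Fits the two-parameter log-logistic time-to-event curve
#' `F(t) = 1 / (1 + (t / t50)^(-b))` to daily rooting records by
#' interval-censored maximum likelihood (each cutting rooting at daily check
#' `d` contributes `F(d) - F(d-1)`; cuttings with `NA` rooting day are
#' right-censored at `max_day`) and returns the fitted median rooting time
#' with a likelihood-based (delta-method) standard error.
#'
#' @param cohort Data frame with one row per cutting: column `root_day`
#'   (1-based day index of first stem-borne root > 3 mm; `NA` = never rooted
#'   within the observation window). Optional columns `cohort_id`,
#'   `collection_date` are carried through.
#' @param max_day Last observation day. Defaults to the largest recorded
#'   `root_day`.
#' @return An object of class `t50_fit` with elements `t50`, `std_error`,
#'   `slope`, `converged`, `residual_scale`, `n`, `data`. `tidy()` and
#'   `glance()` methods are provided.
#' @export
#' @examples
#' ch <- synth_rooting_cohort(true_t50 = 12, slope = 8, n = 60, max_day = 40,
#'                            seed = 2)
#' fit <- estimate_t50(ch)
#' glance(fit)
estimate_t50 <- function(cohort, max_day = NULL) {
  if (!"root_day" %in% names(cohort)) {
    stop("cohort needs a `root_day` column", call. = FALSE)
  }
  rd <- cohort$root_day
  n <- length(rd)
  if (n < 1) stop("empty cohort", call. = FALSE)
  if (any(rd < 1, na.rm = TRUE)) stop("root_day must be >= 1", call. = FALSE)
  n_rooted <- sum(!is.na(rd))
  if (n_rooted / n < 0.5) {
    stop("T50 not identifiable: fewer than 50% of cuttings ever rooted",
         call. = FALSE)
  }
  if (is.null(max_day)) max_day <- max(rd, na.rm = TRUE)
  days <- sort(unique(stats::na.omit(rd)))
  # cumulative rooted fraction at each observation day; NA root_day counts
  # in the denominator only (censored)
  frac <- vapply(days, function(d) sum(!is.na(rd) & rd <= d) / n, numeric(1))
  dat <- tibble::tibble(day = days, frac = frac)

  out <- list(t50 = NA_real_, std_error = NA_real_, slope = NA_real_,
              converged = FALSE, residual_scale = NA_real_, n = n,
              data = dat)
  class(out) <- "t50_fit"

  if (length(days) == 1 || stats::sd(frac) == 0) {
    # degenerate step: everything roots on one day
    out$t50 <- days[which(frac >= 0.5)[1]]
    out$std_error <- 0
    out$slope <- Inf
    out$converged <- TRUE
    out$residual_scale <- 0
    return(out)
  }

  t50_start <- days[which(frac >= 0.5)[1]]
  # interval-censored maximum likelihood: a cutting rooting at daily check d
  # contributes F(d) - F(d-1), a censored cutting 1 - F(max_day), with
  # F(t) = 1 / (1 + (t / t50)^(-b)). Likelihood-based SEs are calibrated
  # where least squares on the (correlated) cumulative fractions is not.
  counts <- table(factor(rd[!is.na(rd)], levels = days))
  n_cens <- sum(is.na(rd))
  Fll <- function(t, b, e) 1 / (1 + (t / e)^(-b))
  nll <- function(par) {
    b <- exp(par[1]); e <- exp(par[2])
    pr <- Fll(days, b, e) - Fll(pmax(days - 1, 0), b, e)
    pc <- 1 - Fll(max_day, b, e)
    -(sum(as.numeric(counts) * log(pmax(pr, 1e-300))) +
        n_cens * log(pmax(pc, 1e-300)))
  }
  fit <- tryCatch(
    stats::optim(c(log(5), log(t50_start)), nll, method = "BFGS",
                 hessian = TRUE),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$convergence != 0) return(out)
  log_e <- fit$par[2]
  se_log_e <- tryCatch({
    v <- solve(fit$hessian)
    sqrt(v[2, 2])
  }, error = function(e) NA_real_)
  out$t50 <- exp(log_e)
  out$std_error <- out$t50 * se_log_e       # delta method on log scale
  out$slope <- exp(fit$par[1])
  out$converged <- is.finite(out$t50) && out$t50 > 0 && is.finite(se_log_e)
  out$residual_scale <- sqrt(2 * fit$value / n)
  out
}

#' @export
print.t50_fit <- function(x, ...) {
  cat("Log-logistic rooting-time fit (n =", x$n, "cuttings)\n")
  cat(sprintf("  T50 = %.2f d (SE %.3f), slope b = %.2f, converged: %s\n",
              x$t50, x$std_error, x$slope, x$converged))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.t50_fit <- function(x, ...) {
  tibble::tibble(
    term = c("t50", "slope"),
    estimate = c(x$t50, x$slope),
    std.error = c(x$std_error, NA_real_)
  )
}

#' @export
glance.t50_fit <- function(x, ...) {
  tibble::tibble(t50 = x$t50, std_error = x$std_error, slope = x$slope,
                 converged = x$converged, residual_scale = x$residual_scale,
                 n = x$n)
}

#' Regress T50 on cumulative thermal time
#'
#' Ordinary least-squares regression of cohort T50 estimates on a cumulative
#' thermal-time metric (cCU, cFU or cGDD at collection), reporting the slope,
#' intercept, R-squared, mean squared residual and the two-sided p-value of
#' the slope t-test.
#'
#' @param data Optional data frame holding the two columns; if supplied,
#'   `t50` and `thermal` are interpreted as column names (tidy-eval).
#' @param t50 T50 estimates, days (or column name in `data`).
#' @param thermal Cumulative thermal-time values (or column name).
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `mse`,
#'   `p_value`, `n`.
#' @export
#' @examples
#' regress_t50(t50 = c(20, 16, 13, 11), thermal = c(1, 3, 6, 8))
regress_t50 <- function(data = NULL, t50, thermal) {
  if (!is.null(data)) {
    t50 <- rlang::eval_tidy(rlang::enquo(t50), data)
    thermal <- rlang::eval_tidy(rlang::enquo(thermal), data)
  }
  if (length(t50) != length(thermal)) stop("length mismatch", call. = FALSE)
  if (length(t50) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(thermal) == 0) {
    stop("zero variance in thermal predictor", call. = FALSE)
  }
  fit <- stats::lm(t50 ~ thermal)
  sm <- summary(fit)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    mse = mean(stats::residuals(fit)^2),
    p_value = sm$coefficients["thermal", "Pr(>|t|)"],
    n = length(t50)
  )
}

#' Plot cumulative thermal time
#'
#' @param thermal Output of [accumulate_thermal()].
#' @param metric Label for the y axis.
#' @return A ggplot object.
#' @export
plot_thermal <- function(thermal, metric = "thermal units") {
  ggplot2::ggplot(thermal, ggplot2::aes(x = .data$date, y = .data$cumulative)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = NULL, y = paste("cumulative", metric)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.t50_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(day = seq(min(dat$day), max(dat$day), length.out = 200))
  if (is.finite(object$slope)) {
    grid$frac <- 1 / (1 + exp(object$slope * (log(grid$day) - log(object$t50))))
  } else {
    grid$frac <- as.numeric(grid$day >= object$t50)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$day, y = .data$frac)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$t50, linetype = 2) +
    ggplot2::labs(x = "days since collection", y = "fraction rooted") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Read weather and rooting CSV files
#'
#' `read_weather_csv()` expects columns `date`, `t_mean`, `t_max`, `t_min`;
#' `read_rooting_csv()` expects `cohort_id`, `collection_date`, `cutting_id`,
#' `root_day` (empty = censored).
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_weather_csv <- function(path) {
  as_weather(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_weather_csv
#' @export
read_rooting_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("cohort_id", "collection_date", "cutting_id", "root_day")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("rooting table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x$root_day <- as.numeric(x$root_day)
  x
}
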