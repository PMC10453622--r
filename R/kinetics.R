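#' Construct a residual-activity time course
#'
#' A time course records the residual activity (% of untreated) of one enzyme
#' after increasing pre-incubation times at a fixed temperature.
#'
#' @param times Minutes, non-negative and strictly increasing (first point is
#'   conventionally 0 with residual 100).
#' @param residual Residual activity (%), same length as `times`, values >= 0.
#' @param mutant_id Optional label.
#' @param temperature Incubation temperature (deg C), optional.
#' @return An object of class `time_course`.
#' @export
time_course <- function(times, residual, mutant_id = NA_character_,
                        temperature = NA_real_) {
  if (length(times) != length(residual)) {
    stop("'times' and 'residual' must have equal length", call. = FALSE)
  }
  if (any(is.na(times)) || any(is.na(residual))) {
    stop("time course contains missing values", call. = FALSE)
  }
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop("'times' must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(residual < 0)) {
    stop("'residual' values must be >= 0", call. = FALSE)
  }
  structure(list(mutant_id = mutant_id, temperature = temperature,
                 times = as.numeric(times), residual = as.numeric(residual)),
            class = "time_course")
}

as_time_course <- function(tc) {
  if (inherits(tc, "time_course")) return(tc)
  if (is.data.frame(tc)) {
    return(time_course(tc$time_min, tc$residual_pct,
                       mutant_id = tc$mutant_id[1] %||% NA_character_,
                       temperature = tc$temperature_C[1] %||% NA_real_))
  }
  stop("expected a 'time_course' or a data.frame with time_min/residual_pct",
       call. = FALSE)
}

#' Fit a first-order thermal-inactivation model
#'
#' Fits `A(t) = A0 * exp(-k * t)` to a residual-activity time course and
#' reports the rate constant `k` (per minute) and half-life
#' `t_half = ln(2)/k`. `method = "nls"` (default) performs nonlinear least
#' squares on the percent scale (via [minpack.lm::nlsLM()], which also handles
#' exact noise-free data); `method = "loglinear"` regresses `ln(residual)` on
#' time over the points with positive residual. `A0` is fitted freely by
#' default — heat-treatment series frequently show a small offset at `t = 0`
#' — or pinned to 100 with `fix_A0 = TRUE`. `r_squared` is computed on the
#' original (percent) scale for either method and clamped to `[0, 1]`.
#'
#' @param tc A [time_course()] (or a data.frame with columns `time_min` and
#'   `residual_pct`).
#' @param method `"nls"` or `"loglinear"`.
#' @param fix_A0 Fix the amplitude at 100% instead of fitting it.
#' @return An object of class `decay_fit`: list with `mutant_id`, `model`
#'   (`"first_order"`), `k` (1/min), `A0` (%), `t_half` (min), `r_squared`
#'   and `method`.
#' @examples
#' tc <- time_course(seq(0, 30, 5), 100 * exp(-seq(0, 30, 5) * log(2) / 23.14))
#' fit_first_order(tc)$t_half  # 23.14
#' @export
fit_first_order <- function(tc, method = c("nls", "loglinear"),
                            fix_A0 = FALSE) {
  method <- match.arg(method)
  tc <- as_time_course(tc)
  t <- tc$times
  y <- tc$residual
  if (length(t) < 3L) {
    stop("insufficient data: at least 3 time points are required",
         call. = FALSE)
  }
  if (!any(y < 100)) {
    stop("no decay: no residual activity below 100%", call. = FALSE)
  }

  # log-linear estimate (also the nls starting value)
  pos <- y > 0
  if (sum(pos) < 2L) {
    stop("insufficient data: fewer than 2 positive residuals", call. = FALSE)
  }
  if (fix_A0) {
    ll_k <- -unname(stats::coef(stats::lm(log(y[pos] / 100) ~ 0 + t[pos])))[1]
    ll_A0 <- 100
  } else {
    cf <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))
    ll_k <- -unname(cf[2])
    ll_A0 <- exp(unname(cf[1]))
  }

  if (method == "loglinear") {
    k <- ll_k
    A0 <- ll_A0
  } else {
    start_k <- if (is.finite(ll_k) && ll_k > 0) ll_k else 1e-3
    fit <- if (fix_A0) {
      minpack.lm::nlsLM(y ~ 100 * exp(-k * t), start = list(k = start_k))
    } else {
      start_A0 <- if (is.finite(ll_A0) && ll_A0 > 0) ll_A0 else max(y)
      minpack.lm::nlsLM(y ~ A0 * exp(-k * t),
                        start = list(A0 = start_A0, k = start_k))
    }
    cf <- stats::coef(fit)
    k <- unname(cf[["k"]])
    A0 <- if (fix_A0) 100 else unname(cf[["A0"]])
  }

  if (!is.finite(k) || k <= 0) {
    stop("no decay: fitted rate constant is not positive", call. = FALSE)
  }

  yhat <- A0 * exp(-k * t)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum((y - yhat)^2) / tss else 1
  r2 <- min(max(r2, 0), 1)

  structure(list(mutant_id = tc$mutant_id, model = "first_order",
                 k = k, A0 = A0, t_half = log(2) / k,
                 r_squared = r2, method = method),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "first-order inactivation fit (%s)%s\n  k = %.5g /min, A0 = %.4g%%, t1/2 = %.4g min, R^2 = %.4f\n",
    x$method,
    if (is.na(x$mutant_id)) "" else paste0(" for ", x$mutant_id),
    x$k, x$A0, x$t_half, x$r_squared))
  invisible(x)
}

#' Model-free half-life by linear interpolation
#'
#' Cross-check for [fit_first_order()]: the time at which the residual
#' activity first crosses 50%, linearly interpolated between the bracketing
#' observations. Errors if the series never reaches 50% within the observed
#' window.
#'
#' @inheritParams fit_first_order
#' @return Half-life in minutes.
#' @examples
#' t_half_interpolated(time_course(c(0, 20, 30), c(100, 60, 40)))  # 25
#' @export
t_half_interpolated <- function(tc) {
  tc <- as_time_course(tc)
  t <- tc$times
  y <- tc$residual
  j <- which(y <= 50)[1]
  if (is.na(j)) {
    stop("out of window: residual activity never crosses 50%", call. = FALSE)
  }
  if (y[j] == 50 || j == 1L) return(t[j])
  t[j - 1] + (y[j - 1] - 50) / (y[j - 1] - y[j]) * (t[j] - t[j - 1])
}

#' Half-life fold-increase over the wild type
#'
#' @param t_half_mut Mutant half-life (min); vectorized.
#' @param t_half_wt Wild-type half-life (min).
#' @return `t_half_mut / t_half_wt`.
#' @examples
#' fold_increase(731.39, 23.14)  # 31.61x
#' @export
fold_increase <- function(t_half_mut, t_half_wt) {
  if (any(t_half_mut <= 0, na.rm = TRUE) || any(t_half_wt <= 0)) {
    stop("half-lives must be positive", call. = FALSE)
  }
  t_half_mut / t_half_wt
}

#' Optimal temperature from an activity-temperature table
#'
#' @param temperatures Screened temperatures (deg C).
#' @param activity Relative activity (%) at each temperature (each enzyme's
#'   own maximum = 100).
#' @return The temperature of maximal activity; ties resolve to the lowest
#'   temperature.
#' @export
optimal_temperature <- function(temperatures, activity) {
  if (is.data.frame(temperatures)) {
    activity <- temperatures$activity_pct
    temperatures <- temperatures$temperature_C
  }
  if (length(temperatures) == 0L || length(temperatures) != length(activity)) {
    stop("non-empty 'temperatures' and 'activity' of equal length required",
         call. = FALSE)
  }
  min(temperatures[activity == max(activity)])
}

#' Fit first-order decays for every series in a long-format table
#'
#' @param data Data.frame with columns `mutant_id`, `temperature_C`,
#'   `time_min`, `residual_pct` (the long format written by
#'   [synth_timecourses()]).
#' @inheritParams fit_first_order
#' @return Data.frame with one row per (`mutant_id`, `temperature_C`):
#'   columns `mutant_id`, `temperature_C`, `k`, `A0`, `t_half`, `r_squared`,
#'   `method`.
#' @export
fit_decays <- function(data, method = c("nls", "loglinear"), fix_A0 = FALSE) {
  method <- match.arg(method)
  need <- c("mutant_id", "temperature_C", "time_min", "residual_pct")
  if (!all(need %in% names(data))) {
    stop("expected columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  key <- interaction(data$mutant_id, data$temperature_C, drop = TRUE)
  out <- lapply(split(data, key), function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    f <- fit_first_order(d, method = method, fix_A0 = fix_A0)
    data.frame(mutant_id = d$mutant_id[1], temperature_C = d$temperature_C[1],
               k = f$k, A0 = f$A0, t_half = f$t_half,
               r_squared = f$r_squared, method = f$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$mutant_id, out$temperature_C), , drop = FALSE]
}
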