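#' Estimate the unsafe-behavior proportion from a pilot study
#'
#' Work sampling estimates the proportion of the behavior of interest
#' as the fraction of pilot observations in which it was seen.
#'
#' @param n1 number of pilot observations showing the behavior of
#'   interest.
#' @param n0 total number of pilot observations (> 0).
#' @return The proportion `n1 / n0`.
#' @examples
#' estimate_p(90, 200)
#' @export
estimate_p <- function(n1, n0) {
  if (!is_count(n0) || n0 == 0) stop("empty pilot", call. = FALSE)
  if (!is_count(n1) || n1 > n0)
    stop("n1 must be a count with 0 <= n1 <= n0", call. = FALSE)
  n1 / n0
}

#' Required number of work-sampling observations
#'
#' Computes the total number of instantaneous observations needed to
#' estimate a behavior proportion `p` to a desired precision, using the
#' normal approximation to the binomial.  The default (`method =
#' "relative"`) treats `s` as a *relative* accuracy (half-width of the
#' confidence interval as a fraction of `p`):
#' \deqn{n = K^2 (1 - p) / (S^2 p).}
#' `method = "absolute"` instead treats `s` as an absolute half-width:
#' \eqn{n = K^2 p (1 - p) / S^2}.
#'
#' @param p anticipated proportion, strictly between 0 and 1.
#' @param k standard-normal multiplier (approximately 2 for 95\%
#'   two-sided confidence); default 2.
#' @param s desired accuracy, in (0, 1); default 0.05.
#' @param method `"relative"` (default) or `"absolute"` precision.
#' @return A list of class `"sample_size_estimate"` with elements
#'   `n` (smallest sufficient integer, i.e. the ceiling), `n_raw`
#'   (unrounded value), `n_nearest_ten` (raw value rounded to the
#'   nearest ten, a conventional presentation), and the inputs.
#' @examples
#' required_sample_size(estimate_p(90, 200))   # n_nearest_ten = 1960
#' @export
required_sample_size <- function(p, k = 2, s = 0.05,
                                 method = c("relative", "absolute")) {
  method <- match.arg(method)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("degenerate proportion: p must lie strictly between 0 and 1",
         call. = FALSE)
  if (!is.numeric(k) || k <= 0) stop("k must be positive", call. = FALSE)
  if (!is.numeric(s) || s <= 0 || s >= 1)
    stop("s must lie strictly between 0 and 1", call. = FALSE)
  n_raw <- if (method == "relative") k^2 * (1 - p) / (s^2 * p)
           else k^2 * p * (1 - p) / s^2
  structure(list(n = as.integer(ceiling(n_raw)), n_raw = n_raw,
                 n_nearest_ten = as.integer(round(n_raw / 10) * 10),
                 p = p, k = k, s = s, method = method),
            class = "sample_size_estimate")
}

#' @export
print.sample_size_estimate <- function(x, ...) {
  cat(sprintf(
    "Work-sampling size (%s precision): p = %.4g, K = %g, S = %g\n",
    x$method, x$p, x$k, x$s))
  cat(sprintf("  raw n = %.2f;  required n = %d;  nearest ten = %d\n",
              x$n_raw, x$n, x$n_nearest_ten))
  invisible(x)
}

#' Design a safety-behavior-sampling campaign
#'
#' Convenience wrapper combining [estimate_p()] and
#' [required_sample_size()]: from pilot counts and precision parameters
#' it returns the estimated proportion and the required total number of
#' observations.
#'
#' @inheritParams estimate_p
#' @inheritParams required_sample_size
#' @return A list of class `"sbs_design"` with the pilot counts, `p`,
#'   `k`, `s` and the [required_sample_size()] result under `$size`.
#' @examples
#' sbs_design(n1 = 90, n0 = 200)
#' @export
sbs_design <- function(n1, n0, k = 2, s = 0.05,
                       method = c("relative", "absolute")) {
  p <- estimate_p(n1, n0)
  if (p <= 0 || p >= 1)
    stop("degenerate proportion: pilot must contain both outcomes",
         call. = FALSE)
  size <- required_sample_size(p, k, s, method)
  structure(list(n0 = n0, n1 = n1, p = p, k = k, s = s, size = size),
            class = "sbs_design")
}

#' @export
print.sbs_design <- function(x, ...) {
  cat(sprintf("Safety behavior sampling design: pilot %d/%d -> p = %.4g\n",
              x$n1, x$n0, x$p))
  print(x$size)
  invisible(x)
}

#' Build a randomized observation schedule
#'
#' Generates `n` (weekday, clock-time) observation slots covering the
#' whole working week.  Slots are drawn by repeatedly shuffling the full
#' weekday-by-hour grid and attaching a uniform random minute within the
#' hour; this keeps each slot marginally uniform over the domain while
#' guaranteeing that every weekday and every whole working hour is
#' visited once `n` reaches the grid size.  The result is deterministic
#' given `seed`.
#'
#' @param n number of observation slots (>= 1).
#' @param weekdays character vector of day labels; default the 7-day
#'   week.
#' @param hours integer vector of whole working hours (start of each
#'   observable hour); default `8:17` (08:00-18:00 working day).
#' @param seed RNG seed.
#' @return A data.frame of class `"observation_schedule"` with columns
#'   `day`, `hour`, `time` (HH:MM) and attribute `"seed"`.
#' @examples
#' head(build_schedule(10, seed = 1))
#' @export
build_schedule <- function(n,
                           weekdays = c("Sat", "Sun", "Mon", "Tue", "Wed",
                                        "Thu", "Fri"),
                           hours = 8:17, seed = 1) {
  if (!is_count(n) || n < 1) stop("n must be a positive count", call. = FALSE)
  if (!length(weekdays) || !length(hours))
    stop("empty weekday/hour domain", call. = FALSE)
  grid <- expand.grid(day = weekdays, hour = hours,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  with_seed(seed, {
    reps <- ceiling(n / nrow(grid))
    rows <- unlist(lapply(seq_len(reps), function(i)
      sample.int(nrow(grid))), use.names = FALSE)[seq_len(n)]
    minute <- floor(runif(n) * 60)
    out <- grid[rows, , drop = FALSE]
    rownames(out) <- NULL
    out$time <- sprintf("%02d:%02d", out$hour, minute)
    structure(out, seed = seed,
              class = c("observation_schedule", "data.frame"))
  })
}
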