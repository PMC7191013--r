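#' Declare a study variable and its discrete states
#'
#' A variable specification names a variable, lists its ordered discrete
#' states, and optionally carries a discretization rule mapping raw
#' numeric measurements onto those states.
#'
#' Numeric discretizers are given as a `breaks` vector of length
#' `length(states) + 1`.  Bins are half-open and lower-inclusive,
#' `[b1, b2), [b2, b3), ...`; the final bin additionally includes its
#' upper bound when that bound is finite, so a working day declared as
#' running to 18:00 still accepts an observation stamped exactly 18:00.
#'
#' @param name variable name (non-empty string).
#' @param states character vector of at least two unique state labels,
#'   in their declared order.
#' @param breaks optional numeric vector of bin edges
#'   (`length(states) + 1`, strictly increasing) for discretizing raw
#'   numeric values.
#' @return An object of class `"variable_spec"`.
#' @seealso [variable_scheme()], [default_scheme()], [discretize()]
#' @export
variable_spec <- function(name, states, breaks = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  states <- as.character(states)
  if (length(states) < 2L)
    stop("variable '", name, "' needs at least 2 states", call. = FALSE)
  if (anyDuplicated(canon_label(states)))
    stop("variable '", name, "' has duplicate state labels", call. = FALSE)
  if (!is.null(breaks)) {
    breaks <- as.numeric(breaks)
    if (length(breaks) != length(states) + 1L)
      stop("variable '", name, "': breaks must have length(states)+1 entries",
           call. = FALSE)
    if (any(diff(breaks) <= 0))
      stop("variable '", name, "': breaks must be strictly increasing",
           call. = FALSE)
  }
  structure(list(name = name, states = states, breaks = breaks),
            class = "variable_spec")
}

#' Assemble a variable scheme
#'
#' A scheme is the ordered collection of study variables together with
#' the designated outcome (target) variable.  It is the contract that
#' observation datasets, network structures and CPTs are validated
#' against.
#'
#' @param variables list of [variable_spec()] objects.
#' @param target name of the outcome variable; must be one of the
#'   declared variables.
#' @return An object of class `"variable_scheme"`: a list with elements
#'   `variables` (named list of specs) and `target`.
#' @export
variable_scheme <- function(variables, target) {
  if (!length(variables)) stop("empty scheme", call. = FALSE)
  nms <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate variable names", call. = FALSE)
  names(variables) <- nms
  if (!target %in% nms)
    stop("target '", target, "' is not a declared variable", call. = FALSE)
  structure(list(variables = variables, target = target),
            class = "variable_scheme")
}

#' @export
print.variable_scheme <- function(x, ...) {
  cat("Variable scheme:", length(x$variables), "variables; target =",
      x$target, "\n")
  for (v in x$variables)
    cat(sprintf("  %-18s %s\n", v$name, paste(v$states, collapse = " | ")))
  invisible(x)
}

# state counts, named by variable
scheme_card <- function(scheme)
  vapply(scheme$variables, function(v) length(v$states), integer(1))

scheme_states <- function(scheme, var) scheme$variables[[var]]$states

#' The default nine-variable workplace behavior scheme
#'
#' Returns the scheme used throughout the package: eight personal and
#' temporal factors plus the binary high-risk unsafe behavior (HRUB)
#' outcome.  Seven variables have three states and two (marital status
#' and the outcome) have two.  Raw numeric values (age and experience in
#' years, number of completed safety training courses, weekday index
#' 1-7, clock time in fractional hours) are discretized by half-open,
#' lower-inclusive bins; see [discretize()].
#'
#' @return A [variable_scheme()] with nine variables and
#'   `target = "HRUB"`.
#' @examples
#' sch <- default_scheme()
#' sapply(sch$variables, function(v) length(v$states))
#' @export
default_scheme <- function() {
  variable_scheme(list(
    variable_spec("Age",
                  c("under 30 years", "from 30 to 40 years", "above 40 years"),
                  breaks = c(0, 30, 40, Inf)),
    variable_spec("Experience",
                  c("under 1 years", "from 1 to 5 years", "above 5 years"),
                  breaks = c(0, 1, 5, Inf)),
    variable_spec("MaritalStatus", c("yes", "no")),
    variable_spec("PreviousAccident",
                  c("no accident", "minor accident", "major accident")),
    variable_spec("EducationalLevel", c("primary", "high school", "academic")),
    variable_spec("Weekday", c("first days", "middle days", "last days"),
                  breaks = c(1, 3, 6, 7)),
    variable_spec("Daytime",
                  c("from 8am to 11am", "from 11am to 2pm", "from 2pm to 6pm"),
                  breaks = c(8, 11, 14, 18)),
    variable_spec("Training", c("s1", "s2", "s3"),
                  breaks = c(1, 3, 5, Inf)),
    variable_spec("HRUB", c("no", "yes"))
  ), target = "HRUB")
}

# Parse a clock time: numeric hours pass through, "HH:MM" strings are
# converted to fractional hours.
parse_clock <- function(x) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec("^\\s*(\\d{1,2}):(\\d{2})\\s*$", as.character(x)))[[1]]
  if (length(m) == 3L) return(as.numeric(m[2]) + as.numeric(m[3]) / 60)
  suppressWarnings(as.numeric(x))
}

discretize_one <- function(spec, value) {
  if (is.na(value) || (is.character(value) && !nzchar(trimws(value))))
    return(NA_character_)
  # already a valid state label?
  idx <- match(canon_label(value), canon_label(spec$states))
  if (!is.na(idx)) return(spec$states[idx])
  if (is.null(spec$breaks))
    stop("invalid state '", value, "' for variable '", spec$name, "'",
         call. = FALSE)
  v <- if (identical(spec$name, "Daytime")) parse_clock(value)
       else suppressWarnings(as.numeric(value))
  if (is.na(v))
    stop("cannot discretize value '", value, "' for variable '", spec$name,
         "'", call. = FALSE)
  b <- spec$breaks
  last <- length(b)
  if (v < b[1] || v > b[last] || (v == b[last] && !is.finite(b[last])))
    stop("value ", v, " for variable '", spec$name,
         "' lies outside the declared domain [", b[1], ", ", b[last], "]",
         call. = FALSE)
  k <- findInterval(v, b, rightmost.closed = TRUE)
  spec$states[k]
}

#' Discretize raw measurements into an observation record
#'
#' Maps raw values (numeric measurements or already-valid state labels)
#' to state labels under a scheme.  Bins are half-open and
#' lower-inclusive, so an age of exactly 30 falls in the 30-40 band.
#' Missing raw values propagate as missing; a numeric value outside
#' every bin is an error naming the variable and value.
#'
#' @param raw named list (or one-row data.frame) of raw values; names
#'   must be scheme variables.
#' @param scheme a [variable_scheme()]; default [default_scheme()].
#' @return Named character vector of state labels (NA for missing),
#'   one entry per supplied variable.
#' @examples
#' discretize(list(Age = 25, Training = 5, Daytime = "13:00"))
#' @export
discretize <- function(raw, scheme = default_scheme()) {
  raw <- as.list(raw)
  unknown <- setdiff(names(raw), names(scheme$variables))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- vapply(names(raw), function(nm)
    discretize_one(scheme$variables[[nm]], raw[[nm]]), character(1))
  out
}
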