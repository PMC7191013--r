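#' Per-state variation of the outcome probability
#'
#' Belief-updating sensitivity: for each state `s` of `variable`, the
#' signed percent change of the adverse-outcome probability when that
#' state is observed, relative to the unconditioned baseline:
#' \deqn{V_s = 100 \, \frac{P(T = t \mid X = s) - P(T = t)}{P(T = t)}.}
#'
#' @param network a `"bn"` or `"bn_fit"` object.
#' @param variable name of the predictor variable.
#' @param target outcome variable; defaults to the scheme's target.
#' @param adverse adverse outcome state; default `"yes"`.
#' @return Named numeric vector of signed percents, one per state of
#'   `variable`.
#' @examples
#' state_variations(ground_truth_network(), "Training")
#' @export
state_variations <- function(network, variable, target = NULL,
                             adverse = "yes") {
  if (inherits(network, "bn_fit")) network <- network$network
  target <- target %||% network$scheme$target
  if (identical(variable, target))
    stop("variable must differ from the target", call. = FALSE)
  base_p <- posterior(network, target)[[adverse]]
  if (!isTRUE(base_p > 0))
    stop("baseline P(", target, " = ", adverse, ") is zero", call. = FALSE)
  states <- scheme_states(network$scheme, variable)
  vapply(setNames(states, states), function(s) {
    cond <- posterior(network, target, setNames(s, variable))[[adverse]]
    100 * (cond - base_p) / base_p
  }, numeric(1))
}

#' Mean absolute variation
#'
#' The arithmetic mean of the absolute per-state variations of a
#' variable; the primary sensitivity-ranking quantity.  A two-state
#' variable simply contributes two terms.
#'
#' @param variations numeric vector of signed percent variations.
#' @return The mean of `abs(variations)`, in percent.
#' @examples
#' absolute_mean_variation(c(48.72, 5.86, -49.82))
#' @export
absolute_mean_variation <- function(variations) {
  variations <- variations[!is.na(variations)]
  if (!length(variations)) stop("empty variation list", call. = FALSE)
  mean(abs(variations))
}

#' Mutual information between two network variables
#'
#' \eqn{I(X;T) = \sum_{x,t} P(x,t) \log_b P(x,t) / (P(x) P(t))}, with
#' the joint and marginals obtained by exact inference and
#' \eqn{0 \log(0/q)} taken as 0.  Base 2 (bits) by default.
#'
#' @param network a `"bn"` or `"bn_fit"` object.
#' @param x,y two distinct variable names.
#' @param base logarithm base; 2 for bits (default), `exp(1)` for nats.
#' @return Non-negative mutual information.
#' @export
mutual_information <- function(network, x, y, base = 2) {
  if (inherits(network, "bn_fit")) network <- network$network
  if (identical(x, y)) stop("x and y must differ", call. = FALSE)
  px <- posterior(network, x)
  joint <- vapply(seq_along(px), function(i) {
    if (px[i] <= 0) return(rep(0, length(scheme_states(network$scheme, y))))
    posterior(network, y,
              setNames(names(px)[i], x)) * px[i]
  }, numeric(length(scheme_states(network$scheme, y))))
  # joint: rows = y states, cols = x states
  py <- rowSums(joint)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    p <- joint[j, i]
    if (p > 0) mi <- mi + p * (base::log(p / (px[i] * py[j])) / base::log(base))
  }
  max(mi, 0)
}

#' Rank variables by sensitivity
#'
#' Orders report entries by descending mean absolute variation, ties
#' broken by descending mutual information, then alphabetically by
#' variable name; rank 1 is the most influential variable.
#'
#' @param entries data.frame with columns `variable`,
#'   `abs_mean_variation` and `mutual_information`.
#' @return The data.frame with a `rank` column added (rows in original
#'   order).
#' @export
rank_variables <- function(entries) {
  entries <- as.data.frame(entries)
  if (!nrow(entries)) stop("no entries to rank", call. = FALSE)
  needed <- c("variable", "abs_mean_variation", "mutual_information")
  miss <- setdiff(needed, names(entries))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  o <- order(-entries$abs_mean_variation, -entries$mutual_information,
             entries$variable)
  entries$rank <- NA_integer_
  entries$rank[o] <- seq_len(nrow(entries))
  entries
}

#' Sensitivity report for the outcome variable
#'
#' Runs the full sensitivity analysis: per-state variations of the
#' adverse-outcome probability under single-variable evidence, their
#' mean absolute value, mutual information with the target, and the
#' resulting influence ranking, for every non-target variable.
#'
#' @param network a `"bn"` or `"bn_fit"` object.
#' @param target outcome variable; defaults to the scheme's target.
#' @param adverse adverse outcome state; default `"yes"`.
#' @param mi_base logarithm base for mutual information; default 2.
#' @return A data.frame of class `"sensitivity_report"` with one row
#'   per variable: columns `variable`, `state1..state3` (signed percent
#'   variations, NA where the variable has fewer states),
#'   `abs_mean_variation`, `mutual_information`, `rank`.  Attributes:
#'   `"variations"` (named list of full per-state vectors),
#'   `"conditionals"` (data.frame of P(target = adverse | state), the
#'   per-state outcome-rate table), `"baseline"`, `"target"`,
#'   `"adverse"`.
#' @examples
#' sensitivity_report(ground_truth_network())
#' @export
sensitivity_report <- function(network, target = NULL, adverse = "yes",
                               mi_base = 2) {
  if (inherits(network, "bn_fit")) network <- network$network
  target <- target %||% network$scheme$target
  vars <- setdiff(network$structure$nodes, target)
  base_p <- posterior(network, target)[[adverse]]
  varlist <- lapply(setNames(vars, vars), function(v)
    state_variations(network, v, target, adverse))
  max_states <- max(lengths(varlist))
  rows <- do.call(rbind, lapply(vars, function(v) {
    vv <- varlist[[v]]
    pad <- c(unname(vv), rep(NA_real_, max_states - length(vv)))
    data.frame(variable = v, t(pad))
  }))
  names(rows) <- c("variable", paste0("state", seq_len(max_states)))
  rows$abs_mean_variation <- vapply(varlist, absolute_mean_variation,
                                    numeric(1))
  rows$mutual_information <- vapply(vars, function(v)
    mutual_information(network, v, target, base = mi_base), numeric(1))
  rows <- rank_variables(rows)
  cond <- do.call(rbind, lapply(vars, function(v) {
    states <- scheme_states(network$scheme, v)
    data.frame(variable = v, state = states,
               probability = vapply(states, function(s)
                 posterior(network, target,
                           setNames(s, v))[[adverse]], numeric(1)))
  }))
  rownames(rows) <- rownames(cond) <- NULL
  base::structure(rows, variations = varlist, conditionals = cond,
                  baseline = base_p, target = target, adverse = adverse,
                  class = c("sensitivity_report", "data.frame"))
}

#' @export
print.sensitivity_report <- function(x, digits = 2, ...) {
  cat(sprintf("Sensitivity of %s = %s (baseline %.4f)\n",
              attr(x, "target"), attr(x, "adverse"), attr(x, "baseline")))
  df <- as.data.frame(x)
  df <- df[order(df$rank), ]
  statecols <- grep("^state", names(df), value = TRUE)
  for (sc in statecols)
    df[[sc]] <- ifelse(is.na(df[[sc]]), "-",
                       formatC(df[[sc]], format = "f", digits = digits))
  df$abs_mean_variation <- formatC(df$abs_mean_variation, format = "f",
                                   digits = digits)
  df$mutual_information <- formatC(df$mutual_information, format = "f",
                                   digits = 5)
  print(df, row.names = FALSE)
  invisible(x)
}
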