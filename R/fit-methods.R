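#' @export
print.bn_fit <- function(x, ...) {
  cat("Bayesian network fitted by EM\n")
  cat(sprintf("  records: %d   iterations: %d   converged: %s\n",
              x$n, x$iterations, x$converged))
  cat(sprintf("  log-likelihood: %.4f\n", tail_ll(x)))
  tgt <- x$network$scheme$target
  mt <- posterior(x$network, tgt)
  cat(sprintf("  fitted P(%s = %s): %.4f\n", tgt, names(mt)[length(mt)],
              mt[length(mt)]))
  invisible(x)
}

tail_ll <- function(x) x$loglik_trace[length(x$loglik_trace)]

#' @export
summary.bn_fit <- function(object, ...) {
  out <- list(fit = object,
              marginals = marginals(object$network),
              loglik = tail_ll(object),
              df = n_parameters(object$network))
  class(out) <- "summary.bn_fit"
  out
}

#' @export
print.summary.bn_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  free parameters: %d\n\n", x$df))
  cat("Fitted marginal distributions:\n")
  for (v in names(x$marginals)) {
    m <- x$marginals[[v]]
    cat(sprintf("  %-18s %s\n", v,
                paste(sprintf("%s: %.3f", names(m), m), collapse = "  ")))
  }
  invisible(x)
}

# number of free CPT parameters: sum over nodes of q * (r - 1)
n_parameters <- function(network) {
  card <- scheme_card(network$scheme)
  st <- network$structure
  sum(vapply(st$nodes, function(v) {
    q <- prod(card[st$parents[[v]]])
    as.integer(q * (card[[v]] - 1L))
  }, integer(1)))
}

#' @export
coef.bn_fit <- function(object, ...) object$network$cpts

#' @export
logLik.bn_fit <- function(object, ...) {
  base::structure(tail_ll(object), df = n_parameters(object$network),
                  nobs = object$n, class = "logLik")
}

#' Posterior prediction of the outcome variable
#'
#' For each row of `newdata` (treated as evidence; missing cells are
#' simply not conditioned on) returns the posterior distribution of the
#' target variable, or the maximum-posterior state.
#'
#' @param object a `"bn_fit"`.
#' @param newdata observation data.frame; `NULL` (default) returns the
#'   unconditional (marginal) prediction as a single row.
#' @param target variable to predict; defaults to the scheme's target.
#' @param type `"distribution"` (default) for a matrix of posterior
#'   probabilities, `"state"` for the modal state labels.
#' @param ... unused.
#' @return Matrix (rows = records, columns = target states) or
#'   character vector.
#' @export
predict.bn_fit <- function(object, newdata = NULL, target = NULL,
                           type = c("distribution", "state"), ...) {
  type <- match.arg(type)
  net <- object$network
  target <- target %||% net$scheme$target
  states <- scheme_states(net$scheme, target)
  if (is.null(newdata)) {
    pr <- matrix(posterior(net, target), nrow = 1,
                 dimnames = list(NULL, states))
  } else {
    m <- encode_observations(newdata, net$scheme)
    m <- m[, setdiff(colnames(m), target), drop = FALSE]
    pr <- t(apply(m, 1L, function(row) {
      obs <- row[!is.na(row)]
      ev <- if (length(obs))
        setNames(mapply(function(v, i) scheme_states(net$scheme, v)[i],
                        names(obs), obs), names(obs)) else NULL
      posterior(net, target, ev)
    }))
    colnames(pr) <- states
  }
  if (type == "state") states[max.col(pr, ties.method = "first")] else pr
}

#' @export
simulate.bn_fit <- function(object, nsim = 1, seed = NULL,
                            n = object$n, missing_rate = 0, ...) {
  sims <- lapply(seq_len(nsim), function(k)
    sample_observations(object$network, n = n, missing_rate = missing_rate,
                        seed = if (is.null(seed)) NULL else seed + k - 1))
  if (nsim == 1) sims[[1]] else sims
}

#' @export
plot.bn_fit <- function(x, ...) plot(x$network, ...)

#' Plot the network structure
#'
#' Draws the DAG with nodes on a circle and arrows along the edges;
#' intentionally dependency-free base graphics.
#'
#' @param x a `"bn"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bn <- function(x, ...) {
  st <- x$structure
  k <- length(st$nodes)
  th <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  xs <- cos(th); ys <- sin(th)
  graphics::plot(xs, ys, xlim = c(-1.45, 1.45), ylim = c(-1.35, 1.35),
                 axes = FALSE, xlab = "", ylab = "", pch = 21,
                 bg = "grey90", cex = 3, ...)
  names(xs) <- names(ys) <- st$nodes
  for (v in st$nodes)
    for (p in st$parents[[v]]) {
      dx <- xs[v] - xs[p]; dy <- ys[v] - ys[p]
      len <- sqrt(dx^2 + dy^2)
      sh <- 0.12 / len
      graphics::arrows(xs[p] + dx * sh, ys[p] + dy * sh,
                       xs[v] - dx * sh, ys[v] - dy * sh,
                       length = 0.08, col = "grey40")
    }
  graphics::text(xs * 1.22, ys * 1.22, st$nodes, cex = 0.8)
  invisible(x)
}
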