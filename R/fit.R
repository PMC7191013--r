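#' Fit Bayesian-network CPTs by Expectation-Maximization
#'
#' Estimates every conditional probability table of a discrete Bayesian
#' network from an observation dataset that may contain missing values.
#' The E-step computes, for each record, the exact joint posterior of
#' its missing variables given its observed ones (by enumeration over
#' the missing states, which is exact) and accumulates expected family
#' counts; the M-step normalizes each expected-count row into a
#' conditional distribution.  Iteration stops when the relative change
#' in log-likelihood falls below `tol` or after `max_iter` iterations.
#'
#' With complete data and `pseudocount = 0` the procedure reduces
#' exactly to relative-frequency (maximum-likelihood) counting and
#' converges in at most two iterations.
#'
#' Smoothing: `pseudocount` is added to every expected count before
#' normalization.  A parent configuration with zero total expected
#' count carries no likelihood information; its row is filled according
#' to `empty_row`: `"pooled"` (default) uses the node's conditional
#' distribution aggregated over all parent configurations, which keeps
#' fitted marginals close to the data's empirical frequencies even when
#' the CPT has far more configurations than there are records;
#' `"uniform"` uses the uniform distribution.
#'
#' @param structure a [bn_structure()].
#' @param data an observation dataset (data.frame of state labels, as
#'   from [read_observations()] or [sample_observations()]); missing
#'   values allowed.
#' @param scheme a [variable_scheme()]; defaults to the scheme attached
#'   to `data`, else [default_scheme()].
#' @param pseudocount non-negative count added to every expected count
#'   (Laplace-style smoothing); default 0.
#' @param tol convergence threshold on the relative log-likelihood
#'   change; default `1e-6`.
#' @param max_iter maximum EM iterations; default 500.
#' @param init `"uniform"` (default) or `"random"` CPT initialization.
#' @param seed RNG seed used when `init = "random"`.
#' @param empty_row fill rule for parent configurations never seen
#'   (expected count zero): `"pooled"` (default) or `"uniform"`.
#' @return An object of class `"bn_fit"`: a list with elements
#'   `network` (the fitted `"bn"`), `loglik_trace` (log-likelihood
#'   after each M-step), `iterations`, `converged`, `n` (records) and
#'   the configuration used.  Methods: `print`, `summary`, `coef`,
#'   `logLik`, `predict`, `simulate`, `plot`.
#' @examples
#' truth <- ground_truth_network()
#' obs <- sample_observations(truth, n = 500, seed = 1)
#' fit <- bn_fit(default_study_network(), obs)
#' round(predict(fit)[["yes"]], 3)
#' @export
bn_fit <- function(structure, data, scheme = NULL, pseudocount = 0,
                   tol = 1e-6, max_iter = 500L,
                   init = c("uniform", "random"), seed = NULL,
                   empty_row = c("pooled", "uniform")) {
  init <- match.arg(init)
  empty_row <- match.arg(empty_row)
  scheme <- scheme %||% attr(data, "scheme") %||% default_scheme()
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  m <- encode_observations(data, scheme)
  if (!nrow(m)) stop("empty dataset", call. = FALSE)
  extra <- setdiff(colnames(m), structure$nodes)
  if (length(extra))
    stop("dataset variables not in the structure: ",
         paste(extra, collapse = ", "), call. = FALSE)
  # nodes absent from the dataset are treated as entirely missing
  absent <- setdiff(structure$nodes, colnames(m))
  if (length(absent)) {
    m <- cbind(m, matrix(NA_integer_, nrow(m), length(absent),
                         dimnames = list(NULL, absent)))
  }
  m <- m[, structure$nodes, drop = FALSE]
  card <- scheme_card(scheme)[structure$nodes]
  fam <- family_layout(structure, card)
  agg <- aggregate_rows(m)

  cpts <- init_cpts(structure, scheme, init, seed)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    es <- expected_counts(agg, cpts, fam, card)
    cpts <- m_step(es$counts, fam, pseudocount, empty_row)
    ll <- em_loglik(agg, cpts, fam, card)
    trace <- c(trace, ll)
    if (iter >= 2L) {
      prev <- trace[iter - 1L]
      if (abs(ll - prev) <= tol * (abs(prev) + .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
    if (iter >= max_iter) break
  }
  net <- bn_network(scheme, structure,
                    finalize_cpts(cpts, structure, scheme))
  base::structure(
    list(network = net, loglik_trace = trace, iterations = iter,
         converged = converged, n = nrow(m),
         config = list(pseudocount = pseudocount, tol = tol,
                       max_iter = as.integer(max_iter), init = init,
                       seed = seed, empty_row = empty_row)),
    class = "bn_fit")
}

# --- internal machinery -----------------------------------------------

# Per-node family layout: member columns (child first, then parents in
# declared order) and the stride vector that maps a state matrix to a
# linear index into the CPT array (child varies fastest, matching R's
# column-major array layout).
family_layout <- function(structure, card) {
  lapply(setNames(structure$nodes, structure$nodes), function(v) {
    members <- c(v, structure$parents[[v]])
    dims <- unname(card[members])
    stride <- cumprod(c(1, dims[-length(dims)]))
    list(node = v, members = members, dims = dims, stride = stride,
         size = prod(dims), r = dims[1])
  })
}

# Collapse duplicate rows (missing pattern included) into unique rows
# with weights; separates complete from incomplete rows.
aggregate_rows <- function(m) {
  key <- apply(m, 1L, paste, collapse = "\r")
  tab <- table(key)
  u <- m[match(names(tab), key), , drop = FALSE]
  w <- as.numeric(tab)
  complete <- !apply(u, 1L, anyNA)
  list(u = u, w = w, complete = complete)
}

init_cpts <- function(structure, scheme, init, seed) {
  card <- scheme_card(scheme)[structure$nodes]
  fam <- family_layout(structure, card)
  lapply(fam, function(f) {
    if (init == "uniform") {
      array(1 / f$r, dim = f$dims)
    } else {
      vals <- with_seed(seed, rgamma(f$size, shape = 1))
      a <- array(vals, dim = f$dims)
      norm_cpt_array(a, f)
    }
  })
}

# normalize an expected-count array into conditional distributions
norm_cpt_array <- function(a, f) {
  if (length(f$dims) == 1L) return(a / sum(a))
  m2 <- matrix(as.numeric(a), nrow = f$r)
  tot <- colSums(m2)
  m2 <- sweep(m2, 2L, ifelse(tot > 0, tot, 1), `/`)
  array(m2, dim = f$dims)
}

# linear index (1-based) of each row of a state matrix into a family's
# CPT array
family_index <- function(states, f) {
  idx <- 1
  for (k in seq_along(f$members))
    idx <- idx + (states[, f$members[k], drop = TRUE] - 1) * f$stride[k]
  idx
}

# probability of each complete row (rows x nodes state matrix) under
# the current CPTs
rows_probability <- function(states, cpts, fam) {
  pr <- rep(1, nrow(states))
  for (f in fam)
    pr <- pr * as.numeric(cpts[[f$node]])[family_index(states, f)]
  pr
}

# all completions of one partially observed row
row_completions <- function(row, miss, card) {
  grid <- as.matrix(expand.grid(lapply(unname(card[miss]), seq_len),
                                KEEP.OUT.ATTRS = FALSE))
  out <- matrix(rep(row, each = nrow(grid)), nrow = nrow(grid),
                dimnames = list(NULL, names(row)))
  out[, miss] <- grid
  out
}

# E-step: expected family counts and the observed-data log-likelihood
# of the *current* parameters.
expected_counts <- function(agg, cpts, fam, card) {
  counts <- lapply(fam, function(f) numeric(f$size))
  ll <- 0
  u <- agg$u; w <- agg$w
  if (any(agg$complete)) {
    sub <- u[agg$complete, , drop = FALSE]
    wc <- w[agg$complete]
    pr <- rows_probability(sub, cpts, fam)
    if (any(pr <= 0)) {
      bad <- which(pr <= 0)[1]
      ll <- -Inf
      attr(ll, "record") <- bad
    } else ll <- ll + sum(wc * base::log(pr))
    for (f in fam) {
      idx <- family_index(sub, f)
      s <- rowsum(wc, idx)
      at <- as.integer(rownames(s))
      counts[[f$node]][at] <- counts[[f$node]][at] + s[, 1]
    }
  }
  for (i in which(!agg$complete)) {
    row <- u[i, ]
    miss <- names(row)[is.na(row)]
    comp <- row_completions(row, miss, card)
    pr <- rows_probability(comp, cpts, fam)
    s <- sum(pr)
    if (s <= 0) {
      ll <- -Inf
      next
    }
    ll <- ll + agg$w[i] * base::log(s)
    wt <- agg$w[i] * pr / s
    for (f in fam) {
      idx <- family_index(comp, f)
      sm <- rowsum(wt, idx)
      at <- as.integer(rownames(sm))
      counts[[f$node]][at] <- counts[[f$node]][at] + sm[, 1]
    }
  }
  list(counts = counts, loglik = ll)
}

m_step <- function(counts, fam, pseudocount, empty_row) {
  lapply(fam, function(f) {
    cnt <- matrix(counts[[f$node]], nrow = f$r)
    tot <- colSums(cnt)
    pooled <- rowSums(cnt) + pseudocount
    pooled <- if (sum(pooled) > 0) pooled / sum(pooled) else rep(1 / f$r, f$r)
    sm <- cnt + pseudocount
    stot <- colSums(sm)
    out <- sweep(sm, 2L, ifelse(stot > 0, stot, 1), `/`)
    if (any(stot == 0)) {
      fill <- if (empty_row == "pooled") pooled else rep(1 / f$r, f$r)
      out[, stot == 0] <- fill
    }
    array(out, dim = f$dims)
  })
}

# observed-data log-likelihood of a parameter set (shared with
# log_likelihood())
em_loglik <- function(agg, cpts, fam, card) {
  ll <- 0
  u <- agg$u; w <- agg$w
  if (any(agg$complete)) {
    pr <- rows_probability(u[agg$complete, , drop = FALSE], cpts, fam)
    if (any(pr <= 0)) return(-Inf)
    ll <- ll + sum(w[agg$complete] * base::log(pr))
  }
  for (i in which(!agg$complete)) {
    row <- u[i, ]
    miss <- names(row)[is.na(row)]
    comp <- row_completions(row, miss, card)
    s <- sum(rows_probability(comp, cpts, fam))
    if (s <= 0) return(-Inf)
    ll <- ll + w[i] * base::log(s)
  }
  ll
}

finalize_cpts <- function(cpts, structure, scheme) {
  out <- lapply(structure$nodes, function(v)
    make_cpt(v, structure$parents[[v]], scheme, values = cpts[[v]]))
  setNames(out, structure$nodes)
}

#' Observed-data log-likelihood of a dataset under a network
#'
#' Sums over records the log-probability of the record's observed
#' variables, with missing variables marginalized out exactly.  A
#' record impossible under the network makes the result `-Inf`; the
#' index of the first such record is attached as attribute
#' `"record"`.
#'
#' @param network a `"bn"` object (or a `"bn_fit"`).
#' @param data an observation dataset.
#' @return Log-likelihood (natural log).
#' @export
log_likelihood <- function(network, data) {
  if (inherits(network, "bn_fit")) network <- network$network
  scheme <- network$scheme
  m <- encode_observations(data, scheme)
  if (!nrow(m)) stop("empty dataset", call. = FALSE)
  st <- network$structure
  absent <- setdiff(st$nodes, colnames(m))
  if (length(absent))
    m <- cbind(m, matrix(NA_integer_, nrow(m), length(absent),
                         dimnames = list(NULL, absent)))
  m <- m[, st$nodes, drop = FALSE]
  card <- scheme_card(scheme)[st$nodes]
  fam <- family_layout(st, card)
  cpts <- lapply(st$nodes, function(v) network$cpts[[v]])
  names(cpts) <- st$nodes
  pr_row <- function(i) {
    row <- m[i, ]
    miss <- names(row)[is.na(row)]
    if (!length(miss))
      return(rows_probability(m[i, , drop = FALSE], cpts, fam))
    sum(rows_probability(row_completions(row, miss, card), cpts, fam))
  }
  agg <- aggregate_rows(m)
  tot <- em_loglik(agg, cpts, fam, card)
  if (identical(tot, -Inf)) {
    for (i in seq_len(nrow(m))) {
      if (pr_row(i) <= 0) {
        attr(tot, "record") <- i
        break
      }
    }
  }
  tot
}
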