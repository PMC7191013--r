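# Discrete factor algebra used by the exact-inference engine.
#
# A factor is a list(vars = character(), tab = numeric array) whose
# array dimensions follow `vars` in order.  Cardinalities are always
# taken from a named integer vector `card` so factors over the same
# variable are guaranteed to align.

new_factor <- function(vars, tab) list(vars = vars, tab = tab)

# Broadcast a factor's table onto the variable set `u` (a superset of
# f's scope), returning an array with dim card[u].
expand_tab <- function(vars, tab, u, card) {
  if (!length(u)) return(as.numeric(tab)[1])
  cu <- card[u]
  if (!length(vars)) return(array(as.numeric(tab)[1], dim = cu))
  lin <- array(0, dim = cu)
  stride <- 1
  for (k in seq_along(vars)) {
    pos <- match(vars[k], u)
    lin <- lin + (slice.index(lin, pos) - 1) * stride
    stride <- stride * card[[vars[k]]]
  }
  array(as.numeric(tab)[lin + 1], dim = cu)
}

factor_product <- function(f1, f2, card) {
  u <- union(f1$vars, f2$vars)
  new_factor(u, expand_tab(f1$vars, f1$tab, u, card) *
                expand_tab(f2$vars, f2$tab, u, card))
}

factor_product_all <- function(factors, card) {
  Reduce(function(a, b) factor_product(a, b, card), factors)
}

# Sum a variable out of a factor.
factor_marginalize <- function(f, var) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  keep <- setdiff(seq_along(f$vars), pos)
  if (!length(keep)) return(new_factor(character(0), sum(f$tab)))
  tab <- apply(f$tab, keep, sum)
  new_factor(f$vars[keep], array(tab, dim = dim(f$tab)[keep]))
}

# Fix a variable to a state index, dropping the dimension.
factor_reduce <- function(f, var, state) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  ix <- rep(list(quote(expr = )), length(f$vars))
  ix[[pos]] <- state
  tab <- do.call(`[`, c(list(f$tab), ix, list(drop = FALSE)))
  d <- dim(f$tab)[-pos]
  if (!length(d)) return(new_factor(character(0), as.numeric(tab)))
  new_factor(f$vars[-pos], array(tab, dim = d))
}

# Min-degree elimination ordering over `elim` given factor scopes.
min_degree_order <- function(scopes, elim) {
  adj <- lapply(setNames(elim, elim), function(v) character(0))
  for (sc in scopes) {
    sv <- intersect(sc, elim)
    for (v in sv) adj[[v]] <- union(adj[[v]], setdiff(sv, v))
  }
  order_out <- character(0)
  remaining <- elim
  while (length(remaining)) {
    deg <- vapply(remaining, function(v)
      length(intersect(adj[[v]], remaining)), integer(1))
    v <- remaining[order(deg, remaining)][1]
    nb <- intersect(adj[[v]], remaining)
    # connect neighbors (fill-in), as elimination creates a clique
    for (a in nb) adj[[a]] <- union(adj[[a]], setdiff(nb, a))
    order_out <- c(order_out, v)
    remaining <- setdiff(remaining, v)
  }
  order_out
}

# Variable elimination: returns the unnormalized factor over `keep`
# after reducing by evidence (named integer state indices) and summing
# out everything else.
ve_eliminate <- function(factors, card, keep, evidence_idx) {
  for (v in names(evidence_idx))
    factors <- lapply(factors, factor_reduce, var = v,
                      state = evidence_idx[[v]])
  all_vars <- unique(unlist(lapply(factors, `[[`, "vars")))
  elim <- setdiff(all_vars, keep)
  ord <- min_degree_order(lapply(factors, `[[`, "vars"), elim)
  for (v in ord) {
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(touch)) next
    prod <- factor_product_all(factors[touch], card)
    factors <- c(factors[!touch], list(factor_marginalize(prod, v)))
  }
  factor_product_all(factors, card)
}
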