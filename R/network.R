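#' Define a Bayesian network structure
#'
#' A structure is a directed acyclic graph given as a named list
#' mapping each node to the ordered character vector of its parents
#' (empty for root nodes).  Acyclicity is verified at construction.
#'
#' @param parents named list; names are the nodes, each element the
#'   (possibly empty) character vector of that node's parents.
#' @return An object of class `"bn_structure"` with elements `nodes`
#'   and `parents`.
#' @examples
#' bn_structure(list(A = character(0), B = "A"))
#' @export
bn_structure <- function(parents) {
  nodes <- names(parents)
  if (is.null(nodes) || any(!nzchar(nodes)) || anyDuplicated(nodes))
    stop("parents must be a named list with unique names", call. = FALSE)
  parents <- lapply(parents, as.character)
  undeclared <- setdiff(unlist(parents), nodes)
  if (length(undeclared))
    stop("undeclared parent node(s): ", paste(undeclared, collapse = ", "),
         call. = FALSE)
  ord <- topological_order(nodes, parents)
  if (is.null(ord))
    stop("graph contains a directed cycle", call. = FALSE)
  structure(list(nodes = nodes, parents = parents, order = ord),
            class = "bn_structure")
}

# Kahn's algorithm; NULL if cyclic.
topological_order <- function(nodes, parents) {
  indeg <- vapply(parents, length, integer(1))[nodes]
  names(indeg) <- nodes
  out <- character(0)
  avail <- nodes[indeg == 0L]
  while (length(avail)) {
    v <- sort(avail)[1]
    avail <- setdiff(avail, v)
    out <- c(out, v)
    for (w in nodes)
      if (v %in% parents[[w]]) {
        indeg[[w]] <- indeg[[w]] - sum(parents[[w]] == v)
        if (indeg[[w]] == 0L) avail <- c(avail, w)
      }
  }
  if (length(out) != length(nodes)) NULL else out
}

#' @export
print.bn_structure <- function(x, ...) {
  cat("Bayesian network structure,", length(x$nodes), "nodes\n")
  for (v in x$nodes) {
    p <- x$parents[[v]]
    cat(sprintf("  %-18s <- %s\n", v,
                if (length(p)) paste(p, collapse = ", ") else "(root)"))
  }
  invisible(x)
}

#' The expert-elicited study network structure
#'
#' The directed acyclic graph used for the workplace-behavior analysis:
#' every personal and temporal factor except age is a direct parent of
#' the high-risk unsafe behavior (HRUB) outcome; age acts only through
#' experience and marital status, and a previous accident influences
#' training participation (employees with an accident are sent to more
#' safety courses).
#'
#' @return A [bn_structure()] over the nine [default_scheme()]
#'   variables.
#' @examples
#' default_study_network()
#' @export
default_study_network <- function() {
  bn_structure(list(
    Age              = character(0),
    Experience       = "Age",
    MaritalStatus    = "Age",
    PreviousAccident = character(0),
    EducationalLevel = character(0),
    Weekday          = character(0),
    Daytime          = character(0),
    Training         = "PreviousAccident",
    HRUB             = c("Experience", "MaritalStatus", "PreviousAccident",
                         "Training", "EducationalLevel", "Weekday", "Daytime")
  ))
}

#' Construct a conditional probability table
#'
#' Builds the CPT array for one node.  The array's first dimension runs
#' over the child's states and the remaining dimensions over the
#' parents' states in declared parent order.
#'
#' `rows`, when used, is a matrix with one row per parent configuration
#' and one column per child state.  Parent configurations are ordered
#' lexicographically by declared parent order (first parent most
#' significant, last parent cycling fastest); see [parent_configs()].
#'
#' @param child node name.
#' @param parents character vector of parent names (order defines the
#'   configuration ordering).
#' @param scheme the [variable_scheme()].
#' @param values a numeric array already in CPT layout, or `NULL` when
#'   `rows` is given.
#' @param rows alternative row-matrix input (configurations x child
#'   states).
#' @return Numeric array with dimnames.
#' @export
make_cpt <- function(child, parents, scheme, values = NULL, rows = NULL) {
  card <- scheme_card(scheme)
  dims <- unname(card[c(child, parents)])
  if (!is.null(rows)) {
    rows <- as.matrix(rows)
    q <- prod(card[parents])
    if (nrow(rows) != q || ncol(rows) != card[[child]])
      stop("rows must be ", q, " x ", card[[child]], " for node '", child,
           "'", call. = FALSE)
    values <- rows_to_cpt(rows, dims)
  }
  values <- array(as.numeric(values), dim = dims)
  dn <- lapply(c(child, parents), function(v) scheme_states(scheme, v))
  names(dn) <- c(child, parents)
  dimnames(values) <- dn
  values
}

#' Enumerate parent configurations in canonical order
#'
#' Configurations are ordered lexicographically by declared parent
#' order: the first parent is the most significant digit and the last
#' parent cycles fastest.  This is the row order used by [make_cpt()]
#' and by the JSON/XMLBIF serializers.
#'
#' @param parents character vector of parent names.
#' @param scheme the [variable_scheme()].
#' @return Integer matrix (one row per configuration) of state indices,
#'   columns named by parent.
#' @export
parent_configs <- function(parents, scheme) {
  card <- scheme_card(scheme)
  if (!length(parents))
    return(matrix(integer(0), nrow = 1, ncol = 0))
  g <- expand.grid(rev(lapply(unname(card[parents]), seq_len)),
                   KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g[, rev(seq_along(parents)), drop = FALSE])
  colnames(m) <- parents
  m
}

# Convert between the row-matrix layout (configs x child states, config
# order per parent_configs) and the internal array layout (child first,
# parents in order, column-major).
rows_to_cpt <- function(rows, dims) {
  r <- dims[1]
  arr <- array(0, dim = dims)
  if (length(dims) == 1L) return(array(as.numeric(rows[1, ]), dim = dims))
  q <- prod(dims[-1])
  # row i corresponds to parent indices in lexicographic order
  cfg <- as.matrix(expand.grid(rev(lapply(dims[-1], seq_len)),
                               KEEP.OUT.ATTRS = FALSE))[,
        rev(seq_along(dims[-1])), drop = FALSE]
  for (i in seq_len(q)) {
    ix <- c(list(seq_len(r)), as.list(cfg[i, ]))
    arr <- do.call(`[<-`, c(list(arr), ix, list(value = as.numeric(rows[i, ]))))
  }
  arr
}

cpt_to_rows <- function(cpt) {
  dims <- dim(cpt)
  if (is.null(dims)) dims <- length(cpt)
  r <- dims[1]
  if (length(dims) == 1L) return(matrix(as.numeric(cpt), nrow = 1))
  q <- prod(dims[-1])
  cfg <- as.matrix(expand.grid(rev(lapply(dims[-1], seq_len)),
                               KEEP.OUT.ATTRS = FALSE))[,
        rev(seq_along(dims[-1])), drop = FALSE]
  out <- matrix(0, q, r)
  for (i in seq_len(q)) {
    ix <- c(list(seq_len(r)), as.list(cfg[i, ]))
    out[i, ] <- do.call(`[`, c(list(cpt), ix))
  }
  out
}

#' Assemble a Bayesian network
#'
#' Combines a scheme, a structure and one CPT per node into the network
#' object consumed by inference, fitting and sensitivity analysis.
#' Invariants (acyclicity, CPT dimensions, row normalization) can be
#' checked with [validate_network()]; construction itself only checks
#' shapes.
#'
#' @param scheme a [variable_scheme()].
#' @param structure a [bn_structure()] whose nodes are scheme variables.
#' @param cpts named list of CPT arrays (see [make_cpt()]), one per
#'   node.
#' @return An object of class `"bn"`.
#' @export
bn_network <- function(scheme, structure, cpts) {
  if (!all(structure$nodes %in% names(scheme$variables)))
    stop("structure nodes must be scheme variables", call. = FALSE)
  missing_cpt <- setdiff(structure$nodes, names(cpts))
  if (length(missing_cpt))
    stop("missing CPT(s): ", paste(missing_cpt, collapse = ", "),
         call. = FALSE)
  net <- structure(list(scheme = scheme, structure = structure,
                        cpts = cpts[structure$nodes]), class = "bn")
  bad_dim <- validate_network(net, what = "dimensions")
  if (length(bad_dim)) stop(bad_dim[1], call. = FALSE)
  net
}

#' Validate a Bayesian network
#'
#' Checks acyclicity, CPT dimensions against the scheme and structure,
#' and row normalization (each conditional distribution non-negative
#' and summing to 1 within `tol`).  Violations are returned, not
#' raised.
#'
#' @param network a `"bn"` object.
#' @param tol normalization tolerance; default `1e-9`.
#' @param what which checks to run (internal use).
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_network <- function(network, tol = 1e-9,
                             what = c("all", "dimensions")) {
  what <- match.arg(what)
  out <- character(0)
  card <- scheme_card(network$scheme)
  st <- network$structure
  if (is.null(topological_order(st$nodes, st$parents)))
    out <- c(out, "structure contains a directed cycle")
  for (v in st$nodes) {
    cpt <- network$cpts[[v]]
    want <- unname(card[c(v, st$parents[[v]])])
    got <- dim(cpt) %||% length(cpt)
    if (!identical(as.integer(got), as.integer(want))) {
      out <- c(out, paste0("CPT dimensions for '", v, "' are (",
                           paste(got, collapse = ","), "), expected (",
                           paste(want, collapse = ","), ")"))
      next
    }
    if (what == "dimensions") next
    rows <- cpt_to_rows(cpt)
    if (any(rows < 0))
      out <- c(out, paste0("CPT for '", v, "' has negative entries"))
    bad <- which(abs(rowSums(rows) - 1) > tol)
    if (length(bad))
      out <- c(out, paste0("CPT row ", bad[1], " for '", v, "' sums to ",
                           format(rowSums(rows)[bad[1]], digits = 10)))
  }
  out
}

#' @export
print.bn <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$structure$nodes), "nodes,",
      sum(lengths(x$structure$parents)), "edges; target =",
      x$scheme$target, "\n")
  print(x$structure)
  invisible(x)
}

# CPT factors of a network (list of new_factor over (child, parents)).
bn_factors <- function(network) {
  st <- network$structure
  lapply(st$nodes, function(v)
    new_factor(c(v, st$parents[[v]]),
               array(as.numeric(network$cpts[[v]]),
                     dim = dim(network$cpts[[v]]) %||%
                           length(network$cpts[[v]]))))
}

# Convert a named character evidence vector/list to integer state
# indices, validating names and labels.
evidence_index <- function(network, evidence) {
  if (!length(evidence)) return(setNames(integer(0), character(0)))
  evidence <- unlist(evidence)
  nm <- names(evidence)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("evidence must be named by variable", call. = FALSE)
  bad <- setdiff(nm, network$structure$nodes)
  if (length(bad))
    stop("evidence on unknown node(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  idx <- vapply(nm, function(v) {
    i <- match_states(evidence[[v]], scheme_states(network$scheme, v))
    if (is.na(i)) stop("invalid state '", evidence[[v]], "' for '", v, "'",
                       call. = FALSE)
    as.integer(i)
  }, integer(1))
  setNames(idx, nm)
}

#' Joint probability of a complete assignment
#'
#' The joint probability of one full state assignment factorizes as the
#' product over nodes of the CPT entry selected by the node's state and
#' its parents' states.
#'
#' @param network a `"bn"` object.
#' @param assignment named character vector/list giving a state for
#'   every node.
#' @param log return the log joint instead.
#' @return A probability (or its natural log).
#' @export
joint_probability <- function(network, assignment, log = FALSE) {
  st <- network$structure
  assignment <- unlist(assignment)
  missing_nodes <- setdiff(st$nodes, names(assignment))
  if (length(missing_nodes))
    stop("incomplete assignment; missing: ",
         paste(missing_nodes, collapse = ", "), call. = FALSE)
  idx <- evidence_index(network, assignment[st$nodes])
  lp <- 0
  for (v in st$nodes) {
    ix <- as.list(idx[c(v, st$parents[[v]])])
    p <- do.call(`[`, c(list(network$cpts[[v]]), ix))
    lp <- lp + base::log(as.numeric(p))
  }
  if (log) lp else exp(lp)
}

#' Exact posterior distribution by variable elimination
#'
#' Computes `P(query | evidence)` exactly.  CPTs reduced by the
#' evidence are combined by variable elimination under a min-degree
#' ordering; the result is normalized over the query's states.
#' Querying a variable that is itself part of the evidence returns a
#' point mass on its evidenced state.  Evidence whose marginal
#' probability is zero is rejected.
#'
#' @param network a `"bn"` object.
#' @param query name of the query variable.
#' @param evidence named character vector/list of observed states
#'   (possibly empty).
#' @return Named numeric vector over the query's states, summing to 1.
#' @examples
#' net <- ground_truth_network()
#' posterior(net, "HRUB", c(Training = "s3"))
#' @export
posterior <- function(network, query, evidence = NULL) {
  if (!query %in% network$structure$nodes)
    stop("unknown query node '", query, "'", call. = FALSE)
  states <- scheme_states(network$scheme, query)
  idx <- evidence_index(network, evidence)
  if (query %in% names(idx)) {
    out <- setNames(numeric(length(states)), states)
    out[idx[[query]]] <- 1
    return(out)
  }
  card <- scheme_card(network$scheme)
  f <- ve_eliminate(bn_factors(network), card, keep = query,
                    evidence_idx = idx)
  tab <- as.numeric(f$tab)
  z <- sum(tab)
  if (!is.finite(z) || z <= 0)
    stop("impossible evidence: observed configuration has probability 0",
         call. = FALSE)
  setNames(tab / z, states)
}

# Brute-force posterior by full-joint enumeration; test oracle.
posterior_enum <- function(network, query, evidence = NULL) {
  st <- network$structure
  card <- scheme_card(network$scheme)[st$nodes]
  states <- scheme_states(network$scheme, query)
  idx <- evidence_index(network, evidence)
  if (query %in% names(idx)) {
    out <- setNames(numeric(length(states)), states)
    out[idx[[query]]] <- 1
    return(out)
  }
  joint <- Reduce(function(a, f) a * expand_tab(f$vars, f$tab, st$nodes, card),
                  bn_factors(network), init = array(1, dim = card))
  ix <- rep(list(quote(expr = )), length(st$nodes))
  for (v in names(idx)) ix[[match(v, st$nodes)]] <- idx[[v]]
  sub <- do.call(`[`, c(list(joint), ix, list(drop = FALSE)))
  qpos <- match(query, st$nodes)
  tab <- apply(sub, qpos, sum)
  z <- sum(tab)
  if (z <= 0) stop("impossible evidence", call. = FALSE)
  setNames(as.numeric(tab) / z, states)
}

#' Marginal distribution of every node
#'
#' Posterior of each node under empty evidence.
#'
#' @param network a `"bn"` object.
#' @return Named list of named probability vectors.
#' @export
marginals <- function(network) {
  setNames(lapply(network$structure$nodes, function(v)
    posterior(network, v)), network$structure$nodes)
}
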