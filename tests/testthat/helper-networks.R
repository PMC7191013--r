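# Fixture builders and an independent brute-force inference oracle.
# The oracle works on the raw CPT arrays by explicit enumeration of
# every full assignment and shares no code with the package's
# variable-elimination engine.

make_scheme <- function(states, target = names(states)[length(states)]) {
  variable_scheme(mapply(variable_spec, names(states), states,
                         SIMPLIFY = FALSE),
                  target = target)
}

# two-node chain A -> B with hand-picked CPTs
chain_bn <- function(pa1 = 0.3, pb1_a1 = 0.5, pb1_a2 = 0.2) {
  sch <- make_scheme(list(A = c("a1", "a2"), B = c("b1", "b2")),
                     target = "B")
  st <- bn_structure(list(A = character(0), B = "A"))
  bn_network(sch, st, list(
    A = make_cpt("A", character(0), sch, values = c(pa1, 1 - pa1)),
    B = make_cpt("B", "A", sch,
                 rows = rbind(c(pb1_a1, 1 - pb1_a1),
                              c(pb1_a2, 1 - pb1_a2)))))
}

# deterministic chain: A is a point mass and B copies A
deterministic_bn <- function() {
  sch <- make_scheme(list(A = c("a1", "a2"), B = c("b1", "b2")),
                     target = "B")
  st <- bn_structure(list(A = character(0), B = "A"))
  bn_network(sch, st, list(
    A = make_cpt("A", character(0), sch, values = c(1, 0)),
    B = make_cpt("B", "A", sch, rows = rbind(c(1, 0), c(0, 1)))))
}

# seeded random network of up to `max_nodes` nodes with 2-3 states
random_bn <- function(seed, max_nodes = 6) {
  set.seed(seed)
  k <- sample(2:max_nodes, 1)
  nodes <- paste0("V", seq_len(k))
  nstates <- sample(2:3, k, replace = TRUE)
  states <- lapply(nstates, function(r) paste0("s", seq_len(r)))
  names(states) <- nodes
  sch <- make_scheme(states, target = nodes[k])
  parents <- setNames(vector("list", k), nodes)
  for (j in seq_len(k)) {
    prior <- seq_len(j - 1)
    parents[[j]] <- nodes[prior[runif(length(prior)) < 0.4]]
  }
  cpts <- lapply(seq_len(k), function(j) {
    r <- nstates[j]
    q <- prod(vapply(parents[[j]], function(p) nstates[match(p, nodes)],
                     numeric(1)), 1)
    rows <- matrix(rgamma(q * r, shape = 1) + 0.05, nrow = q)
    rows <- rows / rowSums(rows)
    make_cpt(nodes[j], parents[[j]], sch, rows = rows)
  })
  names(cpts) <- nodes
  bn_network(sch, bn_structure(parents), cpts)
}

# ---- brute-force oracle ----------------------------------------------

# full joint table: data.frame of state indices plus probability column
oracle_joint <- function(net) {
  nodes <- net$structure$nodes
  card <- vapply(nodes, function(v) length(net$scheme$variables[[v]]$states),
                 integer(1))
  grid <- expand.grid(lapply(card, seq_len), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- nodes
  grid$prob <- vapply(seq_len(nrow(grid)), function(i) {
    p <- 1
    for (v in nodes) {
      ix <- as.list(unlist(grid[i, c(v, net$structure$parents[[v]])]))
      p <- p * do.call(`[`, c(list(net$cpts[[v]]), ix))
    }
    p
  }, numeric(1))
  grid
}

# P(query | evidence) from the enumerated joint; evidence is a named
# character vector of state labels
oracle_posterior <- function(net, query, evidence = NULL) {
  grid <- oracle_joint(net)
  if (length(evidence)) {
    for (v in names(evidence)) {
      si <- match(evidence[[v]], net$scheme$variables[[v]]$states)
      grid <- grid[grid[[v]] == si, , drop = FALSE]
    }
  }
  states <- net$scheme$variables[[query]]$states
  p <- vapply(seq_along(states), function(s)
    sum(grid$prob[grid[[query]] == s]), numeric(1))
  setNames(p / sum(p), states)
}

# P(evidence) by enumeration
oracle_evidence_prob <- function(net, evidence) {
  grid <- oracle_joint(net)
  for (v in names(evidence)) {
    si <- match(evidence[[v]], net$scheme$variables[[v]]$states)
    grid <- grid[grid[[v]] == si, , drop = FALSE]
  }
  sum(grid$prob)
}

# random evidence: a random subset of nodes set to random states
random_evidence <- function(net, p_include = 0.4) {
  nodes <- net$structure$nodes
  take <- nodes[runif(length(nodes)) < p_include]
  if (!length(take)) return(NULL)
  ev <- vapply(take, function(v)
    sample(net$scheme$variables[[v]]$states, 1), character(1))
  ev
}
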