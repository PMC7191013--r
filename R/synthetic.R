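#' Calibrated synthetic ground-truth network
#'
#' A fully parameterized Bayesian network on the default study
#' structure, used to generate synthetic observation campaigns and to
#' evaluate the estimation and sensitivity machinery.  Its CPTs are
#' solved deterministically at first use so that the implied exact
#' probabilities reproduce the study site's reported figures:
#'
#' * P(HRUB = yes) = 0.248,
#' * P(MaritalStatus = yes) = 0.736,
#' * P(PreviousAccident = major accident) = 0.0411,
#' * P(EducationalLevel = high school) = 0.595,
#' * P(HRUB = yes | Training = s3) = 0.123.
#'
#' The outcome CPT over its 1,458 parent configurations follows an
#' additive logistic model: each parent state contributes a fixed
#' log-odds effect (signs and relative sizes chosen so that safety
#' training is by far the strongest driver, inexperience, being
#' unmarried, a previous major accident, primary education, week-end
#' days and afternoon hours all raise the outcome rate), and the
#' intercept together with the `Training = s3` effect are root-found
#' so the two outcome targets above hold exactly.  Remaining CPT
#' entries (age, experience, weekday, daytime distributions and the
#' training response to accidents) are fixed plausible values that are
#' not pinned by any reported figure; they are synthetic.
#'
#' The solved network is cached for the session; the function is fully
#' deterministic.
#'
#' @return A `"bn"` object over [default_scheme()].
#' @examples
#' net <- ground_truth_network()
#' posterior(net, "HRUB")
#' @export
ground_truth_network <- function() {
  if (!is.null(.sbsbn_cache$ground_truth)) return(.sbsbn_cache$ground_truth)
  scheme <- default_scheme()
  st <- default_study_network()

  cpts <- list(
    Age = make_cpt("Age", character(0), scheme,
                   values = c(0.30, 0.45, 0.25)),
    Experience = make_cpt("Experience", "Age", scheme, rows = rbind(
      c(0.35, 0.45, 0.20),    # under 30
      c(0.05, 0.35, 0.60),    # 30-40
      c(0.02, 0.18, 0.80))),  # above 40
    MaritalStatus = make_cpt("MaritalStatus", "Age", scheme, rows = rbind(
      c(0.52, 0.48),
      c(0.80, 0.20),
      c(0.88, 0.12))),        # marginal P(yes) = 0.736 exactly
    PreviousAccident = make_cpt("PreviousAccident", character(0), scheme,
                                values = c(0.80, 0.1589, 0.0411)),
    EducationalLevel = make_cpt("EducationalLevel", character(0), scheme,
                                values = c(0.25, 0.595, 0.155)),
    Weekday = make_cpt("Weekday", character(0), scheme,
                       values = c(0.28, 0.50, 0.22)),
    Daytime = make_cpt("Daytime", character(0), scheme,
                       values = c(0.35, 0.33, 0.32)),
    Training = make_cpt("Training", "PreviousAccident", scheme, rows = rbind(
      c(0.45, 0.35, 0.20),    # no accident
      c(0.25, 0.40, 0.35),    # minor
      c(0.10, 0.35, 0.55)))   # major: pushed into more courses
  )

  # --- outcome CPT: additive logistic effects -------------------------
  hp <- st$parents$HRUB
  effects <- list(
    Experience       = c(0.20, 0.30, -0.30),
    MaritalStatus    = c(-0.12, 0.33),
    PreviousAccident = c(-0.05, 0.10, 0.45),
    Training         = c(0.60, 0.00, NA),   # s3 effect solved below
    EducationalLevel = c(0.28, -0.14, 0.14),
    Weekday          = c(-0.13, -0.07, 0.38),
    Daytime          = c(-0.10, 0.07, 0.07)
  )

  # joint distribution of the outcome's parents, in CPT parent order
  card <- scheme_card(scheme)
  pre <- bn_network(scheme, bn_structure(st$parents[setdiff(st$nodes, "HRUB")]),
                    cpts)
  pj <- ve_eliminate(bn_factors(pre), card, keep = hp,
                     evidence_idx = setNames(integer(0), character(0)))
  perm <- match(hp, pj$vars)
  pjt <- aperm(pj$tab, perm)                # dims follow hp order
  pvec <- as.numeric(pjt)

  # linear predictor per parent configuration (column-major order over
  # hp dims, first parent fastest -- same order as pvec)
  dims <- unname(card[hp])
  eta0 <- numeric(length(pvec))
  s3 <- numeric(length(pvec))
  tmpl <- array(0, dim = dims)
  for (k in seq_along(hp)) {
    si <- as.numeric(slice.index(tmpl, k))
    e <- effects[[hp[k]]]
    if (hp[k] == "Training") {
      eta0 <- eta0 + ifelse(si == 3, 0, e[si])
      s3 <- as.numeric(si == 3)
    } else eta0 <- eta0 + e[si]
  }

  p_yes <- function(b0, d3) plogis(b0 + eta0 + d3 * s3)
  marg <- function(b0, d3) sum(pvec * p_yes(b0, d3))
  cond_s3 <- function(b0, d3)
    sum(pvec * s3 * p_yes(b0, d3)) / sum(pvec * s3)
  solve_b0 <- function(d3)
    uniroot(function(b0) marg(b0, d3) - 0.248, c(-8, 4),
            tol = 1e-13)$root
  d3 <- uniroot(function(d) cond_s3(solve_b0(d), d) - 0.123, c(-5, 0),
                tol = 1e-13)$root
  b0 <- solve_b0(d3)
  py <- p_yes(b0, d3)
  hr <- array(rbind(1 - py, py), dim = c(2L, dims))
  cpts$HRUB <- make_cpt("HRUB", hp, scheme, values = hr)

  net <- bn_network(scheme, st, cpts)
  attr(net, "calibration") <- list(intercept = b0, training_s3 = d3,
                                   effects = effects)
  .sbsbn_cache$ground_truth <- net
  net
}

#' Sample synthetic observation records
#'
#' Draws `n` records from a network by ancestral sampling (each node
#' sampled after its parents, in topological order), then masks each
#' cell independently with probability `missing_rate` (missing
#' completely at random).  Deterministic given `seed`.
#'
#' @param network a `"bn"` object.
#' @param n number of records (>= 0).
#' @param missing_rate MCAR masking probability in `[0, 1)`; default 0.
#' @param seed RNG seed.
#' @return An observation data.frame (class `"observations"`) with the
#'   network's scheme attached.
#' @examples
#' head(sample_observations(ground_truth_network(), 5, seed = 1))
#' @export
sample_observations <- function(network, n, missing_rate = 0, seed = NULL) {
  if (!is_count(n)) stop("n must be a non-negative count", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  st <- network$structure
  card <- scheme_card(network$scheme)[st$nodes]
  m <- matrix(NA_integer_, n, length(st$nodes),
              dimnames = list(NULL, st$nodes))
  with_seed(seed, {
    if (n > 0) {
      for (v in st$order) {
        pa <- st$parents[[v]]
        r <- card[[v]]
        cpt <- network$cpts[[v]]
        rows <- cpt_to_rows(cpt)           # configs x child states
        cfg <- if (!length(pa)) rep(1L, n) else {
          # lexicographic config index matching parent_configs()
          idx <- rep(1, n)
          mult <- 1
          for (k in rev(seq_along(pa))) {
            idx <- idx + (m[, pa[k]] - 1) * mult
            mult <- mult * card[[pa[k]]]
          }
          as.integer(idx)
        }
        cum <- rows %*% upper.tri(diag(r), diag = TRUE)
        u <- runif(n)
        stv <- rep(1L, n)
        if (r > 1)
          for (k in seq_len(r - 1L))
            stv <- stv + as.integer(u > cum[cfg, k])
        m[, v] <- stv
      }
      if (missing_rate > 0) {
        mask <- matrix(runif(n * ncol(m)) < missing_rate, n)
        m[mask] <- NA_integer_
      }
    }
  })
  decode_observations(m, network$scheme)
}

#' @export
simulate.bn <- function(object, nsim = 1, seed = NULL, n = 1960,
                        missing_rate = 0, ...) {
  sims <- lapply(seq_len(nsim), function(k)
    sample_observations(object, n = n, missing_rate = missing_rate,
                        seed = if (is.null(seed)) NULL else seed + k - 1))
  if (nsim == 1) sims[[1]] else sims
}
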