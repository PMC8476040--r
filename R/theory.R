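#' Fraction of network elements claimed by an STM list
#'
#' For a list of `L` random patterns, the probability that a randomly chosen
#' network element (a unit for Model 1, a unit-state for Model 2, a tensor
#' coupling for Models 3a/3b) belongs to at least one listed pattern:
#' \deqn{M1: 1-(1-a)^L, \quad M2: 1-(1-a/S)^L, \quad
#'       M3a: 1-(1-a^2/S^2)^L, \quad M3b: (1-(1-a/S)^L)^2.}
#' As this fraction approaches 1 the boost loses selectivity: long-term
#' memories receive the same kick as the list and interference takes over.
#'
#' @param model one of `"M1"`, `"M2"`, `"M3a"`, `"M3b"`.
#' @param L list length, `>= 0` (vectorized).
#' @param a sparsity; @param S active states per unit.
#' @return The boosted fraction in `[0, 1]`.
#' @export
boosted_fraction <- function(model = c("M1", "M2", "M3a", "M3b"), L, a, S) {
  model <- match.arg(model)
  if (any(L < 0)) stop("L must be >= 0")
  if (a < 0 || a > 1 || S < 1) stop("invalid a or S")
  switch(model,
    M1  = 1 - (1 - a)^L,
    M2  = 1 - (1 - a / S)^L,
    M3a = 1 - (1 - a^2 / S^2)^L,
    M3b = (1 - (1 - a / S)^L)^2
  )
}

#' Critical list length of an STM boost mechanism
#'
#' The list length at which the boosted fraction reaches `1 - 1/e`, beyond
#' which the mechanism can no longer discriminate the list from the rest of
#' long-term memory (natural logarithms):
#' \deqn{M1: -1/\ln(1-a), \quad M2: -1/\ln(1-a/S), \quad
#'       M3a: -1/\ln(1-a^2/S^2), \quad
#'       M3b: \ln(1-\sqrt{1-1/e})/\ln(1-a/S).}
#'
#' @inheritParams boosted_fraction
#' @return The critical length `L_c` (items, continuous).
#' @examples
#' critical_length("M1", a = 0.25)          # ~3.5
#' critical_length("M2", a = 0.25, S = 7)   # ~27.5
#' @export
critical_length <- function(model = c("M1", "M2", "M3a", "M3b"), a, S = NULL) {
  model <- match.arg(model)
  if (a <= 0 || a > 1) stop("a must lie in (0, 1] (a = 0 gives infinite L_c)")
  if (model != "M1") {
    if (is.null(S) || S < 1) stop("S is required for models M2, M3a, M3b")
    if (a / S >= 1) stop("a/S must be < 1")
  }
  switch(model,
    M1  = -1 / log(1 - a),
    M2  = -1 / log(1 - a / S),
    M3a = -1 / log(1 - a^2 / S^2),
    M3b = log(1 - sqrt(1 - exp(-1))) / log(1 - a / S)
  )
}

#' Equal-probability random-walk null model of free recall
#'
#' Simulates recall as uniform draws over `L` items -- by default forbidding
#' immediate repeats, mirroring the adaptation-driven avoidance of close
#' repetitions in the network -- and applies one of the recall stopping rules.
#' The mean distinct-item count grows like `sqrt(L)` for all rules, which is
#' the scaling signature the latching simulations are compared against.
#'
#' @param L number of items, `>= 2`.
#' @param stop_rule `"first_revisit"`, `"repeated_transition"`,
#'   `"third_occurrence"` or `"budget"` (the `2L - h` automaton).
#' @param n_runs Monte-Carlo sample size.
#' @param seed optional integer seed.
#' @param immediate_repeats `"forbid"` (default) or `"allow"` (pure i.i.d.
#'   draws, the classical birthday-problem setting).
#' @return A list with `mean` and `se` of the distinct-item count, plus the
#'   raw `counts`.
#' @export
random_walk_null <- function(L, stop_rule = c("first_revisit",
                                              "repeated_transition",
                                              "third_occurrence", "budget"),
                             n_runs = 1000L, seed = NULL,
                             immediate_repeats = c("forbid", "allow")) {
  stop_rule <- match.arg(stop_rule)
  immediate_repeats <- match.arg(immediate_repeats)
  if (L < 2L) stop("L must be >= 2")
  rule <- match(stop_rule, c("first_revisit", "repeated_transition",
                             "third_occurrence", "budget")) - 1L
  mode <- if (immediate_repeats == "forbid") 1L else 0L
  draw <- function() random_walk_cpp(as.integer(L), as.integer(n_runs),
                                     mode, rule)
  counts <- if (is.null(seed)) draw() else withr_seed(seed, draw())
  list(mean = mean(counts), se = sd(counts) / sqrt(n_runs), counts = counts)
}

#' Exact birthday-problem expectation of distinct items before a revisit
#'
#' Under i.i.d. uniform draws over `L` items, the expected number of distinct
#' items seen when the first revisit occurs is
#' `sum_{n >= 1} prod_{j=1}^{n-1} (1 - j/L)` minus 1 -- equivalently the
#' expected number of draws until the first collision minus one. Computed by
#' direct summation (asymptotically `sqrt(pi L / 2) - 1/3`).
#'
#' @param L number of items.
#' @return The exact expectation.
#' @export
birthday_expected_distinct <- function(L) {
  # pn[n] = P(first n draws all distinct) = P(draws-until-collision > n);
  # E[draws] = 1 + sum(pn), and distinct = draws - 1.
  pn <- cumprod(c(1, 1 - seq_len(L - 1) / L))
  sum(pn)
}

#' Deterministic greedy-similarity search baseline
#'
#' Recall modelled as a deterministic walk on a similarity matrix: from the
#' current item, move to the most similar item other than the current one
#' and the immediately preceding one. Excluding the predecessor is essential:
#' a pure argmax walk falls into a two-cycle between mutually most similar
#' items almost immediately, whereas the one-step memory lets the loop grow
#' with the list, giving the square-root scaling of recalled items. With a
#' symmetric matrix the walk always enters a loop; `R` is the number of
#' distinct items visited when a previously executed transition first
#' recurs. For asymmetric matrices a transition loop may take very long, so
#' the count at the first item revisit is also returned as a surrogate.
#'
#' @param L number of items, `>= 2`.
#' @param similarity optional `L x L` similarity matrix (off-diagonal ties
#'   are perturbed by a tiny jitter); if missing, one is drawn i.i.d.
#'   uniform(0, 1).
#' @param symmetric logical: symmetrize a drawn matrix (ignored when
#'   `similarity` is supplied).
#' @param seed optional integer seed for the drawn matrix.
#' @return A list with `R` (distinct items at the first repeated transition),
#'   `first_revisit` (distinct items at the first item revisit) and the
#'   visited `path`.
#' @export
greedy_similarity_baseline <- function(L, similarity = NULL, symmetric = TRUE,
                                       seed = NULL) {
  if (L < 2L) stop("L must be >= 2")
  if (is.null(similarity)) {
    draw <- function() {
      s <- matrix(runif(L * L), L, L)
      if (symmetric) s <- (s + t(s)) / 2
      s
    }
    similarity <- if (is.null(seed)) draw() else withr_seed(seed, draw())
  }
  stopifnot(nrow(similarity) == L, ncol(similarity) == L)
  off <- similarity[row(similarity) != col(similarity)]
  if (anyDuplicated(off)) {
    similarity <- similarity +
      matrix(seq_len(L * L) * 1e-12, L, L) # deterministic tie-break jitter
  }
  path <- 1L
  cur <- 1L
  prev <- NA_integer_
  seen_trans <- character(0)
  visited <- c(1L)
  R <- NA_integer_; first_revisit <- NA_integer_
  for (t in seq_len(2L * L * L + 10L)) {
    s <- similarity[cur, ]
    s[cur] <- -Inf
    if (!is.na(prev) && L > 2L) s[prev] <- -Inf
    nxt <- which.max(s)
    key <- paste(cur, nxt)
    if (key %in% seen_trans) {
      R <- length(unique(path))
      if (is.na(first_revisit)) first_revisit <- length(unique(path))
      break
    }
    seen_trans <- c(seen_trans, key)
    if (is.na(first_revisit) && nxt %in% visited) {
      first_revisit <- length(unique(path))
    }
    visited <- union(visited, nxt)
    path <- c(path, nxt)
    prev <- cur
    cur <- nxt
  }
  list(R = R, first_revisit = first_revisit, path = path)
}

#' Tabulate the capacity theory over a grid of list lengths
#'
#' @param a sparsity; @param S states; @param L_grid list lengths.
#' @return A data frame with one row per (model, L): the boosted fraction
#'   `P_L` and the model's critical length `L_c`.
#' @export
theory_table <- function(a, S, L_grid = 2^(0:7)) {
  models <- c("M1", "M2", "M3a", "M3b")
  do.call(rbind, lapply(models, function(m) {
    data.frame(model = m, a = a, S = S, L = L_grid,
               P_L = boosted_fraction(m, L_grid, a, S),
               L_c = critical_length(m, a, S))
  }))
}
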