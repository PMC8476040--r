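#' Configure a short-term-memory boost
#'
#' Short-term storage is modelled as a transient increase `delta` of one
#' pre-existing network parameter, restricted to the elements participating in
#' an ordered list of `L` patterns (the items "held in STM"):
#' * `"M1"` boosts the local feedback `w` of every unit active in any listed
#'   pattern;
#' * `"M2"` lowers the adaptive threshold of every (unit, state) pair used by
#'   a listed pattern;
#' * `"M3a"` potentiates tensor couplings whose state pair belongs to a single
#'   listed pattern (items stored at separate times);
#' * `"M3b"` additionally potentiates the cross-item (heteroassociative)
#'   couplings between any pair of listed patterns (items stored together);
#' * `"none"` leaves the network untouched (the long-term-memory control).
#'
#' @param model one of `"none"`, `"M1"`, `"M2"`, `"M3a"`, `"M3b"`.
#' @param delta boost magnitude (`delta_w`, `delta_theta` or `delta_J`
#'   depending on the model), `>= 0`.
#' @param stm_list ordered vector of distinct pattern indices held in STM.
#' @return A `boost_config` list.
#' @export
boost_config <- function(model = c("none", "M1", "M2", "M3a", "M3b"),
                         delta = 0, stm_list = integer(0)) {
  model <- match.arg(model)
  if (delta < 0) stop("delta must be >= 0")
  stm_list <- as.integer(stm_list)
  if (anyDuplicated(stm_list)) stop("stm_list must not contain duplicates")
  structure(list(model = model, delta = delta, stm_list = stm_list),
            class = "boost_config")
}

#' Per-unit local feedback under the unit-level boost (Model 1)
#'
#' A unit gets `w + delta_w` if it is active (state > 0) in at least one of
#' the listed patterns, and the common `w` otherwise.
#'
#' @param w baseline local feedback.
#' @param delta_w boost magnitude, `>= 0`.
#' @param patterns a [potts_patterns][generate_patterns] object.
#' @param stm_list pattern indices held in STM (possibly empty).
#' @return A numeric vector of length `N`.
#' @export
apply_model1 <- function(w, delta_w, patterns, stm_list) {
  if (delta_w < 0) stop("delta_w must be >= 0")
  member <- stm_unit_membership(patterns, stm_list)
  rep(w, patterns$N) + delta_w * member
}

stm_unit_membership <- function(patterns, stm_list) {
  if (length(stm_list) == 0L) return(rep(0L, patterns$N))
  as.integer(colSums(patterns$xi[stm_list, , drop = FALSE] > 0L) > 0L)
}

#' Indicator of (unit, state) pairs used by the STM list (Model 2)
#'
#' `mask[i, k] = 1` iff unit `i` is in active state `k` in at least one listed
#' pattern. The dynamics subtract `delta_theta * mask` inside the adaptive
#' threshold equation, reducing adaptation selectively for those states.
#'
#' @inheritParams apply_model1
#' @return An `N x S` 0/1 integer matrix.
#' @export
model2_theta_mask <- function(patterns, stm_list) {
  N <- patterns$N; S <- patterns$S
  mask <- matrix(0L, N, S)
  for (mu in stm_list) {
    xi <- patterns$xi[mu, ]
    act <- which(xi > 0L)
    mask[cbind(act, xi[act])] <- 1L
  }
  mask
}

#' Potentiate within-item couplings (Model 3a)
#'
#' Adds `delta_J` to every stored coupling whose state pair `(k, l)` equals
#' `(xi_i^mu, xi_j^mu)` for at least one listed pattern `mu` (both states
#' active). The boost is applied once per coupling regardless of how many
#' listed patterns claim it.
#'
#' @param weights a [potts_weights][build_weights] object.
#' @param delta_J boost magnitude, `>= 0`.
#' @inheritParams apply_model1
#' @return A new `potts_weights` object with the boosted tensor.
#' @export
apply_model3a <- function(weights, delta_J, patterns, stm_list) {
  if (delta_J < 0) stop("delta_J must be >= 0")
  J <- boost_weights_cpp(weights$J, weights$jidx, patterns$xi,
                         weights$S, as.integer(stm_list), delta_J,
                         pairwise = FALSE)
  out <- weights
  out$J <- J
  out
}

#' Potentiate within- and cross-item couplings (Model 3b)
#'
#' Adds `delta_J` to every stored coupling with `k = xi_i^mu` and
#' `l = xi_j^nu` for *any* ordered pair `(mu, nu)` of listed patterns, i.e.
#' both the autoassociative couplings of Model 3a and the heteroassociative
#' couplings between different listed items.
#'
#' @inheritParams apply_model3a
#' @return A new `potts_weights` object with the boosted tensor.
#' @export
apply_model3b <- function(weights, delta_J, patterns, stm_list) {
  if (delta_J < 0) stop("delta_J must be >= 0")
  J <- boost_weights_cpp(weights$J, weights$jidx, patterns$xi,
                         weights$S, as.integer(stm_list), delta_J,
                         pairwise = TRUE)
  out <- weights
  out$J <- J
  out
}

#' Heteroassociative couplings encoding a serial-recall instruction
#'
#' Given an instruction sequence `I_1, ..., I_L` of pattern indices, the
#' coupling from state `l` of unit `j` to state `k` of unit `i` equals
#' `lambda` iff `k = xi_i^{I_{mu+1}}` and `l = xi_j^{I_mu}` for some
#' transition `mu` (both states active), and 0 otherwise. These couplings are
#' driven by the adaptive thresholds rather than the activations, so that a
#' *fatiguing* item pushes the network toward its instructed successor. They
#' are not diluted: every ordered pair `j != i` may carry one.
#'
#' @param patterns a [potts_patterns][generate_patterns] object.
#' @param instruction vector of pattern indices (length `>= 1`).
#' @param lambda heteroassociative strength, `>= 0`.
#' @return An object of class `potts_het` holding `lambda` and a compressed
#'   index of the nonzero targets, consumable by [run_potts()]. Use
#'   [as_dense_het()] to expand it on small fixtures.
#' @export
hetero_weights <- function(patterns, instruction, lambda) {
  if (length(instruction) < 1L) stop("instruction must be nonempty")
  if (lambda < 0) stop("lambda must be >= 0")
  instruction <- as.integer(instruction)
  if (any(instruction < 1L) || any(instruction > patterns$p)) {
    stop("instruction items must be valid pattern indices")
  }
  idx <- het_index_cpp(patterns$xi, instruction, patterns$S)
  structure(list(lambda = lambda, instruction = instruction,
                 N = patterns$N, S = patterns$S, index = idx),
            class = "potts_het")
}

#' Densify heteroassociative couplings (small networks only)
#'
#' @param het a [potts_het][hetero_weights] object.
#' @return A dense `N x N x S x S` array with entries in `{0, lambda}` (the
#'   diagonal `i = j` is zero by convention, matching the field sum over
#'   `j != i`).
#' @export
as_dense_het <- function(het) {
  N <- het$N; S <- het$S
  out <- array(0, dim = c(N, N, S, S))
  idx <- het$index
  for (e in seq_along(idx$unit)) {
    i <- idx$unit[e]; k <- idx$state[e]
    lo <- idx$ptr[e] + 1L; hi <- idx$ptr[e + 1L]
    if (hi < lo) next
    for (q in lo:hi) {
      j <- idx$src_unit[q]; l <- idx$src_state[q]
      out[i, j, k, l] <- het$lambda
    }
  }
  out
}

#' Sample serial-recall instruction sequences
#'
#' Draws `n_seq` distinct sequences of length `L` over the given alphabet,
#' excluding any subsequence of the form `AA` (an immediate repeat) or `ABA`
#' (a return after one step): adaptation prevents the Potts network from
#' expressing such sequences, so they are withheld from the instruction set.
#' Each sequence is grown one item at a time, choosing uniformly among the
#' admissible continuations (a constant number at every position, so sequences
#' are uniform over the admissible set); duplicate sequences are rejected and
#' redrawn, up to a hard cap of 1e6 draws.
#'
#' @param n_seq number of sequences.
#' @param L sequence length.
#' @param alphabet vector of item labels (pattern indices); at least 3 items
#'   are needed when `L >= 3`.
#' @param seed optional integer seed.
#' @return A list of `n_seq` integer vectors.
#' @export
sample_instruction_sequences <- function(n_seq, L, alphabet, seed = NULL) {
  alphabet <- as.integer(alphabet)
  K <- length(alphabet)
  if (L >= 3L && K < 3L) stop("alphabet must have >= 3 items for L >= 3")
  if (L >= 2L && K < 2L) stop("alphabet must have >= 2 items for L >= 2")
  n_valid <- if (L == 1L) K else K * (K - 1L) * max(1L, (K - 2L))^max(0L, L - 2L)
  if (n_seq > n_valid) stop("fewer admissible sequences than requested")
  draw_all <- function() {
    seen <- character(0)
    out <- vector("list", n_seq)
    got <- 0L
    draws <- 0L
    while (got < n_seq) {
      draws <- draws + 1L
      if (draws > 1e6) stop("instruction sampling cap exceeded")
      s <- integer(L)
      for (t in seq_len(L)) {
        forbid <- c(if (t >= 2L) s[t - 1L], if (t >= 3L) s[t - 2L])
        cand <- setdiff(alphabet, forbid)
        s[t] <- cand[sample.int(length(cand), 1L)]
      }
      key <- paste(s, collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        got <- got + 1L
        out[[got]] <- s
      }
    }
    out
  }
  if (is.null(seed)) draw_all() else withr_seed(seed, draw_all())
}
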