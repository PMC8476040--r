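#' Build dilute random connectivity
#'
#' Every unit `i` receives input from exactly `c_m` distinct units `j != i`,
#' chosen uniformly at random and independently per unit, so the graph is in
#' general asymmetric.
#'
#' @param N number of units.
#' @param c_m in-degree (number of input connections per unit), `1 <= c_m < N`.
#' @param seed optional integer seed.
#' @return An object of class `potts_connectivity` with `jidx`, an `N x c_m`
#'   integer matrix whose row `i` lists the source units feeding unit `i`.
#' @export
build_connectivity <- function(N, c_m, seed = NULL) {
  if (c_m < 1L || c_m > N - 1L) {
    stop("c_m must satisfy 1 <= c_m <= N - 1")
  }
  draw <- function() {
    t(vapply(seq_len(N), function(i) {
      sample(setdiff(seq_len(N), i), c_m)
    }, integer(c_m)))
  }
  jidx <- if (is.null(seed)) draw() else withr_seed(seed, draw())
  structure(list(jidx = jidx, N = as.integer(N), c_m = as.integer(c_m)),
            class = "potts_connectivity")
}

#' @export
print.potts_connectivity <- function(x, ...) {
  cat(sprintf("Dilute connectivity: N = %d units, in-degree c_m = %d\n",
              x$N, x$c_m))
  invisible(x)
}

#' Hebbian tensor couplings of a Potts network
#'
#' For every connected pair (`c_ij = 1`) and every pair of *active* states
#' `k, l` in `1..S`, the coupling is the covariance learning rule
#' \deqn{J_{ijkl} = \frac{1}{c_m a (1 - a/S)} \sum_{\mu=1}^{p}
#'   \left(\delta_{\xi_i^\mu k} - \frac{a}{S}\right)
#'   \left(\delta_{\xi_j^\mu l} - \frac{a}{S}\right),}
#' with all components involving the background state identically zero.
#' Storage is sparse over the connected `(i, j)` pairs and dense over the
#' `S x S` state block of each pair.
#'
#' @param patterns a [potts_patterns][generate_patterns] object.
#' @param conn a [potts_connectivity][build_connectivity] on the same `N`.
#' @return An object of class `potts_weights` holding the flat block array
#'   `J` (layout: for unit `i`, source slot `n`, states `k`, `l`, the entry is
#'   `J[(((i-1) c_m + n - 1) S + k - 1) S + l]`), plus `jidx`, `N`, `S`, `c_m`
#'   and `a`.
#' @export
build_weights <- function(patterns, conn) {
  stopifnot(inherits(patterns, "potts_patterns"),
            inherits(conn, "potts_connectivity"))
  if (patterns$N != conn$N) stop("patterns and connectivity disagree on N")
  J <- build_weights_cpp(patterns$xi, conn$jidx, patterns$S, patterns$a)
  new_potts_weights(J, conn, patterns)
}

new_potts_weights <- function(J, conn, patterns) {
  structure(
    list(J = J, jidx = conn$jidx, N = conn$N, c_m = conn$c_m,
         S = patterns$S, a = patterns$a),
    class = "potts_weights"
  )
}

#' @export
print.potts_weights <- function(x, ...) {
  cat(sprintf(
    "Potts tensor couplings: N = %d, c_m = %d, S = %d (%d stored entries)\n",
    x$N, x$c_m, x$S, length(x$J)))
  invisible(x)
}

#' Look up one tensor coupling
#'
#' Returns `J[i, j, k, l]`; zero when `j` does not feed `i` or when either
#' state index is the background state 0.
#'
#' @param weights a [potts_weights][build_weights] object.
#' @param i,j unit indices; @param k,l state indices in `0..S`.
#' @return The coupling value.
#' @export
weight_entry <- function(weights, i, j, k, l) {
  if (k == 0L || l == 0L) return(0)
  n <- match(j, weights$jidx[i, ])
  if (is.na(n)) return(0)
  S <- weights$S
  weights$J[(((i - 1L) * weights$c_m + n - 1L) * S + (k - 1L)) * S + l]
}

#' Densify a weight tensor (small networks only)
#'
#' Expands the sparse block storage into a full `N x N x S x S` array, used
#' for brute-force cross-checks on hand-sized fixtures.
#'
#' @param weights a [potts_weights][build_weights] object.
#' @return A dense numeric array indexed `[i, j, k, l]`.
#' @export
as_dense_weights <- function(weights) {
  N <- weights$N; S <- weights$S
  out <- array(0, dim = c(N, N, S, S))
  for (i in seq_len(N)) {
    for (n in seq_len(weights$c_m)) {
      j <- weights$jidx[i, n]
      blk <- matrix(
        weights$J[(((i - 1L) * weights$c_m + n - 1L) * S * S + 1L):
                  (((i - 1L) * weights$c_m + n) * S * S)],
        nrow = S, byrow = TRUE)
      out[i, j, , ] <- blk
    }
  }
  out
}
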