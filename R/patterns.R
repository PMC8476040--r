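#' Generate random sparse Potts patterns
#'
#' Each of the `p` stored memories assigns to every one of the `N` Potts units
#' either the background state 0, with probability `1 - a`, or one of the `S`
#' active states, each with probability `a / S`. Entries are drawn
#' independently across units and patterns, so the number of active units per
#' pattern is binomial with mean `N * a` (it is not forced to be exactly
#' `N * a`).
#'
#' @param p number of patterns (long-term memories).
#' @param N number of Potts units.
#' @param S number of active states per unit.
#' @param a sparsity: probability that a unit is active in a pattern, in
#'   `[0, 1]`.
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return An object of class `potts_patterns`: an integer `p x N` matrix `xi`
#'   with entries in `{0, ..., S}`, carrying `S`, `a`, `p`, `N` (and `seed`)
#'   as attributes.
#' @examples
#' pats <- generate_patterns(p = 5, N = 50, S = 7, a = 0.25, seed = 1)
#' mean(pats$xi > 0) # close to a
#' @export
generate_patterns <- function(p, N, S, a, seed = NULL) {
  if (length(S) != 1L || S < 1L) stop("S must be a positive integer")
  if (length(a) != 1L || is.na(a) || a < 0 || a > 1) {
    stop("sparsity 'a' must lie in [0, 1]")
  }
  if (p < 1L || N < 1L) stop("p and N must be >= 1")
  draw <- function() {
    matrix(
      sample.int(S + 1L, size = p * N, replace = TRUE,
                 prob = c(1 - a, rep(a / S, S))) - 1L,
      nrow = p, ncol = N
    )
  }
  xi <- if (is.null(seed)) draw() else withr_seed(seed, draw())
  new_potts_patterns(xi, S = S, a = a, seed = seed)
}

new_potts_patterns <- function(xi, S, a, seed = NULL) {
  stopifnot(is.matrix(xi), all(xi >= 0L), all(xi <= S))
  structure(
    list(xi = xi, S = as.integer(S), a = a,
         p = nrow(xi), N = ncol(xi), seed = seed),
    class = "potts_patterns"
  )
}

#' @export
print.potts_patterns <- function(x, ...) {
  cat(sprintf(
    "Potts pattern set: p = %d patterns over N = %d units (S = %d, a = %g)\n",
    x$p, x$N, x$S, x$a))
  cat(sprintf("  empirical active fraction: %.4f\n", mean(x$xi > 0L)))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Spawn k reproducible sub-seeds from one root seed, so that patterns,
# connectivity and item selection are independently reproducible.
spawn_seeds <- function(root, k) {
  withr_seed(root, sample.int(.Machine$integer.max - 1L, k))
}

#' Pairwise correlation of two Potts patterns on shared active states
#'
#' `correlation_as(x, mu, nu)` counts units that are active in pattern `mu`
#' *and* sit in the same active state in pattern `nu`, normalized by `N * a`
#' (the mean, not the realized, number of active units). Consequently the
#' self-correlation `correlation_as(x, mu, mu)` equals the realized active
#' fraction of pattern `mu` divided by `a`, which is close to, but not exactly,
#' 1. Over random pattern pairs its expectation is `a / S`.
#'
#' @param patterns a [potts_patterns][generate_patterns] object.
#' @param mu,nu pattern indices in `1..p`.
#' @return A scalar correlation.
#' @export
correlation_as <- function(patterns, mu, nu) {
  xi <- pattern_rows(patterns, mu, nu)
  sum(xi$u > 0L & xi$u == xi$v) / (patterns$N * patterns$a)
}

#' Pairwise correlation of two Potts patterns on discordant active states
#'
#' Counts units active in both patterns but in *different* states, normalized
#' by `N * a`. Zero for identical patterns; expectation `a (S - 1) / S` over
#' random pairs.
#'
#' @inheritParams correlation_as
#' @return A scalar correlation.
#' @export
correlation_ad <- function(patterns, mu, nu) {
  xi <- pattern_rows(patterns, mu, nu)
  sum(xi$u > 0L & xi$v > 0L & xi$u != xi$v) / (patterns$N * patterns$a)
}

#' Semantic distance between two stored patterns
#'
#' `d = (C_ad - C_as + 1) / 2`, where `C_as` and `C_ad` are the same-state and
#' different-state active correlations. It is 0 for a pattern against itself
#' (when the pattern has exactly `N a` active units), 1 for maximally
#' anti-correlated patterns, and has expectation `(S - 2) a / (2 S) + 1/2`
#' over random pairs.
#'
#' @inheritParams correlation_as
#' @return A scalar distance in `[0, 1]` (up to binomial fluctuations of the
#'   realized active count).
#' @export
pattern_distance <- function(patterns, mu, nu) {
  (correlation_ad(patterns, mu, nu) - correlation_as(patterns, mu, nu) + 1) / 2
}

#' Expected distance between random Potts patterns
#'
#' Closed form `(S - 2) a / (2 S) + 1/2` for the mean of
#' [pattern_distance()] over independently drawn patterns.
#'
#' @param S number of active states; @param a sparsity.
#' @return The expected distance.
#' @examples
#' expected_distance(S = 7, a = 0.25) # ~0.589
#' @export
expected_distance <- function(S, a) (S - 2) * a / (2 * S) + 0.5

pattern_rows <- function(patterns, mu, nu) {
  stopifnot(inherits(patterns, "potts_patterns"))
  p <- patterns$p
  if (any(c(mu, nu) < 1L) || any(c(mu, nu) > p)) {
    stop("pattern index out of bounds")
  }
  list(u = patterns$xi[mu, ], v = patterns$xi[nu, ])
}

#' Write / read a pattern set as a plain-text file
#'
#' The format is a `#`-prefixed metadata header (p, N, S, a, seed) followed by
#' one whitespace-separated row of unit states per pattern.
#'
#' @param patterns a [potts_patterns][generate_patterns] object.
#' @param path file path.
#' @return `write_patterns()` returns `path` invisibly; `read_patterns()`
#'   returns a `potts_patterns` object.
#' @export
write_patterns <- function(patterns, path) {
  stopifnot(inherits(patterns, "potts_patterns"))
  hdr <- sprintf("# p=%d N=%d S=%d a=%.17g seed=%s",
                 patterns$p, patterns$N, patterns$S, patterns$a,
                 if (is.null(patterns$seed)) "NA" else patterns$seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(patterns$xi, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#")) stop("missing metadata header")
  kv <- strsplit(trimws(sub("^#", "", hdr)), "\\s+")[[1]]
  meta <- setNames(
    lapply(strsplit(kv, "="), `[`, 2L),
    vapply(strsplit(kv, "="), `[`, "", 1L)
  )
  xi <- as.matrix(read.table(path, skip = 1L))
  dimnames(xi) <- NULL
  storage.mode(xi) <- "integer"
  seed <- suppressWarnings(as.integer(meta$seed))
  new_potts_patterns(xi, S = as.integer(meta$S), a = as.numeric(meta$a),
                     seed = if (is.na(seed)) NULL else seed)
}
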