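# Hand fixtures and independent brute-force oracles used across the suite.
# The oracles deliberately re-derive every quantity with naive loops or
# direct scans, sharing no code with the package implementations.

# The 4-unit fixture: xi^1 = (1,2,0,0), xi^2 = (1,3,0,2), a = 0.5, S = 3.
fixture_pair <- function() {
  new_pats(rbind(c(1L, 2L, 0L, 0L),
                 c(1L, 3L, 0L, 2L)), S = 3L, a = 0.5)
}

new_pats <- function(xi, S, a) {
  structure(list(xi = xi, S = as.integer(S), a = a,
                 p = nrow(xi), N = ncol(xi), seed = NULL),
            class = "potts_patterns")
}

# per-unit brute-force pair statistics
oracle_cas <- function(xi_u, xi_v, N, a) {
  s <- 0
  for (i in seq_len(N)) {
    s <- s + as.integer(xi_u[i] != 0 && xi_u[i] == xi_v[i])
  }
  s / (N * a)
}

oracle_cad <- function(xi_u, xi_v, N, a) {
  s <- 0
  for (i in seq_len(N)) {
    s <- s + as.integer(xi_u[i] != 0 && xi_v[i] != 0 && xi_u[i] != xi_v[i])
  }
  s / (N * a)
}

# quadruple-loop Hebbian tensor oracle (dense array)
oracle_weights <- function(pats, jidx) {
  N <- pats$N; S <- pats$S; a <- pats$a; cm <- ncol(jidx)
  q <- a / S
  J <- array(0, dim = c(N, N, S, S))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (!(j %in% jidx[i, ])) next
    for (k in seq_len(S)) for (l in seq_len(S)) {
      s <- 0
      for (mu in seq_len(pats$p)) {
        s <- s + (as.integer(pats$xi[mu, i] == k) - q) *
                 (as.integer(pats$xi[mu, j] == l) - q)
      }
      J[i, j, k, l] <- s / (cm * a * (1 - q))
    }
  }
  J
}

# direct scanners for the recall metrics, written as literal transcriptions
# of the stopping rules
scan_m_corr <- function(items, stm) {
  visited <- c()
  for (x in items) {
    if (!(x %in% stm)) return(length(visited))
    if (x %in% visited) return(length(visited))
    visited <- c(visited, x)
  }
  length(visited)
}

scan_m_i1 <- function(items, stm) {
  items <- items[items %in% stm]
  visited <- c()
  for (x in items) {
    if (x %in% visited) return(length(visited))
    visited <- c(visited, x)
  }
  length(visited)
}

scan_m_it <- function(items, stm) {
  items <- items[items %in% stm]
  if (length(items) < 2L) return(length(unique(items)))
  trans <- list()
  for (t in 2:length(items)) {
    tr <- c(items[t - 1L], items[t])
    for (old in trans) {
      if (identical(old, tr)) return(length(unique(items[1:(t - 1L)])))
    }
    trans[[length(trans) + 1L]] <- tr
  }
  length(unique(items))
}

scan_m_i <- function(items, stm) {
  items <- items[items %in% stm]
  for (t in seq_along(items)) {
    if (sum(items[1:t] == items[t]) == 3L) {
      return(length(unique(items[1:(t - 1L)])))
    }
  }
  length(unique(items))
}

scan_m_u <- function(items, stm, g) {
  items <- head(items, g + 1L)
  length(unique(items[items %in% stm]))
}

# step-by-step click simulator for the 2L - h budget
scan_budget <- function(items, stm, L, stop_on_violation) {
  recalled <- c()
  clicks <- 0L
  for (x in items) {
    allowed <- 2L * L - length(recalled)
    if (clicks >= allowed) break
    clicks <- clicks + 1L
    if (x %in% stm && !(x %in% recalled)) {
      recalled <- c(recalled, x)
    } else if (stop_on_violation) break
  }
  length(recalled)
}

# joint-histogram mutual information oracle (base-2, plug-in)
oracle_mi <- function(items_list, z) {
  pairs <- NULL
  for (s in items_list) {
    n <- length(s)
    if (n > z) pairs <- rbind(pairs, cbind(s[1:(n - z)], s[(1 + z):n]))
  }
  nj <- table(paste(pairs[, 1], pairs[, 2], sep = "|"))
  pj <- nj / sum(nj)
  p1 <- table(pairs[, 1]) / nrow(pairs)
  p2 <- table(pairs[, 2]) / nrow(pairs)
  keys <- strsplit(names(pj), "|", fixed = TRUE)
  s <- 0
  for (q in seq_along(pj)) {
    mu <- keys[[q]][1]; nu <- keys[[q]][2]
    s <- s + pj[q] * log2(pj[q] / (p1[mu] * p2[nu]))
  }
  as.numeric(s)
}

# synthetic overlap trajectory wrapped as a potts_trajectory
synthetic_traj <- function(m, dt = 0.01, sample_every = 1L,
                           terminated_by = "null_attractor",
                           m_star = 0.5, min_dwell_samples = 1L) {
  cfg <- sim_config(dt = dt, tauA = 4 * dt, tau1 = 8 * dt, tau2 = 80 * dt,
                    tauB = 8000 * dt, sample_every = sample_every,
                    m_star = m_star,
                    min_dwell = dt * sample_every * min_dwell_samples)
  structure(
    list(times = seq_len(nrow(m)) * dt * sample_every, m = m,
         activity = rowMeans(m), terminated_by = terminated_by,
         steps = nrow(m) * sample_every, cue = 1L,
         config = cfg, min_dwell_samples = min_dwell_samples),
    class = "potts_trajectory"
  )
}

# n_pairs disjoint pattern pairs (independent samples) for mean statistics
disjoint_pairs <- function(n_pairs, N, S, a, seed) {
  pats <- generate_patterns(2L * n_pairs, N, S, a, seed = seed)
  list(pats = pats, pairs = cbind(seq_len(n_pairs) * 2L - 1L,
                                  seq_len(n_pairs) * 2L))
}

# tiny network bundle shared by the dynamics tests
tiny_net <- function(seed = 7L, N = 12L, p = 3L, S = 3L, a = 0.5, cm = 5L) {
  pats <- generate_patterns(p, N, S, a, seed = seed)
  conn <- build_connectivity(N, cm, seed = seed + 1L)
  list(pats = pats, conn = conn, W = build_weights(pats, conn))
}
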