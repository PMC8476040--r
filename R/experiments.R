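#' Named parameter presets for the reference simulations
#'
#' `preset_free_recall()` is the free-recall regime used for the boost-model
#' comparison: `p = 200` patterns, `S = 7`, `a = 0.25`, `N = 600`,
#' `c_m = 90`, balanced inhibition (`gammaA = 0.5`) and local feedback
#' `w = 1.1`. `preset_wave()` is the latching-wave regime at the same
#' network size with `w` in `{0.4, 0.8, 1.0}` for
#' `gammaA` in `{0, 0.5, 1}` respectively.
#'
#' @param gammaA inhibition balance for `preset_wave()`: 0, 0.5 or 1.
#' @return A list with `p`, `N`, `S`, `a`, `c_m` and a `config`
#'   ([sim_config()]).
#' @export
preset_free_recall <- function() {
  list(p = 200L, N = 600L, S = 7L, a = 0.25, c_m = 90L,
       config = sim_config(gammaA = 0.5, w = 1.1))
}

#' @rdname preset_free_recall
#' @export
preset_wave <- function(gammaA = 0.5) {
  w <- c(`0` = 0.4, `0.5` = 0.8, `1` = 1.0)[as.character(gammaA)]
  if (is.na(w)) stop("gammaA must be 0, 0.5 or 1 for the wave preset")
  list(p = 200L, N = 600L, S = 7L, a = 0.25, c_m = 90L,
       config = sim_config(gammaA = gammaA, w = unname(w)))
}

# Stable digest of a preset (network size + full dynamics config), stamped
# onto every output row so that tables from different runs can be told apart.
config_hash <- function(preset) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(preset[order(names(preset))], tf, version = 2)
  substr(unname(tools::md5sum(tf)), 1L, 12L)
}

# Build patterns + connectivity + weights for one seed of a preset.
setup_network <- function(preset, seed) {
  seeds <- spawn_seeds(seed, 3L)
  patterns <- generate_patterns(preset$p, preset$N, preset$S, preset$a,
                                seed = seeds[1L])
  conn <- build_connectivity(preset$N, preset$c_m, seed = seeds[2L])
  list(patterns = patterns, conn = conn,
       weights = build_weights(patterns, conn), stm_seed = seeds[3L])
}

#' Multi-seed free-recall experiment for one boost model
#'
#' For each seed, a fresh network is generated (patterns, connectivity,
#' weights) and, for each list length `L`, a random STM list is drawn and the
#' network is cued with its first item. The run is digitized and scored with
#' the full family of recall metrics, with and (optionally) without the
#' boost, so that boost-induced gains such as `Delta M_corr` can be formed.
#' Runs stop early once enough retrieval events have been observed to decide
#' every metric (`2L + 2` events).
#'
#' @param L_values list lengths to test.
#' @param model boost model (`"M1"`, `"M2"`, `"M3a"`, `"M3b"`).
#' @param delta boost magnitude.
#' @param n_seeds number of independent networks per `L`.
#' @param seed root seed; every network, STM list and cue derives from it.
#' @param preset a preset list (default [preset_free_recall()]).
#' @param with_control also run the matched `delta = 0` control (same
#'   network, same STM list, same cue).
#' @param mode `"full"` integrates until `2L + 2` retrieval events and scores
#'   every metric; `"error_limited"` stops each run at the first repeat or
#'   intrusion, which decides `M_corr` and the budgeted `M_corr` at a
#'   fraction of the cost (the budget- and repetition-tolerant metrics are
#'   `NA` in this mode).
#' @param verbose print one line per run.
#' @return A data frame with one row per (seed, L, condition) carrying all
#'   recall metrics, the number of latches and the termination reason.
#' @export
recall_experiment <- function(L_values, model = "M2", delta = 0.3,
                              n_seeds = 20L, seed = 1L,
                              preset = preset_free_recall(),
                              with_control = TRUE,
                              mode = c("full", "error_limited"),
                              verbose = FALSE) {
  mode <- match.arg(mode)
  run_seeds <- spawn_seeds(seed, n_seeds)
  rows <- list()
  for (s in seq_len(n_seeds)) {
    net <- setup_network(preset, run_seeds[s])
    stm_lists <- withr_seed(net$stm_seed, lapply(L_values, function(L) {
      sample.int(preset$p, L)
    }))
    for (li in seq_along(L_values)) {
      L <- L_values[li]
      stm <- stm_lists[[li]]
      conds <- if (with_control) c(delta, 0) else delta
      for (dx in conds) {
        row <- score_run(net, stm, model, dx, L, preset, mode)
        row$seed_index <- s
        row$root_seed <- seed
        rows[[length(rows) + 1L]] <- row
        if (verbose) {
          message(sprintf("seed %d L %d delta %.2f: M_corr %d (%s)",
                          s, L, dx, row$M_corr, row$terminated_by))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$config_hash <- config_hash(preset)
  out
}

score_run <- function(net, stm, model, delta, L, preset, mode = "full") {
  boost <- boost_config(if (delta > 0) model else "none",
                        delta = delta, stm_list = stm)
  error_limited <- mode == "error_limited"
  traj <- run_potts(net$patterns, net$weights, preset$config, boost = boost,
                    cue = stm[1L], max_events = 2L * L + 2L,
                    stop_rule = if (error_limited) "violation" else "none")
  sq <- digitize_trajectory(traj)
  data.frame(
    model = model, delta = delta, L = L,
    n_events = nrow(sq$events), n_latches = sq$n_latches,
    M_corr = m_corr(sq, stm),
    M_it = if (error_limited) NA_integer_ else m_it(sq, stm),
    M_i1 = if (error_limited) NA_integer_ else m_i1(sq, stm),
    M_i = if (error_limited) NA_integer_ else m_i(sq, stm),
    M_u_log = if (error_limited) NA_integer_ else m_u(sq, stm, g_log(max(L, 2L))),
    M_R = if (error_limited) NA_integer_ else m_r_budgeted(sq, stm, L),
    M_corr_budgeted = m_corr_budgeted(sq, stm, L),
    terminated_by = traj$terminated_by,
    stringsAsFactors = FALSE)
}

#' Boost-induced recall gain over a list-length scan
#'
#' Convenience summary of [recall_experiment()]: per list length, the mean
#' over seeds of `M_corr(delta) - M_corr(0)` (matched networks) and the mean
#' budget-limited count `M_corr_budgeted(delta)`.
#'
#' @inheritParams recall_experiment
#' @return A data frame with one row per `L`: `delta_M_corr`,
#'   `M_corr_boost`, `M_corr_control`, `M_corr_budgeted`, and their standard
#'   errors.
#' @export
recall_gain_curve <- function(L_values, model = "M2", delta = 0.3,
                              n_seeds = 20L, seed = 1L,
                              preset = preset_free_recall(),
                              mode = "error_limited", verbose = FALSE) {
  df <- recall_experiment(L_values, model, delta, n_seeds, seed, preset,
                          with_control = TRUE, mode = mode,
                          verbose = verbose)
  out <- lapply(sort(unique(df$L)), function(L) {
    b <- df[df$L == L & df$delta > 0, ]
    c0 <- df[df$L == L & df$delta == 0, ]
    stopifnot(nrow(b) == nrow(c0))
    gain <- b$M_corr - c0$M_corr
    data.frame(
      L = L,
      delta_M_corr = mean(gain),
      se_delta = sd(gain) / sqrt(length(gain)),
      M_corr_boost = mean(b$M_corr), M_corr_control = mean(c0$M_corr),
      M_corr_budgeted = mean(b$M_corr_budgeted),
      se_budgeted = sd(b$M_corr_budgeted) / sqrt(nrow(b)))
  })
  do.call(rbind, out)
}

#' Phase classification along a parameter scan
#'
#' Runs the unboosted network once per (w, gammaA) grid point on a fixed
#' network seed and classifies the resulting trajectory into the four
#' operating phases (no latching, finite latching, infinite latching, stable
#' attractor).
#'
#' @param w_values,gammaA_values grid of local feedback and inhibition
#'   balance values.
#' @param seed network seed.
#' @param preset network size preset; its config's `w`/`gammaA` are
#'   overridden by the grid.
#' @param max_updates update cap used for the scan (stable attractors are
#'   declared at this horizon).
#' @return A data frame with `w`, `gammaA`, `phase`, `n_events`,
#'   `terminated_by`.
#' @export
phase_sweep <- function(w_values, gammaA_values = 0.5, seed = 1L,
                        preset = preset_free_recall(), max_updates = 2e4) {
  net <- setup_network(preset, seed)
  grid <- expand.grid(w = w_values, gammaA = gammaA_values)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    cfg <- preset$config
    cfg$w <- grid$w[g]
    cfg$gammaA <- grid$gammaA[g]
    cfg$max_updates <- as.integer(max_updates)
    traj <- run_potts(net$patterns, net$weights, cfg, cue = 1L)
    sq <- digitize_trajectory(traj)
    data.frame(w = grid$w[g], gammaA = grid$gammaA[g],
               phase = classify_phase(sq, traj),
               n_events = nrow(sq$events),
               terminated_by = traj$terminated_by,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$config_hash <- config_hash(preset)
  out
}

#' Serial-recall experiment with heteroassociative instructions
#'
#' The serial-recall model holds a fixed alphabet of `L0 = 6` items in STM
#' via the adaptive-threshold boost (Model 2) and, per trial, encodes one
#' instruction sequence of length `L` into heteroassociative couplings of
#' strength `lambda`. The network is cued with the first instructed item and
#' a trial is correct when the digitized sequence starts with the full
#' instruction in order. Instructions avoid `AA` and `ABA` subsequences.
#'
#' @param L_values instruction lengths (the reference protocol is `3:10`).
#' @param lambda heteroassociative strength.
#' @param delta_theta Model 2 boost on the alphabet items.
#' @param n_seq instructions per length (80 in the reference protocol, if
#'   the admissible set is large enough).
#' @param seed root seed.
#' @param preset network preset.
#' @param alphabet_size number of STM items forming the instruction alphabet.
#' @param congruous if `TRUE`, instructions are harvested from the network's
#'   own `lambda = 0` latching sequences (restricted to the alphabet)
#'   instead of sampled at random; incongruous controls are their shuffles.
#' @return A list with `table` (per-L proportion correct and mean transition
#'   accuracy) and `capacity` (AUC over `1..max(L_values)`).
#' @export
serial_experiment <- function(L_values = 3:6, lambda = 0.01,
                              delta_theta = 0.1, n_seq = 10L, seed = 1L,
                              preset = preset_free_recall(), alphabet_size = 6L,
                              congruous = FALSE) {
  net <- setup_network(preset, seed)
  alphabet <- seq_len(alphabet_size)
  boost <- boost_config("M2", delta = delta_theta, stm_list = alphabet)
  seeds <- spawn_seeds(seed + 1L, length(L_values))
  tab <- lapply(seq_along(L_values), function(li) {
    L <- L_values[li]
    instructions <- if (congruous) {
      harvest_instructions(net, boost, preset, alphabet, L, n_seq, seeds[li])
    } else {
      sample_instruction_sequences(n_seq, L, alphabet, seed = seeds[li])
    }
    ok <- logical(length(instructions))
    acc <- numeric(length(instructions))
    for (q in seq_along(instructions)) {
      instr <- instructions[[q]]
      het <- hetero_weights(net$patterns, instr, lambda)
      traj <- run_potts(net$patterns, net$weights, preset$config,
                        boost = boost, het = het, cue = instr[1L],
                        max_events = L + 2L)
      sq <- digitize_trajectory(traj)
      ok[q] <- serial_score(sq, instr)
      acc[q] <- serial_transition_accuracy(sq, instr)
    }
    data.frame(L = L, n = length(instructions), P_correct = mean(ok),
               transition_accuracy = mean(acc))
  })
  tab <- do.call(rbind, tab)
  tab$config_hash <- config_hash(preset)
  P <- setNames(tab$P_correct, tab$L)
  list(table = tab, capacity = serial_capacity(P, max(L_values)))
}

# Instructions congruous with the network's spontaneous dynamics: run with
# lambda = 0, keep the digitized items that fall in the alphabet, and cut
# AA/ABA-free windows of length L.
harvest_instructions <- function(net, boost, preset, alphabet, L, n_seq,
                                 seed) {
  out <- list()
  cues <- withr_seed(seed, sample(alphabet, n_seq, replace = TRUE))
  attempt <- 0L
  while (length(out) < n_seq && attempt < 20L * n_seq) {
    attempt <- attempt + 1L
    cue <- cues[(attempt - 1L) %% n_seq + 1L]
    traj <- run_potts(net$patterns, net$weights, preset$config,
                      boost = boost, cue = cue,
                      max_events = 4L * L + 4L)
    items <- digitize_trajectory(traj)$events$pattern
    items <- items[items %in% alphabet]
    if (length(items) < L) next
    for (start in seq_len(length(items) - L + 1L)) {
      cand <- items[start:(start + L - 1L)]
      if (valid_instruction(cand) &&
          !any(vapply(out, identical, logical(1), y = cand))) {
        out[[length(out) + 1L]] <- cand
        break
      }
    }
  }
  if (length(out) == 0L) stop("could not harvest any congruous instruction")
  out
}

valid_instruction <- function(x) {
  n <- length(x)
  if (n >= 2L && any(x[-1L] == x[-n])) return(FALSE) # AA
  if (n >= 3L && any(x[-(1:2)] == x[seq_len(n - 2L)])) return(FALSE) # ABA
  TRUE
}
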