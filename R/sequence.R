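#' Digitize an overlap trajectory into a retrieval sequence
#'
#' An item is considered recalled when its overlap is both the largest across
#' all stored patterns and above the threshold `m_star` for at least
#' `min_dwell` seconds. Each such episode is one retrieval event, with onset,
#' offset and peak overlap; consecutive events on the same pattern are merged.
#' The number of latches is the number of event-to-event transitions.
#'
#' @param traj a [potts_trajectory][run_potts()].
#' @param m_star digitization threshold in `(0, 1)`; defaults to the value in
#'   the trajectory's config.
#' @param min_dwell minimum dwell time (s); defaults to the config value.
#' @return A `latching_sequence`: a data frame `events` with columns
#'   `pattern`, `onset`, `offset`, `peak`, plus `n_latches` and
#'   `terminated_by`.
#' @export
digitize_trajectory <- function(traj, m_star = NULL, min_dwell = NULL) {
  stopifnot(inherits(traj, "potts_trajectory"))
  if (length(traj$times) == 0L) stop("empty trajectory")
  if (is.null(m_star)) m_star <- traj$config$m_star
  if (m_star <= 0 || m_star >= 1) stop("m_star must lie in (0, 1)")
  sample_dt <- traj$config$dt * traj$config$sample_every
  dwell_samples <- if (is.null(min_dwell)) traj$min_dwell_samples else
    max(1L, as.integer(round(min_dwell / sample_dt)))

  m <- traj$m
  nt <- nrow(m)
  winner <- max.col(m, ties.method = "first")
  val <- m[cbind(seq_len(nt), winner)]
  elig <- val > m_star

  events <- list()
  cand <- -1L; cand_run <- 0L; run_start <- 1L
  open <- FALSE; ev_start <- 1L
  close_event <- function(t_end) {
    events[[length(events) + 1L]] <<- c(
      pattern = cand_open, onset = traj$times[ev_start],
      offset = traj$times[t_end],
      peak = max(m[ev_start:t_end, cand_open]))
  }
  cand_open <- -1L
  for (t in seq_len(nt)) {
    if (elig[t]) {
      if (winner[t] == cand) {
        cand_run <- cand_run + 1L
      } else {
        if (open) { close_event(t - 1L); open <- FALSE }
        cand <- winner[t]; cand_run <- 1L; run_start <- t
      }
      if (!open && cand_run == dwell_samples) {
        open <- TRUE; cand_open <- cand; ev_start <- run_start
      }
    } else {
      if (open) { close_event(t - 1L); open <- FALSE }
      cand <- -1L; cand_run <- 0L
    }
  }
  if (open) close_event(nt)

  if (length(events)) {
    ev <- as.data.frame(do.call(rbind, events))
    ev$pattern <- as.integer(ev$pattern)
    # merge consecutive same-pattern events
    keep <- c(TRUE, diff(ev$pattern) != 0L)
    grp <- cumsum(keep)
    ev <- data.frame(
      pattern = ev$pattern[keep],
      onset = tapply(ev$onset, grp, min),
      offset = tapply(ev$offset, grp, max),
      peak = tapply(ev$peak, grp, max),
      row.names = NULL)
  } else {
    ev <- data.frame(pattern = integer(0), onset = numeric(0),
                     offset = numeric(0), peak = numeric(0))
  }
  structure(
    list(events = ev, n_latches = max(0L, nrow(ev) - 1L),
         terminated_by = traj$terminated_by),
    class = "latching_sequence"
  )
}

#' @export
print.latching_sequence <- function(x, ...) {
  cat(sprintf("Latching sequence: %d retrieval events, %d latches (%s)\n",
              nrow(x$events), x$n_latches, x$terminated_by))
  if (nrow(x$events)) {
    cat("  items:", paste(x$events$pattern, collapse = " -> "), "\n")
  }
  invisible(x)
}

# Accept either a latching_sequence or a bare vector of item labels.
as_items <- function(seq) {
  if (inherits(seq, "latching_sequence")) return(seq$events$pattern)
  as.integer(seq)
}

#' Recall metrics on a digitized retrieval sequence
#'
#' A family of counts with different stopping rules, mirroring free-recall
#' scoring conventions. All counts exclude the event that triggers the stop.
#'
#' * `m_corr()`: distinct STM items recalled from the start until the network
#'   either repeats an already-visited item or retrieves a non-STM (long-term
#'   memory) item -- recall terminated by errors.
#' * `m_it()`: non-STM events are discarded first; distinct items until an
#'   ordered transition (consecutive pair) recurs -- the analogue of entering
#'   a loop in a deterministic search.
#' * `m_i1()`: distinct items until any item is revisited.
#' * `m_i()`: distinct items until some item occurs a third time (is repeated
#'   twice).
#' * `m_u()`: distinct STM items among the first `g + 1` events, ignoring
#'   errors and repetitions -- recall limited by a latch budget `g`.
#'
#' @param seq a [latching_sequence][digitize_trajectory] or an integer vector
#'   of item labels.
#' @param stm_list the items held in short-term memory.
#' @param g latch budget for `m_u()` (see [g_log()]).
#' @return An integer count.
#' @export
m_corr <- function(seq, stm_list) {
  items <- as_items(seq)
  visited <- integer(0)
  for (x in items) {
    if (!(x %in% stm_list) || x %in% visited) break
    visited <- c(visited, x)
  }
  length(visited)
}

#' @rdname m_corr
#' @export
m_it <- function(seq, stm_list) {
  items <- strip_errors(as_items(seq), stm_list)
  n <- length(items)
  if (n == 0L) return(0L)
  seen_items <- items[1L]
  seen_trans <- character(0)
  if (n >= 2L) for (t in 2:n) {
    key <- paste(items[t - 1L], items[t])
    if (key %in% seen_trans) {
      return(length(unique(items[seq_len(t - 1L)])))
    }
    seen_trans <- c(seen_trans, key)
  }
  length(unique(items))
}

#' @rdname m_corr
#' @export
m_i1 <- function(seq, stm_list) {
  items <- strip_errors(as_items(seq), stm_list)
  visited <- integer(0)
  for (x in items) {
    if (x %in% visited) break
    visited <- c(visited, x)
  }
  length(visited)
}

#' @rdname m_corr
#' @export
m_i <- function(seq, stm_list) {
  items <- strip_errors(as_items(seq), stm_list)
  occ <- integer(0)
  for (t in seq_along(items)) {
    x <- as.character(items[t])
    cnt <- if (is.na(occ[x])) 0L else occ[x]
    if (cnt >= 2L) return(length(unique(items[seq_len(t - 1L)])))
    occ[x] <- cnt + 1L
  }
  length(unique(items))
}

#' @rdname m_corr
#' @export
m_u <- function(seq, stm_list, g) {
  if (g < 0) stop("g must be >= 0")
  items <- as_items(seq)
  items <- items[seq_len(min(length(items), g + 1L))]
  length(unique(items[items %in% stm_list]))
}

strip_errors <- function(items, stm_list) items[items %in% stm_list]

#' Latch budgets for time-limited recall
#'
#' `g_log(L) = 4 log2(L) - 2` emulates recall periods that grow by a constant
#' amount per doubling of the list; `g_linear(L) = L`; `g_const()` is the
#' logarithmic budget frozen at its `L = 64` value, 22 latches.
#'
#' @param L list length.
#' @return A latch budget (number of allowed retrieval events).
#' @export
g_log <- function(L) 4 * log2(L) - 2

#' @rdname g_log
#' @export
g_linear <- function(L) L

#' @rdname g_log
#' @export
g_const <- function(L = 64) 4 * log2(64) - 2

#' Budget-limited recall counts (the 2L - h click rule)
#'
#' Events are consumed one at a time under a dynamic budget: a trial allows
#' `2L - h` events in total, where `h` is the running number of distinct
#' correctly recalled STM items -- every novel correct recall effectively
#' grants one event back. `m_r_budgeted()` ignores errors and repetitions and
#' counts the correct recalls accumulated when the budget runs out;
#' `m_corr_budgeted()` additionally stops at the first error (non-STM item)
#' or repetition of an already-recalled STM item. One automaton implements
#' both rules.
#'
#' @inheritParams m_corr
#' @param L list length defining the budget `2L`.
#' @return An integer count of distinct correctly recalled STM items.
#' @export
m_r_budgeted <- function(seq, stm_list, L) {
  budget_automaton(as_items(seq), stm_list, L, stop_on_violation = FALSE)
}

#' @rdname m_r_budgeted
#' @export
m_corr_budgeted <- function(seq, stm_list, L) {
  budget_automaton(as_items(seq), stm_list, L, stop_on_violation = TRUE)
}

budget_automaton <- function(items, stm_list, L, stop_on_violation) {
  if (L < 1L) stop("L must be >= 1")
  recalled <- integer(0)
  consumed <- 0L
  for (x in items) {
    if (consumed >= 2L * L - length(recalled)) break
    consumed <- consumed + 1L
    novel <- (x %in% stm_list) && !(x %in% recalled)
    if (novel) {
      recalled <- c(recalled, x)
    } else if (stop_on_violation) {
      break
    }
  }
  length(recalled)
}

#' Quality of latching: overlap margin minus residual condensation
#'
#' `d12` is the time average of the gap between the largest and second
#' largest overlaps; `Q` is the time average of the mean overlap of the
#' `L - 1` next-largest patterns (excluding the maximum). Their difference is
#' large when the sequence is cleanly digitized -- one pattern at a time, the
#' others quiescent -- and small or negative when several patterns are
#' simultaneously, partially active.
#'
#' @param traj a [potts_trajectory][run_potts()] over at least `L` patterns.
#' @param L number of STM items (the condensation average uses `L - 1`
#'   patterns); must be `>= 2`.
#' @return A list with `d12`, `Q` and `quality = d12 - Q`.
#' @export
latching_quality <- function(traj, L) {
  if (L < 2L) stop("L must be >= 2")
  m <- traj$m
  if (ncol(m) < L) stop("trajectory has fewer than L patterns")
  per_t <- t(apply(m, 1L, function(row) {
    s <- sort(row, decreasing = TRUE)
    c(d12 = s[1L] - s[2L], q = mean(s[2:L]))
  }))
  list(d12 = mean(per_t[, "d12"]), Q = mean(per_t[, "q"]),
       quality = mean(per_t[, "d12"]) - mean(per_t[, "q"]))
}

#' Transition counts and visiting frequencies over STM items
#'
#' Restricts the digitized sequences to STM items and tallies ordered
#' transitions between consecutive retained events, plus per-item visit
#' frequencies.
#'
#' @param seqs a list of sequences (or a single one).
#' @param stm_list the STM items (row/column order of the output).
#' @return A list with `counts` (transition count matrix), `probs`
#'   (row-stochastic where rows have mass), and `frequencies` (named visit
#'   counts summing to the number of retained events).
#' @export
transition_stats <- function(seqs, stm_list) {
  if (!is.list(seqs)) seqs <- list(seqs)
  k <- length(stm_list)
  counts <- matrix(0L, k, k, dimnames = list(stm_list, stm_list))
  freq <- setNames(integer(k), stm_list)
  for (s in seqs) {
    items <- strip_errors(as_items(s), stm_list)
    idx <- match(items, stm_list)
    for (x in idx) freq[x] <- freq[x] + 1L
    if (length(idx) >= 2L) {
      for (t in 2:length(idx)) {
        counts[idx[t - 1L], idx[t]] <- counts[idx[t - 1L], idx[t]] + 1L
      }
    }
  }
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  list(counts = counts, probs = probs, frequencies = freq)
}

#' Normalized mutual information across a latching sequence
#'
#' Plug-in estimate of the mutual information `I(z)` between the items at
#' positions `n` and `n + z` of the pooled sequences (pairs never straddle a
#' sequence boundary), in bits, divided by the entropy `H` of the pooled item
#' distribution. `0 log 0` is taken as 0 and no small-sample bias correction
#' is applied.
#'
#' @param seqs list of sequences or bare item vectors.
#' @param z_max largest separation to evaluate.
#' @return A data frame with columns `z`, `I`, `H`, `ratio`.
#' @export
mutual_information_profile <- function(seqs, z_max) {
  if (!is.list(seqs)) seqs <- list(seqs)
  pools <- lapply(seqs, as_items)
  all_items <- unlist(pools)
  if (length(all_items) == 0L) stop("empty sequence pool")
  marg <- table(all_items) / length(all_items)
  H <- -sum(marg * log2(marg))
  out <- data.frame(z = seq_len(z_max), I = NA_real_, H = H, ratio = NA_real_)
  for (z in seq_len(z_max)) {
    from <- integer(0); to <- integer(0)
    for (s in pools) {
      n <- length(s)
      if (n > z) {
        from <- c(from, s[seq_len(n - z)])
        to <- c(to, s[(z + 1L):n])
      }
    }
    if (length(from) == 0L) next
    joint <- table(from, to) / length(from)
    pr <- rowSums(joint); pc <- colSums(joint)
    terms <- joint * log2(joint / outer(pr, pc))
    I <- sum(terms[joint > 0])
    out$I[z] <- I
    out$ratio[z] <- if (H > 0) I / H else NA_real_
  }
  out
}

#' Distance distribution at a given separation along sequences
#'
#' Collects the pattern-space distance [pattern_distance()] between every
#' pair of items separated by `z` positions in the digitized sequences.
#'
#' @param seqs list of sequences or item vectors (pattern indices).
#' @param patterns the stored pattern set.
#' @param z relative separation (lag) along the sequence, `>= 0`.
#' @return A numeric vector of distances.
#' @export
distance_distribution <- function(seqs, patterns, z) {
  if (!is.list(seqs)) seqs <- list(seqs)
  out <- numeric(0)
  for (s in seqs) {
    items <- as_items(s)
    n <- length(items)
    if (n > z) {
      for (t in seq_len(n - z)) {
        out <- c(out, pattern_distance(patterns, items[t], items[t + z]))
      }
    }
  }
  out
}

#' Classify the operating phase of a run
#'
#' * `"SA"` (stable attractor): a single retrieval event persists until the
#'   update cap;
#' * `"noL"` (no latching): at most one event and the run ends in the null
#'   attractor;
#' * `"L"` (finite latching): two or more events, then the null attractor;
#' * `"infL"` (infinite latching): two or more events still going at the cap.
#'
#' @param seq the digitized [latching_sequence][digitize_trajectory].
#' @param traj the trajectory it came from.
#' @return One of `"noL"`, `"L"`, `"infL"`, `"SA"`.
#' @export
classify_phase <- function(seq, traj) {
  n_ev <- nrow(seq$events)
  term <- traj$terminated_by
  if (term == "event_cap") {
    stop("run was truncated by the event cap; rerun with max_events = 0 ",
         "to classify its phase")
  }
  if (term == "step_cap") {
    if (n_ev >= 2L) "infL" else if (n_ev == 1L) "SA" else "noL"
  } else {
    if (n_ev >= 2L) "L" else "noL"
  }
}

#' Score a serial-recall run against its instruction
#'
#' `serial_score()` is strict prefix matching: the first `length(instruction)`
#' retrieved items must equal the instruction in order.
#' `serial_transition_accuracy()` is the softer per-transition reading: the
#' fraction of instructed consecutive pairs realized at their position.
#'
#' @param seq digitized sequence or item vector.
#' @param instruction the instructed item sequence.
#' @return `serial_score()`: logical; `serial_transition_accuracy()`: a
#'   fraction in `[0, 1]`.
#' @export
serial_score <- function(seq, instruction) {
  if (length(instruction) == 0L) stop("instruction must be nonempty")
  items <- as_items(seq)
  L <- length(instruction)
  length(items) >= L && all(items[seq_len(L)] == as.integer(instruction))
}

#' @rdname serial_score
#' @export
serial_transition_accuracy <- function(seq, instruction) {
  items <- as_items(seq)
  L <- length(instruction)
  if (L < 2L) stop("instruction must have at least 2 items")
  ok <- vapply(seq_len(L - 1L), function(mu) {
    length(items) > mu &&
      items[mu] == instruction[mu] && items[mu + 1L] == instruction[mu + 1L]
  }, logical(1))
  mean(ok)
}

#' Serial-recall capacity as the area under the accuracy curve
#'
#' `C = sum_{L=1}^{Lmax} P(L)` with the convention `P(1) = P(2) = 1` (lengths
#' below the tested range are credited as perfect).
#'
#' @param P proportion correct for each tested length; either a named vector
#'   (names = L) or an unnamed vector assumed to start at `L = 1`. Entries for
#'   `L = 1, 2` are forced to 1 regardless of the input.
#' @param L_max largest length entering the sum.
#' @return The capacity (items).
#' @export
serial_capacity <- function(P, L_max) {
  Ls <- if (!is.null(names(P))) as.integer(names(P)) else seq_along(P)
  full <- setNames(numeric(L_max), seq_len(L_max))
  keep <- Ls <= L_max
  full[as.character(Ls[keep])] <- P[keep]
  full[1:2] <- 1
  sum(full)
}
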