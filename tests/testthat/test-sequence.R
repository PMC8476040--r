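# block overlap matrix helper: value `hi` for pattern `pat` over `len`
# samples, all other patterns at `lo`
blocks <- function(specs, p = 4, lo = 0.05) {
  do.call(rbind, lapply(specs, function(s) {
    m <- matrix(lo, s$len, p)
    if (!is.na(s$pat)) m[, s$pat] <- s$hi
    m
  }))
}

test_that("digitization turns overlap blocks into the right event strings", {
  # single retrieval then decay: one event, zero latches
  tr <- synthetic_traj(blocks(list(list(pat = 1, hi = 0.9, len = 6),
                                   list(pat = NA, hi = 0, len = 6))))
  sq <- digitize_trajectory(tr)
  expect_equal(sq$events$pattern, 1L)
  expect_equal(sq$n_latches, 0L)
  # alternation 1, 2, 1: three events, two latches
  tr <- synthetic_traj(blocks(list(list(pat = 1, hi = 0.8, len = 5),
                                   list(pat = 2, hi = 0.8, len = 5),
                                   list(pat = 1, hi = 0.8, len = 5))))
  sq <- digitize_trajectory(tr)
  expect_equal(sq$events$pattern, c(1L, 2L, 1L))
  expect_equal(sq$n_latches, 2L)
  # everything below threshold: no events
  tr <- synthetic_traj(blocks(list(list(pat = 1, hi = 0.4, len = 10))))
  expect_equal(nrow(digitize_trajectory(tr)$events), 0L)
  # same pattern interrupted by a sub-threshold gap merges into one event
  tr <- synthetic_traj(blocks(list(list(pat = 3, hi = 0.9, len = 4),
                                   list(pat = NA, hi = 0, len = 3),
                                   list(pat = 3, hi = 0.9, len = 4))))
  sq <- digitize_trajectory(tr)
  expect_equal(sq$events$pattern, 3L)
  # the dwell requirement suppresses one-sample blips
  tr <- synthetic_traj(blocks(list(list(pat = 1, hi = 0.9, len = 6),
                                   list(pat = 2, hi = 0.9, len = 1),
                                   list(pat = 1, hi = 0.9, len = 6))),
                       min_dwell_samples = 3L)
  expect_equal(digitize_trajectory(tr)$events$pattern, 1L)
  # onsets/offsets are ordered and peaks recorded
  tr <- synthetic_traj(blocks(list(list(pat = 2, hi = 0.7, len = 5),
                                   list(pat = 4, hi = 0.95, len = 5))))
  ev <- digitize_trajectory(tr)$events
  expect_true(all(ev$onset < ev$offset))
  expect_equal(ev$peak, c(0.7, 0.95))
  expect_error(digitize_trajectory(tr, m_star = 1.2), "m_star")
})

test_that("recall metrics reproduce their worked examples", {
  stm <- 1:5
  expect_equal(m_corr(c(1, 2, 3, 1, 4), stm), 3)     # stops at repeated 1
  expect_equal(m_corr(c(1, 99, 2), stm), 1)          # stops at intrusion
  expect_equal(m_corr(integer(0), stm), 0)
  expect_equal(m_it(c(1, 2, 3, 1, 2, 4), stm), 3)    # transition 1->2 repeats
  expect_equal(m_i1(c(1, 2, 3, 1, 2), stm), 3)       # item 1 revisited
  expect_equal(m_i(c(1, 2, 1, 2, 1), stm), 2)        # third 1
  expect_equal(m_it(5, stm), 1)
  expect_equal(m_i1(5, stm), 1)
  expect_equal(m_i(5, stm), 1)
  expect_equal(m_u(c(1, 2, 1, 3), stm, g = 3), 3)
  expect_equal(m_u(c(1, 2, 3), stm, g = 0), 1)
  # errors are ignored by the repetition-based metrics
  expect_equal(m_i1(c(1, 99, 2, 98, 1), stm), 2)
})

test_that("all metrics agree with direct scanners on random strings", {
  set.seed(123)
  stm <- 1:8
  for (rep in 1:400) {
    n <- sample(0:14, 1)
    items <- sample(1:10, n, replace = TRUE) # 9, 10 act as intrusions
    g <- sample(0:6, 1)
    L <- sample(1:6, 1)
    expect_equal(m_corr(items, stm), scan_m_corr(items, stm))
    expect_equal(m_it(items, stm), scan_m_it(items, stm))
    expect_equal(m_i1(items, stm), scan_m_i1(items, stm))
    expect_equal(m_i(items, stm), scan_m_i(items, stm))
    expect_equal(m_u(items, stm, g), scan_m_u(items, stm, g))
    expect_equal(m_r_budgeted(items, stm, L),
                 scan_budget(items, stm, L, FALSE))
    expect_equal(m_corr_budgeted(items, stm, L),
                 scan_budget(items, stm, L, TRUE))
  }
})

test_that("ordering invariants hold between the repetition metrics", {
  set.seed(321)
  stm <- 1:6
  for (rep in 1:200) {
    items <- sample(1:6, sample(1:20, 1), replace = TRUE)
    expect_lte(m_i1(items, stm), m_i(items, stm))
    expect_lte(m_i1(items, stm), m_it(items, stm) + 1L)
  }
})

test_that("budgeted metrics obey their boundary cases", {
  stm <- 1:4
  expect_equal(m_r_budgeted(1:4, stm, 4), 4)       # perfect run
  expect_equal(m_corr_budgeted(1:4, stm, 4), 4)
  expect_equal(m_r_budgeted(rep(9, 20), stm, 3), 0) # all errors
  expect_equal(m_corr_budgeted(rep(9, 20), stm, 3), 0)
})

test_that("latching quality separates clean from condensed retrieval", {
  # one pattern fully retrieved, the rest silent: d12 = 1, Q = 0
  m <- matrix(0, 10, 5); m[, 2] <- 1
  q <- latching_quality(synthetic_traj(m, m_star = 0.5), L = 3)
  expect_equal(q$quality, 1)
  expect_equal(q$Q, 0)
  # all overlaps equal: d12 = 0, quality = -Q
  m2 <- matrix(0.3, 10, 5)
  q2 <- latching_quality(synthetic_traj(m2), L = 4)
  expect_equal(q2$d12, 0)
  expect_equal(q2$quality, -0.3)
  # two-block trajectory against hand-computed time averages
  m3 <- rbind(matrix(c(0.9, 0.4, 0.1, 0, 0), 3, 5, byrow = TRUE),
              matrix(c(0.2, 0.7, 0.3, 0.1, 0), 2, 5, byrow = TRUE))
  q3 <- latching_quality(synthetic_traj(m3), L = 3)
  d12_hand <- (3 * (0.9 - 0.4) + 2 * (0.7 - 0.3)) / 5
  Q_hand <- (3 * (0.4 + 0.1) / 2 + 2 * (0.3 + 0.2) / 2) / 5
  expect_equal(q3$d12, d12_hand)
  expect_equal(q3$Q, Q_hand)
  expect_error(latching_quality(synthetic_traj(m3), L = 1), "L")
})

test_that("transition statistics count ordered pairs and visits", {
  st <- transition_stats(c(1, 2, 1), stm_list = 1:3)
  expect_equal(st$counts["1", "2"], 1L)
  expect_equal(st$counts["2", "1"], 1L)
  expect_equal(sum(st$counts), 2L)
  expect_equal(sum(st$frequencies), 3L)
  # rows with mass are stochastic; errors are stripped first
  st2 <- transition_stats(list(c(1, 9, 2, 3), c(2, 1)), stm_list = 1:3)
  expect_equal(sum(st2$frequencies), 5L)
  expect_equal(unname(rowSums(st2$probs)[rowSums(st2$counts) > 0]),
               c(1, 1))
})

test_that("mutual information matches the histogram oracle and its bounds", {
  # deterministic cycle: I(z)/H = 1 at every lag
  cyc <- rep(1:4, 25)
  mi <- mutual_information_profile(cyc, z_max = 5)
  # up to the O(z/n) granularity of the plug-in pair counts
  expect_equal(mi$ratio, rep(1, 5), tolerance = 2e-3)
  # i.i.d. uniform: ratio near zero (within plug-in bias ~ (K-1)^2/(2 n ln 2 H))
  set.seed(11)
  iid <- sample(1:6, 4000, replace = TRUE)
  mi2 <- mutual_information_profile(iid, z_max = 3)
  bias_bound <- 3 * (6 - 1)^2 / (2 * 4000 * log(2)) / mi2$H[1]
  expect_true(all(mi2$ratio < bias_bound))
  expect_true(all(mi2$ratio >= 0))
  # plug-in equals a brute-force joint-histogram computation on a fixture
  set.seed(5)
  fix <- list(sample(1:5, 60, replace = TRUE), sample(1:5, 40, replace = TRUE))
  mi3 <- mutual_information_profile(fix, z_max = 4)
  for (z in 1:4) expect_equal(mi3$I[z], oracle_mi(fix, z), tolerance = 1e-12)
  expect_error(mutual_information_profile(list(), 3), "empty")
})

test_that("distance distributions along sequences match direct enumeration", {
  pats <- generate_patterns(6, 50, 4, 0.4, seed = 31)
  s <- c(1, 4, 2, 6, 3)
  # z = 0: each value is a self-distance near zero
  d0 <- distance_distribution(s, pats, z = 0)
  self <- vapply(s, function(mu) pattern_distance(pats, mu, mu), numeric(1))
  expect_equal(d0, self)
  # direct enumeration at z = 2
  d2 <- distance_distribution(s, pats, z = 2)
  want <- c(pattern_distance(pats, 1, 2), pattern_distance(pats, 4, 6),
            pattern_distance(pats, 2, 3))
  expect_equal(d2, want)
})

test_that("phase classification follows event count and termination", {
  persist <- synthetic_traj(blocks(list(list(pat = 1, hi = 0.9, len = 20))),
                            terminated_by = "step_cap")
  expect_equal(classify_phase(digitize_trajectory(persist), persist), "SA")
  decay <- synthetic_traj(blocks(list(list(pat = 1, hi = 0.9, len = 5),
                                      list(pat = NA, hi = 0, len = 10))),
                          terminated_by = "null_attractor")
  expect_equal(classify_phase(digitize_trajectory(decay), decay), "noL")
  five <- synthetic_traj(blocks(lapply(1:5, function(k)
    list(pat = ((k - 1) %% 3) + 1, hi = 0.8, len = 4))),
    terminated_by = "null_attractor")
  expect_equal(classify_phase(digitize_trajectory(five), five), "L")
  forever <- synthetic_traj(blocks(list(list(pat = 1, hi = 0.8, len = 5),
                                        list(pat = 2, hi = 0.8, len = 5))),
                            terminated_by = "step_cap")
  expect_equal(classify_phase(digitize_trajectory(forever), forever), "infL")
})

test_that("serial scoring uses prefix matching and the AUC capacity sum", {
  expect_true(serial_score(c(2, 4, 3, 1), c(2, 4, 3)))
  expect_false(serial_score(c(2, 3, 4), c(2, 4, 3)))
  expect_false(serial_score(c(2, 4), c(2, 4, 3))) # too short
  expect_equal(serial_transition_accuracy(c(2, 4, 1, 5), c(2, 4, 3, 5)), 1 / 3)
  expect_equal(serial_capacity(rep(1, 10), L_max = 10), 10)
  expect_equal(serial_capacity(c(1, 1, 0.8, 0.4, rep(0, 6)), L_max = 10), 3.2)
  # named form starting at L = 3
  expect_equal(serial_capacity(setNames(c(0.8, 0.4), c(3, 4)), L_max = 10),
               3.2)
})
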