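test_that("softmax activations are exactly normalized in every regime", {
  set.seed(1)
  r <- matrix(rnorm(40, sd = 5), 10, 4)
  thA <- runif(10); thB <- runif(10)
  # beta -> 0: uniform over S + 1 states
  s0 <- update_activations(r, thA, thB, beta = 1e-12, U = 0.3)
  expect_equal(s0, matrix(1 / 5, 10, 5), tolerance = 1e-9)
  # zero potentials and thresholds: uniform at any beta
  su <- update_activations(matrix(0, 3, 4), rep(0, 3), rep(0, 3), 7, 0)
  expect_equal(su, matrix(1 / 5, 3, 5))
  # large beta: argmax state wins
  r1 <- matrix(0, 2, 3); r1[, 1] <- 2
  sb <- update_activations(r1, rep(0, 2), rep(0, 2), beta = 300, U = 0)
  expect_gt(sb[1, 2], 1 - 1e-9)
  # extreme arguments do not break normalization (max-subtraction)
  sx <- update_activations(matrix(c(1e4, -1e4, 0, 1), 2, 2), c(0, 1e4),
                           c(0, 0), beta = 50, U = 0)
  expect_equal(rowSums(sx), c(1, 1))
  expect_true(all(sx >= 0 & sx <= 1))
})

test_that("normalization holds at every step of an integrated run", {
  net <- tiny_net(seed = 5)
  cfg <- sim_config(max_updates = 300, sample_every = 5)
  st <- initial_state(12, 3, cfg)
  Jd <- as_dense_weights(net$W)
  cf <- cue_field(net$pats, 1)
  for (step in 1:120) {
    st <- potts_step(st, Jd, cfg, cue_field = if (step <= 80) cf else NULL)
    expect_lt(max(abs(rowSums(st$sigma) - 1)), 1e-12)
    expect_true(all(st$sigma > 0 & st$sigma < 1))
  }
})

test_that("the field matches its definition on fixtures", {
  # all-zero couplings and state-uniform activations: the feedback term
  # vanishes because sigma_ik equals its own mean
  sig <- cbind(0.4, matrix(0.2, 5, 3))
  h0 <- compute_field(sig, array(0, c(5, 5, 3, 3)), w = 2)
  expect_equal(h0, matrix(0, 5, 3))
  # lambda = 0 heteroassociation leaves the field unchanged
  net <- tiny_net(seed = 9, N = 6L, cm = 3L)
  Jd <- as_dense_weights(net$W)
  set.seed(2)
  sig <- update_activations(matrix(rnorm(18), 6, 3), runif(6), runif(6),
                            5, 0.1)
  th <- matrix(runif(18, 0, 0.3), 6, 3)
  h_free <- compute_field(sig, Jd, w = 1.1)
  h_l0 <- compute_field(sig, Jd, w = 1.1, theta = th,
                        het_dense = 0 * Jd)
  expect_equal(h_free, h_l0)
  # explicit-loop cross-check of one entry, heteroassociative term included
  hd <- as_dense_het(hetero_weights(net$pats, c(1, 2), 0.07))
  h <- compute_field(sig, Jd, w = 1.1, theta = th, het_dense = hd)
  i <- 3; k <- 2
  acc <- 1.1 * (sig[i, k + 1] - mean(sig[i, -1]))
  for (j in setdiff(1:6, i)) for (l in 1:3) {
    acc <- acc + Jd[i, j, k, l] * sig[j, l + 1] + hd[i, j, k, l] * th[j, l]
  }
  expect_equal(h[i, k], acc)
})

test_that("threshold dynamics settle on the shifted fixed point (Model 2)", {
  # with beta ~ 0 the activations stay pinned at the uniform value, so the
  # adaptive threshold ODE has the closed-form equilibrium sigma - delta_theta
  # on masked states and sigma elsewhere, while r settles at h - theta
  net <- tiny_net(seed = 13, N = 6L, cm = 3L)
  cfg <- sim_config(beta = 1e-9, tauB = 5, max_updates = 1)
  mask <- matrix(0L, 6, 3); mask[1, 2] <- 1L; mask[4, 1] <- 1L
  Jd <- as_dense_weights(net$W)
  st <- initial_state(6, 3, cfg)
  for (step in 1:6000) {
    st <- potts_step(st, Jd, cfg, theta_mask = mask, delta_theta = 0.15)
  }
  sig_act <- st$sigma[, -1]
  expect_equal(st$theta, sig_act - 0.15 * mask, tolerance = 1e-6,
               ignore_attr = TRUE)
  h <- compute_field(st$sigma, Jd, cfg$w)
  expect_equal(st$r, h - st$theta, tolerance = 1e-5)
})

test_that("compiled and reference integrators agree to machine precision", {
  net <- tiny_net(seed = 7)
  cfg <- sim_config(max_updates = 400, sample_every = 5)
  b <- boost_config("M2", delta = 0.2, stm_list = c(1L, 2L))
  het <- hetero_weights(net$pats, c(1L, 2L, 3L), lambda = 0.02)
  t_cpp <- run_potts(net$pats, net$W, cfg, boost = b, het = het, cue = 1,
                     engine = "cpp")
  t_r <- run_potts(net$pats, net$W, cfg, boost = b, het = het, cue = 1,
                   engine = "r")
  expect_equal(t_cpp$m, t_r$m, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(t_cpp$activity, t_r$activity, tolerance = 1e-12)
  expect_identical(t_cpp$terminated_by, t_r$terminated_by)
  # Model 1 and 3a paths too
  b1 <- boost_config("M1", delta = 0.4, stm_list = 2L)
  expect_equal(run_potts(net$pats, net$W, cfg, boost = b1, cue = 2)$m,
               run_potts(net$pats, net$W, cfg, boost = b1, cue = 2,
                         engine = "r")$m,
               tolerance = 1e-12, ignore_attr = TRUE)
  b3 <- boost_config("M3a", delta = 0.3, stm_list = c(1L, 3L))
  expect_equal(run_potts(net$pats, net$W, cfg, boost = b3, cue = 1)$m,
               run_potts(net$pats, net$W, cfg, boost = b3, cue = 1,
                         engine = "r")$m,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identical seeds give bitwise-identical runs", {
  pre <- list(p = 40L, N = 120L, S = 5L, a = 0.3, c_m = 20L,
              config = sim_config(max_updates = 1500))
  net1 <- pottslatch:::setup_network(pre, 99L)
  net2 <- pottslatch:::setup_network(pre, 99L)
  expect_identical(net1$patterns$xi, net2$patterns$xi)
  expect_identical(net1$weights$J, net2$weights$J)
  t1 <- run_potts(net1$patterns, net1$weights, pre$config, cue = 3)
  t2 <- run_potts(net2$patterns, net2$weights, pre$config, cue = 3)
  expect_identical(t1$m, t2$m)
  expect_identical(t1$terminated_by, t2$terminated_by)
})

test_that("cueing works as an additive transient field", {
  net <- tiny_net(seed = 3)
  cfg <- sim_config(max_updates = 300)
  # zero-strength cue: identical to an uncued run
  cfg0 <- cfg; cfg0$cue_strength <- 0
  t_a <- run_potts(net$pats, net$W, cfg0, cue = 1)
  t_b <- run_potts(net$pats, net$W, cfg0, cue = 2)
  expect_identical(t_a$m, t_b$m)
  # a strong cue pins the cued pattern as the top overlap at cue offset
  pre <- list(p = 20L, N = 200L, S = 5L, a = 0.25, c_m = 30L,
              config = sim_config(w = 0.5, max_updates = 200,
                                  cue_strength = 2))
  net2 <- pottslatch:::setup_network(pre, 17L)
  tr <- run_potts(net2$patterns, net2$weights, pre$config, cue = 7)
  off <- which.min(abs(tr$times - pre$config$cue_duration))
  expect_equal(unname(which.max(tr$m[off, ])), 7L)
  expect_gt(tr$m[off, 7], 0.8)
  expect_error(run_potts(net2$patterns, net2$weights, pre$config, cue = 50),
               "cue")
})

test_that("dynamics are invariant under pattern relabeling", {
  net <- tiny_net(seed = 23, N = 30L, p = 6L, S = 3L, a = 0.4, cm = 8L)
  cfg <- sim_config(max_updates = 600)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  pats_perm <- pottslatch:::new_potts_patterns(
    net$pats$xi[perm, , drop = FALSE], S = 3L, a = 0.4)
  W_perm <- build_weights(pats_perm, net$conn)
  t_orig <- run_potts(net$pats, net$W, cfg, cue = 4)
  t_perm <- run_potts(pats_perm, W_perm, cfg, cue = 1) # pattern 4 is now 1
  expect_equal(t_perm$m, t_orig$m[, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("halving the step size changes overlaps at first order", {
  net <- tiny_net(seed = 19)
  horizon <- 0.4
  run_dt <- function(dt) {
    cfg <- sim_config(dt = dt, sample_every = as.integer(round(0.05 / dt)),
                      max_updates = as.integer(round(horizon / dt)))
    run_potts(net$pats, net$W, cfg, cue = 1)$m
  }
  m1 <- run_dt(0.00125)
  m2 <- run_dt(0.000625)
  mref <- run_dt(0.000125)
  ns <- min(nrow(m1), nrow(m2), nrow(mref))
  e1 <- max(abs(m1[1:ns, ] - mref[1:ns, ]))
  e2 <- max(abs(m2[1:ns, ] - mref[1:ns, ]))
  expect_lt(e2, e1) # error shrinks with dt
  expect_gt(e1 / e2, 1.5) # consistent with first-order convergence
})

test_that("a diverging state aborts with a diagnostic", {
  net <- tiny_net(seed = 29)
  cfg <- sim_config(max_updates = 100, cue_strength = 1e308)
  expect_error(run_potts(net$pats, net$W, cfg, cue = 1), "non-finite")
})
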