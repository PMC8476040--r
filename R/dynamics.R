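#' Simulation configuration for the Potts dynamics
#'
#' Collects the time constants, gain parameters and numerical settings of the
#' firing-rate equations. The defaults are the regime in which the network
#' expresses latching with a balanced mixture of fast and slow inhibition:
#' potential time constant `tau1 = 0.01` s, adaptation `tau2 = 0.2` s, fast
#' inhibition `tauA = 0.005` s, slow inhibition `tauB = 100` s, balance
#' `gammaA = 0.5`, inverse temperature `beta = 11`, common threshold
#' `U = 0.1`, local feedback `w = 1.1`. Integration is synchronous explicit
#' Euler with `dt = tauA / 4`; one "update" is one full-network step, capped
#' at `max_updates = 1e5`.
#'
#' @param tau1,tau2,tauA,tauB time constants (s) of potentials, adaptive
#'   thresholds, fast and slow inhibition; the model assumes
#'   `tauA < tau1 << tau2 << tauB` (a warning is raised otherwise).
#' @param gammaA share of fast inhibition, in `[0, 1]`.
#' @param beta inverse temperature of the softmax.
#' @param U common activation threshold.
#' @param w local feedback (attractor depth within a patch); a scalar here,
#'   possibly promoted to a per-unit vector by the Model 1 boost.
#' @param dt Euler step (s); must be `< tauA`.
#' @param max_updates cap on the number of full-network updates.
#' @param cue_strength amplitude of the additive cueing field.
#' @param cue_duration cue window length (s); default `10 * tau1`.
#' @param sample_every record overlaps every this many updates.
#' @param m_star digitization threshold on the winning overlap.
#' @param min_dwell minimum time (s) above threshold for a retrieval event;
#'   default `tau2 / 4`.
#' @param m_null,act_null null-attractor thresholds: the run stops once every
#'   overlap stays below `m_null` and the mean active fraction below
#'   `act_null` for a full `tau2` window. `act_null = NULL` defaults to 1.5
#'   times the quiescent fixed-point activity (see [quiescent_activity()]);
#'   the softmax background keeps a nonzero residual activity, so the
#'   threshold must sit between that residual and the activity of genuine
#'   retrieval episodes.
#' @return A `potts_config` list.
#' @export
sim_config <- function(tau1 = 0.01, tau2 = 0.2, tauA = 0.005, tauB = 100,
                       gammaA = 0.5, beta = 11, U = 0.1, w = 1.1,
                       dt = tauA / 4, max_updates = 1e5,
                       cue_strength = 1.0, cue_duration = 10 * tau1,
                       sample_every = 10L, m_star = 0.5,
                       min_dwell = tau2 / 4,
                       m_null = 0.1, act_null = NULL) {
  if (gammaA < 0 || gammaA > 1) stop("gammaA must lie in [0, 1]")
  if (dt >= tauA) stop("dt must be smaller than tauA")
  if (!(tauA < tau1 && tau1 < tau2 && tau2 < tauB)) {
    warning("time constants violate tauA < tau1 << tau2 << tauB")
  }
  structure(
    list(tau1 = tau1, tau2 = tau2, tauA = tauA, tauB = tauB,
         gammaA = gammaA, beta = beta, U = U, w = w, dt = dt,
         max_updates = as.integer(max_updates),
         cue_strength = cue_strength, cue_duration = cue_duration,
         sample_every = as.integer(sample_every), m_star = m_star,
         min_dwell = min_dwell, m_null = m_null, act_null = act_null),
    class = "potts_config"
  )
}

#' Input field of every unit and active state
#'
#' Reference (pure-R) implementation of the field
#' `h_ik = sum_{j != i, l} J_ijkl sigma_jl + w_i (sigma_ik - mean_l sigma_il)`
#' plus, when heteroassociative couplings are present, the threshold-driven
#' term `sum_{j != i, l} Jhet_ijkl theta_jl`. Used for small fixtures and as
#' the oracle against the compiled engine.
#'
#' @param sigma `N x (S+1)` activation matrix (background state in column 1).
#' @param J_dense dense `N x N x S x S` coupling array (see
#'   [as_dense_weights()]).
#' @param w scalar or per-unit local feedback.
#' @param theta `N x S` adaptive thresholds (needed only with `het_dense`).
#' @param het_dense optional dense heteroassociative array of the same shape.
#' @return An `N x S` field matrix.
#' @export
compute_field <- function(sigma, J_dense, w, theta = NULL, het_dense = NULL) {
  N <- dim(J_dense)[1]; S <- dim(J_dense)[3]
  sig_act <- sigma[, -1, drop = FALSE]
  w <- rep_len(w, N)
  h <- matrix(0, N, S)
  for (i in seq_len(N)) {
    for (k in seq_len(S)) {
      acc <- 0
      for (j in seq_len(N)) {
        if (j == i) next
        acc <- acc + sum(J_dense[i, j, k, ] * sig_act[j, ])
        if (!is.null(het_dense)) {
          acc <- acc + sum(het_dense[i, j, k, ] * theta[j, ])
        }
      }
      h[i, k] <- acc + w[i] * (sig_act[i, k] - mean(sig_act[i, ]))
    }
  }
  h
}

#' Softmax activation update
#'
#' `sigma_ik = exp(beta r_ik) / Z_i` for active states and
#' `sigma_i0 = exp(beta (U + thetaA_i + thetaB_i)) / Z_i` for the background,
#' computed with max-subtraction so the normalization is exact for any `beta`.
#'
#' @param r `N x S` potentials.
#' @param thetaA,thetaB length-`N` inhibitory thresholds.
#' @param beta inverse temperature; @param U common threshold.
#' @return An `N x (S+1)` activation matrix with unit row sums (background
#'   first).
#' @export
update_activations <- function(r, thetaA, thetaB, beta, U) {
  N <- nrow(r)
  e <- cbind(beta * (U + thetaA + thetaB), beta * r)
  e <- e - apply(e, 1L, max)
  e <- exp(e)
  e / rowSums(e)
}

#' One Euler step of the Potts equations (reference implementation)
#'
#' Advances potentials, adaptive thresholds and the two inhibitory thresholds
#' by one explicit-Euler step, then refreshes the activations by the softmax
#' rule. The Model 2 boost enters as a constant subtraction `delta_theta` in
#' the threshold equation on the masked (unit, state) pairs.
#'
#' @param state list with `sigma`, `r`, `theta`, `thetaA`, `thetaB`, `t`.
#' @param J_dense dense couplings; @param config a [sim_config()].
#' @param w per-unit or scalar local feedback (defaults to `config$w`).
#' @param theta_mask optional `N x S` 0/1 matrix; @param delta_theta Model 2
#'   boost magnitude.
#' @param het_dense,lambda optional dense heteroassociative couplings and
#'   their strength.
#' @param cue_field optional `N x S` additive external field.
#' @return The advanced state list.
#' @export
potts_step <- function(state, J_dense, config, w = config$w,
                       theta_mask = NULL, delta_theta = 0,
                       het_dense = NULL, lambda = 0,
                       cue_field = NULL) {
  dt <- config$dt
  hd <- if (!is.null(het_dense) && lambda > 0) lambda * het_dense else NULL
  h <- compute_field(state$sigma, J_dense, w, theta = state$theta,
                     het_dense = hd)
  if (!is.null(cue_field)) h <- h + cue_field
  sig_act <- state$sigma[, -1, drop = FALSE]
  act <- rowSums(sig_act)
  drive <- sig_act - state$theta
  if (!is.null(theta_mask) && delta_theta != 0) {
    drive <- drive - delta_theta * theta_mask
  }
  if (any(!is.finite(h))) stop("non-finite field in potts_step")
  r <- state$r + dt / config$tau1 * (h - state$theta - state$r)
  theta <- state$theta + dt / config$tau2 * drive
  thetaA <- state$thetaA + dt / config$tauA * (config$gammaA * act - state$thetaA)
  thetaB <- state$thetaB + dt / config$tauB * ((1 - config$gammaA) * act - state$thetaB)
  sigma <- update_activations(r, thetaA, thetaB, config$beta, config$U)
  list(sigma = sigma, r = r, theta = theta, thetaA = thetaA,
       thetaB = thetaB, t = state$t + dt)
}

#' Quiescent (null-attractor) activity of the softmax unit
#'
#' In the globally quiescent state the adaptive thresholds equal the
#' activations and the inhibitory thresholds sum to the mean activity, so the
#' per-unit active fraction solves the self-consistency equation
#' `act = S exp(-beta act / S) / (S exp(-beta act / S) + exp(beta (U + act)))`.
#' Because the background state never absorbs all probability mass, this
#' residual activity is well above zero (about 0.19 at `beta = 11`,
#' `U = 0.1`, `S = 7`); null-attractor detection therefore uses a threshold
#' *relative* to it rather than an absolute near-zero cutoff.
#'
#' @param beta inverse temperature; @param U common threshold; @param S
#'   number of active states.
#' @return The fixed-point mean active fraction.
#' @export
quiescent_activity <- function(beta, U, S) {
  g <- function(act) {
    e <- S * exp(-beta * act / S)
    e / (e + exp(beta * (U + act))) - act
  }
  stats::uniroot(g, c(1e-9, 0.999))$root
}

#' Initial network state
#'
#' All potentials and thresholds start at zero and the activations at their
#' softmax equilibrium for that condition (a background-biased resting state).
#'
#' @param N,S network dimensions; @param config a [sim_config()].
#' @return A state list as consumed by [potts_step()].
#' @export
initial_state <- function(N, S, config) {
  r <- matrix(0, N, S)
  thetaA <- numeric(N); thetaB <- numeric(N)
  list(sigma = update_activations(r, thetaA, thetaB, config$beta, config$U),
       r = r, theta = matrix(0, N, S), thetaA = thetaA, thetaB = thetaB,
       t = 0)
}

#' Aligned cueing field for a stored pattern
#'
#' The cue is a transient additive field `strength * (delta_{xi_i^mu, k} -
#' a/S)` applied for the configured duration, after which it is removed and
#' the dynamics run free.
#'
#' @param patterns a [potts_patterns][generate_patterns] object.
#' @param mu pattern index to cue; @param strength cue amplitude.
#' @return An `N x S` field matrix.
#' @export
cue_field <- function(patterns, mu, strength = 1.0) {
  if (mu < 1L || mu > patterns$p) stop("invalid cue pattern index")
  S <- patterns$S
  xi <- patterns$xi[mu, ]
  f <- matrix(-strength * patterns$a / S, patterns$N, S)
  act <- which(xi > 0L)
  f[cbind(act, xi[act])] <- f[cbind(act, xi[act])] + strength
  f
}

#' Overlap of a network state with every stored pattern
#'
#' `m^mu = 1 / (N a (1 - a/S)) * sum_{i,k} (delta_{xi_i^mu, k} - a/S)
#' sigma_ik`, normalized to 1 at perfect retrieval.
#'
#' @param sigma `N x (S+1)` activations; @param patterns the pattern set.
#' @return A numeric vector of length `p`.
#' @export
overlaps <- function(sigma, patterns) {
  S <- patterns$S; a <- patterns$a; N <- patterns$N
  sig_act <- sigma[, -1, drop = FALSE]
  act_i <- 1 - sigma[, 1L]
  vapply(seq_len(patterns$p), function(mu) {
    xi <- patterns$xi[mu, ]
    on <- xi > 0L
    aligned <- sum(sig_act[cbind(which(on), xi[on])])
    (aligned - (a / S) * sum(act_i)) / (N * a * (1 - a / S))
  }, numeric(1))
}

#' Integrate the Potts network and record an overlap trajectory
#'
#' Initializes the network at rest, cues it with one stored pattern, removes
#' the cue, and integrates until the network falls into the globally
#' quiescent null attractor (all overlaps below `m_null` and mean activity
#' below `act_null` for a full `tau2` window), the update cap is reached, or
#' -- optionally -- a requested number of digitized retrieval events has been
#' observed (`max_events`, an early-stopping convenience for recall scoring).
#'
#' @param patterns a [potts_patterns][generate_patterns] object.
#' @param weights a [potts_weights][build_weights] object (boosts of Models
#'   3a/3b should already be applied, or supply `boost` below).
#' @param config a [sim_config()].
#' @param boost optional [boost_config()]; Models 1/2/3a/3b are applied here.
#' @param het optional [hetero_weights()] couplings for serial recall.
#' @param cue pattern index to cue (default: first STM item if a boost is
#'   given, else pattern 1).
#' @param max_events stop after this many digitized events (0 = no limit).
#' @param stop_rule `"none"`, or `"violation"` to stop as soon as a digitized
#'   event repeats an already-retrieved item or falls outside the boost's STM
#'   list -- the stopping condition of error-limited recall scoring; the
#'   offending event is recorded before the run ends.
#' @param engine `"cpp"` for the compiled integrator, `"r"` for the
#'   reference pure-R loop (tiny networks only).
#' @return A `potts_trajectory`: `times`, `m` (samples x p overlap matrix),
#'   `activity`, `terminated_by` (`"null_attractor"`, `"step_cap"` or
#'   `"event_cap"`), the applied config and boost.
#' @export
run_potts <- function(patterns, weights, config = sim_config(), boost = NULL,
                      het = NULL, cue = NULL, max_events = 0L,
                      stop_rule = c("none", "violation"),
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stop_rule <- match.arg(stop_rule)
  stopifnot(inherits(patterns, "potts_patterns"),
            inherits(weights, "potts_weights"))
  N <- patterns$N; S <- patterns$S; a <- patterns$a
  if (is.null(boost)) boost <- boost_config("none")
  if (is.null(cue)) {
    cue <- if (length(boost$stm_list) > 0L) boost$stm_list[1L] else 1L
  }
  if (cue < 1L || cue > patterns$p) stop("invalid cue pattern index")

  wvec <- rep(config$w, N)
  mask <- matrix(0L, 0L, 0L)
  delta_theta <- 0
  W <- weights
  if (boost$model == "M1") {
    wvec <- apply_model1(config$w, boost$delta, patterns, boost$stm_list)
  } else if (boost$model == "M2") {
    mask <- model2_theta_mask(patterns, boost$stm_list)
    delta_theta <- boost$delta
  } else if (boost$model == "M3a") {
    W <- apply_model3a(weights, boost$delta, patterns, boost$stm_list)
  } else if (boost$model == "M3b") {
    W <- apply_model3b(weights, boost$delta, patterns, boost$stm_list)
  }

  act_null <- if (is.null(config$act_null)) {
    1.5 * quiescent_activity(config$beta, config$U, S)
  } else config$act_null
  cue_steps <- max(1L, as.integer(round(config$cue_duration / config$dt)))
  null_window <- max(1L, as.integer(round(
    config$tau2 / (config$dt * config$sample_every))))
  min_dwell_samples <- max(1L, as.integer(round(
    config$min_dwell / (config$dt * config$sample_every))))

  if (engine == "cpp") {
    res <- run_potts_cpp(
      patterns$xi, W$jidx, W$J, S, a, wvec, mask, delta_theta,
      if (is.null(het)) list() else het$index,
      if (is.null(het)) 0 else het$lambda,
      config$beta, config$U, config$tau1, config$tau2, config$tauA,
      config$tauB, config$gammaA, config$dt,
      config$max_updates, config$sample_every,
      cue, config$cue_strength, cue_steps,
      config$m_null, act_null, null_window,
      config$m_star, min_dwell_samples, as.integer(max_events),
      as.integer(boost$stm_list), stop_rule == "violation")
  } else {
    res <- run_potts_r(patterns, W, config, wvec, mask, delta_theta, het,
                       cue, cue_steps, act_null, null_window,
                       min_dwell_samples, as.integer(max_events),
                       boost$stm_list, stop_rule == "violation")
  }
  structure(
    list(times = res$times, m = res$m, activity = res$activity,
         terminated_by = res$terminated_by, steps = res$steps,
         cue = cue, config = config, boost = boost,
         min_dwell_samples = min_dwell_samples),
    class = "potts_trajectory"
  )
}

#' @export
print.potts_trajectory <- function(x, ...) {
  cat(sprintf(
    "Potts overlap trajectory: %d samples over %.2f s, %d patterns\n",
    length(x$times), if (length(x$times)) max(x$times) else 0, ncol(x$m)))
  cat(sprintf("  cue = pattern %d, terminated by %s\n", x$cue,
              x$terminated_by))
  invisible(x)
}

# Pure-R twin of the compiled integrator, for oracle tests on tiny fixtures.
run_potts_r <- function(patterns, weights, config, wvec, mask, delta_theta,
                        het, cue, cue_steps, act_null, null_window,
                        min_dwell_samples, max_events, stm_list = integer(0),
                        stop_on_violation = FALSE) {
  N <- patterns$N; S <- patterns$S
  Jd <- as_dense_weights(weights)
  hd <- if (!is.null(het)) as_dense_het(het) else NULL
  lam <- if (!is.null(het)) 1 else 0 # as_dense_het already carries lambda
  cf <- cue_field(patterns, cue, config$cue_strength)
  st <- initial_state(N, S, config)
  times <- numeric(0); mm <- NULL; act <- numeric(0)
  term <- "step_cap"; null_run <- 0L
  cand <- -1L; cand_run <- 0L; last_event <- -1L; n_events <- 0L
  seen <- logical(patterns$p)
  msk <- if (nrow(mask)) mask else NULL
  step <- 0L
  while (step < config$max_updates) {
    step <- step + 1L
    st <- potts_step(st, Jd, config, w = wvec,
                     theta_mask = msk, delta_theta = delta_theta,
                     het_dense = hd, lambda = lam,
                     cue_field = if (step <= cue_steps) cf else NULL)
    if (step %% config$sample_every == 0L) {
      m <- overlaps(st$sigma, patterns)
      mean_act <- mean(1 - st$sigma[, 1L])
      times <- c(times, step * config$dt)
      mm <- rbind(mm, m)
      act <- c(act, mean_act)
      if (max(m) < config$m_null && mean_act < act_null) {
        null_run <- null_run + 1L
        if (null_run >= null_window) { term <- "null_attractor"; break }
      } else null_run <- 0L
      if (max_events > 0L || stop_on_violation) {
        if (max(m) > config$m_star) {
          am <- which.max(m)
          if (am == cand) cand_run <- cand_run + 1L
          else { cand <- am; cand_run <- 1L }
          if (cand_run == min_dwell_samples && cand != last_event) {
            n_events <- n_events + 1L
            last_event <- cand
            if (max_events > 0L && n_events > max_events) {
              term <- "event_cap"; break
            }
            if (stop_on_violation &&
                (!(cand %in% stm_list) || seen[cand])) {
              term <- "event_cap"; break
            }
            seen[cand] <- TRUE
          }
        } else { cand <- -1L; cand_run <- 0L }
      }
    }
  }
  rownames(mm) <- NULL
  list(times = times, m = mm, activity = act, terminated_by = term,
       steps = step, n_events_engine = n_events)
}
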