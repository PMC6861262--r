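#' Configuration of the headless swarm simulator
#'
#' The simulator replaces the real-time networked answer board with a
#' deterministic (given the seed) agent model: a shared puck starts at
#' the origin of the unit-circle answer board; every tick each agent
#' pulls it with a unit-magnitude force toward the target of the bin it
#' currently intends, and the puck moves with velocity equal to the
#' speed constant times the mean agent force. A session ends when the
#' puck has stayed within the convergence radius of one target for the
#' dwell count, or at the 60 s timeout, in which case the bin with the
#' largest accumulated impulse wins (ties go to the lower-probability
#' bin, favouring the negative diagnosis).
#'
#' Agent policies: `"stubborn"` agents always pull toward the bin
#' containing their own belief; `"conciliatory"` agents (default) sample
#' their intended bin each tick with probability proportional to
#' `exp(-|midpoint - belief| / tau)`, so they compromise toward adjacent
#' bins and split panels can still converge.
#'
#' @param tick tick duration in seconds.
#' @param max_duration session timeout in seconds.
#' @param speed puck speed constant (board units per second at unit mean
#'   force).
#' @param conv_radius convergence radius around a target (board units).
#' @param dwell_ticks consecutive in-radius ticks required to converge.
#' @param policy `"conciliatory"` or `"stubborn"`.
#' @param tau softmax temperature of the conciliatory policy
#'   (probability units).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(tick = 0.1, max_duration = 60, speed = 0.8,
                         conv_radius = 0.45, dwell_ticks = 5,
                         policy = c("conciliatory", "stubborn"),
                         tau = 0.08, seed = NULL) {
  policy <- match.arg(policy)
  stopifnot(tick > 0, max_duration >= tick, speed > 0, conv_radius > 0,
            dwell_ticks >= 1, tau > 0)
  structure(list(tick = tick, max_duration = max_duration, speed = speed,
                 conv_radius = conv_radius, dwell_ticks = dwell_ticks,
                 policy = policy, tau = tau, seed = seed),
            class = "swarm_config")
}

# Per-agent categorical distribution over intended bins under a policy.
# Rows: agents; columns: bins. Stubborn agents are a point mass on the
# bin containing their belief.
agent_bin_probs <- function(beliefs, scheme, config) {
  k <- nrow(scheme)
  own <- prob_bin(beliefs, scheme)
  if (config$policy == "stubborn") {
    m <- matrix(0, length(beliefs), k)
    m[cbind(seq_along(beliefs), own)] <- 1
    return(m)
  }
  d <- abs(outer(beliefs, scheme$midpoint, "-"))
  w <- exp(-d / config$tau)
  w / rowSums(w)
}

#' Simulate one swarm session
#'
#' @param beliefs numeric vector, one probability per agent (>= 2
#'   agents).
#' @param scheme a [bin_scheme()].
#' @param config a [swarm_config()].
#' @param keep_forces record per-tick per-agent force vectors in the
#'   trace (heavier; off by default).
#' @return list of class `swarm_session` with elements
#'   \describe{
#'     \item{impulse}{accumulated impulse per bin, force x time, all
#'       >= 0 with positive total.}
#'     \item{chosen_bin}{index of the winning bin.}
#'     \item{converged}{logical; `FALSE` means timeout.}
#'     \item{elapsed_ticks}{session length in ticks.}
#'     \item{trace}{puck path (ticks x 2), per-tick intended bins, and
#'       optionally forces.}
#'   }
#' @export
simulate_swarm <- function(beliefs, scheme = bin_scheme(),
                           config = swarm_config(), keep_forces = FALSE) {
  n <- length(beliefs)
  if (n < 2L) stop("a swarm needs at least 2 agents", call. = FALSE)
  if (any(beliefs < 0 | beliefs > 1))
    stop("beliefs outside [0,1]", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  k <- nrow(scheme)
  targets <- bin_targets(scheme)
  max_ticks <- as.integer(ceiling(config$max_duration / config$tick))
  pmat <- agent_bin_probs(beliefs, scheme, config)

  # Intended bins are independent of puck state, so pre-sample the whole
  # session in one pass per agent.
  intents <- matrix(0L, max_ticks, n)
  for (a in seq_len(n)) {
    if (config$policy == "stubborn") {
      intents[, a] <- which.max(pmat[a, ])
    } else {
      intents[, a] <- sample.int(k, max_ticks, replace = TRUE,
                                 prob = pmat[a, ])
    }
  }

  puck <- c(0, 0)
  path <- matrix(NA_real_, max_ticks, 2L)
  forces <- if (keep_forces) array(NA_real_, c(max_ticks, n, 2L)) else NULL
  step <- config$speed * config$tick
  dwell <- 0L
  dwell_target <- 0L
  converged <- FALSE
  chosen <- NA_integer_
  elapsed <- max_ticks

  for (t in seq_len(max_ticks)) {
    tb <- intents[t, ]
    dx <- targets[tb, 1L] - puck[1L]
    dy <- targets[tb, 2L] - puck[2L]
    nrm <- pmax(sqrt(dx * dx + dy * dy), 1e-12)
    fx <- dx / nrm
    fy <- dy / nrm
    if (keep_forces) { forces[t, , 1L] <- fx; forces[t, , 2L] <- fy }
    puck <- puck + step * c(mean(fx), mean(fy))
    path[t, ] <- puck

    d2 <- (targets[, 1L] - puck[1L])^2 + (targets[, 2L] - puck[2L])^2
    near <- which.min(d2)
    if (d2[near] <= config$conv_radius^2) {
      if (near == dwell_target) dwell <- dwell + 1L
      else { dwell_target <- near; dwell <- 1L }
      if (dwell >= config$dwell_ticks) {
        converged <- TRUE
        chosen <- near
        elapsed <- t
        break
      }
    } else {
      dwell <- 0L
      dwell_target <- 0L
    }
  }

  # Full attribution: each tick adds tick-duration x 1 to the intended
  # bin of each agent.
  used <- intents[seq_len(elapsed), , drop = FALSE]
  impulse <- config$tick * tabulate(as.integer(used), nbins = k)
  if (!converged) chosen <- which.max(impulse)  # first max = lower bin

  structure(list(
    impulse = impulse, chosen_bin = chosen, converged = converged,
    elapsed_ticks = elapsed,
    trace = list(puck = path[seq_len(elapsed), , drop = FALSE],
                 intents = used,
                 forces = if (keep_forces)
                   forces[seq_len(elapsed), , , drop = FALSE])),
    class = "swarm_session")
}

#' Squared-impulse interpolation of a refined probability
#'
#' Converts a session's accumulated per-bin impulse F(i) into a refined
#' probabilistic diagnosis: weights `w_i = F(i)^2 / sum_a F(a)^2` over
#' the bin midpoints `v_i`, returning `sum(w_i * v_i)`. The result lies
#' in the convex hull of midpoints with nonzero impulse; scaling all
#' F(i) by a positive constant leaves it unchanged.
#'
#' @param impulse non-negative numeric vector, one entry per bin, with
#'   positive total.
#' @param scheme a [bin_scheme()] with as many bins as `impulse`.
#' @return the interpolated probability.
#' @examples
#' interpolate_impulse(c(1, 0, 0, 0, 0))  # midpoint of the 0-5% bin
#' @export
interpolate_impulse <- function(impulse, scheme = bin_scheme()) {
  if (length(impulse) != nrow(scheme))
    stop("impulse length must match bin count", call. = FALSE)
  if (any(impulse < 0)) stop("impulse entries must be >= 0", call. = FALSE)
  s2 <- sum(impulse^2)
  if (s2 <= 0)
    stop("all-zero impulse profile carries no behavioural signal",
         call. = FALSE)
  w <- impulse^2 / s2
  sum(w * scheme$midpoint)
}

#' Run a swarm session over a full case set
#'
#' For each case, the panel's per-case probabilities become the agents'
#' beliefs, one session is simulated, and the squared-impulse
#' interpolation yields that case's swarm probability.
#'
#' @param cases a [case_set()].
#' @param panel list of reader `diagnosis_set`s; every reader must cover
#'   every case.
#' @param scheme a [bin_scheme()].
#' @param config a [swarm_config()]; its seed (required for
#'   reproducibility across calls) seeds the whole session sequence.
#' @param source_id label for the resulting diagnosis set.
#' @param trace_dir optional directory; per-case session traces are
#'   written there as JSON.
#' @return a `diagnosis_set` of kind `"swarm"`.
#' @export
run_swarm_session <- function(cases, panel, scheme = bin_scheme(),
                              config = swarm_config(), source_id = "swarm",
                              trace_dir = NULL) {
  if (length(panel) < 2L)
    stop("a swarm needs at least 2 readers", call. = FALSE)
  beliefs <- matrix(vapply(panel, probs_for, numeric(nrow(cases)),
                           cases = cases), nrow = nrow(cases))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$seed <- NULL  # sessions draw sequentially from the seeded stream
  if (!is.null(trace_dir) && !dir.exists(trace_dir))
    dir.create(trace_dir, recursive = TRUE)
  out <- numeric(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    ses <- simulate_swarm(beliefs[i, ], scheme, cfg)
    out[i] <- interpolate_impulse(ses$impulse, scheme)
    if (!is.null(trace_dir)) {
      jsonlite::write_json(
        list(case_id = cases$case_id[i],
             config = cfg[c("tick", "max_duration", "speed", "conv_radius",
                            "dwell_ticks", "policy", "tau")],
             puck = ses$trace$puck, intents = ses$trace$intents,
             chosen_bin = ses$chosen_bin, converged = ses$converged,
             impulse = ses$impulse, interpolated = out[i]),
        file.path(trace_dir, paste0(cases$case_id[i], ".json")),
        digits = NA, auto_unbox = TRUE)
    }
  }
  diagnosis_set(source_id, stats::setNames(out, cases$case_id),
                kind = "swarm", cases = cases)
}
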