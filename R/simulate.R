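# Stochastic twin of the deterministic model: exact Gillespie realisations
# of independent polyprotein domains under a piecewise-constant force
# protocol, rendered as noisy staircase extension traces and reduced to
# refolding-count datasets like the ones an AFM force-clamp experiment
# produces.

#' Simulation settings for synthetic force-clamp experiments
#'
#' @param n_domains_max polyprotein length: maximum number of domains a
#'   recording can pick up (9 for the ubiquitin nonamer, 8 for I27/Z1
#'   octamers).
#' @param pickup_min minimum number of tethered domains per recording; the
#'   actual count is drawn uniformly in \code{[pickup_min, n_domains_max]},
#'   so some recordings fall below the five-step quality filter and
#'   exercise it.
#' @param step_size unfolding step size in nm (20 for ubiquitin, 25 for Z1).
#' @param noise_sd white Gaussian noise on the extension signal (nm).
#' @param n_recordings number of recordings to simulate.
#' @param seed master RNG seed; each recording uses its own stream derived
#'   deterministically from it, so any single recording can be reproduced.
#' @param baseline_per_state 5x2 matrix (states x regimes
#'   \code{c("pulse","quench")}) of per-domain extension contributions in
#'   units of \code{step_size}. The default renders folded domains at 0,
#'   extended domains at 1 step and collapsed domains at half a step under
#'   force, and everything at 0 during the quench (the relaxed chain
#'   carries no length signal). Half-step re-extension jumps of collapsed
#'   domains in the test pulse thus fall outside the step-size acceptance
#'   window and are not mistaken for unfolding steps.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_domains_max = 9, pickup_min = 4, step_size = 20,
                       noise_sd = 1, n_recordings = 50, seed = 1,
                       baseline_per_state = NULL) {
  if (pickup_min < 1 || pickup_min > n_domains_max)
    stop("need 1 <= pickup_min <= n_domains_max")
  if (step_size <= 0) stop("step_size must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_recordings < 1) stop("n_recordings must be >= 1")
  if (is.null(baseline_per_state)) {
    baseline_per_state <- cbind(pulse = c(0, 1, 1, 0.5, 0.5),
                                quench = c(0, 0, 0, 0, 0))
    rownames(baseline_per_state) <- .FC_STATES
  }
  stopifnot(is.matrix(baseline_per_state),
            nrow(baseline_per_state) == 5L, ncol(baseline_per_state) == 2L)
  structure(list(n_domains_max = as.integer(n_domains_max),
                 pickup_min = as.integer(pickup_min),
                 step_size = step_size, noise_sd = noise_sd,
                 n_recordings = as.integer(n_recordings),
                 seed = as.integer(seed),
                 baseline_per_state = baseline_per_state),
            class = "sim_config")
}

# Deterministic per-recording stream seed derived from the master seed.
.rec_seed <- function(seed, rec) {
  as.integer((as.double(seed) * 48271 + rec * 16807) %% 2147483647)
}

# Fast Gillespie core over precomputed per-segment generators.
# Qs: list of 5x5 generators; bounds: segment end times; returns an event
# data.frame and the state index at every segment boundary.
.ssa_events <- function(Qs, durations, state) {
  t <- 0
  ev_time <- numeric(0); ev_from <- integer(0); ev_to <- integer(0)
  for (i in seq_along(Qs)) {
    Q <- Qs[[i]]
    seg_end <- t + durations[i]
    repeat {
      r <- -Q[state, state]
      if (r <= 0) { t <- seg_end; break }
      dt <- rexp(1L, r)
      if (t + dt >= seg_end) { t <- seg_end; break }
      t <- t + dt
      rates <- Q[, state]; rates[state] <- 0
      nxt <- sample.int(5L, 1L, prob = rates)
      ev_time <- c(ev_time, t); ev_from <- c(ev_from, state); ev_to <- c(ev_to, nxt)
      state <- nxt
    }
  }
  list(events = data.frame(time = ev_time, from = .FC_STATES[ev_from],
                           to = .FC_STATES[ev_to]),
       final = state)
}

#' Stochastic trajectory of a single substrate domain
#'
#' Draws one exact continuous-time Markov realisation of the five-state
#' model through a force protocol (Gillespie direct method with the
#' generator refreshed at every segment boundary; no jump straddles a
#' boundary).
#'
#' @param scheme a \code{\link{kinetic_scheme}}. \code{fold_competence}
#'   is applied here as a Bernoulli draw: an incompetent domain has its
#'   collapsed-to-folded rate set to zero.
#' @param protocol a \code{\link{force_protocol}}.
#' @param seed optional integer seed for reproducibility.
#' @param init initial state label (default \code{"folded"}).
#' @return a list with \code{events} (data.frame of time/from/to jumps),
#'   \code{final} state label and \code{competent} flag.
#' @examples
#' simulate_domain(kinetic_scheme(), force_quench_protocol(), seed = 7)
#' @export
simulate_domain <- function(scheme, protocol, seed = NULL, init = "folded") {
  if (!is.null(seed)) set.seed(seed)
  init <- match.arg(init, .FC_STATES)
  competent <- scheme$fold_competence >= 1 ||
    (scheme$fold_competence > 0 && runif(1L) < scheme$fold_competence)
  sch <- scheme
  if (!competent) sch$k_f0 <- 0
  seg <- protocol$segments
  Qs <- lapply(seg$force, function(f) rate_matrix(sch, f))
  res <- .ssa_events(Qs, seg$duration, which(.FC_STATES == init))
  list(events = res$events, final = .FC_STATES[res$final],
       competent = competent)
}

# State index of one domain at each requested time, from its event list.
.state_at <- function(events, times, init_idx) {
  if (nrow(events) == 0L) return(rep(init_idx, length(times)))
  idx <- findInterval(times, events$time)
  states <- c(init_idx, match(events$to, .FC_STATES))
  states[idx + 1L]
}

#' Simulate a synthetic force-clamp refolding experiment
#'
#' Generates \code{n_recordings} recordings. Each recording tethers a
#' uniform random number of domains in \code{[pickup_min, n_domains_max]},
#' simulates every domain independently through the protocol, counts
#' unfolding steps in the initial (unfold + extend) and test pulses, and
#' optionally renders the summed noisy extension trace.
#'
#' \code{steps_test} counts re-unfolding of domains that unfolded during
#' the initial pulse; the rare domain that unfolds for the first time
#' during the test pulse is visible in the trace and in the recorded final
#' extensions (so the equal-extension quality filter can reject the
#' recording) but never inflates \code{steps_test}, keeping
#' \code{steps_test <= steps_initial} by construction.
#'
#' @param scheme a \code{\link{kinetic_scheme}}.
#' @param protocol a \code{\link{force_protocol}} with an unfold pulse;
#'   a test pulse is required for refolding counts.
#' @param config a \code{\link{sim_config}}.
#' @param render_traces render noisy extension traces (disable for large
#'   count-only sweeps).
#' @param condition label stored with every record.
#' @return a list with \code{dataset} (one row per recording:
#'   recording_id, condition, t_q, t_ext, extend_force, n_domains,
#'   steps_initial, steps_test, final_ext_initial, final_ext_test) and
#'   \code{traces} (list of \code{fc_trajectory} or NULL).
#' @export
simulate_experiment <- function(scheme, protocol, config,
                                render_traces = TRUE, condition = "cond") {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  seg <- protocol$segments
  if (!"unfold" %in% seg$label) stop("protocol needs an unfold pulse")
  seg_end <- cumsum(seg$duration)
  seg_start <- c(0, head(seg_end, -1))
  initial_ix <- which(seg$label %in% c("unfold", "extend"))
  test_ix <- which(seg$label == "test")
  quench_ix <- which(seg$label == "quench")
  t_q <- if (length(quench_ix)) sum(seg$duration[quench_ix]) else 0
  t_ext <- if (any(seg$label == "extend")) sum(seg$duration[seg$label == "extend"]) else 0
  extend_force <- if (any(seg$label == "extend"))
    seg$force[which(seg$label == "extend")[1]] else seg$force[1]

  in_window <- function(times, ix) {
    if (!length(ix) || !length(times)) return(rep(FALSE, length(times)))
    hit <- rep(FALSE, length(times))
    for (i in ix) hit <- hit | (times > seg_start[i] & times <= seg_end[i])
    hit
  }

  Qs_comp <- lapply(seg$force, function(f) rate_matrix(scheme, f))
  sch0 <- scheme; sch0$k_f0 <- 0
  Qs_incomp <- lapply(seg$force, function(f) rate_matrix(sch0, f))

  n_rec <- config$n_recordings
  rows <- vector("list", n_rec)
  traces <- if (render_traces) vector("list", n_rec) else NULL
  total_T <- sum(seg$duration)
  if (render_traces) {
    tgrid <- seq(0, total_T, by = 1 / protocol$sampling_rate)
    samp_seg <- pmin(findInterval(tgrid, seg_start), nrow(seg))
    regime <- ifelse(seg$force[samp_seg] > .FC_FORCE_THRESHOLD, 1L, 2L)
    seg_label <- seg$label[samp_seg]
    forces <- seg$force[samp_seg]
  }

  for (rec in seq_len(n_rec)) {
    set.seed(.rec_seed(config$seed, rec))
    n_dom <- if (config$pickup_min == config$n_domains_max) config$pickup_min
      else sample(config$pickup_min:config$n_domains_max, 1L)
    steps_initial <- 0L; steps_test <- 0L
    state_mat <- if (render_traces) matrix(1L, length(tgrid), n_dom)
    events_all <- if (render_traces) vector("list", n_dom)
    final_states <- integer(n_dom)
    init_end_states <- integer(n_dom)
    t_init_end <- seg_end[max(initial_ix)]
    for (d in seq_len(n_dom)) {
      competent <- scheme$fold_competence >= 1 ||
        runif(1L) < scheme$fold_competence
      res <- .ssa_events(if (competent) Qs_comp else Qs_incomp,
                         seg$duration, 1L)
      ev <- res$events
      unf <- ev$from == "folded" & ev$to == "ext_free"
      n_init <- sum(unf & in_window(ev$time, initial_ix))
      steps_initial <- steps_initial + n_init
      if (n_init > 0L)
        steps_test <- steps_test + sum(unf & in_window(ev$time, test_ix))
      final_states[d] <- res$final
      init_end_states[d] <- .state_at(ev, t_init_end, 1L)
      if (render_traces) {
        state_mat[, d] <- .state_at(ev, tgrid, 1L)
        if (nrow(ev)) {
          ev$domain <- d
          events_all[[d]] <- ev
        }
      }
    }
    # ground-truth final extensions for the equal-extension QC
    base <- config$baseline_per_state * config$step_size
    ext_of <- function(states, reg) sum(base[cbind(states, reg)])
    reg_init <- if (seg$force[max(initial_ix)] > .FC_FORCE_THRESHOLD) 1L else 2L
    last_reg <- if (seg$force[nrow(seg)] > .FC_FORCE_THRESHOLD) 1L else 2L
    final_ext_initial <- ext_of(init_end_states, reg_init)
    final_ext_test <- ext_of(final_states, last_reg)
    if (render_traces) {
      contrib <- matrix(base[cbind(as.vector(state_mat),
                                   rep(regime, n_dom))],
                        nrow = length(tgrid))
      extension <- rowSums(contrib)
      if (config$noise_sd > 0)
        extension <- extension + rnorm(length(tgrid), 0, config$noise_sd)
      evdf <- if (length(events_all)) do.call(rbind, events_all) else NULL
      traces[[rec]] <- structure(
        list(time = tgrid, force = forces, extension = extension,
             segment = seg_label,
             metadata = list(recording_id = rec, condition = condition,
                             n_domains = n_dom,
                             seed = .rec_seed(config$seed, rec),
                             sampling_rate = protocol$sampling_rate,
                             step_size = config$step_size),
             events = evdf),
        class = "fc_trajectory")
    }
    rows[[rec]] <- data.frame(
      recording_id = rec, condition = condition, t_q = t_q, t_ext = t_ext,
      extend_force = extend_force, n_domains = n_dom,
      steps_initial = steps_initial, steps_test = steps_test,
      final_ext_initial = final_ext_initial, final_ext_test = final_ext_test)
  }
  dataset <- do.call(rbind, rows)
  rownames(dataset) <- NULL
  list(dataset = dataset, traces = traces)
}

#' @export
print.fc_trajectory <- function(x, ...) {
  cat(sprintf("Force-clamp trajectory: %d samples, %.3g s, %d domains (%s)\n",
              length(x$time), max(x$time), x$metadata$n_domains,
              x$metadata$condition))
  invisible(x)
}
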