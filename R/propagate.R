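# Deterministic propagation of the five-state model.
#
# The force is piecewise constant, so the linear ODE dx/dt = Q(F) x is
# solved exactly segment by segment with matrix exponentials; within a
# segment the sample-to-sample propagator expm(Q * dt) is computed once and
# applied repeatedly. This removes ODE-solver tolerance as a source of
# error: population conservation holds to ~1e-12.

.seg_propagator <- function(Q, dt) {
  as.matrix(Matrix::expm(Q * dt))
}

#' Propagate the five-state populations through a force protocol
#'
#' Solves the population dynamics exactly (per-segment matrix exponential)
#' and returns the state fractions on a regular time grid that includes
#' every segment boundary.
#'
#' @param scheme a \code{\link{kinetic_scheme}}.
#' @param protocol a \code{\link{force_protocol}}.
#' @param init initial \code{\link{population_state}}; defaults to all
#'   folded.
#' @param dt output time step (s); defaults to 100 samples per segment.
#'   Accuracy does not depend on \code{dt} (the solution is exact at every
#'   grid point), only output resolution does.
#' @return a data.frame with columns \code{time}, \code{segment},
#'   \code{force} and one column per state fraction.
#' @examples
#' pr <- force_quench_protocol(t_unfold = 4, t_q = 6, t_test = 0)
#' sol <- propagate(kinetic_scheme(), pr)
#' tail(sol, 1)  # mostly refolded after a 6-s quench
#' @export
propagate <- function(scheme, protocol, init = pure_state("folded"),
                      dt = NULL) {
  if (!inherits(protocol, "force_protocol")) stop("protocol must be a force_protocol")
  if (!inherits(init, "population_state")) init <- population_state(init)
  seg <- protocol$segments
  if (nrow(seg) == 0L) stop("empty protocol")
  out <- vector("list", nrow(seg))
  x <- as.numeric(init)
  t0 <- 0
  for (i in seq_len(nrow(seg))) {
    Q <- rate_matrix(scheme, seg$force[i])
    dur <- seg$duration[i]
    step <- if (is.null(dt)) dur / 100 else min(dt, dur)
    n <- max(1L, ceiling(dur / step - 1e-9))
    h <- dur / n
    P <- .seg_propagator(Q, h)
    states <- matrix(0, n + 1L, 5L)
    states[1L, ] <- x
    for (k in seq_len(n)) {
      x <- as.numeric(P %*% x)
      states[k + 1L, ] <- x
    }
    times <- t0 + h * (0:n)
    out[[i]] <- data.frame(time = times, segment = seg$label[i],
                           force = seg$force[i], states)
    t0 <- t0 + dur
  }
  res <- do.call(rbind, out)
  names(res)[4:8] <- .FC_STATES
  rownames(res) <- NULL
  res
}

# Exact end-of-protocol state: one matrix exponential per segment, no
# intermediate sampling. Used heavily inside the chi-square objective.
.propagate_final <- function(scheme, protocol, init) {
  seg <- protocol$segments
  x <- as.numeric(init)
  for (i in seq_len(nrow(seg))) {
    P <- .seg_propagator(rate_matrix(scheme, seg$force[i]), seg$duration[i])
    x <- as.numeric(P %*% x)
  }
  x
}

#' Predicted refolding yield for a force-quench protocol
#'
#' Runs the deterministic model through the protocol and returns the
#' fraction of domains expected to produce an unfolding step in the test
#' pulse: the folded fraction at the end of the (last) quench segment,
#' scaled by \code{fold_competence}. Domains still extended or collapsed
#' (bound or free) at the end of the quench re-extend without a step and
#' do not count. Protocol segments after the quench do not influence the
#' yield and are ignored.
#'
#' @param scheme a \code{\link{kinetic_scheme}}.
#' @param protocol a \code{\link{force_protocol}} containing a quench
#'   segment, or with \code{t_q = 0} interpreted as "yield at quench
#'   start".
#' @param init initial populations; the default, all extended-free, matches
#'   the experimental normalisation in which only domains unfolded during
#'   the initial pulse enter the yield denominator.
#' @return refolding fraction in [0, 1].
#' @examples
#' pr <- force_quench_protocol(t_unfold = 0, t_q = 5, t_test = 0)
#' predict_yield(kinetic_scheme(fold_competence = 0.75), pr,
#'               init = pure_state("ext_free"))
#' @export
predict_yield <- function(scheme, protocol, init = pure_state("ext_free")) {
  seg <- protocol$segments
  iq <- which(seg$label == "quench")
  last <- if (length(iq)) max(iq) else {
    pre <- which(seg$label %in% c("unfold", "extend"))
    if (!length(pre)) stop("protocol has no quench segment and no pre-quench pulse")
    max(pre) # t_q = 0: evaluate at the end of the pre-quench pulses
  }
  sub <- force_protocol(seg[seq_len(last), , drop = FALSE],
                        protocol$sampling_rate)
  x <- .propagate_final(scheme, sub, init)
  scheme$fold_competence * x[1L]
}

#' Equilibrium unbound fraction of the substrate
#'
#' For a chaperone-substrate interaction in binding equilibrium, the
#' fraction of substrate free of chaperone is K_d / (K_d + [chaperone]).
#' Multiplying by the intrinsic (no-chaperone) refolding yield gives the
#' residual refolding expected when binding has fully equilibrated, e.g.
#' at long extended-hold times.
#'
#' @param K_d dissociation constant (M), > 0.
#' @param conc chaperone concentration (M), >= 0.
#' @return unbound fraction in (0, 1].
#' @examples
#' equilibrium_unbound_fraction(9.4e-7, 5e-6)  # ~0.158
#' @export
equilibrium_unbound_fraction <- function(K_d, conc) {
  if (!is.finite(K_d) || K_d <= 0) stop("K_d must be > 0")
  if (!is.finite(conc) || conc < 0) stop("conc must be >= 0")
  K_d / (K_d + conc)
}

#' Pseudo-first-order binding relaxation rate
#'
#' The apparent exponential rate at which a binding reaction relaxes to
#' equilibrium at fixed free-chaperone concentration:
#' k = k_on * conc + k_off. When binding to the extended state dominates
#' the loss of refolding competence, this is the expected decay rate of
#' yield versus extended-hold time.
#'
#' @param k_on association rate (1/(M s)).
#' @param k_off dissociation rate (1/s).
#' @param conc chaperone concentration (M).
#' @return rate in 1/s.
#' @export
pseudo_first_order_rate <- function(k_on, k_off, conc) {
  if (any(c(k_on, k_off, conc) < 0)) stop("inputs must be >= 0")
  k_on * conc + k_off
}

#' Force-dependent association-rate multiplier from an energy profile
#'
#' Converts the dihedral-remodeling free-energy cost DDG(F) (in kBT,
#' normalised so the minimum over force is 0) into a Boltzmann multiplier
#' exp(-DDG(F)/kBT) on the association rate: binding is fastest at the
#' force where remodeling the backbone to its bound geometry is cheapest.
#' Linear interpolation is used between tabulated forces.
#'
#' @param profile an \code{\link{energy_profile}}.
#' @param force force in pN; must lie within the tabulated range unless
#'   \code{extrapolate = TRUE} (which clamps to the nearest endpoint).
#' @param extrapolate allow forces outside the tabulated range.
#' @return dimensionless multiplier in (0, 1], equal to 1 at the
#'   profile minimum.
#' @export
kon_multiplier_from_energy <- function(profile, force, extrapolate = FALSE) {
  if (!inherits(profile, "energy_profile")) stop("profile must be an energy_profile")
  pf <- profile$force
  if (!extrapolate && (force < min(pf) || force > max(pf)))
    stop(sprintf("force %g pN outside tabulated range [%g, %g]; set extrapolate = TRUE to clamp",
                 force, min(pf), max(pf)))
  dg <- profile$dg_mean - min(profile$dg_mean) # normalise so min = 0
  ddg <- approx(pf, dg, xout = min(max(force, min(pf)), max(pf)))$y
  exp(-ddg)
}
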