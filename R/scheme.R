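# Canonical ordering of the five substrate states. All matrices, population
# vectors and simulator states use this order.
.FC_STATES <- c("folded", "ext_free", "ext_bound", "coll_free", "coll_bound")

# Force (pN) separating the "pulse" rate rules from the "quench" rules.
# Experiments only ever use ~0 pN versus >= 30 pN, so any value between
# those regimes is equivalent; 10 pN is used throughout.
.FC_FORCE_THRESHOLD <- 10

#' Five-state kinetic scheme for a substrate domain under force
#'
#' A substrate domain visits five states: natively folded, mechanically
#' extended (chaperone-free or chaperone-bound) and collapsed
#' molten-globule-like (free or bound). Which transitions are active depends
#' on the force regime: under a stretching pulse the domain unfolds
#' (\code{k_u}), collapsed conformations re-extend (\code{k_uc}) and the
#' chaperone exchanges on the extended state; at quench (force ~0) the free
#' extended chain collapses (\code{k_c}), the free collapsed chain folds
#' (\code{k_f0}) and the chaperone exchanges on both non-native free states.
#' Bound states never fold, and a bound extended chain does not collapse
#' until the chaperone dissociates.
#'
#' @param k_u unfolding rate (1/s) folded -> extended-free at the pulling
#'   force. Stored per reference force; no force law is applied.
#' @param k_c collapse rate (1/s) extended-free -> collapsed-free at quench.
#' @param k_f0 folding rate (1/s) collapsed-free -> folded at quench.
#' @param k_uc re-extension rate (1/s) collapsed -> extended under force
#'   (same rate for free and bound; binding status is preserved).
#' @param k_on_ext,k_on_coll chaperone association rates (1/(M s)) to the
#'   extended and collapsed conformations.
#' @param k_off_ext,k_off_coll dissociation rates (1/s).
#' @param chaperone_conc chaperone concentration (M).
#' @param fold_competence fraction in [0,1] of domains able to reach the
#'   folded state. Implemented as a partition of domains, not a sixth
#'   state: predictions are scaled and simulated domains are assigned
#'   competence once at birth.
#' @param kon_force_profile optional \code{\link{energy_profile}}; when
#'   present, \code{k_on_ext} is multiplied by
#'   \code{exp(-DDG(F)/kBT)} during force pulses (see
#'   \code{\link{kon_multiplier_from_energy}}).
#'
#' @return An object of class \code{kinetic_scheme}.
#' @examples
#' sch <- kinetic_scheme(k_u = 0.93, k_c = 8, k_f0 = 0.52,
#'                       k_on_ext = 4.8e4, k_off_ext = 0.045,
#'                       chaperone_conc = 5e-6)
#' Kd(sch, "ext")
#' @export
kinetic_scheme <- function(k_u = 0.93, k_c = 8, k_f0 = 0.52, k_uc = 50,
                           k_on_ext = 0, k_on_coll = 0,
                           k_off_ext = 0, k_off_coll = 0,
                           chaperone_conc = 0, fold_competence = 1,
                           kon_force_profile = NULL) {
  num <- function(x) suppressWarnings(as.numeric(x)) # tolerate "4.8e4" from YAML
  rates <- c(k_u = num(k_u), k_c = num(k_c), k_f0 = num(k_f0),
             k_uc = num(k_uc), k_on_ext = num(k_on_ext),
             k_on_coll = num(k_on_coll), k_off_ext = num(k_off_ext),
             k_off_coll = num(k_off_coll))
  chaperone_conc <- num(chaperone_conc)
  fold_competence <- num(fold_competence)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0")
  if (!is.finite(chaperone_conc) || chaperone_conc < 0)
    stop("chaperone_conc must be >= 0")
  if (!is.finite(fold_competence) || fold_competence < 0 || fold_competence > 1)
    stop("fold_competence must lie in [0, 1]")
  if (!is.null(kon_force_profile) &&
      !inherits(kon_force_profile, "energy_profile"))
    stop("kon_force_profile must be an energy_profile or NULL")
  structure(c(as.list(rates),
              list(chaperone_conc = chaperone_conc,
                   fold_competence = fold_competence,
                   kon_force_profile = kon_force_profile)),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Five-state kinetic scheme\n")
  cat(sprintf("  k_u = %g /s, k_c = %g /s, k_f0 = %g /s, k_uc = %g /s\n",
              x$k_u, x$k_c, x$k_f0, x$k_uc))
  cat(sprintf("  extended:  k_on = %g /(M s), k_off = %g /s\n",
              x$k_on_ext, x$k_off_ext))
  cat(sprintf("  collapsed: k_on = %g /(M s), k_off = %g /s\n",
              x$k_on_coll, x$k_off_coll))
  cat(sprintf("  [chaperone] = %g M, fold competence = %g\n",
              x$chaperone_conc, x$fold_competence))
  if (!is.null(x$kon_force_profile))
    cat("  force-dependent k_on_ext via attached energy profile\n")
  invisible(x)
}

#' Dissociation constant of a chaperone-conformation pair
#'
#' @param scheme a \code{\link{kinetic_scheme}}.
#' @param conformation \code{"ext"} or \code{"coll"}.
#' @return K_d = k_off / k_on in molar; defined only when k_on > 0.
#' @export
Kd <- function(scheme, conformation = c("ext", "coll")) {
  conformation <- match.arg(conformation)
  kon <- scheme[[paste0("k_on_", conformation)]]
  koff <- scheme[[paste0("k_off_", conformation)]]
  if (kon <= 0) stop("K_d undefined: k_on_", conformation, " is zero")
  koff / kon
}

#' Piecewise-constant force protocol
#'
#' Ordered force segments applied to the tethered polyprotein. Labels follow
#' the standard force-quench vocabulary: an \code{unfold} pulse, an optional
#' \code{extend} hold, a \code{quench} at ~0 pN and a \code{test} restretch.
#'
#' @param segments a data.frame with columns \code{label}, \code{force}
#'   (pN) and \code{duration} (s). Quench segments must have force below
#'   the 10 pN regime threshold, other segments above it. Zero-duration
#'   segments are dropped.
#' @param sampling_rate sampling frequency (Hz) used when rendering traces.
#' @return An object of class \code{force_protocol}.
#' @examples
#' pr <- force_protocol(data.frame(
#'   label = c("unfold", "quench", "test"),
#'   force = c(120, 0, 120),
#'   duration = c(5, 5, 5)))
#' @export
force_protocol <- function(segments, sampling_rate = 1000) {
  req <- c("label", "force", "duration")
  if (!is.data.frame(segments) || !all(req %in% names(segments)))
    stop("segments must be a data.frame with columns label, force, duration")
  segments$label <- as.character(segments$label)
  if (!all(segments$label %in% c("unfold", "extend", "quench", "test")))
    stop("segment labels must be unfold, extend, quench or test")
  segments <- segments[segments$duration > 0, , drop = FALSE]
  if (nrow(segments) == 0L) stop("protocol has no segments of positive duration")
  if (any(segments$duration < 0) || any(segments$force < 0))
    stop("durations and forces must be >= 0")
  quench <- segments$label == "quench"
  if (any(segments$force[quench] > .FC_FORCE_THRESHOLD))
    stop("quench segments must have force at or near 0 pN")
  if (any(segments$force[!quench] <= .FC_FORCE_THRESHOLD))
    stop("non-quench segments must have force above the 10 pN threshold")
  lab <- segments$label
  if ("unfold" %in% lab && which(lab == "unfold")[1] != 1L)
    stop("the unfold pulse must come first")
  if ("test" %in% lab && max(which(lab == "test")) != length(lab))
    stop("the test pulse must come last")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  rownames(segments) <- NULL
  structure(list(segments = segments[, req], sampling_rate = sampling_rate),
            class = "force_protocol")
}

#' Standard force-quench protocol builder
#'
#' Convenience constructor for the three-pulse protocols used throughout:
#' unfold at high force, optionally hold extended (possibly at a different
#' force), quench to 0 pN for \code{t_q}, then restretch in a test pulse.
#' Any duration set to 0 drops that segment (e.g. \code{t_q = 0} yields a
#' protocol without a quench).
#'
#' @param unfold_force,t_unfold force (pN) and duration (s) of the initial
#'   unfolding pulse.
#' @param extend_force,t_ext optional hold of the extended chain before the
#'   quench; \code{t_ext = 0} omits it.
#' @param t_q quench duration (s) at 0 pN.
#' @param test_force,t_test test restretch; \code{t_test = 0} omits it.
#' @param sampling_rate Hz, for trace rendering.
#' @return a \code{\link{force_protocol}}.
#' @export
force_quench_protocol <- function(unfold_force = 120, t_unfold = 5,
                                  extend_force = unfold_force, t_ext = 0,
                                  t_q = 5, test_force = unfold_force,
                                  t_test = 5, sampling_rate = 1000) {
  seg <- data.frame(
    label = c("unfold", "extend", "quench", "test"),
    force = c(unfold_force, extend_force, 0, test_force),
    duration = c(t_unfold, t_ext, t_q, t_test))
  force_protocol(seg[seg$duration > 0, , drop = FALSE], sampling_rate)
}

#' @export
print.force_protocol <- function(x, ...) {
  cat("Force protocol (", nrow(x$segments), " segments, ",
      x$sampling_rate, " Hz)\n", sep = "")
  print(x$segments)
  invisible(x)
}

#' Population state over the five substrate states
#'
#' @param fractions numeric vector of length 5 (order: folded, extended
#'   free, extended bound, collapsed free, collapsed bound); must be
#'   nonnegative and sum to 1 within 1e-9.
#' @return a named numeric vector of class \code{population_state}.
#' @export
population_state <- function(fractions) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 5L) stop("need 5 state fractions")
  if (any(fractions < -1e-12)) stop("fractions must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(stats::setNames(pmax(fractions, 0), .FC_STATES),
            class = "population_state")
}

#' All-mass-in-one-state population
#' @param state one of \code{"folded"}, \code{"ext_free"},
#'   \code{"ext_bound"}, \code{"coll_free"}, \code{"coll_bound"}.
#' @return a \code{\link{population_state}}.
#' @export
pure_state <- function(state = "folded") {
  state <- match.arg(state, .FC_STATES)
  population_state(as.numeric(.FC_STATES == state))
}

#' Generator matrix of the five-state model at a given force
#'
#' Builds the 5x5 rate-generator Q in the column convention
#' (dx/dt = Q x): \code{Q[j, i]} is the rate of the i -> j transition and
#' every column sums to zero. The active transitions switch with the force
#' regime: above the 10 pN threshold (force pulse) the folded state unfolds,
#' collapsed conformations re-extend (binding status preserved) and the
#' chaperone exchanges on the extended chain; at or below the threshold
#' (quench) the free extended chain collapses, the free collapsed chain
#' folds and the chaperone exchanges on both free non-native states. Bound
#' states never fold and the bound extended chain does not collapse.
#'
#' @param scheme a \code{\link{kinetic_scheme}}.
#' @param force applied force in pN (>= 0).
#' @return a 5x5 matrix with dimnames over the state labels.
#' @examples
#' Q <- rate_matrix(kinetic_scheme(), force = 120)
#' colSums(Q)   # all zero
#' @export
rate_matrix <- function(scheme, force) {
  if (!inherits(scheme, "kinetic_scheme")) stop("scheme must be a kinetic_scheme")
  if (!is.finite(force) || force < 0) stop("force must be a nonnegative number")
  Q <- matrix(0, 5, 5, dimnames = list(.FC_STATES, .FC_STATES))
  conc <- scheme$chaperone_conc
  add <- function(from, to, rate) {
    Q[to, from] <<- Q[to, from] + rate
    Q[from, from] <<- Q[from, from] - rate
  }
  if (force > .FC_FORCE_THRESHOLD) {
    kmul <- if (is.null(scheme$kon_force_profile)) 1
            else kon_multiplier_from_energy(scheme$kon_force_profile, force)
    add("folded", "ext_free", scheme$k_u)
    add("coll_free", "ext_free", scheme$k_uc)
    add("coll_bound", "ext_bound", scheme$k_uc)
    add("ext_free", "ext_bound", scheme$k_on_ext * conc * kmul)
    add("ext_bound", "ext_free", scheme$k_off_ext)
  } else {
    add("ext_free", "coll_free", scheme$k_c)
    add("coll_free", "folded", scheme$k_f0)
    add("ext_free", "ext_bound", scheme$k_on_ext * conc)
    add("ext_bound", "ext_free", scheme$k_off_ext)
    add("coll_free", "coll_bound", scheme$k_on_coll * conc)
    add("coll_bound", "coll_free", scheme$k_off_coll)
  }
  Q
}
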