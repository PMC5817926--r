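# Reference parameterisations of the five-state model.
#
# The two conformational reference rates are fixed across all conditions:
# the unfolding rate at the standard 120 pN pulling force and the
# collapsed-to-folded rate, chosen so the no-chaperone quench kinetics
# plateau with an apparent folding rate of ~0.52 1/s. Binding constants
# are chosen so that K_d = k_off/k_on matches the reported affinities and,
# for the extended-state binder, so that the pseudo-first-order relaxation
# k_on * conc + k_off at 5 uM reproduces the observed ~0.27 1/s decay of
# yield versus extended-hold time.

#' Reference kinetic schemes
#'
#' \code{ubiquitin_scheme()} is the chaperone-free ubiquitin
#' parameterisation: k_u = 0.93 1/s (120 pN), fast collapse k_c = 8 1/s,
#' k_f0 = 0.52 1/s, fold competence 0.75 (the observed long-quench yield
#' plateau). \code{dnaj_scheme()} adds an extended-state binder with
#' K_d = 9.4e-7 M (k_on = 4.8e4 1/(M s), k_off = 0.045 1/s) at
#' concentration \code{conc}. \code{dnak_scheme()} adds a collapsed-state
#' binder with K_d = 1.4e-7 M (k_on = 2e5 1/(M s), k_off = 0.028 1/s; the
#' k_on/k_off split is chosen so that a 5 uM quench-time sweep plateaus
#' near the observed ~30% yield).
#'
#' @param conc chaperone concentration (M).
#' @param ... overrides passed to \code{\link{kinetic_scheme}}.
#' @return a \code{\link{kinetic_scheme}}.
#' @export
ubiquitin_scheme <- function(...) {
  args <- modifyList(list(k_u = 0.93, k_c = 8, k_f0 = 0.52, k_uc = 50,
                          fold_competence = 0.75), list(...))
  do.call(kinetic_scheme, args)
}

#' @rdname ubiquitin_scheme
#' @export
dnaj_scheme <- function(conc = 5e-6, ...) {
  args <- modifyList(list(k_on_ext = 4.8e4, k_off_ext = 0.045,
                          chaperone_conc = conc), list(...))
  do.call(ubiquitin_scheme, args)
}

#' @rdname ubiquitin_scheme
#' @export
dnak_scheme <- function(conc = 5e-6, ...) {
  args <- modifyList(list(k_on_coll = 2e5, k_off_coll = 0.028,
                          chaperone_conc = conc), list(...))
  do.call(ubiquitin_scheme, args)
}
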