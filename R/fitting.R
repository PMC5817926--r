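# Chi-square fitting of the five-state model to refolding-yield curves.
#
# Observed yields (with bootstrap SEMs) from one or more protocol
# families -- quench-time sweeps, extended-hold sweeps, stretching-force
# sweeps -- are compared with deterministic model predictions; free rate
# constants are optimised in log10 space with box bounds and
# Latin-hypercube multi-start.

.FC_RATE_NAMES <- c("k_u", "k_c", "k_f0", "k_uc",
                    "k_on_ext", "k_on_coll", "k_off_ext", "k_off_coll")

.default_bounds <- function(par) {
  if (grepl("^k_on", par)) c(1e2, 1e8)        # 1/(M s)
  else if (grepl("^k_off", par)) c(1e-4, 1e2) # 1/s
  else c(1e-4, 1e3)                           # conformational rates, 1/s
}

#' Fit dataset: one observed yield curve plus its protocol family
#'
#' @param data data.frame with columns \code{x} (the swept variable),
#'   \code{yield} and \code{sem}.
#' @param sweep which protocol variable \code{x} is: \code{"t_q"} (quench
#'   time), \code{"t_ext"} (extended hold) or \code{"force"} (hold force).
#' @param t_ext,extend_force,t_q values of the non-swept protocol
#'   variables (s, pN, s).
#' @param t_unfold,unfold_force duration and force of the initial
#'   unfolding pulse. With \code{t_unfold = 0} the model starts fully
#'   extended and free; with \code{t_unfold > 0} it starts folded, domains
#'   unfold stochastically during the initial pulse (so chaperone exposure
#'   varies realistically across domains) and the predicted yield is
#'   conditioned on having unfolded before the quench, matching the
#'   experimental normalisation over initial-pulse steps.
#' @return a list of class \code{fit_dataset}.
#' @export
fit_dataset <- function(data, sweep = c("t_q", "t_ext", "force"),
                        t_ext = 5, extend_force = 120, t_q = 5,
                        t_unfold = 0, unfold_force = 120) {
  sweep <- match.arg(sweep)
  stopifnot(all(c("x", "yield") %in% names(data)))
  if (is.null(data$sem)) data$sem <- NA_real_
  structure(list(data = data, sweep = sweep, t_ext = t_ext,
                 extend_force = extend_force, t_q = t_q,
                 t_unfold = t_unfold, unfold_force = unfold_force),
            class = "fit_dataset")
}

# Model-predicted yields for every point of a fit_dataset.
.predict_dataset <- function(scheme, fd) {
  vapply(fd$data$x, function(x) {
    args <- switch(fd$sweep,
      t_q = list(t_ext = fd$t_ext, extend_force = fd$extend_force, t_q = x),
      t_ext = list(t_ext = x, extend_force = fd$extend_force, t_q = fd$t_q),
      force = list(t_ext = fd$t_ext, extend_force = x, t_q = fd$t_q))
    pr <- force_quench_protocol(unfold_force = fd$unfold_force,
                                t_unfold = fd$t_unfold,
                                extend_force = args$extend_force,
                                t_ext = args$t_ext, t_q = args$t_q,
                                t_test = 0)
    if (fd$t_unfold <= 0)
      return(predict_yield(scheme, pr, init = pure_state("ext_free")))
    # folded start: condition on having unfolded during the initial pulse
    fc <- scheme$fold_competence
    if (fc <= 0) return(0)
    f_end <- predict_yield(scheme, pr, init = pure_state("folded")) / fc
    f_remain <- exp(-scheme$k_u * (fd$t_unfold + args$t_ext))
    fc * max(f_end - f_remain, 0) / (1 - f_remain)
  }, 0)
}

#' Fit specification: datasets, free parameters, optimiser settings
#'
#' Exactly the parameters named in \code{free} are optimised; all others
#' are held at their values in \code{scheme} (the reference/fixed rates).
#' Points with missing or zero SEM receive the median positive SEM of
#' their dataset.
#'
#' @param scheme template \code{\link{kinetic_scheme}} holding the fixed
#'   rates (and concentration, competence, ...).
#' @param datasets list of \code{\link{fit_dataset}} objects; two or more
#'   protocol families are needed for a well-identified binding pair (a
#'   warning is issued otherwise).
#' @param free character vector of free rate names (subset of the eight
#'   rate constants).
#' @param lower,upper optional named bounds (natural units); defaults:
#'   k_on in [1e2, 1e8] 1/(M s), k_off in [1e-4, 1e2] 1/s, conformational
#'   rates in [1e-4, 1e3] 1/s.
#' @param n_starts multi-start count (Latin hypercube in log10 space).
#' @return a list of class \code{fit_spec}.
#' @export
fit_spec <- function(scheme, datasets, free = c("k_on_ext", "k_off_ext"),
                     lower = NULL, upper = NULL, n_starts = 16) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (inherits(datasets, "fit_dataset")) datasets <- list(datasets)
  stopifnot(all(vapply(datasets, inherits, TRUE, "fit_dataset")))
  if (!length(free)) stop("free parameter set must be nonempty")
  if (!all(free %in% .FC_RATE_NAMES))
    stop("free parameters must be among: ", paste(.FC_RATE_NAMES, collapse = ", "))
  fams <- unique(vapply(datasets, `[[`, "", "sweep"))
  if (length(fams) < 2)
    warning("only one protocol family supplied; binding parameters may not be identifiable")
  bounds <- vapply(free, .default_bounds, numeric(2))
  lo <- bounds[1, ]; hi <- bounds[2, ]
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(lo <= 0)) stop("bounds must be positive (rates are fitted in log space)")
  # median-SEM imputation per dataset
  datasets <- lapply(datasets, function(fd) {
    s <- fd$data$sem
    bad <- !is.finite(s) | s <= 0
    if (any(bad)) {
      med <- stats::median(s[!bad])
      if (!is.finite(med)) med <- 0.05
      fd$data$sem[bad] <- med
    }
    fd
  })
  structure(list(scheme = scheme, datasets = datasets, free = free,
                 lower = lo, upper = hi, n_starts = as.integer(n_starts)),
            class = "fit_spec")
}

# Scheme with free parameters substituted.
.apply_params <- function(scheme, params) {
  for (nm in names(params)) scheme[[nm]] <- as.numeric(params[[nm]])
  scheme
}

#' Chi-square of a parameter set against a fit specification
#'
#' sum over all points of ((observed - predicted) / sem)^2, with
#' predictions from the deterministic five-state model.
#'
#' @param params named numeric vector of rate values (natural units) for
#'   (a subset of) the free parameters.
#' @param spec a \code{\link{fit_spec}}.
#' @return the chi-square value.
#' @examples
#' fd <- fit_dataset(data.frame(x = c(1, 5), yield = c(.3, .6),
#'                              sem = c(.05, .05)), sweep = "t_q")
#' sp <- suppressWarnings(fit_spec(kinetic_scheme(), fd))
#' chi_square(c(k_on_ext = 1e5, k_off_ext = 0.05), sp)
#' @export
chi_square <- function(params, spec) {
  stopifnot(inherits(spec, "fit_spec"))
  sch <- .apply_params(spec$scheme, params)
  total <- 0
  for (fd in spec$datasets) {
    if (any(fd$data$sem <= 0)) stop("all SEMs must be > 0")
    pred <- .predict_dataset(sch, fd)
    total <- total + sum(((fd$data$yield - pred) / fd$data$sem)^2)
  }
  total
}

#' Fit free rate constants by bound-constrained chi-square minimisation
#'
#' Optimises log10 of the free rates with L-BFGS-B from \code{n_starts}
#' Latin-hypercube starting points (plus the template scheme's own values
#' when inside the bounds), and returns the best converged start.
#'
#' @param spec a \code{\link{fit_spec}}.
#' @param seed RNG seed for the multi-start design.
#' @return a list of class \code{fitted_params}: \code{params} (best
#'   point estimates), \code{Kd} (derived k_off/k_on per conformation
#'   where both rates are available), \code{chisq}, \code{n_points},
#'   \code{starts} (per-start results table), \code{converged}.
#' @export
fit_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "fit_spec"))
  free <- spec$free
  d <- length(free)
  n_pts <- sum(vapply(spec$datasets, function(fd) nrow(fd$data), 0L))
  obj <- function(logp) {
    p <- setNames(10^logp, free)
    chi_square(p, spec)
  }
  llo <- log10(spec$lower); lhi <- log10(spec$upper)
  set.seed(seed)
  starts <- lhs::randomLHS(max(spec$n_starts - 1L, 1L), d)
  starts <- sweep(sweep(starts, 2, lhi - llo, "*"), 2, llo, "+")
  tmpl <- log10(pmin(pmax(unlist(spec$scheme[free]), spec$lower), spec$upper))
  if (all(is.finite(tmpl))) starts <- rbind(tmpl, starts)
  rows <- vector("list", nrow(starts))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = llo, upper = lhi,
                   control = list(maxit = 500, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(res)) {
      rows[[i]] <- data.frame(start = i, chisq = NA_real_, converged = FALSE)
      next
    }
    rows[[i]] <- data.frame(start = i, chisq = res$value,
                            converged = res$convergence == 0)
    if (is.null(best) || res$value < best$value) best <- res
  }
  starts_tab <- do.call(rbind, rows)
  if (is.null(best)) {
    return(structure(list(params = setNames(rep(NA_real_, d), free),
                          Kd = NULL, chisq = NA_real_, n_points = n_pts,
                          starts = starts_tab, converged = FALSE),
                     class = "fitted_params"))
  }
  params <- setNames(10^best$par, free)
  sch <- .apply_params(spec$scheme, params)
  Kd_out <- list()
  for (conf in c("ext", "coll")) {
    kon <- sch[[paste0("k_on_", conf)]]
    if (kon > 0) Kd_out[[conf]] <- sch[[paste0("k_off_", conf)]] / kon
  }
  structure(list(params = params, Kd = Kd_out, chisq = best$value,
                 n_points = n_pts, starts = starts_tab,
                 converged = any(starts_tab$converged, na.rm = TRUE)),
            class = "fitted_params")
}

#' @export
print.fitted_params <- function(x, ...) {
  cat("Fitted rate constants (chi-square = ", format(x$chisq, digits = 4),
      " over ", x$n_points, " points)\n", sep = "")
  for (nm in names(x$params))
    cat(sprintf("  %-10s = %.4g\n", nm, x$params[[nm]]))
  for (conf in names(x$Kd))
    cat(sprintf("  K_d(%s)   = %.3g M\n", conf, x$Kd[[conf]]))
  if (!x$converged) cat("  WARNING: no start converged\n")
  invisible(x)
}

#' Chi-square profile of one free parameter
#'
#' Holds \code{parameter} at each grid value, refits the remaining free
#' parameters, and returns the profile. A flat profile (relative range of
#' chi-square below \code{flat_tol}) triggers a non-identifiability
#' warning.
#'
#' @param spec a \code{\link{fit_spec}}.
#' @param parameter one of the spec's free parameters.
#' @param grid values (natural units) at which to pin the parameter.
#' @param seed passed to the inner fits.
#' @param n_starts multi-start count for the inner fits (default 4).
#' @param flat_tol relative chi-square range below which the profile is
#'   declared flat.
#' @return data.frame with columns \code{value} and \code{chisq}.
#' @export
identifiability_sweep <- function(spec, parameter, grid, seed = 1,
                                  n_starts = 4, flat_tol = 0.05) {
  stopifnot(inherits(spec, "fit_spec"))
  if (!parameter %in% spec$free) stop(parameter, " is not a free parameter")
  others <- setdiff(spec$free, parameter)
  prof <- vapply(grid, function(v) {
    sch <- .apply_params(spec$scheme, setNames(v, parameter))
    if (!length(others)) return(chi_square(setNames(v, parameter), spec))
    sub <- spec
    sub$scheme <- sch
    sub$free <- others
    sub$lower <- spec$lower[others]
    sub$upper <- spec$upper[others]
    sub$n_starts <- as.integer(n_starts)
    fit_model(sub, seed = seed)$chisq
  }, 0)
  rng <- range(prof)
  if (diff(rng) < flat_tol * max(rng[1], 1))
    warning("flat chi-square profile: ", parameter,
            " is not identifiable from the supplied datasets")
  data.frame(value = grid, chisq = prof)
}
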