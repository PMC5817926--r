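# Analysis of step events and refolding counts: normalized unfolding
# probability P(u) with single-exponential rate, pooled refolding yields
# with quality filters, bootstrap standard errors and weighted
# exponential fits of yield curves.

.fit_result <- function(form, rate = NA_real_, rate_se = NA_real_,
                        amplitude = NA_real_, offset = NA_real_,
                        n = NA_integer_, ok = TRUE, message = "") {
  structure(list(form = form, rate = rate, rate_se = rate_se,
                 amplitude = amplitude, offset = offset, n = n,
                 ok = ok, message = message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!x$ok) {
    cat("Fit failed (", x$form, "): ", x$message, "\n", sep = "")
  } else {
    cat(sprintf("%s fit: rate = %.4g +/- %.2g 1/s", x$form, x$rate, x$rate_se))
    if (is.finite(x$amplitude)) cat(sprintf(", amplitude = %.3g", x$amplitude))
    if (is.finite(x$offset)) cat(sprintf(", offset = %.3g", x$offset))
    cat(sprintf(" (n = %d)\n", x$n))
  }
  invisible(x)
}

#' Unfolding kinetics from detected step events
#'
#' Reproduces the standard P(u) analysis: traces with at least
#' \code{min_events} unfolding events are kept; each trace's cumulative
#' step count versus time is rescaled to [0, 1]; the per-trace curves are
#' averaged on a common time grid; the averaged curve is fitted to the
#' single exponential 1 - exp(-k_u t).
#'
#' @param event_list list of \code{\link{detect_steps}} results (or plain
#'   data.frames with \code{time} and \code{multiplicity}), one per trace,
#'   with times measured from the start of the unfolding pulse.
#' @param min_events minimum unfolding events per trace (default 6).
#' @param grid_n number of points on the common time grid.
#' @return a list with \code{curve} (data.frame time, p_u, n_traces) and
#'   \code{fit} (a \code{fit_result} with the unfolding rate k_u).
#' @export
unfolding_kinetics <- function(event_list, min_events = 6, grid_n = 200) {
  times <- lapply(event_list, function(ev) {
    if (nrow(ev) == 0L) return(numeric(0))
    rep(ev$time, if (!is.null(ev$multiplicity)) ev$multiplicity else 1L)
  })
  keep <- vapply(times, length, 0L) >= min_events
  if (!any(keep))
    stop("no traces with >= ", min_events, " unfolding events")
  times <- times[keep]
  t_max <- max(unlist(times))
  grid <- seq(0, t_max, length.out = grid_n)
  # per-trace normalized cumulative count, then average across traces
  pu <- rowMeans(vapply(times, function(tt) {
    ecdf_vals <- findInterval(grid, sort(tt)) / length(tt)
    ecdf_vals
  }, numeric(grid_n)))
  curve <- data.frame(time = grid, p_u = pu)
  if (max(unlist(times)) <= 0 || all(pu[-1] >= 1 - 1e-12)) {
    return(list(curve = curve,
                fit = .fit_result("saturating", n = length(times), ok = FALSE,
                                  message = "degenerate kinetics: all events at t = 0")))
  }
  fit <- tryCatch({
    # log-linearised start, then nonlinear least squares on 1 - exp(-k t)
    inside <- pu > 0.02 & pu < 0.98
    k0 <- if (sum(inside) >= 2)
      stats::coef(stats::lm(log(1 - pu[inside]) ~ 0 + grid[inside]))[[1]] * -1
      else 1 / stats::median(unlist(times))
    m <- minpack.lm::nlsLM(p_u ~ 1 - exp(-k * time), data = curve,
                           start = list(k = max(k0, 1e-6)),
                           lower = 1e-9, upper = 1e6)
    s <- summary(m)$coefficients
    .fit_result("saturating", rate = s["k", "Estimate"],
                rate_se = s["k", "Std. Error"], amplitude = 1,
                n = length(times))
  }, error = function(e)
    .fit_result("saturating", n = length(times), ok = FALSE,
                message = conditionMessage(e)))
  list(curve = curve, fit = fit)
}

#' Quality-control settings for refolding datasets
#'
#' @param min_steps_initial minimum unfolding steps in the initial pulse
#'   for a recording to be kept (default 5).
#' @param ext_tol_frac maximum allowed mismatch between the extension at
#'   the end of the initial and test pulses, as a fraction of the
#'   recording's fully unfolded length (default 0.10).
#' @param step_size step size (nm) used to convert the fraction into nm.
#' @return a list of class \code{yield_qc}.
#' @export
yield_qc <- function(min_steps_initial = 5, ext_tol_frac = 0.10,
                     step_size = 20) {
  structure(list(min_steps_initial = min_steps_initial,
                 ext_tol_frac = ext_tol_frac, step_size = step_size),
            class = "yield_qc")
}

# Apply the QC filters; returns the retained rows.
.qc_filter <- function(dataset, qc) {
  keep <- dataset$steps_initial >= qc$min_steps_initial
  if (all(c("final_ext_initial", "final_ext_test") %in% names(dataset))) {
    tol <- qc$ext_tol_frac * dataset$steps_initial * qc$step_size
    keep <- keep &
      abs(dataset$final_ext_initial - dataset$final_ext_test) <= tol
  }
  dataset[keep, , drop = FALSE]
}

#' Pooled refolding yield of a dataset
#'
#' Applies the quality filters (at least five initial unfolding steps;
#' equal extension at the end of the initial and test pulses within
#' tolerance), then pools domains across recordings: yield =
#' sum(steps_test) / sum(steps_initial), treating each domain as an
#' independent observation. The standard error is estimated by
#' nonparametric bootstrap over recordings.
#'
#' @param dataset refolding records data.frame (columns
#'   \code{steps_initial}, \code{steps_test}, optionally the final
#'   extension pair).
#' @param qc a \code{\link{yield_qc}}.
#' @param B bootstrap replicates (default 500); \code{B = 0} skips the SEM.
#' @param seed bootstrap seed.
#' @return a list: \code{yield}, \code{sem}, \code{n_recordings},
#'   \code{n_domains}, \code{yield_per_recording} (mean of per-recording
#'   ratios, for comparison).
#' @export
refolding_yield <- function(dataset, qc = yield_qc(), B = 500, seed = 1) {
  if (nrow(dataset) == 0L) stop("empty dataset")
  kept <- .qc_filter(dataset, qc)
  if (nrow(kept) == 0L) stop("all recordings fail quality control")
  yield <- sum(kept$steps_test) / sum(kept$steps_initial)
  sem <- if (B > 0 && nrow(kept) >= 2)
    bootstrap_sem(kept, function(d) sum(d$steps_test) / sum(d$steps_initial),
                  B = B, seed = seed)
    else NA_real_
  list(yield = yield, sem = sem, n_recordings = nrow(kept),
       n_domains = sum(kept$steps_initial),
       yield_per_recording = mean(kept$steps_test / kept$steps_initial))
}

#' Bootstrap standard error of a dataset statistic
#'
#' Resamples recordings (rows) with replacement \code{B} times, treating
#' each recording as an independent data point, and returns the standard
#' deviation of the statistic across resamples.
#'
#' @param dataset data.frame of recordings.
#' @param statistic function mapping a dataset to a scalar.
#' @param B number of resamples (>= 2; default 500).
#' @param seed RNG seed (resampling is reproducible under it).
#' @return the bootstrap SEM.
#' @export
bootstrap_sem <- function(dataset, statistic, B = 500, seed = 1) {
  if (B < 2) stop("B must be >= 2")
  if (nrow(dataset) < 2) stop("need >= 2 recordings to bootstrap")
  set.seed(seed)
  n <- nrow(dataset)
  vals <- vapply(seq_len(B), function(b)
    statistic(dataset[sample.int(n, n, replace = TRUE), , drop = FALSE]), 0)
  stats::sd(vals)
}

#' Weighted exponential fit of a yield curve
#'
#' Fits refolding yield versus time to one of the two standard forms:
#' \itemize{
#'   \item \code{"saturating"}: y = A (1 - exp(-k t)) -- yield versus
#'     quench time t_q; A is the plateau, k the folding rate k_f.
#'   \item \code{"decaying"}: y = Yinf + (Y0 - Yinf) exp(-k t) -- yield
#'     versus extended-hold time t_ext; Yinf is the residual yield, k the
#'     apparent binding relaxation rate.
#' }
#' Weighted nonlinear least squares with 1/sem^2 weights; the start point
#' comes from a log-linearised estimate.
#'
#' @param grid time values (s), >= 3 points.
#' @param yields observed yields (fractions).
#' @param sems per-point standard errors; NULL or all-equal gives an
#'   unweighted fit. Zero SEMs are replaced by the median positive SEM.
#' @param form \code{"saturating"} or \code{"decaying"}.
#' @return a \code{fit_result}; on non-identifiable (flat) data the result
#'   has \code{ok = FALSE} rather than a spurious rate.
#' @examples
#' tq <- c(0.5, 1, 2, 5, 10, 15)
#' y <- 0.75 * (1 - exp(-0.52 * tq))
#' fit_yield_curve(tq, y, form = "saturating")
#' @export
fit_yield_curve <- function(grid, yields, sems = NULL,
                            form = c("saturating", "decaying")) {
  form <- match.arg(form)
  if (length(grid) < 3) stop("need >= 3 points")
  if (length(yields) != length(grid)) stop("grid and yields differ in length")
  w <- if (is.null(sems)) rep(1, length(grid)) else {
    s <- sems
    if (any(s <= 0, na.rm = TRUE) || anyNA(s)) {
      med <- stats::median(s[s > 0], na.rm = TRUE)
      if (!is.finite(med)) med <- 1
      s[!is.finite(s) | s <= 0] <- med
    }
    1 / s^2
  }
  if (stats::sd(yields) < 1e-12)
    return(.fit_result(form, n = length(grid), ok = FALSE,
                       message = "flat data: rate not identifiable"))
  df <- data.frame(t = grid, y = yields)
  fit <- tryCatch({
    if (form == "saturating") {
      A0 <- max(yields) * 1.05
      pos <- yields < A0 & yields > 0
      k0 <- if (sum(pos) >= 2)
        -stats::coef(stats::lm(log(1 - yields[pos] / A0) ~ 0 + grid[pos]))[[1]]
        else 1 / stats::median(grid)
      m <- minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)), data = df,
                             weights = w,
                             start = list(A = min(A0, 1), k = max(k0, 1e-6)),
                             lower = c(0, 1e-9), upper = c(1.5, 1e6))
      s <- summary(m)$coefficients
      .fit_result(form, rate = s["k", "Estimate"],
                  rate_se = s["k", "Std. Error"],
                  amplitude = s["A", "Estimate"], n = length(grid))
    } else {
      Yinf0 <- min(yields) * 0.9
      Y00 <- max(yields)
      span <- pmax(yields - Yinf0, 1e-6)
      k0 <- -stats::coef(stats::lm(log(span / (Y00 - Yinf0)) ~ 0 + grid))[[1]]
      m <- minpack.lm::nlsLM(y ~ Yinf + (Y0 - Yinf) * exp(-k * t), data = df,
                             weights = w,
                             start = list(Yinf = max(Yinf0, 0), Y0 = Y00,
                                          k = max(k0, 1e-6)),
                             lower = c(0, 0, 1e-9), upper = c(1, 1.5, 1e6))
      s <- summary(m)$coefficients
      .fit_result(form, rate = s["k", "Estimate"],
                  rate_se = s["k", "Std. Error"],
                  amplitude = s["Y0", "Estimate"],
                  offset = s["Yinf", "Estimate"], n = length(grid))
    }
  }, error = function(e)
    .fit_result(form, n = length(grid), ok = FALSE,
                message = conditionMessage(e)))
  fit
}

#' Analyse a set of refolding datasets into a results summary
#'
#' Convenience wrapper: computes the pooled yield, SEM and counts per
#' condition and, when a sweep variable is given, fits the corresponding
#' exponential form across conditions.
#'
#' @param datasets named list of refolding record data.frames (one per
#'   condition).
#' @param sweep optional: name of the dataset column that varies across
#'   conditions (\code{"t_q"} or \code{"t_ext"}); selects the saturating
#'   or decaying fit respectively.
#' @param qc a \code{\link{yield_qc}}.
#' @param B bootstrap replicates.
#' @param seed bootstrap seed.
#' @return a list with per-condition summaries and (optionally)
#'   \code{fit}.
#' @export
analyze_refolding <- function(datasets, sweep = NULL, qc = yield_qc(),
                              B = 500, seed = 1) {
  per <- lapply(datasets, refolding_yield, qc = qc, B = B, seed = seed)
  out <- list(conditions = per)
  if (!is.null(sweep) && length(datasets) < 3) {
    message("fewer than 3 conditions: skipping the ", sweep, " curve fit")
    sweep <- NULL
  }
  if (!is.null(sweep)) {
    xs <- vapply(datasets, function(d) d[[sweep]][1], 0)
    ys <- vapply(per, `[[`, 0, "yield")
    ss <- vapply(per, `[[`, 0, "sem")
    form <- if (sweep == "t_ext") "decaying" else "saturating"
    out$fit <- fit_yield_curve(xs, ys, ss, form = form)
    out$curve <- data.frame(x = xs, yield = ys, sem = ss)
    names(out$curve)[1] <- sweep
  }
  out
}
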