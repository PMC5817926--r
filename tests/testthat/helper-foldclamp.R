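# Shared helpers for the test suite.

# Closed-form folded fraction of the irreversible two-step quench chain
# extended -(k_c)-> collapsed -(k_f0)-> folded, starting fully extended.
chain_folded <- function(t, k_c, k_f0) {
  if (abs(k_c - k_f0) < 1e-12) return(1 - exp(-k_c * t) * (1 + k_c * t))
  1 - (k_f0 * exp(-k_c * t) - k_c * exp(-k_f0 * t)) / (k_f0 - k_c)
}

# Greedy matching of detected against true event times within a tolerance;
# returns the number of true positives.
match_events <- function(det_times, true_times, tol = 0.05) {
  used <- rep(FALSE, length(det_times))
  tp <- 0L
  for (tt in true_times) {
    d <- abs(det_times - tt)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}

# Unfolding (folded -> extended-free) event times of a trajectory.
true_unfold_times <- function(trace) {
  ev <- trace$events
  if (is.null(ev)) return(numeric(0))
  ev$time[ev$from == "folded" & ev$to == "ext_free"]
}

# Random kinetic scheme with all transitions active, for property tests.
random_scheme <- function() {
  kinetic_scheme(k_u = runif(1, 0.1, 5), k_c = runif(1, 0.5, 20),
                 k_f0 = runif(1, 0.05, 2), k_uc = runif(1, 5, 100),
                 k_on_ext = 10^runif(1, 3, 6), k_on_coll = 10^runif(1, 3, 6),
                 k_off_ext = 10^runif(1, -2, 0), k_off_coll = 10^runif(1, -2, 0),
                 chaperone_conc = 10^runif(1, -7, -5))
}

# Brute-force checker for the DnaJ consensus: tests one 7-mer against the
# position rules written out longhand.
brute_force_dnaj <- function(kmer) {
  aa <- strsplit(kmer, "")[[1]]
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  length(aa) == 7 &&
    aa[1] == "G" &&
    aa[2] %in% std &&
    aa[3] %in% c("L", "M", "Q") &&
    (aa[4] %in% std && aa[4] != "P") &&
    aa[5] %in% std &&
    (aa[6] %in% std && aa[6] != "P") &&
    (aa[7] %in% std && !aa[7] %in% c("C", "I", "M", "P", "V", "W"))
}
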