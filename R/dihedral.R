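# Dihedral-remodeling free-energy estimator.
#
# Per-residue (phi, psi) backbone dihedral samples -- normally harvested
# from force-conditioned MD, here drawn from force-dependent von Mises
# mixtures -- give, at each force, the probability of observing the
# chaperone-bound dihedral values. The free-energy cost of remodeling the
# fragment backbone to its bound geometry is the summed negative
# log-density over the constrained (phi, psi) couples, in kBT, averaged
# over replicates and normalised so the minimum over force is zero.

#' Free-energy profile versus force
#'
#' @param force forces (pN), strictly increasing.
#' @param dg_mean mean remodeling free energies (kBT) per force.
#' @param dg_sd replicate standard deviations (kBT); 0 when only one
#'   replicate.
#' @param normalized whether \code{dg_mean} has been shifted so its
#'   minimum is exactly 0.
#' @return an object of class \code{energy_profile}.
#' @export
energy_profile <- function(force, dg_mean, dg_sd = rep(0, length(force)),
                           normalized = FALSE) {
  stopifnot(length(force) == length(dg_mean),
            length(force) == length(dg_sd))
  if (is.unsorted(force, strictly = TRUE)) stop("forces must be strictly increasing")
  if (any(dg_sd < 0)) stop("SDs must be >= 0")
  if (normalized && abs(min(dg_mean)) > 1e-9)
    stop("normalized profile must have minimum 0")
  structure(list(force = force, dg_mean = dg_mean, dg_sd = dg_sd,
                 normalized = normalized),
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat("Dihedral-remodeling free-energy profile",
      if (x$normalized) "(normalized)" else "(raw)", "\n")
  print(data.frame(force_pN = x$force, dG_kBT = round(x$dg_mean, 3),
                   sd_kBT = round(x$dg_sd, 3)))
  invisible(x)
}

# Wrap angles into (-180, 180].
.wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# von Mises sampler (Best & Fisher 1979 rejection scheme), angles in
# degrees. kappa = 0 falls back to the circular uniform.
.rvm_deg <- function(n, mu_deg, kappa) {
  if (kappa <= 0) return(runif(n, -180, 180))
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok]) + mu
      take <- seq_len(sum(ok))
      out[got + take] <- th
      got <- got + sum(ok)
    }
  }
  .wrap180(out * 180 / pi)
}

# von Mises density per degree.
.dvm_deg <- function(theta_deg, mu_deg, kappa) {
  th <- theta_deg * pi / 180
  mu <- mu_deg * pi / 180
  exp(kappa * cos(th - mu)) / (2 * pi * besselI(kappa, 0)) * pi / 180
}

#' Analytic (phi, psi) mixture density of a basin specification
#'
#' Product-von Mises mixture density per square degree, used as the
#' closed-form reference for the estimators.
#'
#' @param phi,psi angles in degrees.
#' @param components data.frame with columns \code{mu_phi}, \code{mu_psi},
#'   \code{kappa_phi}, \code{kappa_psi}, \code{weight}.
#' @return density values (1/deg^2).
#' @export
vm_mixture_density <- function(phi, psi, components) {
  w <- components$weight / sum(components$weight)
  dens <- 0
  for (i in seq_len(nrow(components)))
    dens <- dens + w[i] *
      .dvm_deg(phi, components$mu_phi[i], components$kappa_phi[i]) *
      .dvm_deg(psi, components$mu_psi[i], components$kappa_psi[i])
  dens
}

#' Basin specification for the synthetic dihedral generator
#'
#' Each residue carries one or more product-von Mises components in
#' (phi, psi) whose mixture weights depend on force. The default spec
#' models the five constrained couples of the ubiquitin-DnaJ consensus
#' fragment (LYS48-ASP52): GLN49 and LEU50 occupy a compact low-force
#' basin and move into the extended beta/PPII basin as force rises
#' (sigmoid midpoint 100 pN), while LYS48, GLU51 and ASP52 start in
#' helical-region basins favoured at low force and are pushed toward
#' extended values only at high force (midpoint 200 pN). With the bound
#' reference taken as the beta values for GLN49/LEU50 and the low-force
#' values for the other three, the remodeling cost is high at both force
#' extremes and minimal at intermediate force.
#'
#' @param residues residue labels.
#' @param components named list (per residue) of data.frames with columns
#'   \code{mu_phi}, \code{mu_psi}, \code{kappa_phi}, \code{kappa_psi} and
#'   \code{midpoint}, \code{width} (pN) of the logistic weight of the
#'   *second* (high-force) component; single-component residues omit the
#'   sigmoid columns.
#' @return a list of class \code{basin_spec}.
#' @export
basin_spec_default <- function() {
  two_state <- function(mu1p, mu1s, mu2p, mu2s, mid, width = 30,
                        kappa = 8) {
    data.frame(mu_phi = c(mu1p, mu2p), mu_psi = c(mu1s, mu2s),
               kappa_phi = kappa, kappa_psi = kappa,
               midpoint = mid, width = width)
  }
  spec <- list(
    LYS48 = two_state(-65, -35, -150, 155, mid = 200),
    GLN49 = two_state(-70, -20, -120, 130, mid = 100),
    LEU50 = two_state(-75, -15, -125, 135, mid = 100),
    GLU51 = two_state(-60, -40, -155, 150, mid = 200),
    ASP52 = two_state(-65, -30, -145, 160, mid = 200))
  structure(spec, class = "basin_spec")
}

#' Bound-reference dihedrals of the consensus fragment
#'
#' The (phi*, psi*) values each constrained residue adopts in the
#' chaperone-substrate complex. These are inputs (in a real study they
#' come from a simulation of the bound complex); the default pairs with
#' \code{\link{basin_spec_default}}: the beta-basin values for
#' GLN49/LEU50 and the low-force-basin values for LYS48/GLU51/ASP52.
#'
#' @param spec a \code{basin_spec} (used for residue names and defaults).
#' @return data.frame with columns \code{residue}, \code{phi}, \code{psi}.
#' @export
bound_reference_default <- function(spec = basin_spec_default()) {
  pick <- function(res, comp) data.frame(
    residue = res, phi = spec[[res]]$mu_phi[comp],
    psi = spec[[res]]$mu_psi[comp])
  rbind(pick("LYS48", 1), pick("GLN49", 2), pick("LEU50", 2),
        pick("GLU51", 1), pick("ASP52", 1))
}

# Mixture weights of a residue's components at a force.
.basin_weights <- function(comp, force) {
  if (nrow(comp) == 1L) return(1)
  w2 <- 1 / (1 + exp(-(force - comp$midpoint[1]) / comp$width[1]))
  w <- c(1 - w2, w2)
  if (nrow(comp) > 2L) stop("at most two components per residue supported")
  if (any(!is.finite(w)) || sum(w) <= 0) stop("weights not normalizable")
  w / sum(w)
}

#' Generate synthetic per-residue dihedral samples
#'
#' Draws (phi, psi) samples from the force-dependent von Mises mixtures of
#' a basin specification, for every residue, force and replicate --
#' a synthetic stand-in for force-conditioned MD sampling.
#'
#' @param spec a \code{basin_spec} (see \code{\link{basin_spec_default}}).
#' @param forces force grid in pN.
#' @param n_per_replicate samples per (residue, force, replicate).
#' @param replicates number of independent replicates (default 5).
#' @param seed RNG seed.
#' @return a data.frame of class \code{dihedral_samples} with columns
#'   \code{residue}, \code{force}, \code{replicate}, \code{phi},
#'   \code{psi}.
#' @export
generate_dihedral_samples <- function(spec = basin_spec_default(),
                                      forces = seq(50, 300, by = 50),
                                      n_per_replicate = 4000,
                                      replicates = 5, seed = 1) {
  set.seed(seed)
  out <- vector("list", length(spec) * length(forces) * replicates)
  k <- 0L
  for (res in names(spec)) {
    comp <- spec[[res]]
    for (f in forces) {
      w <- .basin_weights(comp, f)
      for (r in seq_len(replicates)) {
        ci <- sample.int(nrow(comp), n_per_replicate, replace = TRUE, prob = w)
        phi <- psi <- numeric(n_per_replicate)
        for (i in seq_len(nrow(comp))) {
          sel <- ci == i
          if (!any(sel)) next
          phi[sel] <- .rvm_deg(sum(sel), comp$mu_phi[i], comp$kappa_phi[i])
          psi[sel] <- .rvm_deg(sum(sel), comp$mu_psi[i], comp$kappa_psi[i])
        }
        k <- k + 1L
        out[[k]] <- data.frame(residue = res, force = f, replicate = r,
                               phi = phi, psi = psi)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("dihedral_samples", "data.frame")
  res
}

#' Periodic 2D density estimate on the (phi, psi) torus
#'
#' Two estimators are available. \code{"hist"}: 2D histogram with
#' \code{bin} - degree bins and a Laplace pseudo-count (so the density is
#' strictly positive everywhere, and bound-reference lookups can never hit
#' zero support). \code{"vm_kde"}: product von Mises kernel density with
#' concentration \code{kde_kappa}, smoother and preferred when evaluating
#' the density at isolated points.
#'
#' @param phi,psi sample angles in degrees, >= 100 samples.
#' @param method \code{"hist"} or \code{"vm_kde"}.
#' @param bin histogram bin width in degrees (must divide 360).
#' @param pseudo Laplace pseudo-count added to every histogram bin.
#' @param kde_kappa kernel concentration for \code{"vm_kde"}.
#' @return a function \code{f(phi, psi)} returning the density per square
#'   degree (integrates to 1 over the torus); the histogram grid or kernel
#'   settings are attached as attributes.
#' @export
estimate_density <- function(phi, psi, method = c("hist", "vm_kde"),
                             bin = 5, pseudo = 1, kde_kappa = 200) {
  method <- match.arg(method)
  n <- length(phi)
  if (n < 100L) stop("need >= 100 samples for a density estimate")
  if (length(psi) != n) stop("phi and psi differ in length")
  phi <- .wrap180(phi); psi <- .wrap180(psi)
  if (method == "hist") {
    nb <- round(360 / bin)
    if (abs(nb * bin - 360) > 1e-9) stop("bin width must divide 360")
    ix <- pmin(pmax(ceiling((phi + 180) / bin), 1L), nb)
    iy <- pmin(pmax(ceiling((psi + 180) / bin), 1L), nb)
    counts <- matrix(0, nb, nb)
    tab <- table(factor(ix, levels = 1:nb), factor(iy, levels = 1:nb))
    counts[] <- as.numeric(tab)
    dens <- (counts + pseudo) / (n + pseudo * nb * nb) / bin^2
    f <- function(phi, psi) {
      phi <- .wrap180(phi); psi <- .wrap180(psi)
      i <- pmin(pmax(ceiling((phi + 180) / bin), 1L), nb)
      j <- pmin(pmax(ceiling((psi + 180) / bin), 1L), nb)
      dens[cbind(i, j)]
    }
    attr(f, "grid") <- dens
    attr(f, "bin") <- bin
  } else {
    sphi <- phi; spsi <- psi; kap <- kde_kappa
    f <- function(phi, psi) {
      phi <- .wrap180(phi); psi <- .wrap180(psi)
      vapply(seq_along(phi), function(i)
        mean(.dvm_deg(phi[i], sphi, kap) * .dvm_deg(psi[i], spsi, kap)), 0)
    }
    attr(f, "kappa") <- kde_kappa
  }
  attr(f, "method") <- method
  attr(f, "n") <- n
  f
}

#' Free-energy cost of remodeling the backbone to its bound dihedrals
#'
#' For each force and replicate, estimates the joint log-probability of
#' finding every constrained residue at its bound (phi*, psi*) value and
#' returns the remodeling cost
#' dG(F) = -sum over residues of log p[residue, F](phi*, psi*) in kBT.
#' The replicate mean and SD are computed per force on the raw values;
#' the mean profile is then shifted so its minimum over force is zero.
#'
#' @param samples a \code{dihedral_samples} data.frame.
#' @param ref bound reference: data.frame with \code{residue}, \code{phi},
#'   \code{psi}; its residues must all be present in \code{samples}.
#' @param method,... passed to \code{\link{estimate_density}}.
#' @param normalize shift the mean profile to a zero minimum (the
#'   convention used for reporting; disable to keep raw values).
#' @return an \code{\link{energy_profile}}; per-replicate raw values in
#'   \code{attr(, "replicates")}.
#' @export
delta_g <- function(samples, ref, method = "vm_kde", normalize = TRUE, ...) {
  if (!all(ref$residue %in% samples$residue))
    stop("reference residues missing from samples: ",
         paste(setdiff(ref$residue, samples$residue), collapse = ", "))
  forces <- sort(unique(samples$force))
  reps <- sort(unique(samples$replicate))
  vals <- matrix(NA_real_, length(reps), length(forces),
                 dimnames = list(reps, forces))
  for (fi in seq_along(forces)) {
    for (ri in seq_along(reps)) {
      dg <- 0
      for (j in seq_len(nrow(ref))) {
        sub <- samples[samples$residue == ref$residue[j] &
                       samples$force == forces[fi] &
                       samples$replicate == reps[ri], ]
        f <- estimate_density(sub$phi, sub$psi, method = method, ...)
        p <- f(ref$phi[j], ref$psi[j])
        if (p <= 0)
          stop("bound reference falls in a zero-support region; ",
               "use method = 'hist' with a pseudo-count or 'vm_kde'")
        dg <- dg - log(p)
      }
      vals[ri, fi] <- dg
    }
  }
  mu <- unname(colMeans(vals))
  sdv <- if (length(reps) > 1) unname(apply(vals, 2, stats::sd))
         else rep(0, length(forces))
  if (normalize) mu <- mu - min(mu)
  prof <- energy_profile(forces, mu, sdv, normalized = normalize)
  attr(prof, "replicates") <- vals
  prof
}

#' Classify a backbone conformation into a Ramachandran region
#'
#' Rectangular-region classification: \code{beta/PPII} is the extended
#' top-left region (phi in [-180, -45), psi in [45, 180] or
#' psi in [-180, -150)); \code{alphaR} the right-handed helical region
#' (phi in [-180, -20), psi in [-120, 45)); \code{alphaL} the left-handed
#' helical region (phi in (0, 150], psi in [-30, 100)); everything else is
#' \code{other}.
#'
#' @param phi,psi angles in degrees (vectorised).
#' @return character vector of region labels.
#' @examples
#' ramachandran_classify(-120, 130)  # beta/PPII
#' ramachandran_classify(-60, -45)   # alphaR
#' @export
ramachandran_classify <- function(phi, psi) {
  phi <- .wrap180(phi); psi <- .wrap180(psi)
  out <- rep("other", length(phi))
  out[phi >= -180 & phi < -45 & (psi >= 45 | psi < -150)] <- "beta/PPII"
  out[phi >= -180 & phi < -20 & psi >= -120 & psi < 45] <- "alphaR"
  out[phi > 0 & phi <= 150 & psi >= -30 & psi < 100] <- "alphaL"
  out
}

#' Write / read dihedral samples as TSV
#'
#' Columns: residue, force_pN, replicate, phi_deg, psi_deg.
#' @param samples a \code{dihedral_samples} data.frame.
#' @param path file path.
#' @return \code{path} (write) or the samples (read).
#' @export
write_dihedral_samples <- function(samples, path) {
  df <- data.frame(residue = samples$residue, force_pN = samples$force,
                   replicate = samples$replicate, phi_deg = samples$phi,
                   psi_deg = samples$psi)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# schema=fc-dihedral/1", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dihedral_samples
#' @export
read_dihedral_samples <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  out <- data.frame(residue = df$residue, force = df$force_pN,
                    replicate = df$replicate, phi = df$phi_deg,
                    psi = df$psi_deg)
  class(out) <- c("dihedral_samples", "data.frame")
  out
}
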