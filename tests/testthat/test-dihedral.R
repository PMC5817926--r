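test_that("Ramachandran classification matches the canonical-angle table", {
  canon <- data.frame(
    phi = c(-120, -135, -75, -60, -90, 60, 50, 100, -170),
    psi = c(130, 150, 160, -45, 0, 45, 30, -120, -170),
    region = c("beta/PPII", "beta/PPII", "beta/PPII", "alphaR", "alphaR",
               "alphaL", "alphaL", "other", "beta/PPII"))
  expect_equal(ramachandran_classify(canon$phi, canon$psi), canon$region)
})

test_that("von Mises generator hits its target moments and seed", {
  s1 <- generate_dihedral_samples(n_per_replicate = 500, replicates = 2,
                                  seed = 12)
  s2 <- generate_dihedral_samples(n_per_replicate = 500, replicates = 2,
                                  seed = 12)
  expect_identical(s1, s2)

  # single-component residue: circular mean within 2 degrees at n = 10000
  spec <- structure(list(RES1 = data.frame(mu_phi = -70, mu_psi = 140,
                                           kappa_phi = 6, kappa_psi = 6)),
                    class = "basin_spec")
  s <- generate_dihedral_samples(spec, forces = 100,
                                 n_per_replicate = 10000, replicates = 1,
                                 seed = 3)
  circ_mean <- function(a) atan2(mean(sin(a * pi / 180)),
                                 mean(cos(a * pi / 180))) * 180 / pi
  expect_lt(abs(circ_mean(s$phi) - (-70)), 2)
  expect_lt(abs(circ_mean(s$psi) - 140), 2)

  # kappa = 0 gives a uniform marginal (tiny resultant length)
  spec0 <- structure(list(RES1 = data.frame(mu_phi = 0, mu_psi = 0,
                                            kappa_phi = 0, kappa_psi = 0)),
                     class = "basin_spec")
  s0 <- generate_dihedral_samples(spec0, forces = 100,
                                  n_per_replicate = 20000, replicates = 1,
                                  seed = 4)
  R <- sqrt(mean(cos(s0$phi * pi / 180))^2 + mean(sin(s0$phi * pi / 180))^2)
  expect_lt(R, 0.02)
})

test_that("density estimates integrate to one, are uniform-consistent and periodic", {
  set.seed(21)
  phi_u <- runif(20000, -180, 180)
  psi_u <- runif(20000, -180, 180)
  f <- estimate_density(phi_u, psi_u, method = "hist")
  expect_equal(sum(attr(f, "grid")) * 5^2, 1, tolerance = 1e-9)
  # flat within estimator error: the average over many probe points is
  # 1/360^2 and no single bin strays beyond Poisson scatter
  probes_phi <- runif(300, -180, 180)
  probes_psi <- runif(300, -180, 180)
  dens <- f(probes_phi, probes_psi)
  expect_equal(mean(dens), 1 / 360^2, tolerance = 0.1)
  expect_lt(max(abs(dens - 1 / 360^2)), 3 / 360^2)

  # wrap-around: a mode straddling +/-180 is a single seam mode
  phi_s <- foldclamp:::.wrap180(179 + rnorm(5000, 0, 4))
  psi_s <- foldclamp:::.wrap180(-179 + rnorm(5000, 0, 4))
  g <- estimate_density(phi_s, psi_s, method = "vm_kde")
  expect_gt(g(180, 180), 50 * g(0, 0))
  expect_gt(g(-179, 179), g(0, 0) * 50)

  expect_error(estimate_density(runif(50, -180, 180), runif(50, -180, 180)),
               "100 samples")
})

test_that("estimated log-density at a von Mises mode matches the closed form", {
  set.seed(9)
  comp <- data.frame(mu_phi = -70, mu_psi = 140, kappa_phi = 4,
                     kappa_psi = 4, weight = 1)
  phi <- foldclamp:::.rvm_deg(20000, -70, 4)
  psi <- foldclamp:::.rvm_deg(20000, 140, 4)
  f <- estimate_density(phi, psi, method = "vm_kde")
  expect_equal(log(f(-70, 140)), log(vm_mixture_density(-70, 140, comp)),
               tolerance = 0.1)
})

test_that("remodeling free energy reproduces analytic log-density differences", {
  # two forces shift a two-basin mixture away from the bound reference;
  # the Delta-G difference must equal the analytic difference
  spec <- structure(list(RES1 = data.frame(
    mu_phi = c(-70, -130), mu_psi = c(-30, 140),
    kappa_phi = 5, kappa_psi = 5, midpoint = 150, width = 40)),
    class = "basin_spec")
  ref <- data.frame(residue = "RES1", phi = -130, psi = 140)
  forces <- c(50, 250)
  s <- generate_dihedral_samples(spec, forces = forces,
                                 n_per_replicate = 20000, replicates = 1,
                                 seed = 8)
  prof <- delta_g(s, ref, method = "vm_kde", normalize = FALSE)
  analytic <- vapply(forces, function(f) {
    w <- foldclamp:::.basin_weights(spec$RES1, f)
    comp <- transform(spec$RES1, weight = w)
    -log(vm_mixture_density(-130, 140, comp))
  }, 0)
  expect_equal(diff(prof$dg_mean), diff(analytic), tolerance = 0.1)

  # delta-like sampling at the reference marks the profile minimum
  spec2 <- structure(list(RES1 = data.frame(
    mu_phi = c(-130, -70), mu_psi = c(140, -30),
    kappa_phi = 40, kappa_psi = 40, midpoint = 150, width = 30)),
    class = "basin_spec")
  s2 <- generate_dihedral_samples(spec2, forces = c(50, 150, 250),
                                  n_per_replicate = 3000, replicates = 2,
                                  seed = 5)
  # reference sits in the low-force basin: minimum must be at 50 pN
  prof2 <- delta_g(s2, ref, method = "vm_kde")
  expect_equal(prof2$force[which.min(prof2$dg_mean)], 50)
  expect_equal(min(prof2$dg_mean), 0)
})

test_that("normalization pins the minimum at zero and preserves differences", {
  samp <- generate_dihedral_samples(n_per_replicate = 1200, replicates = 2,
                                    seed = 31)
  raw <- delta_g(samp, bound_reference_default(), method = "vm_kde",
                 normalize = FALSE)
  norm <- delta_g(samp, bound_reference_default(), method = "vm_kde",
                  normalize = TRUE)
  expect_equal(min(norm$dg_mean), 0)
  expect_equal(diff(norm$dg_mean), diff(raw$dg_mean), tolerance = 1e-9)
  # SDs are computed before normalization and unchanged by it
  expect_equal(norm$dg_sd, raw$dg_sd)
  # the default study design yields an interior (intermediate-force) minimum
  k <- which.min(norm$dg_mean)
  expect_gt(k, 1)
  expect_lt(k, length(norm$force))
})

test_that("replicate scatter shrinks with sample size", {
  spec <- structure(list(RES1 = data.frame(mu_phi = -70, mu_psi = 140,
                                           kappa_phi = 5, kappa_psi = 5)),
                    class = "basin_spec")
  ref <- data.frame(residue = "RES1", phi = -70, psi = 140)
  sd_at <- function(n, seed) {
    s <- generate_dihedral_samples(spec, forces = 100, n_per_replicate = n,
                                   replicates = 6, seed = seed)
    delta_g(s, ref, method = "vm_kde", normalize = FALSE)$dg_sd
  }
  ratio <- sd_at(400, 2) / sd_at(3600, 2)
  expect_gt(ratio, 1.3) # ~3 expected for a 9x sample-size ratio
  expect_lt(ratio, 7)
})

test_that("dihedral samples round-trip through TSV", {
  s <- generate_dihedral_samples(n_per_replicate = 200, replicates = 1,
                                 forces = c(50, 150), seed = 2)
  td <- withr::local_tempdir()
  p <- file.path(td, "dihedrals.tsv")
  write_dihedral_samples(s, p)
  back <- read_dihedral_samples(p)
  expect_equal(back$phi, s$phi, tolerance = 1e-6)
  expect_equal(back$residue, s$residue)
  expect_equal(back$force, s$force)
})
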