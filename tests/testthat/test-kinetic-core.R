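test_that("rate matrix is a proper generator in both force regimes", {
  set.seed(101)
  for (i in 1:20) {
    sch <- random_scheme()
    for (f in c(0, 120)) {
      Q <- rate_matrix(sch, f)
      expect_equal(colSums(Q), setNames(rep(0, 5), colnames(Q)),
                   tolerance = 1e-12)
      off <- Q
      diag(off) <- 0
      expect_true(all(off >= 0))
    }
  }
})

test_that("regime rules gate the allowed transitions", {
  sch <- kinetic_scheme(k_on_ext = 1e5, k_off_ext = 0.1, k_on_coll = 1e5,
                        k_off_coll = 0.1, chaperone_conc = 1e-6)
  Qp <- rate_matrix(sch, 120)
  # no folding or collapse under force
  expect_equal(Qp["folded", "coll_free"], 0)
  expect_equal(Qp["coll_free", "ext_free"], 0)
  expect_equal(Qp["ext_free", "folded"], sch$k_u)
  expect_equal(Qp["ext_free", "coll_free"], sch$k_uc)
  expect_equal(Qp["ext_bound", "coll_bound"], sch$k_uc)
  Qq <- rate_matrix(sch, 0)
  # no unfolding or re-extension at quench; bound states never fold
  expect_equal(Qq["ext_free", "folded"], 0)
  expect_equal(Qq["ext_free", "coll_free"], 0)
  expect_equal(Qq["folded", "coll_bound"], 0)
  expect_equal(Qq["folded", "ext_bound"], 0)
  expect_equal(Qq["coll_bound", "ext_bound"], 0) # bound chain cannot collapse
  expect_equal(Qq["folded", "coll_free"], sch$k_f0)

  # no-chaperone limit: all binding fluxes vanish
  Q0 <- rate_matrix(kinetic_scheme(chaperone_conc = 0, k_on_ext = 1e6,
                                   k_on_coll = 1e6, k_off_ext = 0,
                                   k_off_coll = 0), 0)
  bound <- c("ext_bound", "coll_bound")
  expect_true(all(Q0[bound, ] == 0) && all(Q0[, bound] == 0))

  # quench with k_c = 0: extended-free is absorbing among free states
  Qa <- rate_matrix(kinetic_scheme(k_c = 0, chaperone_conc = 0), 0)
  expect_equal(Qa[, "ext_free"], setNames(rep(0, 5), rownames(Qa)))

  expect_error(kinetic_scheme(k_u = -1), "rate")
  expect_error(kinetic_scheme(chaperone_conc = -1e-6), "chaperone_conc")
  expect_error(rate_matrix(kinetic_scheme(), -5), "force")
})

test_that("propagate conserves probability and matches the quench chain closed form", {
  set.seed(202)
  pr <- force_quench_protocol(t_unfold = 2, t_ext = 3, t_q = 4, t_test = 2)
  for (i in 1:5) {
    sol <- propagate(random_scheme(), pr)
    expect_true(all(abs(rowSums(sol[, 4:8]) - 1) < 1e-9))
    expect_true(all(sol[, 4:8] > -1e-12))
  }

  # all-folded at zero force: nothing happens
  quench_only <- force_protocol(data.frame(label = "quench", force = 0,
                                           duration = 5))
  sol <- propagate(kinetic_scheme(), quench_only, init = pure_state("folded"))
  expect_equal(sol$folded, rep(1, nrow(sol)), tolerance = 1e-12)

  # irreversible two-exponential chain against the analytic solution
  k_c <- 2.4; k_f0 <- 0.7
  sch <- kinetic_scheme(k_c = k_c, k_f0 = k_f0, chaperone_conc = 0)
  sol <- propagate(sch, quench_only, init = pure_state("ext_free"))
  expect_equal(sol$folded, chain_folded(sol$time, k_c, k_f0),
               tolerance = 1e-9)

  # long quench, no chaperone: folded fraction approaches 1
  long_q <- force_protocol(data.frame(label = "quench", force = 0,
                                      duration = 60))
  sol <- propagate(sch, long_q, init = pure_state("ext_free"))
  expect_equal(tail(sol$folded, 1), 1, tolerance = 1e-6)
})

test_that("piecewise propagation is segment-composable", {
  sch <- dnaj_scheme()
  prAB <- force_quench_protocol(t_unfold = 3, t_q = 4, t_test = 0)
  end_AB <- tail(propagate(sch, prAB), 1)
  prA <- force_protocol(data.frame(label = "unfold", force = 120, duration = 3))
  prB <- force_protocol(data.frame(label = "quench", force = 0, duration = 4))
  mid <- unlist(tail(propagate(sch, prA), 1)[, 4:8])
  end_B <- tail(propagate(sch, prB, init = population_state(mid)), 1)
  expect_equal(unlist(end_AB[, 4:8]), unlist(end_B[, 4:8]), tolerance = 1e-9)
})

test_that("binding equilibrates to the law-of-mass-action bound fraction", {
  # only binding/unbinding active on the extended state
  sch <- kinetic_scheme(k_u = 0, k_c = 0, k_f0 = 0, k_uc = 0,
                        k_on_ext = 1e5, k_off_ext = 0.05,
                        chaperone_conc = 2e-6)
  long_q <- force_protocol(data.frame(label = "quench", force = 0,
                                      duration = 2000))
  sol <- propagate(sch, long_q, init = pure_state("ext_free"))
  expected_bound <- sch$chaperone_conc / (sch$chaperone_conc + Kd(sch, "ext"))
  expect_equal(tail(sol$ext_bound, 1), expected_bound, tolerance = 1e-6)
})

test_that("predicted yield behaves across quench-time limits and is monotone", {
  sch <- kinetic_scheme(fold_competence = 0.75, chaperone_conc = 0)
  long <- force_quench_protocol(t_unfold = 0, t_q = 200, t_test = 0)
  expect_equal(predict_yield(sch, long), 0.75, tolerance = 1e-6)

  none <- force_quench_protocol(t_unfold = 0, t_ext = 2, t_q = 0, t_test = 0)
  expect_equal(predict_yield(sch, none), 0) # still extended at quench start

  tq <- c(0.25, 0.5, 1, 2, 4, 8, 16)
  ys <- vapply(tq, function(q)
    predict_yield(sch, force_quench_protocol(t_unfold = 0, t_q = q,
                                             t_test = 0)), 0)
  expect_true(all(diff(ys) >= 0))
  expect_error(propagate(sch, structure(list(segments = data.frame()),
                                        class = "force_protocol")), "empty")
})

test_that("equilibrium unbound fraction follows Kd/(Kd + c)", {
  expect_equal(equilibrium_unbound_fraction(1e-7, 0), 1.0)
  expect_equal(equilibrium_unbound_fraction(3e-6, 3e-6), 0.5)
  expect_error(equilibrium_unbound_fraction(0, 1e-6), "K_d")
  expect_error(equilibrium_unbound_fraction(1e-7, -1), "conc")
})

test_that("pseudo-first-order rate matches the model's yield decay in t_ext", {
  expect_equal(pseudo_first_order_rate(0, 0.3, 1e-5), 0.3)
  expect_equal(pseudo_first_order_rate(1e5, 0, 0), 0)
  expect_error(pseudo_first_order_rate(-1, 0, 0))

  # with collapse and folding much faster than binding, the yield decay
  # rate in t_ext equals k_on * conc + k_off
  sch <- kinetic_scheme(k_c = 50, k_f0 = 20, k_on_ext = 1e5,
                        k_off_ext = 0.01, chaperone_conc = 5e-6)
  k_expected <- pseudo_first_order_rate(1e5, 0.01, 5e-6)
  te <- c(0.5, 1, 2, 4, 6, 9, 12)
  ys <- vapply(te, function(x)
    predict_yield(sch, force_quench_protocol(t_unfold = 0, t_ext = x,
                                             t_q = 5, t_test = 0)), 0)
  fit <- fit_yield_curve(te, ys, form = "decaying")
  expect_true(fit$ok)
  expect_equal(fit$rate, k_expected, tolerance = 0.05)
})

test_that("energy-profile multiplier is Boltzmann and feeds the force sweep", {
  prof <- energy_profile(c(50, 100, 150, 200, 250, 300),
                         c(3, 1.2, 0, 1.5, 4, 8), normalized = TRUE)
  expect_equal(kon_multiplier_from_energy(prof, 150), 1.0)
  expect_equal(kon_multiplier_from_energy(prof, 50), exp(-3))
  expect_error(kon_multiplier_from_energy(prof, 400), "outside")
  expect_equal(kon_multiplier_from_energy(prof, 400, extrapolate = TRUE),
               exp(-8))

  # binding is strongest -- and predicted refolding lowest -- at the force
  # where the remodeling cost is minimal
  sch <- dnaj_scheme(kon_force_profile = prof)
  forces <- c(50, 100, 150, 200, 250, 300)
  ys <- vapply(forces, function(f)
    predict_yield(sch, force_quench_protocol(t_unfold = 0, extend_force = f,
                                             t_ext = 15, t_q = 5,
                                             t_test = 0)), 0)
  expect_equal(forces[which.min(ys)], 150)
  # higher yield at both force extremes than at the optimum-binding force
  expect_gt(ys[1], min(ys) + 0.05)
  expect_gt(ys[6], min(ys) + 0.05)
})
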