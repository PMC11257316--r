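test_that("trajectories start from the canonical initial state", {
  tr <- tr_split()
  expect_equal(unlist(tr[1, c("S", "I", "E", "X", "Y", "P", "Q")]),
               c(S = 1, I = 1, E = 1, X = 0, Y = 0, P = 0, Q = 0))
  expect_true(all(diff(tr$tau) > 0))
})

test_that("conservation planes hold to integrator accuracy", {
  res <- conservation_residuals(tr_split())
  expect_lt(res$res_VPS, 1e-6)
  expect_lt(res$res_UQI, 1e-6)
  expect_lt(res$res_E, 1e-6)
  # Euler at dtau = 1e-5 is first-order accurate
  te <- simulate_full(ps_timescale_split(), tau_end = 2, method = "euler")
  rese <- conservation_residuals(te)
  expect_lt(rese$res_VPS, 1e-3)
  expect_lt(rese$res_UQI, 1e-3)
})

test_that("products are monotone and reactants deplete", {
  # products are strictly monotone; reactants may rise transiently by a
  # hair when complex dissociation balances binding (bimodal regime), so
  # their bound is looser
  for (tr in list(tr_split(), tr_bimS(), tr_part())) {
    expect_true(all(diff(tr$P) > -1e-9))
    expect_true(all(diff(tr$S) < 1e-4))
    if ("Q" %in% names(tr)) {
      expect_true(all(diff(tr$Q) > -1e-9))
      expect_true(all(diff(tr$I) < 1e-4))
    }
  }
  tr <- tr_split()
  expect_lt(tr$S[nrow(tr)], 1e-2)
  expect_gt(tr$P[nrow(tr)], 0.99)
})

test_that("Euler scheme matches the reference integrator", {
  p <- ps_timescale_split()
  # the EI channel is the stiff one here; a step well under the 1e-5
  # ceiling keeps the first-order error inside the 1e-4 band
  te <- simulate_full(p, tau_end = 2, dtau = 2e-6, method = "euler")
  tr <- simulate_full(p, tau_end = 2, n_out = 8000)
  expect_lt(max(abs(traj_at(tr, te$tau, "X") - te$X)), 1e-4)
  expect_lt(max(abs(traj_at(tr, te$tau, "Y") - te$Y)), 1e-4)
  pp <- ps_partial()
  tep <- simulate_partial(pp, tau_end = 2, method = "euler")
  trp <- simulate_partial(pp, tau_end = 2, n_out = 8000)
  expect_lt(max(abs(traj_at(trp, tep$tau, "X") - tep$X)), 1e-4)
  expect_lt(max(abs(traj_at(trp, tep$tau, "Y") - tep$Y)), 1e-4)
})

test_that("coarse Euler steps are refused", {
  expect_error(simulate_full(ps_timescale_split(), dtau = 1e-3,
                             method = "euler"), "dtau")
})

test_that("steady-state events split into primary and secondary maxima", {
  ev2 <- ev_of("split", tr_split)
  mxS <- ev2[ev2$channel == "substrate" & ev2$type == "maximum", ]
  mxI <- ev2[ev2$channel == "inhibitor" & ev2$type == "maximum", ]
  expect_equal(nrow(mxS), 1)
  expect_equal(nrow(mxI), 1)
  expect_lt(mxI$tau, mxS$tau)  # EI complex peaks first here
  expect_equal(mxS$order, "primary")
})

test_that("a monotone trajectory yields no events and degenerate input errors", {
  fake <- ciket:::.new_trajectory(
    tibble::tibble(tau = seq(0, 1, length.out = 50),
                   S = exp(-seq(0, 1, length.out = 50)),
                   I = 1, E = 1,
                   X = exp(-seq(0, 1, length.out = 50)),
                   Y = exp(-2 * seq(0, 1, length.out = 50)),
                   P = seq(0, 1, length.out = 50), Q = 0,
                   V = 0, U = 0),
    "full", ps_symmetric(), "reference")
  expect_equal(nrow(detect_steady_states(fake)), 0)
  expect_error(detect_steady_states(fake[1:2, ]), "at least 3")
})

test_that("a corrupted product channel is flagged by the residuals", {
  tr <- tr_split()
  bad <- tr
  bad$P <- bad$P + 0.1
  expect_equal(conservation_residuals(bad)$res_VPS, 0.1, tolerance = 1e-6)
})

test_that("partial trajectories reach the EI binding equilibrium", {
  tr <- tr_part()
  eq <- partial_equilibrium(ps_partial())
  expect_lt(abs(tr$Y[nrow(tr)] - eq$Y_inf), 1e-3)
  expect_lt(abs(tr$I[nrow(tr)] - eq$I_inf), 1e-3)
  expect_lt(tr$S[nrow(tr)], 1e-3)
  # beta_I = 2 sqrt(eps_I) makes the radical vanish: full sequestration
  pp1 <- partial_dimless(0.02, 0.1, 0.1, 0.03, 1, 1e-9)
  eq1 <- partial_equilibrium(pp1)
  expect_equal(eq1$Y_inf, 1, tolerance = 1e-3)
  expect_equal(eq1$I_inf, 0, tolerance = 1e-3)
})

test_that("phi linear system matches its characteristic quartic", {
  for (p in list(ps_phi_small_eps(), ps_timescale_split(),
                 ps_symmetric())) {
    qc <- phi_quartic_coeffs(p)
    A <- ciket:::.phi_system_matrix(p)
    ev <- sort(Re(eigen(A)$values))
    rr <- sort(Re(qc$roots[[1]]))
    expect_lt(max(abs(ev - rr)) / max(abs(ev)), 1e-8)
  }
})

test_that("phi trajectory starts at rest and matches the full dynamics", {
  p <- ps_phi_small_eps()
  tp <- simulate_phi(p, tau_end = 200, n_out = 3000)
  expect_equal(unlist(tp[1, c("P", "Q", "V", "U")]),
               c(P = 0, Q = 0, V = 0, U = 0))
  tf <- simulate_full(p, tau_end = 200, n_out = 3000)
  # velocity agrees on the whole window; states agree before deep depletion
  expect_lt(max(abs(traj_at(tp, tf$tau, "V") - tf$V)), 0.1 * max(tf$V))
  w <- tf$I >= 0.6
  expect_lt(max(abs(traj_at(tp, tf$tau[w], "I") - tf$I[w])), 0.05)
  expect_lt(max(abs(traj_at(tp, tf$tau[w], "S") - tf$S[w])), 0.05)
})

test_that("the phi approximation converges as the phi weights shrink", {
  gap_for <- function(h) {
    p <- full_dimless(0.06, 0.08 * h, 8.1, 0.03, 0.04 * h, 1.2, rho = 1)
    tf <- simulate_full(p, tau_end = 100, n_out = 1500)
    tp <- simulate_phi(p, tau_end = 100, n_out = 1500)
    max(abs(traj_at(tp, tf$tau, "I") - tf$I))
  }
  g <- vapply(c(0.2, 0.1, 0.05), gap_for, 0)
  expect_true(all(diff(g) < 0))
  expect_lt(g[3], 0.2 * g[1])
})

test_that("euler and reference phi integrators agree", {
  p <- ps_phi_small_eps()
  te <- simulate_phi(p, tau_end = 1, method = "euler")
  tr <- simulate_phi(p, tau_end = 1, n_out = 4000)
  expect_lt(max(abs(traj_at(tr, te$tau, "P") - te$P)), 1e-4)
})
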