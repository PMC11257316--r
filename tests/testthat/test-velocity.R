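test_that("classical sQSSA reduces to Michaelis-Menten without inhibitor", {
  p <- ps_bimodal_S()
  dr <- derived_ratios(p)
  S <- c(0.2, 0.5, 1)
  out <- sqssa_velocity(p, S = S, I = 0)
  expect_equal(out$V, p$eps_S * S / (S + dr$mu_S), tolerance = 1e-12)
  expect_equal(sqssa_velocity(p, S = 0, I = 0.5)$V, 0)
  st <- sqssa_velocity(p, stationary = TRUE)
  expect_equal(st$V,
               p$eps_S / (1 + dr$mu_S * (1 + 1 / dr$mu_I)),
               tolerance = 1e-12)
})

test_that("refined stationary velocities satisfy the alpha identity", {
  for (p in list(ps_bimodal_S(), ps_timescale_split(), ps_balanced())) {
    dr <- derived_ratios(p)
    st <- refined_sqssa_velocity(p, stationary = TRUE)
    expect_equal(st$V, p$eps_S * (dr$alpha_I - 1) /
                   (dr$alpha_S * dr$alpha_I - 1), tolerance = 1e-12)
    expect_equal(st$U, p$rho * p$eps_I * (dr$alpha_S - 1) /
                   (dr$alpha_S * dr$alpha_I - 1), tolerance = 1e-12)
  }
  # symmetric parameters: both channels identical
  st <- refined_sqssa_velocity(ps_symmetric(), stationary = TRUE)
  expect_equal(st$V, st$U, tolerance = 1e-12)
  # inhibitor-free limit (kappa_I -> Inf): single-substrate refined MM,
  # v2 = vmax s0 / (s0 + e0 + K_MS) in dimensionless form
  p0 <- full_dimless(0.01, 0.05, 0.1, 0.01, 0.05, 1e9, rho = 1)
  dr0 <- derived_ratios(p0)
  expect_equal(refined_sqssa_velocity(p0, stationary = TRUE)$V,
               p0$eps_S / (1 + dr0$mu_S_t), tolerance = 1e-6)
})

test_that("coupling curves invert and hit the endpoints", {
  p <- ps_bimodal_S()
  delta <- derived_ratios(p)$delta
  cc <- coupling_curves(p, S = c(0, 0.3, 1))
  expect_equal(cc$I, c(0, 0.3^(1 / delta), 1))
  expect_equal(coupling_curves(p, I = cc$I)$S, cc$S, tolerance = 1e-12)
  # P <-> Q inversion
  cq <- coupling_curves(p, P = 0.4)
  expect_equal(coupling_curves(p, Q = cq$Q)$P, 0.4, tolerance = 1e-12)
  # delta = 1/2 power evaluation
  p5 <- ps_symmetric()
  p5$rho <- derived_ratios(p5)$mu_I_t * p5$eps_S /
    (0.5 * derived_ratios(p5)$mu_S_t * p5$eps_I)
  expect_equal(derived_ratios(p5)$delta, 0.5, tolerance = 1e-12)
  expect_equal(coupling_curves(p5, S = 0.25)$I, 0.0625, tolerance = 1e-12)
})

test_that("product-space cubic root matches a dense scan oracle", {
  withr::with_seed(11, {
    for (i in 1:100) {
      v <- exp(stats::runif(6, log(0.01), log(2)))
      p <- full_dimless(v[1], v[2], v[3], v[4], v[5], v[6],
                        rho = exp(stats::runif(1, -1, 1)))
      P <- stats::runif(1, 0, 0.6)
      Q <- stats::runif(1, 0, 0.6)
      res <- tryCatch(cubic_qssa_vpq(p, P, Q), error = function(e) NULL)
      if (is.null(res)) next
      expect_lt(res$residual, 1e-10)
      # brute-force: sign changes of the cubic on a dense Y grid
      dr <- derived_ratios(p)
      aS <- dr$alpha_S; aI <- dr$alpha_I; eS <- p$eps_S; eI <- p$eps_I
      a3 <- eI * (aI * eS - aS * eI + eI - eS)
      a2 <- -P * aI * eI + P * eI^2 + P * eI + Q * aI * eS -
        2 * Q * aS * eI + Q * eI * eS + 2 * Q * eI - Q * eS -
        aI^2 * eS + aI * aS * eI + aI * eS + aS * eI - eI^2 -
        eI * eS - 2 * eI
      a1 <- -(Q - 1) * (P * aI - P * eI - P + Q * aS - Q * eS - Q -
                          aI * aS + 2 * aI * eS - aS * eI + 2 * eI -
                          eS + 1)
      a0 <- (Q - 1)^2 * (aS - eS - 1)
      Yg <- seq(0, 1, by = 1e-5)
      fg <- a0 + a1 * Yg + a2 * Yg^2 + a3 * Yg^3
      sc <- which(sign(fg[-1]) != sign(fg[-length(fg)]))
      expect_true(any(abs(Yg[sc] - res$Y) < 2e-5))
    }
  })
})

test_that("cubic at zero products agrees with refined sQSSA for small eta", {
  p <- full_dimless(1e-4, 0.05, 0.2, 1e-4, 0.05, 0.2, rho = 1)
  res <- cubic_qssa_vpq(p, 0, 0)
  ref <- refined_sqssa_velocity(p, stationary = TRUE)
  expect_equal(res$V, ref$V, tolerance = 0.05)
  expect_equal(res$U, ref$U, tolerance = 0.05)
})

test_that("one-channel-closed post branches track the simulated decay", {
  # delta < 1: the (U, I) branch is the accurate one
  pa <- ps_bimodal_S()
  tra <- tr_bimS()
  eva <- ev_of("bimS", tr_bimS)
  tCI <- first_max(eva, "inhibitor")$tau
  post <- tra[tra$tau > 2 * tCI & tra$I > 0.02 & tra$I < 0.95, ]
  au <- caseII_post_velocity(pa, I = post$I)$U
  expect_lt(max(abs(au - post$U)) / max(post$U), 0.05)
  # delta > 1: the (V, S) branch
  pb <- ps_bimodal_I()
  trb <- tr_bimI()
  evb <- ev_of("bimI", tr_bimI)
  tCS <- first_max(evb, "substrate")$tau
  postb <- trb[trb$tau > 2 * tCS & trb$S > 0.02 & trb$S < 0.95, ]
  av <- caseII_post_velocity(pb, S = postb$S)$V
  expect_lt(max(abs(av - postb$V)) / max(postb$V), 0.05)
  # velocities vanish with the reactant
  expect_lt(caseII_post_velocity(pa, S = 1e-12)$V, 1e-10)
})

test_that("delta expansion is exact at delta = 1 and first-order accurate", {
  p1 <- ps_symmetric()
  S <- c(0.2, 0.5, 0.9)
  tv <- taylor_delta_velocity(p1, S = S)
  ref <- refined_sqssa_velocity(p1, S = S, I = S^(1 / 1))
  expect_equal(tv$V, ref$V, tolerance = 1e-12)
  # exact delta-coupled velocity for comparison
  exact_V <- function(p, S) {
    dr <- derived_ratios(p)
    p$eps_S * S / (S + dr$mu_S_t * (1 + S^(1 / dr$delta) / dr$mu_I_t))
  }
  mk <- function(delta) {
    p <- ps_symmetric()
    dr <- derived_ratios(p)
    p$rho <- dr$mu_I_t * p$eps_S / (delta * dr$mu_S_t * p$eps_I)
    p
  }
  e1 <- abs(taylor_delta_velocity(mk(1.01), S = 0.5)$V -
              exact_V(mk(1.01), 0.5))
  e2 <- abs(taylor_delta_velocity(mk(1.02), S = 0.5)$V -
              exact_V(mk(1.02), 0.5))
  expect_lt(e1, 1e-5)
  # quadrupling with doubled (delta - 1): second-order remainder
  expect_equal(e2 / e1, 4, tolerance = 0.2)
})

test_that("exact steady relations reproduce trajectory velocities", {
  p <- ps_timescale_split()
  ev <- ev_of("split", tr_split)
  xev <- first_max(ev, "substrate")
  yev <- first_max(ev, "inhibitor")
  rel <- exact_steady_relations(p, S_CP = xev$S, U_CP = xev$U,
                                I_CQ = yev$I, V_CQ = yev$V)
  expect_lt(abs(rel$V_CP - xev$V), 1e-3)
  expect_lt(abs(rel$U_CQ - yev$U), 1e-3)
  # no cross-channel flux: pure Michaelis-Menten factor
  dr <- derived_ratios(p)
  mm <- exact_steady_relations(p, S_CP = 0.5, U_CP = 0)
  expect_equal(mm$V_CP, p$eps_S * 0.5 / (0.5 + dr$mu_S), tolerance = 1e-12)
})

test_that("secondary steady-state formulas locate the prolonged extrema", {
  ssA <- secondary_steady_state(ps_bimodal_S())
  evA <- ev_of("bimS", tr_bimS)
  S2 <- last_max(evA, "substrate")$S
  expect_equal(ssA$channel, "substrate")
  expect_true(ssA$valid)
  expect_lt(abs(ssA$level - S2) / S2, 0.15)
  ssB <- secondary_steady_state(ps_bimodal_I())
  evB <- ev_of("bimI", tr_bimI)
  I2 <- last_max(evB, "inhibitor")$I
  expect_equal(ssB$channel, "inhibitor")
  expect_lt(abs(ssB$level - I2) / I2, 0.15)
  expect_error(secondary_steady_state(ps_symmetric()), "delta = 1")
})

test_that("tQSSA root is physical, accurate, and has the right limits", {
  p <- ps_timescale_split()
  tq <- tqssa_velocity(p)
  expect_lt(tq$residual, 1e-10)
  # at enzyme excess with split timescales the inhibitor channel is the
  # single-steady one; tQSSA lands on its event velocity
  ev <- ev_of("split", tr_split)
  Uev <- first_max(ev, "inhibitor")$U
  expect_lt(abs(tq$U - Uev) / Uev, 0.10)
  # on the delta<1 set it lands on the common plateau at the EI event
  # (the first ES maximum is a transient overshoot it does not model)
  pa <- ps_bimodal_S()
  tqa <- tqssa_velocity(pa)
  eva <- ev_of("bimS", tr_bimS)
  plateau <- first_max(eva, "inhibitor")
  expect_lt(abs(tqa$V - plateau$V) / plateau$V, 0.10)
  expect_lt(abs(tqa$U - plateau$U) / plateau$U, 0.10)
  # vanishing EI affinity (kappa_I -> Inf, so Y -> 0): reduces to the
  # single-substrate total-QSSA quadratic (1 - eps_S X)(1 - X) = mu_S X
  p0 <- full_dimless(0.05, 0.5, 0.2, 0.05, 0.05, 1e7, rho = 1)
  tq0 <- tqssa_velocity(p0)
  dr0 <- derived_ratios(p0)
  f <- function(X) (1 - p0$eps_S * X) * (1 - X) - dr0$mu_S * X
  Xq <- stats::uniroot(f, c(0, 1), tol = 1e-14)$root
  expect_equal(tq0$V, p0$eps_S * Xq, tolerance = 1e-5)
})

test_that("tQSSA matches a dense scan oracle over random draws", {
  withr::with_seed(23, {
    for (i in 1:100) {
      v <- exp(stats::runif(6, log(0.01), log(3)))
      p <- full_dimless(v[1], v[2], v[3], v[4], v[5], v[6],
                        rho = exp(stats::runif(1, -1, 1)))
      tq <- tryCatch(tqssa_velocity(p), error = function(e) NULL)
      if (is.null(tq)) next
      expect_lt(tq$residual, 1e-10)
      dr <- derived_ratios(p)
      eS <- p$eps_S; eI <- p$eps_I; mS <- dr$mu_S; mI <- dr$mu_I
      Yg <- seq(0, min(1, 1 / eI - 1e-9), length.out = 1e5)
      fg <- (eI^2 * mS - eI * eS * mI) * Yg^3 +
        (-eI^2 * mS + eI * eS * mI - eI * mI * mS - eI * mI -
           2 * eI * mS + eS * mI^2 + eS * mI) * Yg^2 +
        (2 * eI * mS - eS * mI + mI * mS + mI + mS) * Yg - mS
      sc <- which(sign(fg[-1]) != sign(fg[-length(fg)]))
      expect_true(any(abs(Yg[sc] - tq$Y) < 2 * diff(Yg[1:2])))
    }
  })
})

test_that("partial-scheme sQSSA variants have the stated limits", {
  pp <- ps_partial()
  g <- ciket:::.drp(pp)
  S <- c(0.3, 0.7, 1)
  cl <- partial_sqssa(pp, S = S, I = 0)
  expect_equal(cl$V, pp$eps_S * S / (S + g$mu_S), tolerance = 1e-12)
  # strong dissociation removes the inhibition factor
  pp2 <- partial_dimless(0.02, 0.1, 0.1, 0.03, 0.06, 1e9)
  g2 <- ciket:::.drp(pp2)
  expect_equal(partial_sqssa(pp2, S = 0.5, I = 1)$V,
               pp2$eps_S * 0.5 / (0.5 + g2$mu_S), tolerance = 1e-6)
  # refined stationary form equals the beta_I plateau identity
  st <- partial_sqssa(pp, refined = TRUE, stationary = TRUE)
  expect_equal(st$V, pp$eps_S * (g$beta_I - 1) /
                 (g$alpha_S * g$beta_I - 1), tolerance = 1e-12)
})

test_that("partial post-steady branch is exact at S = 0 and accurate", {
  pp <- ps_partial()
  eq <- partial_equilibrium(pp)
  at0 <- partial_post_vs(pp, 0)
  expect_equal(at0$Y, eq$Y_inf, tolerance = 1e-12)
  expect_equal(at0$V, 0)
  # eps_I -> 0 reduces to the classical sQSSA at stationary inhibitor
  pp0 <- partial_dimless(0.02, 0.1, 0.1, 0.03, 1e-8, 0.5)
  g0 <- ciket:::.drp(pp0)
  S <- c(0.2, 0.6, 0.9)
  expect_equal(partial_post_vs(pp0, S)$V,
               pp0$eps_S * S / (S + g0$mu_S * (1 + 1 / pp0$kappa_I)),
               tolerance = 1e-6)
  # tracks the simulated post branch, and better than the refined sQSSA
  tr <- tr_part()
  ev <- ev_of("part", tr_part)
  tCS <- first_max(ev, "substrate")$tau
  post <- tr[tr$tau > 2 * tCS & tr$S > 0.02 & tr$S < 0.9, ]
  vpost <- partial_post_vs(pp, post$S)$V
  vref <- partial_sqssa(pp, S = post$S, refined = TRUE)$V
  err_post <- max(abs(vpost - post$V)) / max(post$V)
  err_ref <- max(abs(vref - post$V)) / max(post$V)
  expect_lt(err_post, 0.05)
  expect_lt(err_post, err_ref)
})
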