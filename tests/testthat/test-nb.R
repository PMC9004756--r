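test_that("within-season integration recovers the classical escape fraction", {
  spec <- season_spec(attack_rate("constant", c = 0.8))
  for (case in list(c(H = 1, P = 1, R = 2), c(H = 0.3, P = 2.5, R = 7))) {
    s <- season_integrate(spec, case["H"], case["P"], case["R"])
    expect_equal(s$survivors, case[["R"]] * case[["H"]] * exp(-0.8 * case[["P"]]),
                 tolerance = 1e-9)
    expect_equal(s$parasitized, case[["R"]] * case[["H"]] - s$survivors,
                 tolerance = 1e-9)
  }
  # no parasitoids: only background larval mortality acts
  s0 <- season_integrate(season_spec(attack_rate("constant", c = 1), gammaL = 0.4),
                         H = 1, P = 0, R = 3)
  expect_equal(s0$survivors, 3 * exp(-0.4))
  expect_equal(s0$parasitized, 0)
})

test_that("total larvae are conserved within a season when mortalities are zero", {
  spec <- season_spec(attack_rate("monomial", c = 1, a = 0.7, b = -0.3))
  path <- season_integrate(spec, H = 0.9, P = 1.4, R = 2.5, keep_path = TRUE)
  total <- path$survivors + path$parasitized
  expect_lt(max(abs(total - 2.5 * 0.9)) / (2.5 * 0.9), 1e-9)
  expect_equal(path$parasitoids, rep(1.4, nrow(path)))   # gammaP = 0
})

test_that("the closed-form generalized map equals semi-discrete integration", {
  set.seed(5)
  for (i in 1:12) {
    fh <- runif(1, -0.6, 1.8); fp <- runif(1, -0.8, 0.8)
    R <- runif(1, 1.3, 8); H <- exp(runif(1, -1.5, 0.7)); P <- exp(runif(1, -1.5, 0.7))
    spec <- season_spec(attack_rate("monomial", c = 1, a = fh, b = fp))
    s <- season_integrate(spec, H, P, R, rtol = 1e-11, atol = 1e-14)
    mp <- nb_map(H, P, fh, fp, R)
    expect_equal(mp$H, s$survivors, tolerance = 1e-8)
    expect_equal(mp$P, s$parasitized, tolerance = 1e-8)
  }
})

test_that("the generalized map has the expected limits and absorbing states", {
  # fh = fp = 0 is the classical model with unit attack rate
  expect_equal(nb_map(1.3, 0.7, 0, 0, 2),
               tibble::tibble(H = 2 * 1.3 * exp(-0.7),
                              P = 2 * 1.3 * (1 - exp(-0.7))))
  # near-zero fh goes through the exponential limit continuously
  expect_equal(nb_map(1, 1, 1e-9, 0.3, 2)$H, nb_map(1, 1, 1.1e-8, 0.3, 2)$H,
               tolerance = 1e-7)
  # the (fh, fp) = (1, 0), R = 2 fixed point at 1/sqrt(2)
  s2 <- 1 / sqrt(2)
  expect_equal(unlist(nb_map(s2, s2, 1, 0, 2)), c(H = s2, P = s2))
  # extinction is absorbing; host depletion maps to full parasitism
  expect_equal(unlist(nb_map(0, 3, 0.5, 0, 2)), c(H = 0, P = 0))
  depl <- nb_map(1, 50, -0.5, 0, 2)    # bracket 1 + fh*x <= 0
  expect_equal(unlist(depl), c(H = 0, P = 2))
  expect_error(nb_map(1, 1, -1, 0, 2), class = "parastab_precondition_error")
})

test_that("the map equilibrium satisfies P* = (R-1) H* and the known closed forms", {
  eq <- nb_equilibrium(1, 0, 2)
  expect_equal(eq$Hstar, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(eq$Pstar, 1 / sqrt(2), tolerance = 1e-12)
  # fh -> 0 continuity toward the classical equilibrium H* = ln R / (R-1)
  eq0 <- nb_equilibrium(1e-10, 0, 2)
  expect_equal(eq0$Hstar, log(2), tolerance = 1e-8)
  expect_equal(eq0$Pstar, log(2), tolerance = 1e-8)
  set.seed(31)
  for (i in 1:25) {
    fh <- runif(1, -0.9, 2); fp <- runif(1, -0.9, 1.5); R <- runif(1, 1.1, 25)
    if (1 + fh + fp <= 0.05) next
    e <- nb_equilibrium(fh, fp, R)
    expect_equal(e$Pstar / e$Hstar, R - 1, tolerance = 1e-12)
    expect_lt(e$residual, 1e-10)
  }
  expect_error(nb_equilibrium(0, 0, 0.9), "R > 1",
               class = "parastab_precondition_error")
  expect_error(nb_equilibrium(-0.5, -0.6, 2), "1 \\+ fh \\+ fp",
               class = "parastab_precondition_error")
})

test_that("the discrete Jacobian matches central differences of the map", {
  set.seed(17)
  done <- 0
  while (done < 100) {
    fh <- runif(1, -0.9, 2); fp <- runif(1, -0.9, 1.5); R <- runif(1, 1.1, 25)
    if (1 + fh + fp <= 0.05) next
    done <- done + 1
    eq <- nb_equilibrium(fh, fp, R)
    f <- function(x) unlist(nb_map(x[1], x[2], fh, fp, R))
    Jnum <- numeric_jacobian(f, c(eq$Hstar, eq$Pstar))
    expect_equal(Jnum, unname(nb_jacobian(fh, fp, R)), tolerance = 1e-6)
  }
  # classical model: spectral radius above one at any R > 1
  expect_gt(max(Mod(eigen(nb_jacobian(0, 0, 2))$values)), 1)
  # Type III threshold: spectral radius exactly one at (1, 0)
  for (R in c(2, 5, 20))
    expect_equal(max(Mod(eigen(nb_jacobian(1, 0, R))$values)), 1,
                 tolerance = 1e-9)
})

test_that("discrete stability verdicts reproduce the known cases", {
  expect_equal(nb_stability(0, 0, 2)$status, "unstable")
  expect_equal(nb_stability(0.5, -0.3, 2)$status, "stable")
  expect_equal(nb_stability(0, -0.2, 2)$status, "unstable")
  # the combination effect: moderate interference + moderate acceleration,
  # neither stabilizing alone, together stable
  expect_equal(nb_stability(0.5, -0.2, 2)$status, "stable")
  for (R in c(1.5, 2, 20))
    expect_equal(nb_stability(-0.5, -0.6, R)$status, "unstable")
  # boundary ordinates behind those verdicts
  expect_equal(boundary_fp_discrete(0.5, 2), -0.1464466, tolerance = 1e-6)
  expect_equal(boundary_fp_discrete(0, 2), -0.2786525, tolerance = 1e-6)
})

test_that("the third Jury condition holds throughout the admissible region", {
  for (fh in seq(-0.95, 3, by = 0.25)) {
    for (fp in seq(-0.95, 1.5, by = 0.25)) {
      if (1 + fh + fp <= 0.01) next
      for (R in c(1.2, 2, 20)) {
        v <- nb_stability(fh, fp, R)
        expect_gt(v$jury$neg_slack, 0)
      }
    }
  }
})

test_that("analytic and Jury verdicts agree away from the boundaries", {
  set.seed(303)
  n <- 0
  while (n < 200) {
    fh <- runif(1, -1, 2); fp <- runif(1, -1, 2); R <- runif(1, 1.2, 30)
    if (min(abs(boundary_fp_discrete(fh, R) - fp), abs(1 + fh + fp)) <= 0.05) next
    if (fh <= -1 + 1e-6 || fp <= -1 + 1e-6) next
    n <- n + 1
    v <- nb_stability(fh, fp, R)
    expect_equal(v$eigen_status, v$analytic_status)
  }
})

test_that("the boundary's removable singularity matches its closed-form limit", {
  for (R in c(1.5, 2, 20, 1e3)) {
    lim <- -(R * log(R) + 1 - R) / (R * log(R))
    expect_equal(boundary_fp_discrete(1e-8, R), lim, tolerance = 1e-6)
    expect_equal(boundary_fp_discrete(-1e-8, R), lim, tolerance = 1e-6)
    expect_equal(boundary_fp_discrete(0, R), lim)
  }
})

test_that("iterated trajectories behave per the verdict", {
  eq <- nb_equilibrium(1, 0, 2)
  const <- nb_iterate(eq$Hstar, eq$Pstar, 1, 0, 2, generations = 50)
  expect_lt(max(rel_deviation(const, eq)), 1e-10)
  # classical model: diverging oscillations
  eq0 <- nb_equilibrium(1e-12, 0, 2)
  div <- nb_iterate(eq0$Hstar * 1.001, eq0$Pstar * 1.001, 0, 0, 2, 300)
  expect_equal(classify_trajectory(div, eq0), "diverging")
  # strong Type III acceleration: damped
  eq1 <- nb_equilibrium(1.5, 0, 2)
  dmp <- nb_iterate(eq1$Hstar * 1.001, eq1$Pstar * 1.001, 1.5, 0, 2, 300)
  expect_equal(classify_trajectory(dmp, eq1), "damped")
})

test_that("the phenomenological substitution disagrees with the semi-discrete route on Type III", {
  # same log sensitivities (1.5, 0): the semi-discrete map is stable at R = 2
  # while the phenomenological fixed point is linearly unstable
  expect_equal(nb_stability(1.5, 0, 2)$status, "stable")
  m <- attack_rate("monomial", c = 1, a = 1.5, b = 0)
  # phenomenological fixed point: R exp(-H^1.5 P) = 1 with P = (R-1) H
  Hp <- log(2)^0.4
  expect_equal(nb_map_phenomenological(m, Hp, Hp, 2)$H, Hp, tolerance = 1e-12)
  f <- function(x) unlist(nb_map_phenomenological(m, x[1], x[2], 2))
  Jp <- numeric_jacobian(f, c(Hp, Hp))
  expect_gt(max(Mod(eigen(Jp)$values)), 1)
  # and the iterates leave the neighbourhood of the fixed point
  H <- Hp * 1.001; P <- Hp * 1.001; maxdev <- 0
  for (t in 1:200) {
    nxt <- nb_map_phenomenological(m, H, P, 2)
    H <- nxt$H; P <- nxt$P
    maxdev <- max(maxdev, abs(H - Hp) / Hp)
    if (!is.finite(H) || H > 1e6) break
  }
  expect_gt(maxdev, 1)
})
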