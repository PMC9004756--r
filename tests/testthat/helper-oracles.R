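# Independent numerical oracles used across the suite. These deliberately
# avoid the package's analytic formulas so that analytic and numeric routes
# stay independent.

# central-difference Jacobian of a 2-vector map/field at a point
numeric_jacobian <- function(f, x, rel_step = 1e-6) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    h <- rel_step * max(abs(x[j]), 1)
    xp <- x; xm <- x
    xp[j] <- x[j] + h; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# right-hand side of the continuous model, for a given attack model
lv_rhs <- function(model, r, gamma) {
  function(x) {
    f <- attack_eval(model, x[1], x[2])
    c(r * x[1] - f * x[1] * x[2], f * x[1] * x[2] - gamma * x[2])
  }
}

# conserved quantity of the classical (constant attack rate) model
lv_energy <- function(h, p, c, r, gamma) c * (h + p) - gamma * log(h) - r * log(p)

# relative deviation of a trajectory from an equilibrium point
rel_deviation <- function(traj, eq) {
  dens <- if ("host" %in% names(traj)) cbind(traj$host, traj$parasitoid)
          else cbind(traj$H, traj$P)
  ec <- if ("hstar" %in% names(eq)) c(eq$hstar, eq$pstar) else c(eq$Hstar, eq$Pstar)
  sqrt(((dens[, 1] - ec[1]) / ec[1])^2 + ((dens[, 2] - ec[2]) / ec[2])^2)
}
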