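#' @noRd
new_stability_verdict <- function(framework, status, cond1_slack, cond2_slack,
                                  eigenvalues, analytic_status, eigen_status,
                                  params, jury = NULL) {
  structure(list(
    framework = framework,
    status = status,
    cond1_slack = cond1_slack,
    cond2_slack = cond2_slack,
    eigenvalues = eigenvalues,
    analytic_status = analytic_status,
    eigen_status = eigen_status,
    jury = jury,
    params = params,
    method = "analytic"        # primary verdict route; eigen route recorded alongside
  ), class = "stability_verdict")
}

# classify from the two signed slacks of a strict-inequality criterion
status_from_slacks <- function(slacks, tol = .parastab$marginal_tol_analytic) {
  if (any(slacks < -tol)) "unstable"
  else if (any(abs(slacks) <= tol)) "marginal"
  else "stable"
}

#' @export
print.stability_verdict <- function(x, ...) {
  pars <- paste(names(x$params), signif(unlist(x$params), 6),
                sep = " = ", collapse = ", ")
  cat("<stability_verdict> [", x$framework, "] ", toupper(x$status), "\n", sep = "")
  cat("  ", pars, "\n", sep = "")
  cat(sprintf("  condition slacks: %.6g (attack-rate condition), %.6g (1 + fh + fp)\n",
              x$cond1_slack, x$cond2_slack))
  ev <- x$eigenvalues
  if (all(is.na(ev))) {
    cat("  eigenvalues: not defined (no admissible equilibrium)\n")
  } else if (x$framework == "continuous") {
    cat(sprintf("  eigenvalues: %s (max Re = %.6g) -> %s\n",
                paste(format(ev, digits = 6), collapse = ", "),
                max(Re(ev)), x$eigen_status))
  } else {
    cat(sprintf("  eigenvalues: %s (spectral radius = %.6g) -> %s\n",
                paste(format(ev, digits = 6), collapse = ", "),
                max(Mod(ev)), x$eigen_status))
  }
  invisible(x)
}

#' Tidy a stability verdict into one row per condition
#'
#' @param x A `stability_verdict` from [lv_stability()] or [nb_stability()].
#' @param ... Unused.
#' @return A tibble with columns `condition`, `slack`, `satisfied`.
#' @export
tidy.stability_verdict <- function(x, ...) {
  cond1 <- if (x$framework == "continuous") "fp < r*fh/gamma" else "fp < discrete boundary (Jury: det < 1)"
  out <- tibble::tibble(
    condition = c(cond1, "1 + fh + fp > 0"),
    slack = c(x$cond1_slack, x$cond2_slack),
    satisfied = c(x$cond1_slack, x$cond2_slack) > 0)
  if (!is.null(x$jury)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      condition = c("jury: 1 - det(A) > 0", "jury: 1 - tr(A) + det(A) > 0",
                    "jury: 1 + tr(A) + det(A) > 0"),
      slack = c(x$jury$det_slack, x$jury$flip_slack, x$jury$neg_slack),
      satisfied = c(x$jury$det_slack, x$jury$flip_slack, x$jury$neg_slack) > 0))
  }
  out
}

#' One-row summary of a stability verdict
#'
#' @param x A `stability_verdict`.
#' @param ... Unused.
#' @return A one-row tibble with the parameters, the two analytic slacks, the
#'   eigenvalue-based stability measure (`max_re` for the continuous
#'   framework, `spectral_radius` for the discrete one), and both the
#'   analytic and eigenvalue verdicts.
#' @export
glance.stability_verdict <- function(x, ...) {
  ev <- x$eigenvalues
  measure <- if (all(is.na(ev))) NA_real_
             else if (x$framework == "continuous") max(Re(ev)) else max(Mod(ev))
  tibble::as_tibble(c(
    x$params,
    list(framework = x$framework,
         status = x$status,
         cond1_slack = x$cond1_slack,
         cond2_slack = x$cond2_slack,
         analytic_status = x$analytic_status,
         eigen_status = x$eigen_status),
    if (x$framework == "continuous") list(max_re = measure)
    else list(spectral_radius = measure)))
}
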