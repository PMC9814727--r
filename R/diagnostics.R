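#' Work-distribution overlap convergence measure
#'
#' Quantifies the overlap of forward and reverse work distributions to
#' diagnose whether a bi-directional estimate is trustworthy. Two
#' internal estimates of the same overlap integral are compared: a
#' first-moment estimate and a second-moment estimate. With the Fermi
#' function \eqn{\phi(x) = 1/(1+e^x)}, reduced works \eqn{u} and
#' \eqn{f = \Delta G/kT}:
#' \deqn{f_i = \phi(u^F_i - f), \quad g_j = \phi(u^R_j + f)}
#' \deqn{a_1 = \tfrac12(\overline{f_i} + \overline{g_j}), \quad
#'       a_2 = \overline{f_i^2} + \overline{g_j^2}}
#' and the measure is \eqn{(a_1 - a_2)/(a_1 + a_2)}. It ranges from -1
#' to 1; well-converged estimates (good overlap) return a value close to
#' 0, while disjoint work distributions return a value close to 1. When
#' every \eqn{\phi} term underflows to zero (no overlap at all) the
#' measure is defined as exactly 1.
#'
#' @param ws a [work_set()] with both directions non-empty.
#' @param dg free energy (kJ/mol) at which to evaluate the measure;
#'   defaults to the BAR estimate of `ws` itself, matching per-estimate
#'   convergence reporting.
#' @return an object of class `overlap_report`: fields `measure`,
#'   `a_first`, `a_second`, `dg_used` (kJ/mol), `n_forward`,
#'   `n_reverse`.
#' @export
convergence_measure <- function(ws, dg = NULL) {
  stopifnot(inherits(ws, "work_set"))
  if (length(ws$w_forward) == 0L || length(ws$w_reverse) == 0L)
    stop("convergence measure requires both directions")
  kT <- kT_kJmol(ws$temperature)
  uF <- ws$w_forward / kT
  uR <- ws$w_reverse / kT
  if (is.null(dg)) dg <- est_bar_u(uF, uR) * kT
  f <- dg / kT
  fi <- fermi(uF - f)
  gj <- fermi(uR + f)
  a1 <- 0.5 * (mean(fi) + mean(gj))
  a2 <- mean(fi^2) + mean(gj^2)
  measure <- if (a1 + a2 > 0) (a1 - a2) / (a1 + a2) else 1
  structure(list(measure = measure, a_first = a1, a_second = a2,
                 dg_used = dg, n_forward = length(uF),
                 n_reverse = length(uR)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "overlap_report: measure = %.4f (a1 = %.4g, a2 = %.4g) at dG = %.4f kJ/mol\n",
    x$measure, x$a_first, x$a_second, x$dg_used))
  invisible(x)
}

#' Descriptive summary of the work distributions
#'
#' Per-direction sample count, mean and standard deviation of the work,
#' and the dissipated work \eqn{\langle W_F\rangle - \Delta G}
#' (forward) and \eqn{\langle W_R\rangle + \Delta G} (reverse; works as
#' performed), reported in kJ/mol and kT. Dissipation is non-negative in
#' expectation (second law) and zero in the reversible limit.
#'
#' @param ws a [work_set()]; directions may be empty (their summary is
#'   then absent).
#' @param dg free energy (kJ/mol) used for the dissipation; defaults to
#'   the BAR estimate when both directions are present, otherwise
#'   required.
#' @return list of class `work_summary` with elements `forward` and/or
#'   `reverse`, plus `dg_used` and `temperature`.
#' @export
distribution_summary <- function(ws, dg = NULL) {
  stopifnot(inherits(ws, "work_set"))
  kT <- kT_kJmol(ws$temperature)
  both <- length(ws$w_forward) > 0L && length(ws$w_reverse) > 0L
  if (is.null(dg)) {
    if (!both)
      stop("dg is required when only one direction is present")
    dg <- est_bar_u(ws$w_forward / kT, ws$w_reverse / kT) * kT
  }
  one <- function(w, sign) {
    if (length(w) == 0L) return(NULL)
    diss <- mean(w) + sign * dg
    list(n = length(w),
         mean_kJmol = mean(w), sd_kJmol = if (length(w) > 1L) sd(w) else NA_real_,
         mean_kT = mean(w) / kT, sd_kT = if (length(w) > 1L) sd(w) / kT else NA_real_,
         dissipation_kJmol = diss, dissipation_kT = diss / kT)
  }
  structure(list(forward = one(ws$w_forward, -1),
                 reverse = one(ws$w_reverse, +1),
                 dg_used = dg, temperature = ws$temperature),
            class = "work_summary")
}

#' @export
print.work_summary <- function(x, ...) {
  cat(sprintf("work_summary at dG = %.4f kJ/mol:\n", x$dg_used))
  for (d in c("forward", "reverse")) {
    s <- x[[d]]
    if (is.null(s)) next
    cat(sprintf("  %s: n = %d, <W> = %.3f (sd %.3f) kJ/mol, dissipation %.3f kT\n",
                d, s$n, s$mean_kJmol, s$sd_kJmol, s$dissipation_kT))
  }
  invisible(x)
}
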