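# Independent oracles used across the suite. Each deliberately takes a
# different numerical route than the implementation it checks.

# Bennett/Crooks maximum-likelihood estimate by direct maximisation of
# the logistic log-likelihood (the implementation solves the score
# equation by root-finding instead). Works in reduced units.
oracle_bar_loglik <- function(uF, uR) {
  M <- log(length(uF) / length(uR))
  # log sigmoid, stable in both tails: log(1/(1+exp(-z))) = -log1p(exp(-z))
  logsig <- function(z) ifelse(z > -30, -log1p(exp(-z)), z)
  negll <- function(f)
    -(sum(logsig(M + uF - f)) + sum(logsig(uR + f - M)))
  B <- max(abs(c(uF, uR))) + abs(M) + 10
  stats::optimize(negll, c(-B, B), tol = 1e-10)$minimum
}

# brute-force bootstrap of a work estimator, second implementation;
# matching the package's seed-splitting rule reproduces its stream
oracle_bootstrap_se <- function(ws, estimator, n_boot, seed) {
  kT <- neqfe::kT_kJmol(ws$temperature)
  uF <- ws$w_forward / kT
  uR <- ws$w_reverse / kT
  point <- function(bF, bR) {
    switch(estimator,
           bar = oracle_bar_loglik(bF, bR),
           jarzynski_forward = -log(mean(exp(-bF))),
           jarzynski_reverse = log(mean(exp(-bR))))
  }
  reps <- vapply(seq_len(n_boot), function(r) {
    set.seed((seed + r) %% .Machine$integer.max)
    bF <- if (length(uF)) uF[sample.int(length(uF), replace = TRUE)]
    bR <- if (length(uR)) uR[sample.int(length(uR), replace = TRUE)]
    point(bF, bR)
  }, numeric(1))
  stats::sd(reps) * kT
}

# Kendall tau-b by exhaustive pair enumeration with explicit tie counts
oracle_kendall_tb <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1L; ty <- ty + 1L }
    else if (dx == 0) tx <- tx + 1L
    else if (dy == 0) ty <- ty + 1L
    else if (dx == dy) conc <- conc + 1L
    else disc <- disc + 1L
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# configurational-integral oracle for the Boresch restraint: the 6-D
# integral factorises into independent 1-D quadratures
# Z = [int r^2 e^-br] [int sinT e^-bT]_A [..]_B [int e^-bphi]^3
oracle_boresch_quadrature <- function(r) {
  kT <- neqfe::kJ_to_kcal(neqfe::kT_kJmol(r$temperature))
  zr <- stats::integrate(function(x)
    x^2 * exp(-0.5 * r$kr * (x - r$r0)^2 / kT),
    lower = 0, upper = r$r0 + 30 * sqrt(kT / r$kr),
    rel.tol = 1e-10)$value
  zth <- function(th0, k) stats::integrate(function(x)
    sin(x) * exp(-0.5 * k * (x - th0)^2 / kT),
    lower = 0, upper = pi, rel.tol = 1e-10)$value
  zphi <- function(k) stats::integrate(function(x)
    exp(-0.5 * k * x^2 / kT),
    lower = -pi, upper = pi, rel.tol = 1e-10)$value
  z <- zr * zth(r$thetaA0, r$kthA) * zth(r$thetaB0, r$kthB) *
    zphi(r$kphiA) * zphi(r$kphiB) * zphi(r$kphiC)
  -kT * log(8 * pi^2 * r$v0 / z)
}

# brute-force combined parametric + non-parametric bootstrap of a
# benchmark accuracy metric (second implementation)
oracle_bootstrap_metric <- function(t, metric, n_boot, seed) {
  fn <- switch(metric,
               aue = function(c, r) mean(abs(c - r)),
               rmse = function(c, r) sqrt(mean((c - r)^2)),
               pearson = function(c, r) suppressWarnings(cor(c, r)))
  reps <- vapply(seq_len(n_boot), function(rr) {
    set.seed((seed + rr) %% .Machine$integer.max)
    idx <- sample.int(nrow(t), replace = TRUE)
    calc <- stats::rnorm(nrow(t), t$dg_calc[idx], t$se_calc[idx])
    fn(calc, t$dg_ref[idx])
  }, numeric(1))
  stats::sd(reps[is.finite(reps)])
}

# reduced-unit temperature shared by many fixtures
kT0 <- neqfe::reduced_temperature()
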