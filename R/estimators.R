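#' Free energy estimate container
#'
#' @param dg free energy difference (kJ/mol).
#' @param se standard error (kJ/mol, >= 0).
#' @param method one of `"jarzynski_forward"`, `"jarzynski_reverse"`,
#'   `"bar"`, `"zwanzig_chain"`, `"bar_chain"`.
#' @param n_forward,n_reverse sample counts.
#' @param temperature Kelvin.
#' @param convergence optional overlap-based convergence measure in
#'   \[-1, 1\] (only meaningful for bi-directional estimates).
#' @param se_degenerate logical flag: `TRUE` when the standard error is
#'   reported as 0 only because a direction had a single sample.
#' @return object of class `fe_estimate`.
#' @export
fe_estimate <- function(dg, se, method, n_forward, n_reverse, temperature,
                        convergence = NA_real_, se_degenerate = FALSE) {
  stopifnot(is.finite(dg), se >= 0, n_forward + n_reverse >= 1)
  structure(list(dg = dg, se = se, method = method,
                 n_forward = as.integer(n_forward),
                 n_reverse = as.integer(n_reverse),
                 temperature = temperature,
                 convergence = convergence,
                 se_degenerate = isTRUE(se_degenerate)),
            class = "fe_estimate")
}

#' @export
print.fe_estimate <- function(x, ...) {
  kT <- kT_kJmol(x$temperature)
  cat(sprintf("%s: dG = %.4f +/- %.4f kJ/mol (%.4f +/- %.4f kT)\n",
              x$method, x$dg, x$se, x$dg / kT, x$se / kT))
  cat(sprintf("  n_forward = %d, n_reverse = %d", x$n_forward, x$n_reverse))
  if (is.finite(x$convergence))
    cat(sprintf(", convergence = %.4f", x$convergence))
  cat("\n")
  invisible(x)
}

# ---- point estimators in reduced units (internal, used by the bootstrap) ----

# Jarzynski in reduced units; u are works-as-performed / kT.
# forward: dG = -ln <exp(-u)>; reverse (dG of the forward process):
# dG = +ln <exp(-u)>. Log-sum-exp shifted, overflow-free.
est_jarzynski_u <- function(u, direction) {
  lse <- logsumexp(-u) - log(length(u))
  if (direction == "forward") -lse else lse
}

# Bennett/Crooks maximum-likelihood estimate in reduced units.
# Solves g(f) = sum(fermi(M + uF - f)) - sum(fermi(-M + uR + f)) = 0,
# the score equation of the logistic likelihood; g is strictly monotone
# in f so the bracketed root is unique. uR follow the work-as-performed
# convention (reversible limit: uR = -dG/kT).
est_bar_u <- function(uF, uR, tol = 1e-8) {
  M <- log(length(uF) / length(uR))
  if (length(uF) == 1L && length(uR) == 1L) return((uF - uR) / 2)
  g <- function(f) sum(fermi(M + uF - f)) - sum(fermi(-M + uR + f))
  B <- max(abs(c(uF, uR))) + abs(M) + 10
  uniroot(g, lower = -B, upper = B, tol = tol)$root
}

#' Jarzynski (uni-directional) free energy estimate
#'
#' Applies Jarzynski's equality \eqn{e^{-\beta\Delta G} =
#' \langle e^{-\beta W}\rangle} to work samples from a single switching
#' direction. Reverse-direction works (as performed) yield the free
#' energy of the forward process with the opposite sign inside the
#' exponential average. The exponential averages are computed with a
#' log-sum-exp shift, so overflow cannot occur.
#'
#' The estimator is biased from above (forward) for finite samples of
#' dissipative work — the well-known slow convergence of
#' uni-directional estimates.
#'
#' @param works numeric work values in kJ/mol (as performed).
#' @param direction `"forward"` or `"reverse"`.
#' @param temperature Kelvin.
#' @param n_boot bootstrap replicates for the standard error
#'   (default 1000); ignored when `bootstrap = FALSE` or n = 1.
#' @param seed integer seed for the bootstrap.
#' @param bootstrap compute a bootstrap standard error? When `FALSE`
#'   (or n = 1) `se` is 0.
#' @return an [fe_estimate()].
#' @export
jarzynski <- function(works, direction = c("forward", "reverse"),
                      temperature, n_boot = 1000L, seed = 1L,
                      bootstrap = TRUE) {
  direction <- match.arg(direction)
  works <- as.numeric(works)
  if (length(works) == 0L) stop("no samples")
  kT <- kT_kJmol(temperature)
  u <- works / kT
  dg <- est_jarzynski_u(u, direction) * kT
  method <- paste0("jarzynski_", direction)
  if (length(works) == 1L || !bootstrap) {
    return(fe_estimate(dg, 0, method,
                       n_forward = if (direction == "forward") length(works) else 0L,
                       n_reverse = if (direction == "reverse") length(works) else 0L,
                       temperature = temperature,
                       se_degenerate = length(works) == 1L))
  }
  ws <- if (direction == "forward")
    work_set(w_forward = works, temperature = temperature)
  else
    work_set(w_reverse = works, temperature = temperature)
  se <- bootstrap_se(ws, estimator = method, n_boot = n_boot, seed = seed)
  fe_estimate(dg, se, method,
              n_forward = if (direction == "forward") length(works) else 0L,
              n_reverse = if (direction == "reverse") length(works) else 0L,
              temperature = temperature)
}

#' Bennett/Crooks maximum-likelihood (BAR) free energy estimate
#'
#' Bi-directional estimate from forward and reverse work samples: the
#' unique root \eqn{f} (in kT) of
#' \deqn{g(f) = \sum_i \phi(M + u^F_i - f) - \sum_j \phi(-M + u^R_j + f)}
#' with \eqn{\phi(x) = 1/(1+e^x)}, \eqn{M = \ln(n_F/n_R)}, and reduced
#' works \eqn{u = W/kT} following the work-as-performed convention. This
#' is the maximum-likelihood estimator for non-equilibrium work samples
#' consistent with the Crooks fluctuation theorem, equivalent to
#' Bennett's acceptance ratio for equilibrium ensembles. The root is
#' found by bracketed root-finding to 1e-8 kT; with one sample per
#' direction the closed form \eqn{f = (u^F - u^R)/2} is used.
#'
#' @param ws a [work_set()] with both directions non-empty.
#' @param n_boot bootstrap replicates for the standard error.
#' @param seed integer bootstrap seed.
#' @param bootstrap compute the bootstrap standard error?
#' @param convergence attach the work-distribution overlap
#'   [convergence_measure()] evaluated at the estimate?
#' @return an [fe_estimate()] with `method = "bar"`.
#' @export
bar <- function(ws, n_boot = 1000L, seed = 1L, bootstrap = TRUE,
                convergence = TRUE) {
  stopifnot(inherits(ws, "work_set"))
  if (length(ws$w_forward) == 0L || length(ws$w_reverse) == 0L)
    stop("bar requires both directions; use jarzynski() for one-sided samples")
  kT <- kT_kJmol(ws$temperature)
  uF <- ws$w_forward / kT
  uR <- ws$w_reverse / kT
  dg <- est_bar_u(uF, uR) * kT
  degenerate <- length(uF) == 1L && length(uR) == 1L
  se <- 0
  if (degenerate) {
    warning("single work value per direction: standard error reported as 0")
  } else if (bootstrap) {
    se <- bootstrap_se(ws, estimator = "bar", n_boot = n_boot, seed = seed)
  }
  conv <- NA_real_
  if (convergence)
    conv <- convergence_measure(ws, dg = dg)$measure
  fe_estimate(dg, se, "bar", n_forward = length(uF),
              n_reverse = length(uR), temperature = ws$temperature,
              convergence = conv, se_degenerate = degenerate)
}

# run fn() with the global RNG state restored afterwards
with_preserved_rng <- function(fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  fn()
}

#' Bootstrap standard error of a work-based estimator
#'
#' Resamples each direction independently with replacement (preserving
#' sample sizes), re-runs the estimator, and returns the standard
#' deviation (n-1 denominator) of the bootstrap distribution of the
#' estimate, in kJ/mol. Replicate RNG streams are derived by the
#' splitting rule `seed + replicate index`, so results are reproducible
#' across platforms and independent of the order replicates run in. The
#' caller's RNG state is left untouched.
#'
#' @param ws a [work_set()].
#' @param estimator `"bar"`, `"jarzynski_forward"`, or
#'   `"jarzynski_reverse"`.
#' @param n_boot number of replicates (>= 2, default 1000).
#' @param seed integer seed.
#' @return standard error in kJ/mol.
#' @export
bootstrap_se <- function(ws,
                         estimator = c("bar", "jarzynski_forward",
                                       "jarzynski_reverse"),
                         n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(ws, "work_set"))
  estimator <- match.arg(estimator)
  n_boot <- as.integer(n_boot)
  if (n_boot < 2L) stop("n_boot must be >= 2")
  kT <- kT_kJmol(ws$temperature)
  uF <- ws$w_forward / kT
  uR <- ws$w_reverse / kT
  if (estimator == "bar" && (length(uF) == 0L || length(uR) == 0L))
    stop("bar requires both directions")
  if (estimator == "jarzynski_forward" && length(uF) == 0L)
    stop("no forward samples")
  if (estimator == "jarzynski_reverse" && length(uR) == 0L)
    stop("no reverse samples")

  with_preserved_rng(function() {
    reps <- numeric(n_boot)
    failures <- 0L
    for (r in seq_len(n_boot)) {
      set.seed((seed + r) %% .Machine$integer.max)
      bF <- if (length(uF)) uF[sample.int(length(uF), replace = TRUE)]
      bR <- if (length(uR)) uR[sample.int(length(uR), replace = TRUE)]
      reps[r] <- tryCatch(
        switch(estimator,
               bar = est_bar_u(bF, bR),
               jarzynski_forward = est_jarzynski_u(bF, "forward"),
               jarzynski_reverse = est_jarzynski_u(bR, "reverse")),
        error = function(e) { failures <<- failures + 1L; NA_real_ })
    }
    if (failures > 0.01 * n_boot)
      stop(sprintf("estimator failed in %d of %d bootstrap replicates",
                   failures, n_boot))
    sd(reps, na.rm = TRUE) * kT
  })
}

#' Chain per-window estimates into a total free energy difference
#'
#' For stratified calculations the end-state free energy difference is
#' recovered by adding the estimates between all lambda windows:
#' \eqn{\Delta G = \sum_w \Delta G_w}, with standard errors combined in
#' quadrature. Two per-window estimators are supported: `"bar"` (each
#' window a [work_set()] of forward/backward energy differences or
#' works) and `"zwanzig"` (each window a numeric vector of forward
#' energy differences \eqn{\Delta U} in kJ/mol, exponential averaging
#' \eqn{\Delta G_w = -kT \ln\langle e^{-\Delta U/kT}\rangle}).
#'
#' @param windows list of [work_set()] objects (`method = "bar"`) or of
#'   numeric \eqn{\Delta U} vectors in kJ/mol (`method = "zwanzig"`).
#' @param method `"bar"` or `"zwanzig"`.
#' @param temperature Kelvin; required for `"zwanzig"`, taken from the
#'   work sets (which must agree) for `"bar"`.
#' @param n_boot,seed bootstrap controls for the per-window standard
#'   errors.
#' @return an [fe_estimate()] with method `"bar_chain"` or
#'   `"zwanzig_chain"`.
#' @export
chain_windows <- function(windows, method = c("bar", "zwanzig"),
                          temperature = NULL, n_boot = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (!is.list(windows) || length(windows) < 1L)
    stop("windows must be a non-empty list")
  dgs <- numeric(length(windows))
  ses <- numeric(length(windows))
  nF <- 0L; nR <- 0L
  for (w in seq_along(windows)) {
    res <- tryCatch({
      if (method == "bar") {
        ws <- windows[[w]]
        if (!inherits(ws, "work_set"))
          stop("expected a work_set")
        if (!is.null(temperature) && ws$temperature != temperature)
          stop("window temperature differs from the stated temperature")
        temperature <- ws$temperature
        est <- bar(ws, n_boot = n_boot, seed = seed + w,
                   bootstrap = TRUE, convergence = FALSE)
        nF <- nF + est$n_forward; nR <- nR + est$n_reverse
        c(est$dg, est$se)
      } else {
        du <- as.numeric(windows[[w]])
        if (length(du) == 0L) stop("no samples")
        if (is.null(temperature))
          stop("temperature is required for zwanzig chaining")
        kT <- kT_kJmol(temperature)
        dg <- -kT * (logsumexp(-du / kT) - log(length(du)))
        se <- if (length(du) == 1L) 0 else with_preserved_rng(function() {
          reps <- vapply(seq_len(n_boot), function(r) {
            set.seed((seed + w * 100003L + r) %% .Machine$integer.max)
            b <- du[sample.int(length(du), replace = TRUE)]
            -kT * (logsumexp(-b / kT) - log(length(b)))
          }, numeric(1))
          sd(reps)
        })
        nF <- nF + length(du)
        c(dg, se)
      }
    }, error = function(e)
      stop(sprintf("window %d: %s", w, conditionMessage(e)), call. = FALSE))
    dgs[w] <- res[1]; ses[w] <- res[2]
  }
  fe_estimate(sum(dgs), sqrt(sum(ses^2)),
              method = paste0(method, "_chain"),
              n_forward = nF, n_reverse = nR, temperature = temperature)
}
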