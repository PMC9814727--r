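#' Harmonic lambda-dependent toy potential
#'
#' \eqn{H(x;\lambda) = \tfrac12 k(\lambda)(x - x_0(\lambda))^2} with
#' linearly interpolated stiffness \eqn{k(\lambda) = (1-\lambda)k_A +
#' \lambda k_B} and centre \eqn{x_0(\lambda) = (1-\lambda)a + \lambda
#' b}. The free energy difference between the end states is analytic:
#' \eqn{\Delta F = \tfrac{kT}{2}\ln(k_B/k_A)} (independent of the
#' centres).
#'
#' @param k_A,k_B end-state stiffnesses (> 0, reduced energy per
#'   length^2).
#' @param a,b end-state centres.
#' @return object of class `toy_potential`.
#' @export
harmonic_potential <- function(k_A, k_B, a = 0, b = 0) {
  stopifnot(k_A > 0, k_B > 0)
  structure(list(type = "harmonic", k_A = k_A, k_B = k_B, a = a, b = b),
            class = "toy_potential")
}

#' Double-well / harmonic toy potential pair
#'
#' End state A is a symmetric double well \eqn{U_A(x) =
#' h\,((x/w)^2 - 1)^2} (barrier height `h`, minima at \eqn{\pm w});
#' end state B is harmonic \eqn{U_B(x) = \tfrac12 k_B (x-b)^2}. The
#' Hamiltonians are mixed linearly: \eqn{H(x;\lambda) = (1-\lambda)U_A +
#' \lambda U_B}, so \eqn{\partial H/\partial\lambda = U_B - U_A}. The
#' end-state free energy difference has no closed form and is computed
#' by 1-D quadrature of the two configurational integrals
#' ([toy_free_energy()]). This potential emulates a system whose
#' initial state has two metastable conformations: initializing the
#' equilibrium sampling from a single basin biases the estimate.
#'
#' @param h barrier height (> 0, reduced energy).
#' @param w half-separation of the minima (> 0).
#' @param k_B stiffness of end state B (> 0).
#' @param b centre of end state B.
#' @return object of class `toy_potential`.
#' @export
double_well_potential <- function(h, w = 1, k_B = 1, b = 0) {
  stopifnot(h > 0, w > 0, k_B > 0)
  structure(list(type = "double_well", h = h, w = w, k_B = k_B, b = b),
            class = "toy_potential")
}

# ---- potential internals (vectorised over x) ----

pot_energy <- function(p, x, lam) {
  if (p$type == "harmonic") {
    k <- (1 - lam) * p$k_A + lam * p$k_B
    x0 <- (1 - lam) * p$a + lam * p$b
    0.5 * k * (x - x0)^2
  } else {
    uA <- p$h * ((x / p$w)^2 - 1)^2
    uB <- 0.5 * p$k_B * (x - p$b)^2
    (1 - lam) * uA + lam * uB
  }
}

pot_dHdl <- function(p, x, lam) {
  if (p$type == "harmonic") {
    k <- (1 - lam) * p$k_A + lam * p$k_B
    x0 <- (1 - lam) * p$a + lam * p$b
    0.5 * (p$k_B - p$k_A) * (x - x0)^2 - k * (p$b - p$a) * (x - x0)
  } else {
    uA <- p$h * ((x / p$w)^2 - 1)^2
    uB <- 0.5 * p$k_B * (x - p$b)^2
    uB - uA
  }
}

pot_dHdx <- function(p, x, lam) {
  if (p$type == "harmonic") {
    k <- (1 - lam) * p$k_A + lam * p$k_B
    x0 <- (1 - lam) * p$a + lam * p$b
    k * (x - x0)
  } else {
    dA <- 4 * p$h * x * ((x / p$w)^2 - 1) / p$w^2
    dB <- p$k_B * (x - p$b)
    (1 - lam) * dA + lam * dB
  }
}

# effective stiffness governing the Euler-Maruyama stability bound
pot_keff <- function(p) {
  if (p$type == "harmonic") max(p$k_A, p$k_B)
  else max(8 * p$h / p$w^2, p$k_B)  # curvature at the double-well minima
}

#' Toy alchemical campaign configuration
#'
#' Reduced units throughout (energies in kT when `temperature = 1`);
#' the Euler-Maruyama stability bound `dt * k_eff / friction < 0.1` is
#' enforced at construction.
#'
#' @param potential a [harmonic_potential()] or
#'   [double_well_potential()].
#' @param temperature reduced temperature (kT in the potential's energy
#'   unit; default 1).
#' @param friction Langevin friction gamma (> 0).
#' @param dt integration time step (> 0).
#' @param n_steps_switch steps per non-equilibrium switch; 0 means an
#'   instantaneous switch.
#' @param n_equil_samples length (steps) of the equilibrium stream used
#'   when starts are sampled by Langevin dynamics.
#' @param snapshot_count equilibrium snapshots (= transitions) per
#'   direction; must not exceed `n_equil_samples`.
#' @param seed mandatory integer seed.
#' @param init how end-state-A starts are drawn for double wells:
#'   `"exact"` (inverse-CDF draw from the Boltzmann distribution, the
#'   unbiased reference), `"left"` or `"right"` (a thinned Langevin
#'   stream started in that basin — with a high barrier this never
#'   crosses, emulating single-conformation initialization). Harmonic
#'   end states always use exact Gaussian draws.
#' @return object of class `toy_config`.
#' @export
toy_config <- function(potential, temperature = 1, friction = 1,
                       dt = 0.01, n_steps_switch = 1000L,
                       n_equil_samples = 10000L, snapshot_count = 100L,
                       seed, init = c("exact", "left", "right")) {
  stopifnot(inherits(potential, "toy_potential"),
            temperature > 0, friction > 0, dt > 0,
            n_steps_switch >= 0, snapshot_count >= 1)
  init <- match.arg(init)
  if (missing(seed)) stop("seed is mandatory")
  if (snapshot_count > n_equil_samples)
    stop("snapshot_count must not exceed n_equil_samples")
  if (dt * pot_keff(potential) / friction >= 0.1)
    stop("stability bound violated: dt * k_eff / friction must be < 0.1")
  structure(list(potential = potential, temperature = temperature,
                 friction = friction, dt = dt,
                 n_steps_switch = as.integer(n_steps_switch),
                 n_equil_samples = as.integer(n_equil_samples),
                 snapshot_count = as.integer(snapshot_count),
                 seed = as.integer(seed), init = init),
            class = "toy_config")
}

#' Analytic / quadrature free energy difference of a toy potential
#'
#' \eqn{\Delta F = -kT \ln(Z_B/Z_A)} between the lambda = 1 and
#' lambda = 0 end states. Harmonic pairs have the closed form
#' \eqn{\tfrac{kT}{2}\ln(k_B/k_A)}; the double-well case integrates the
#' two configurational integrals numerically (the built-in oracle).
#'
#' @param potential a `toy_potential`.
#' @param kT reduced temperature (default 1).
#' @return free energy difference in the same reduced energy unit.
#' @export
toy_free_energy <- function(potential, kT = 1) {
  stopifnot(inherits(potential, "toy_potential"), kT > 0)
  p <- potential
  if (p$type == "harmonic") return(0.5 * kT * log(p$k_B / p$k_A))
  span <- max(p$w, 1) * 8 + sqrt(kT / p$k_B) * 8 + abs(p$b)
  zA <- integrate(function(x) exp(-pot_energy(p, x, 0) / kT),
                  -span, span, rel.tol = 1e-10)$value
  zB <- integrate(function(x) exp(-pot_energy(p, x, 1) / kT),
                  -span, span, rel.tol = 1e-10)$value
  -kT * log(zB / zA)
}

# ---- equilibrium start sampling ----

# exact inverse-CDF draw from exp(-U(x, lam)/kT) on a fine grid
sample_boltzmann_grid <- function(p, lam, kT, n) {
  span <- max(p$w, 1) * 6 + sqrt(kT) * 6 + abs(p$b)
  xg <- seq(-span, span, length.out = 8192L)
  u <- pot_energy(p, xg, lam)
  dens <- exp(-(u - min(u)) / kT)
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0)
  approx(cdf[keep], xg[keep], xout = runif(n), rule = 2)$y
}

# thinned Langevin stream at fixed lambda, started at x_init
sample_stream <- function(p, lam, kT, cfg, x_init, n) {
  gam <- cfg$friction; dt <- cfg$dt
  burn <- ceiling(cfg$n_equil_samples / 10)
  total <- cfg$n_equil_samples + burn
  noise <- sqrt(2 * kT * dt / gam)
  x <- x_init
  out <- numeric(total)
  for (i in seq_len(total)) {
    x <- x - (dt / gam) * pot_dHdx(p, x, lam) + noise * rnorm(1L)
    out[i] <- x
  }
  kept <- out[(burn + 1):total]
  kept[round(seq(1, length(kept), length.out = n))]
}

# starts for the given direction's initial end state; assumes the RNG
# is already positioned (callers seed once per campaign/call)
draw_starts <- function(cfg, direction, n) {
  p <- cfg$potential
  kT <- cfg$temperature
  lam0 <- if (direction == "forward") 0 else 1
  if (p$type == "harmonic") {
    k <- (1 - lam0) * p$k_A + lam0 * p$k_B
    x0 <- (1 - lam0) * p$a + lam0 * p$b
    return(rnorm(n, mean = x0, sd = sqrt(kT / k)))
  }
  if (lam0 == 1)  # end state B is harmonic: exact draw
    return(rnorm(n, mean = p$b, sd = sqrt(kT / p$k_B)))
  switch(cfg$init,
         exact = sample_boltzmann_grid(p, 0, kT, n),
         left = sample_stream(p, 0, kT, cfg, -p$w, n),
         right = sample_stream(p, 0, kT, cfg, p$w, n))
}

# vectorised switching engine: one overdamped Langevin step per lambda
# increment, work accumulated by the trapezoid over the (x, lambda)
# pairs actually visited; lambda advances after the coordinate update.
switch_works <- function(cfg, direction, starts) {
  p <- cfg$potential
  kT <- cfg$temperature
  nst <- cfg$n_steps_switch
  lam0 <- if (direction == "forward") 0 else 1
  if (nst == 0L) {
    lam1 <- 1 - lam0
    return(pot_energy(p, starts, lam1) - pot_energy(p, starts, lam0))
  }
  dlam <- if (direction == "forward") 1 / nst else -1 / nst
  gam <- cfg$friction; dt <- cfg$dt
  noise <- sqrt(2 * kT * dt / gam)
  x <- starts
  n <- length(x)
  lam <- lam0
  w <- numeric(n)
  g0 <- pot_dHdl(p, x, lam)
  for (s in seq_len(nst)) {
    x <- x - (dt / gam) * pot_dHdx(p, x, lam) + noise * rnorm(n)
    lam <- lam + dlam
    g1 <- pot_dHdl(p, x, lam)
    w <- w + 0.5 * (g0 + g1) * dlam
    g0 <- g1
  }
  w
}

#' Simulate non-equilibrium switch work values
#'
#' Draws `n` equilibrium starts from the initial end state of the given
#' direction (exact Gaussian draws for harmonic states; see
#' [toy_config()] for double wells), then drives each through the
#' alchemical switch with overdamped Langevin dynamics
#' (Euler-Maruyama), lambda advancing linearly by \eqn{1/n_{steps}} per
#' step, accumulating the work \eqn{W = \sum \partial H/\partial\lambda
#' \,\Delta\lambda} by the trapezoid over visited states.
#' `n_steps_switch = 0` performs an instantaneous switch,
#' \eqn{W = H(x;\lambda_{end}) - H(x;\lambda_{start})}. Works follow
#' the as-performed sign convention, in reduced energy units.
#'
#' @param cfg a [toy_config()].
#' @param direction `"forward"` (lambda 0 to 1) or `"reverse"`.
#' @param n number of independent transitions.
#' @return numeric vector of `n` work values (reduced units).
#' @export
simulate_switch_work <- function(cfg, direction = c("forward", "reverse"),
                                 n = 1L) {
  stopifnot(inherits(cfg, "toy_config"))
  direction <- match.arg(direction)
  with_preserved_rng(function() {
    set.seed(cfg$seed + if (direction == "forward") 0L else 1L)
    starts <- draw_starts(cfg, direction, n)
    switch_works(cfg, direction, starts)
  })
}

#' Run a bidirectional toy campaign
#'
#' Mirrors the two-step non-equilibrium protocol: equilibrium sampling
#' of both physical end states, extraction of `snapshot_count`
#' equidistant snapshots per state, then one fixed-length switch per
#' snapshot in each direction. Returns the resulting [work_set()]
#' (exported at the reduced-unit temperature, so work values in kJ/mol
#' equal reduced works numerically when `temperature = 1`) together
#' with the analytic ground-truth free energy difference.
#'
#' @param cfg a [toy_config()].
#' @return list with elements `ws` (a [work_set()] with snapshot
#'   indices as origin times), `dg_true` (reduced units), and `config`.
#' @export
run_toy_campaign <- function(cfg) {
  stopifnot(inherits(cfg, "toy_config"))
  n <- cfg$snapshot_count
  with_preserved_rng(function() {
    set.seed(cfg$seed)
    wf <- switch_works(cfg, "forward", draw_starts(cfg, "forward", n))
    wr <- switch_works(cfg, "reverse", draw_starts(cfg, "reverse", n))
    ws <- work_set(wf, wr,
                   temperature = cfg$temperature / kB_kJmol,
                   origin_forward = seq_len(n), origin_reverse = seq_len(n))
    list(ws = ws, dg_true = toy_free_energy(cfg$potential, cfg$temperature),
         config = cfg)
  })
}

#' Crooks-consistent Gaussian work sample
#'
#' Generates forward and reverse work samples satisfying the Crooks
#' fluctuation theorem exactly at a known free energy difference:
#' forward works ~ Normal(dg + sigma^2/2, sigma^2), reverse works (as
#' performed) ~ Normal(-dg + sigma^2/2, sigma^2), all in kT. The two
#' Gaussians then obey \eqn{\ln[p_F(W)/p_R(-W)] = W - \Delta G} (in
#' kT), the symmetry every bi-directional estimator assumes.
#'
#' @param dg true free energy difference in kT.
#' @param sigma work distribution width in kT (>= 0; 0 is the
#'   reversible limit).
#' @param n_forward,n_reverse sample counts (>= 0, not both 0).
#' @param seed integer seed (mandatory; deterministic output).
#' @param temperature Kelvin at which the works are exported; default
#'   [reduced_temperature()], i.e. work values in kJ/mol numerically
#'   equal to kT units.
#' @return a [work_set()].
#' @export
gaussian_cft_sample <- function(dg, sigma, n_forward, n_reverse, seed,
                                temperature = reduced_temperature()) {
  stopifnot(sigma >= 0, n_forward >= 0, n_reverse >= 0,
            n_forward + n_reverse > 0)
  if (missing(seed)) stop("seed is mandatory")
  kT <- kT_kJmol(temperature)
  with_preserved_rng(function() {
    set.seed(seed)
    wf <- if (n_forward > 0) rnorm(n_forward, dg + sigma^2 / 2, sigma) * kT
    wr <- if (n_reverse > 0) rnorm(n_reverse, -dg + sigma^2 / 2, sigma) * kT
    work_set(w_forward = if (is.null(wf)) numeric(0) else wf,
             w_reverse = if (is.null(wr)) numeric(0) else wr,
             temperature = temperature,
             origin_forward = if (!is.null(wf)) seq_len(n_forward),
             origin_reverse = if (!is.null(wr)) seq_len(n_reverse))
  })
}
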