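test_that("jarzynski reproduces closed-form cases", {
  # constant works: the exponential average collapses
  # at the reduced temperature kT = 1 kJ/mol, so works in kT == kJ/mol
  expect_equal(jarzynski(c(2, 2, 2), "forward", kT0,
                         bootstrap = FALSE)$dg, 2)
  expect_equal(jarzynski(c(0, 2), "forward", kT0, bootstrap = FALSE)$dg,
               -log((1 + exp(-2)) / 2))
  # reverse works as performed: dG of the forward process
  expect_equal(jarzynski(c(3, 3), "reverse", kT0, bootstrap = FALSE)$dg, -3)
  expect_error(jarzynski(numeric(0), "forward", kT0), "no samples")

  # n = 1: se degenerate-zero
  e1 <- jarzynski(5, "forward", kT0)
  expect_equal(e1$se, 0)
  expect_true(e1$se_degenerate)

  # log-sum-exp shift: huge works do not overflow
  expect_equal(jarzynski(c(2000, 2000), "forward", kT0,
                         bootstrap = FALSE)$dg, 2000)
})

test_that("bar reproduces closed forms and validates input", {
  # symmetric dissipation
  ws <- work_set(1, 1, temperature = kT0)
  expect_equal(suppressWarnings(bar(ws, convergence = FALSE)$dg), 0)
  # n = 1 each: f = (uF - uR)/2
  ws2 <- work_set(3, -1, temperature = kT0)
  e <- suppressWarnings(bar(ws2, convergence = FALSE))
  expect_equal(e$dg, 2)
  expect_equal(e$se, 0)
  expect_true(e$se_degenerate)

  expect_error(bar(work_set(w_forward = 1:3, temperature = kT0)),
               "jarzynski")
})

test_that("bar recovers the truth on Crooks-consistent samples", {
  ws <- gaussian_cft_sample(dg = 5, sigma = 2, n_forward = 2000,
                            n_reverse = 2000, seed = 42)
  est <- bar(ws, n_boot = 200, seed = 1)
  expect_lt(abs(est$dg - 5), 3 * est$se)
  expect_gt(est$se, 0)
  # convergence measure near 0 for well-overlapping samples
  expect_lt(abs(est$convergence), 0.05)
})

test_that("bar is antisymmetric and shift-covariant", {
  for (seed in 1:10) {
    ws <- gaussian_cft_sample(dg = runif(1, -4, 4), sigma = runif(1, .5, 3),
                              n_forward = 40 + seed, n_reverse = 60,
                              seed = seed)
    f <- bar(ws, bootstrap = FALSE, convergence = FALSE)$dg
    swapped <- work_set(ws$w_reverse, ws$w_forward, ws$temperature)
    expect_equal(bar(swapped, bootstrap = FALSE, convergence = FALSE)$dg,
                 -f, tolerance = 1e-7)
    cshift <- 2.5  # kT (= kJ/mol at the reduced temperature)
    shifted <- work_set(ws$w_forward + cshift, ws$w_reverse - cshift,
                        ws$temperature)
    expect_equal(bar(shifted, bootstrap = FALSE, convergence = FALSE)$dg,
                 f + cshift, tolerance = 1e-7)
  }
})

test_that("bar agrees with the independent likelihood-maximisation oracle", {
  for (seed in 1:20) {
    set.seed(seed + 1000)
    nF <- sample(5:200, 1); nR <- sample(5:200, 1)
    uF <- rnorm(nF, runif(1, -3, 6), runif(1, 0.3, 3))
    uR <- rnorm(nR, runif(1, -6, 3), runif(1, 0.3, 3))
    ws <- work_set(uF, uR, temperature = kT0)
    expect_equal(bar(ws, bootstrap = FALSE, convergence = FALSE)$dg,
                 oracle_bar_loglik(uF, uR), tolerance = 1e-6)
  }
})

test_that("jarzynski forward is biased above for dissipative samples", {
  # Jensen bias of the exponential average: uni-directional estimates
  # overestimate dG for finite dissipative samples
  errs <- vapply(1:200, function(s) {
    ws <- gaussian_cft_sample(dg = 5, sigma = 2, n_forward = 50,
                              n_reverse = 0, seed = 5000 + s)
    jarzynski(ws$w_forward, "forward", kT0, bootstrap = FALSE)$dg - 5
  }, numeric(1))
  expect_gt(mean(errs), 0)
  expect_gt(mean(errs) / (sd(errs) / sqrt(length(errs))), 3)
})

test_that("Gaussian limit identities hold at large n", {
  ws <- gaussian_cft_sample(dg = 3, sigma = 1.5, n_forward = 1e5,
                            n_reverse = 0, seed = 99)
  est <- jarzynski(ws$w_forward, "forward", kT0, n_boot = 100, seed = 2)
  expect_lt(abs(est$dg - 3), 3 * max(est$se, 1e-3))
  # second-order cumulant identity: <W> - sigma^2/2 -> dG
  expect_lt(abs(mean(ws$w_forward) - 1.5^2 / 2 - 3),
            3 * sd(ws$w_forward) / sqrt(1e5))
})

test_that("bootstrap_se is deterministic and matches brute force", {
  ws <- gaussian_cft_sample(dg = 1, sigma = 1, n_forward = 40,
                            n_reverse = 40, seed = 11)
  # determinism
  s1 <- bootstrap_se(ws, "bar", n_boot = 100, seed = 7)
  expect_identical(s1, bootstrap_se(ws, "bar", n_boot = 100, seed = 7))
  expect_false(isTRUE(all.equal(
    s1, bootstrap_se(ws, "bar", n_boot = 100, seed = 8))))

  # identical works in both directions: no variance at all
  ws0 <- work_set(rep(2, 10), rep(-2, 10), temperature = kT0)
  expect_equal(bootstrap_se(ws0, "bar", n_boot = 50, seed = 1), 0)
  expect_equal(bootstrap_se(ws0, "jarzynski_forward", n_boot = 50,
                            seed = 1), 0)

  # matched seed-splitting: the brute-force second implementation
  # reproduces the replicate stream exactly
  # (1e-6 kT slack: the oracle maximises the likelihood rather than
  # solving the score equation, so the roots differ at solver tolerance)
  for (est in c("bar", "jarzynski_forward", "jarzynski_reverse")) {
    expect_equal(bootstrap_se(ws, est, n_boot = 200, seed = 3),
                 oracle_bootstrap_se(ws, est, 200, 3), tolerance = 1e-6)
  }

  # independent streams agree within 5% (spec example: forward {0, 2} kT)
  wsj <- work_set(w_forward = c(0, 2), temperature = kT0)
  a <- bootstrap_se(wsj, "jarzynski_forward", n_boot = 4000, seed = 21)
  b <- oracle_bootstrap_se(wsj, "jarzynski_forward", 4000, 90021)
  expect_lt(abs(a - b) / b, 0.05)
})

test_that("bootstrap_se leaves the caller RNG untouched", {
  set.seed(99)
  ws <- work_set(rnorm(10) + 9, rnorm(10) - 9, temperature = kT0)
  set.seed(123); before <- .Random.seed
  invisible(bootstrap_se(ws, "bar", n_boot = 20, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("chain_windows adds window estimates and propagates errors", {
  # degenerate windows with known per-window dG and zero se
  win <- function(dg) work_set(dg, -dg, temperature = kT0)
  est <- suppressWarnings(chain_windows(list(win(1), win(2), win(-0.5)),
                                        method = "bar"))
  expect_equal(est$dg, 2.5)
  expect_equal(est$se, 0)
  expect_equal(est$method, "bar_chain")

  # single window == the one-window estimate
  ws <- gaussian_cft_sample(2, 1, 50, 50, seed = 3)
  single <- chain_windows(list(ws), method = "bar", n_boot = 100, seed = 4)
  direct <- bar(ws, n_boot = 100, seed = 5, convergence = FALSE)
  expect_equal(single$dg, direct$dg)

  # zwanzig chaining: constant dU windows are exact with zero variance
  zw <- chain_windows(list(rep(1.5, 5), rep(-0.5, 5)), method = "zwanzig",
                      temperature = kT0, n_boot = 50, seed = 1)
  expect_equal(zw$dg, 1.0)
  expect_equal(zw$se, 0)
  expect_equal(zw$method, "zwanzig_chain")

  # failures name the window
  expect_error(
    suppressWarnings(chain_windows(
      list(win(1), work_set(w_forward = 1, temperature = kT0)),
      method = "bar")),
    "window 2")
  expect_error(chain_windows(list(), method = "bar"), "non-empty")
})

test_that("staged and single-stage estimates agree on the toy system", {
  # harmonic half-steps built directly from Boltzmann draws
  # (instantaneous switching): window [0, 0.5] then [0.5, 1]
  kA <- 1; kB <- 4
  kmid <- 0.5 * (kA + kB)
  set.seed(17)
  n <- 4000
  # duF(k0, k1): work (as performed) of an instantaneous k0 -> k1
  # switch started from the k0 equilibrium; reverse windows use the
  # same construction from the other end state, unnegated
  duF <- function(k0, k1) {
    x <- rnorm(n, 0, sqrt(1 / k0)); 0.5 * (k1 - k0) * x^2
  }
  win1 <- work_set(duF(kA, kmid), duF(kmid, kA), temperature = kT0)
  win2 <- work_set(duF(kmid, kB), duF(kB, kmid), temperature = kT0)
  wsingle <- work_set(duF(kA, kB), duF(kB, kA), temperature = kT0)
  chain <- chain_windows(list(win1, win2), method = "bar",
                         n_boot = 100, seed = 6)
  single <- bar(wsingle, n_boot = 100, seed = 7, convergence = FALSE)
  expect_lt(abs(chain$dg - single$dg),
            3 * sqrt(chain$se^2 + single$se^2))
  expect_lt(abs(chain$dg - 0.5 * log(kB / kA)), 3 * chain$se)
})
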