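#' Boresch-style orientational restraint definition
#'
#' One distance, two angles, and three dihedrals restraining a decoupled
#' ligand to its binding pose, each with a harmonic force constant and a
#' reference value. Distances are in Angstrom, angles in radians, force
#' constants in kcal/mol/A^2 (distance) and kcal/mol/rad^2 (angles and
#' dihedrals).
#'
#' @param r0 reference distance (A, > 0).
#' @param thetaA0,thetaB0 reference angles (rad, strictly inside
#'   (0, pi): the analytical correction diverges at sin(theta) = 0).
#' @param kr distance force constant (kcal/mol/A^2).
#' @param kthA,kthB angle force constants (kcal/mol/rad^2).
#' @param kphiA,kphiB,kphiC dihedral force constants (kcal/mol/rad^2).
#' @param temperature Kelvin.
#' @param v0 standard-state volume in A^3; default 1660 (1 M).
#' @return object of class `boresch_restraint`.
#' @export
boresch_restraint <- function(r0, thetaA0, thetaB0, kr, kthA, kthB,
                              kphiA, kphiB, kphiC,
                              temperature = 298.15, v0 = 1660) {
  ks <- c(kr = kr, kthA = kthA, kthB = kthB,
          kphiA = kphiA, kphiB = kphiB, kphiC = kphiC)
  if (any(!is.finite(ks)) || any(ks <= 0))
    stop("all force constants must be positive")
  if (!is.finite(r0) || r0 <= 0) stop("r0 must be positive")
  for (th in c(thetaA0, thetaB0))
    if (!is.finite(th) || th <= 0 || th >= pi || sin(th) == 0)
      stop("reference angles must lie strictly inside (0, pi)")
  stopifnot(temperature > 0, v0 > 0)
  structure(list(r0 = r0, thetaA0 = thetaA0, thetaB0 = thetaB0,
                 kr = kr, kthA = kthA, kthB = kthB, kphiA = kphiA,
                 kphiB = kphiB, kphiC = kphiC,
                 temperature = temperature, v0 = v0),
            class = "boresch_restraint")
}

#' Analytical standard-state restraint correction
#'
#' Free energy of releasing a Boresch-restrained, decoupled ligand to
#' the standard-state volume, in the stiff-spring approximation:
#' \deqn{\Delta G_{restr} = -kT \ln\left[\frac{8\pi^2 V^0
#'   \sqrt{K_r K_{\theta A} K_{\theta B} K_{\phi A} K_{\phi B}
#'   K_{\phi C}}}{r_0^2 \sin\theta_{A0} \sin\theta_{B0}
#'   (2\pi kT)^3}\right]}
#'
#' Unit bookkeeping: with kT in kcal/mol, force constants in
#' kcal/mol/A^2 and kcal/mol/rad^2, r0 in A and V0 in A^3, the square
#' root carries kcal^3 mol^-3 A^-1 rad^-5, the prefactor
#' \eqn{V^0/r_0^2} carries A, and \eqn{(2\pi kT)^3} carries kcal^3
#' mol^-3, so the logarithm's argument is dimensionless (radians being
#' dimensionless). The returned sign is the one that enters the binding
#' cycle additively with the protein-coupling leg (see
#' [assemble_cycle()]): for typical stiff restraints the value is
#' negative.
#'
#' @param r a [boresch_restraint()].
#' @return \eqn{\Delta G_{restr}} in kcal/mol.
#' @export
boresch_dg <- function(r) {
  stopifnot(inherits(r, "boresch_restraint"))
  kT <- kJ_to_kcal(kT_kJmol(r$temperature))  # kcal/mol
  arg <- 8 * pi^2 * r$v0 *
    sqrt(r$kr * r$kthA * r$kthB * r$kphiA * r$kphiB * r$kphiC) /
    (r$r0^2 * sin(r$thetaA0) * sin(r$thetaB0) * (2 * pi * kT)^3)
  -kT * log(arg)
}

#' Combine independent calculation repeats into one estimate
#'
#' Each repeat's estimate is treated as a normal distribution with mean
#' equal to its free energy and standard deviation equal to its
#' (bootstrapped) uncertainty. The combined estimate is the mean of the
#' repeat means; the combined uncertainty is the standard error across
#' the mixture of those normals, which incorporates both the estimator
#' uncertainty and the variance of the repeated calculations:
#' \deqn{\sigma_{mix}^2 = \overline{se_i^2} + \mathrm{var}(dg_i),
#'   \qquad se = \sigma_{mix}/\sqrt{n}}
#' with the between-repeat variance using the n-1 denominator (0 when
#' n = 1).
#'
#' @param dg numeric vector of repeat estimates (any consistent unit).
#' @param se numeric vector of per-repeat standard errors (>= 0),
#'   recycled if scalar.
#' @return list with elements `dg`, `se`, `n`.
#' @export
combine_repeats <- function(dg, se = 0) {
  dg <- as.numeric(dg)
  if (length(dg) == 0L) stop("at least one repeat is required")
  se <- rep_len(as.numeric(se), length(dg))
  if (any(se < 0)) stop("standard errors must be >= 0")
  n <- length(dg)
  between <- if (n > 1L) var(dg) else 0
  mix_var <- mean(se^2) + between
  list(dg = mean(dg), se = sqrt(mix_var) / sqrt(n), n = n)
}

#' One leg of a thermodynamic cycle
#'
#' @param name leg name: `"solv"` (ligand coupling in water), `"prot"`
#'   (coupling of the restrained ligand in the protein), `"restr"`
#'   (analytical restraint release to standard state), or `"custom"`.
#' @param dg free energy of the leg (consistent units across legs).
#' @param se standard error (>= 0).
#' @param sign +1 or -1, the coefficient in the cycle sum. Defaults by
#'   name to the absolute-binding preset: solv -1, prot +1, restr +1;
#'   required for `"custom"`.
#' @return object of class `cycle_leg`.
#' @export
cycle_leg <- function(name = c("solv", "prot", "restr", "custom"),
                      dg, se = 0, sign = NULL) {
  name <- match.arg(name)
  if (is.null(sign)) {
    sign <- switch(name, solv = -1, prot = +1, restr = +1,
                   custom = stop("sign is required for a custom leg"))
  }
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  if (se < 0) stop("se must be >= 0")
  structure(list(name = name, dg = dg, se = se, sign = sign),
            class = "cycle_leg")
}

#' Assemble a thermodynamic cycle into a binding free energy
#'
#' Sums the legs with their signs and propagates the uncertainties in
#' quadrature: \eqn{\Delta G_{bind} = \sum_i s_i\,dg_i},
#' \eqn{se = \sqrt{\sum_i se_i^2}}. The default leg signs implement the
#' absolute-binding convention \eqn{\Delta G_{bind} = \Delta G_{prot} -
#' \Delta G_{solv} + \Delta G_{restr}}, where "prot" couples the
#' restrained ligand in the protein, "solv" couples the ligand in
#' water, and "restr" releases the restraints to the standard state.
#'
#' @param legs list of [cycle_leg()] objects (>= 1, names unique).
#' @return list with `dg`, `se`, and a `legs` data frame.
#' @export
assemble_cycle <- function(legs) {
  if (!is.list(legs) || length(legs) == 0L)
    stop("at least one leg is required")
  if (!all(vapply(legs, inherits, logical(1), "cycle_leg")))
    stop("legs must be cycle_leg objects")
  nm <- vapply(legs, `[[`, character(1), "name")
  dup <- nm[duplicated(nm) & nm != "custom"]
  if (length(dup)) stop("duplicate legs: ", paste(unique(dup), collapse = ", "))
  dg <- vapply(legs, `[[`, numeric(1), "dg")
  se <- vapply(legs, `[[`, numeric(1), "se")
  sg <- vapply(legs, `[[`, numeric(1), "sign")
  list(dg = sum(sg * dg), se = sqrt(sum(se^2)),
       legs = data.frame(name = nm, dg = dg, se = se, sign = sg))
}
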