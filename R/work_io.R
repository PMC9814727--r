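#' dH/dlambda trace from a single non-equilibrium transition
#'
#' A `dhdl_trace` holds the time series of the Hamiltonian derivative
#' \eqn{\partial H/\partial\lambda} recorded while one alchemical
#' transition was driven between the end states. Times are in ps,
#' derivatives in kJ/mol. The lambda schedule may be attached at
#' construction (explicit per-sample lambda values) or later at
#' integration time (linear-in-time schedule).
#'
#' @param times numeric, simulation times in ps, strictly increasing.
#' @param dhdl numeric, \eqn{\partial H/\partial\lambda} in kJ/mol,
#'   same length as `times`.
#' @param direction `"forward"` (lambda 0 to 1) or `"reverse"`
#'   (lambda 1 to 0).
#' @param lam optional numeric lambda value per sample, in \[0, 1\],
#'   monotone non-decreasing for forward traces and non-increasing for
#'   reverse traces.
#' @param origin_time optional time (ns) of the equilibrium snapshot
#'   this transition was started from.
#' @return an object of class `dhdl_trace`.
#' @seealso [parse_dhdl_xvg()], [integrate_work()]
#' @export
dhdl_trace <- function(times, dhdl, direction = c("forward", "reverse"),
                       lam = NULL, origin_time = NA_real_) {
  direction <- match.arg(direction)
  times <- as.numeric(times)
  dhdl <- as.numeric(dhdl)
  if (length(times) != length(dhdl))
    stop("times and dhdl must have the same length")
  if (length(times) < 2L) stop("insufficient samples: need at least 2")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(lam)) {
    lam <- as.numeric(lam)
    if (length(lam) != length(times))
      stop("lam must have the same length as times")
    if (any(lam < 0 | lam > 1)) stop("lambda values must lie in [0, 1]")
    d <- diff(lam)
    if (direction == "forward" && any(d < 0))
      stop("lambda must be monotone non-decreasing for a forward trace")
    if (direction == "reverse" && any(d > 0))
      stop("lambda must be monotone non-increasing for a reverse trace")
  }
  structure(list(times = times, dhdl = dhdl, lam = lam,
                 direction = direction,
                 origin_time = as.numeric(origin_time)),
            class = "dhdl_trace")
}

#' @export
print.dhdl_trace <- function(x, ...) {
  cat(sprintf("dhdl_trace: %d samples, %s, t = [%g, %g] ps%s\n",
              length(x$times), x$direction, x$times[1],
              x$times[length(x$times)],
              if (is.null(x$lam)) " (no lambda column)" else ""))
  invisible(x)
}

#' Parse a dH/dlambda XVG file
#'
#' Reads the xmgrace-dialect files written by MD engines alongside each
#' alchemical transition: lines starting with `#` or `@` are metadata and
#' are skipped; data lines are whitespace-separated numbers with column 1
#' the time (ps) and column 2 the \eqn{\partial H/\partial\lambda}
#' (kJ/mol). Duplicate time stamps (restarted trajectories appending
#' corrected frames) are deduplicated keeping the last occurrence.
#'
#' @param file path to an XVG file; ignored when `text` is given.
#' @param text optional character scalar or vector holding the file
#'   contents directly.
#' @param direction transition direction, passed to [dhdl_trace()].
#' @param origin_time optional snapshot origin time (ns).
#' @param dhdl_columns integer vector of the data columns summed to form
#'   the Hamiltonian derivative (default `2`, the single-coordinate
#'   decoupling setting; multi-component lambda files can sum `2:k`).
#' @return a [dhdl_trace()].
#' @export
parse_dhdl_xvg <- function(file = NULL, text = NULL,
                           direction = c("forward", "reverse"),
                           origin_time = NA_real_, dhdl_columns = 2L) {
  direction <- match.arg(direction)
  if (is.null(text)) {
    if (is.null(file)) stop("either file or text must be given")
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  dhdl_columns <- as.integer(dhdl_columns)
  if (any(dhdl_columns < 2L)) stop("dhdl_columns must be >= 2")

  is_meta <- grepl("^\\s*[#@]", lines) | !nzchar(trimws(lines))
  data_idx <- which(!is_meta)
  if (length(data_idx) == 0L) stop("no samples")

  ncol_needed <- max(dhdl_columns)
  tm <- numeric(length(data_idx))
  dh <- numeric(length(data_idx))
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (anyNA(vals))
      stop(sprintf("parse error at line %d: non-numeric token '%s'",
                   i, tok[which(is.na(vals))[1]]))
    if (length(vals) < ncol_needed)
      stop(sprintf("parse error at line %d: expected at least %d columns, found %d",
                   i, ncol_needed, length(vals)))
    tm[k] <- vals[1]
    dh[k] <- sum(vals[dhdl_columns])
  }

  # duplicate timestamps: keep the last occurrence
  keep <- !duplicated(tm, fromLast = TRUE)
  tm <- tm[keep]; dh <- dh[keep]
  ord <- order(tm)
  tm <- tm[ord]; dh <- dh[ord]
  if (length(tm) < 2L) stop("insufficient samples: need at least 2")

  dhdl_trace(tm, dh, direction = direction, origin_time = origin_time)
}

#' Integrate a dH/dlambda trace into a work value
#'
#' Trapezoidal integration of \eqn{\partial H/\partial\lambda} over
#' lambda yields the work performed on the system during the transition,
#' in its own direction: forward transitions integrate from lambda 0 to
#' 1, reverse transitions from 1 to 0 (so a reversible reverse
#' transition yields \eqn{W_R = -\Delta G}). This "work as performed"
#' sign convention makes the Crooks symmetry explicit and is assumed by
#' [bar()], [jarzynski()] and [gaussian_cft_sample()].
#'
#' When the trace carries no explicit lambda column (and `lam` is not
#' supplied), a linear-in-time schedule over `[t0, t1]` is used:
#' \eqn{\lambda_i = (t_i - t_0)/(t_1 - t_0)}, mirrored for reverse
#' traces. This matches transitions driven at constant rate over a fixed
#' switching time.
#'
#' @param trace a [dhdl_trace()].
#' @param t0,t1 start/end times (ps) of the linear schedule; default the
#'   first and last sample times.
#' @param lam optional explicit per-sample lambda values, overriding both
#'   the trace's lambda column and the linear schedule.
#' @return work in kJ/mol (scalar).
#' @export
integrate_work <- function(trace, t0 = NULL, t1 = NULL, lam = NULL) {
  stopifnot(inherits(trace, "dhdl_trace"))
  n <- length(trace$times)
  if (is.null(lam)) lam <- trace$lam
  if (is.null(lam)) {
    if (is.null(t0)) t0 <- trace$times[1]
    if (is.null(t1)) t1 <- trace$times[n]
    if (t1 == t0) stop("degenerate schedule: t1 == t0")
    lam <- (trace$times - t0) / (t1 - t0)
    if (trace$direction == "reverse") lam <- 1 - lam
  } else {
    lam <- as.numeric(lam)
    if (length(lam) != n) stop("lam must match the trace length")
  }
  d <- diff(lam)
  if (trace$direction == "forward" && any(d < 0))
    stop("non-monotone lambda: forward trace requires non-decreasing lambda")
  if (trace$direction == "reverse" && any(d > 0))
    stop("non-monotone lambda: reverse trace requires non-increasing lambda")
  y <- trace$dhdl
  sum(0.5 * (y[-1] + y[-n]) * d)
}

#' Forward and reverse work samples at a stated temperature
#'
#' Container for the work values (kJ/mol) of many independent
#' non-equilibrium transitions in the two switching directions, with
#' optional per-transition equilibrium snapshot origin times (ns). Works
#' follow the "as performed" sign convention of [integrate_work()].
#'
#' @param w_forward,w_reverse numeric work values (kJ/mol) for
#'   0-to-1 and 1-to-0 transitions; at least one direction non-empty.
#' @param temperature temperature in Kelvin (> 0).
#' @param origin_forward,origin_reverse optional numeric snapshot origin
#'   times (ns), one per work value.
#' @return an object of class `work_set`.
#' @export
work_set <- function(w_forward = numeric(0), w_reverse = numeric(0),
                     temperature, origin_forward = NULL,
                     origin_reverse = NULL) {
  w_forward <- as.numeric(w_forward)
  w_reverse <- as.numeric(w_reverse)
  if (length(w_forward) == 0L && length(w_reverse) == 0L)
    stop("at least one direction must be non-empty")
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a single positive number (Kelvin)")
  if (anyNA(w_forward) || anyNA(w_reverse))
    stop("work values must be finite")
  chk_origin <- function(o, w, what) {
    if (is.null(o)) return(NULL)
    o <- as.numeric(o)
    if (length(o) != length(w))
      stop(sprintf("origin_%s must have one entry per %s work", what, what))
    o
  }
  structure(list(
    w_forward = w_forward, w_reverse = w_reverse,
    temperature = temperature,
    origin_forward = chk_origin(origin_forward, w_forward, "forward"),
    origin_reverse = chk_origin(origin_reverse, w_reverse, "reverse")),
    class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  kT <- kT_kJmol(x$temperature)
  cat(sprintf("work_set: %d forward, %d reverse works at %.2f K (kT = %.4f kJ/mol)\n",
              length(x$w_forward), length(x$w_reverse), x$temperature, kT))
  if (length(x$w_forward))
    cat(sprintf("  <W_F> = %.3f kJ/mol\n", mean(x$w_forward)))
  if (length(x$w_reverse))
    cat(sprintf("  <W_R> = %.3f kJ/mol\n", mean(x$w_reverse)))
  invisible(x)
}

# reduced works u = W / kT for one direction
reduced_works <- function(ws, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  w <- if (direction == "forward") ws$w_forward else ws$w_reverse
  w / kT_kJmol(ws$temperature)
}

#' Truncate a work set to an initial fraction of the equilibrium sampling
#'
#' Emulates shorter equilibrium simulations: only transitions launched
#' from snapshots within the first `fraction` of the sampled equilibrium
#' time are retained (origin_time <= fraction * max origin time, the
#' maximum taken over all transitions), each direction filtered
#' independently. Used to trace estimate bias and accuracy against
#' invested sampling time.
#'
#' @param ws a [work_set()] with origin times for every work value.
#' @param fraction number in (0, 1\].
#' @return a [work_set()] with the surviving transitions.
#' @export
truncate_workset <- function(ws, fraction) {
  stopifnot(inherits(ws, "work_set"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be a single number in (0, 1]")
  has_f <- length(ws$w_forward) > 0L
  has_r <- length(ws$w_reverse) > 0L
  if ((has_f && is.null(ws$origin_forward)) ||
      (has_r && is.null(ws$origin_reverse)))
    stop("origin times are required for every work value")
  tmax <- max(c(ws$origin_forward, ws$origin_reverse))
  thr <- fraction * tmax
  kf <- if (has_f) ws$origin_forward <= thr else logical(0)
  kr <- if (has_r) ws$origin_reverse <= thr else logical(0)
  if (!any(kf) && !any(kr)) stop("no transitions survive truncation")
  work_set(ws$w_forward[kf], ws$w_reverse[kr],
           temperature = ws$temperature,
           origin_forward = if (has_f && any(kf)) ws$origin_forward[kf],
           origin_reverse = if (has_r && any(kr)) ws$origin_reverse[kr])
}

#' Write a work set to CSV
#'
#' Columns: `direction`, `origin_time_ns`, `work_kJmol` — the schema
#' shared by the command-line tools.
#'
#' @param ws a [work_set()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_works_csv <- function(ws, file) {
  stopifnot(inherits(ws, "work_set"))
  nf <- length(ws$w_forward); nr <- length(ws$w_reverse)
  df <- data.frame(
    direction = c(rep("forward", nf), rep("reverse", nr)),
    origin_time_ns = c(
      if (is.null(ws$origin_forward)) rep(NA_real_, nf) else ws$origin_forward,
      if (is.null(ws$origin_reverse)) rep(NA_real_, nr) else ws$origin_reverse),
    work_kJmol = c(ws$w_forward, ws$w_reverse))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read a work set from CSV
#'
#' @param file CSV path with columns `direction`, `origin_time_ns`,
#'   `work_kJmol` (as written by [write_works_csv()]).
#' @param temperature temperature in Kelvin to attach to the set.
#' @return a [work_set()].
#' @export
read_works_csv <- function(file, temperature) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("direction", "work_kJmol")
  if (!all(need %in% names(df)))
    stop("works CSV must have columns direction and work_kJmol")
  if (nrow(df) == 0L) stop("no samples")
  f <- df$direction == "forward"
  r <- df$direction == "reverse"
  if (!all(f | r)) stop("direction must be 'forward' or 'reverse'")
  orig <- if ("origin_time_ns" %in% names(df)) df$origin_time_ns else
    rep(NA_real_, nrow(df))
  of <- orig[f]; or <- orig[r]
  work_set(df$work_kJmol[f], df$work_kJmol[r], temperature = temperature,
           origin_forward = if (any(f) && !anyNA(of)) of,
           origin_reverse = if (any(r) && !anyNA(or)) or)
}
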