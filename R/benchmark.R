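#' Benchmark table of calculated vs reference free energies
#'
#' One row per system: calculated free energy, its standard error, and
#' the experimental (or other) reference value, all in one declared
#' unit.
#'
#' @param system character system identifiers, unique.
#' @param dg_calc calculated free energies.
#' @param dg_ref reference free energies.
#' @param se_calc standard errors of the calculated values (>= 0),
#'   recycled if scalar.
#' @param unit `"kJ"` or `"kcal"` (per mol); informational, metrics are
#'   unit-covariant.
#' @return a `data.frame` of class `benchmark_table` with attribute
#'   `unit`.
#' @export
benchmark_table <- function(system, dg_calc, dg_ref, se_calc = 0,
                            unit = c("kcal", "kJ")) {
  unit <- match.arg(unit)
  system <- as.character(system)
  if (anyDuplicated(system)) stop("duplicate system ids")
  dg_calc <- as.numeric(dg_calc)
  dg_ref <- as.numeric(dg_ref)
  se_calc <- rep_len(as.numeric(se_calc), length(system))
  if (length(dg_calc) != length(system) || length(dg_ref) != length(system))
    stop("system, dg_calc and dg_ref must have equal lengths")
  if (any(se_calc < 0)) stop("se_calc must be >= 0")
  out <- data.frame(system = system, dg_calc = dg_calc,
                    se_calc = se_calc, dg_ref = dg_ref,
                    stringsAsFactors = FALSE)
  attr(out, "unit") <- unit
  class(out) <- c("benchmark_table", "data.frame")
  out
}

# Kendall tau-b and Spearman with average ranks come from stats::cor;
# constant columns make correlations undefined (flagged, not an error).
metric_value <- function(calc, ref, metric) {
  switch(metric,
         aue = mean(abs(calc - ref)),
         rmse = sqrt(mean((calc - ref)^2)),
         pearson = suppressWarnings(cor(calc, ref, method = "pearson")),
         spearman = suppressWarnings(cor(calc, ref, method = "spearman")),
         kendall = suppressWarnings(cor(calc, ref, method = "kendall")),
         stop("unknown metric: ", metric))
}

#' Accuracy metrics of calculated vs reference values
#'
#' Average unsigned error (AUE), root-mean-squared error (RMSE), and the
#' Pearson, Spearman (average ranks for ties), and Kendall tau-b
#' (tie-corrected) correlations between the calculated and reference
#' columns of a benchmark table. A constant column makes the
#' correlations undefined; they are reported as `NA` with
#' `correlations_defined = FALSE` rather than raising an error.
#'
#' @param t a [benchmark_table()] (>= 1 row; >= 2 rows for
#'   correlations).
#' @return list of class `accuracy_metrics`: `n`, `aue`, `rmse`,
#'   `pearson`, `spearman`, `kendall`, `correlations_defined`, `unit`.
#' @export
accuracy_metrics <- function(t) {
  stopifnot(inherits(t, "benchmark_table"), nrow(t) >= 1L)
  calc <- t$dg_calc; ref <- t$dg_ref
  out <- list(n = nrow(t),
              aue = metric_value(calc, ref, "aue"),
              rmse = metric_value(calc, ref, "rmse"))
  if (nrow(t) >= 2L && sd(calc) > 0 && sd(ref) > 0) {
    out$pearson <- metric_value(calc, ref, "pearson")
    out$spearman <- metric_value(calc, ref, "spearman")
    out$kendall <- metric_value(calc, ref, "kendall")
    out$correlations_defined <- TRUE
  } else {
    out[c("pearson", "spearman", "kendall")] <- NA_real_
    out$correlations_defined <- FALSE
  }
  out$unit <- attr(t, "unit")
  class(out) <- "accuracy_metrics"
  out
}

#' @export
print.accuracy_metrics <- function(x, ...) {
  cat(sprintf("n = %d: AUE = %.4f, RMSE = %.4f %s/mol\n",
              x$n, x$aue, x$rmse, x$unit))
  if (x$correlations_defined)
    cat(sprintf("  Pearson = %.4f, Spearman = %.4f, Kendall tau-b = %.4f\n",
                x$pearson, x$spearman, x$kendall))
  else
    cat("  correlations undefined (constant column)\n")
  invisible(x)
}

#' Combined parametric and non-parametric bootstrap of a metric
#'
#' Error bars for accuracy metrics that account both for the variation
#' in the dataset and for the uncertainty of the individual estimates:
#' each iteration resamples rows with replacement (non-parametric) and
#' then, for each drawn row, redraws the calculated value from a normal
#' distribution with its stated mean and standard error (parametric).
#' Reference values are treated as fixed, since experimental references
#' typically come without uncertainties; supply `ref_se` to perturb
#' them too. Iterations on which a correlation is undefined (constant
#' resample) are discarded; more than 20% discards is an error.
#'
#' @param t a [benchmark_table()] with `se_calc` present.
#' @param metric `"aue"`, `"rmse"`, `"pearson"`, `"spearman"`, or
#'   `"kendall"`.
#' @param n_boot iterations (>= 2, default 1000).
#' @param seed integer seed; replicate streams derive from
#'   `seed + iteration`.
#' @param ref_se optional per-row standard errors for the reference
#'   column.
#' @return list with `metric` (point value on the original table),
#'   `se`, `n_boot`, `n_discarded`.
#' @export
bootstrap_metric_se <- function(t, metric = c("aue", "rmse", "pearson",
                                              "spearman", "kendall"),
                                n_boot = 1000L, seed = 1L, ref_se = NULL) {
  stopifnot(inherits(t, "benchmark_table"))
  metric <- match.arg(metric)
  n_boot <- as.integer(n_boot)
  if (n_boot < 2L) stop("n_boot must be >= 2")
  n <- nrow(t)
  if (!is.null(ref_se)) ref_se <- rep_len(as.numeric(ref_se), n)
  point <- metric_value(t$dg_calc, t$dg_ref, metric)
  reps <- with_preserved_rng(function() {
    vapply(seq_len(n_boot), function(r) {
      set.seed((seed + r) %% .Machine$integer.max)
      idx <- sample.int(n, replace = TRUE)
      calc <- rnorm(n, mean = t$dg_calc[idx], sd = t$se_calc[idx])
      ref <- t$dg_ref[idx]
      if (!is.null(ref_se)) ref <- rnorm(n, mean = ref, sd = ref_se[idx])
      metric_value(calc, ref, metric)
    }, numeric(1))
  })
  bad <- !is.finite(reps)
  if (sum(bad) > 0.2 * n_boot)
    stop(sprintf("metric undefined in %d of %d bootstrap iterations",
                 sum(bad), n_boot))
  list(metric = point, se = sd(reps[!bad]), n_boot = n_boot,
       n_discarded = sum(bad))
}

#' Bias of truncated estimates relative to the final estimate
#'
#' Given per-system free energy estimates at a grid of sampling times
#' (the last column being the estimate from the full sampling), the bias
#' at time tau is the mean over systems of
#' \eqn{|dg(\tau) - dg(T_{final})|}; it is exactly 0 at the final time.
#'
#' @param x a `data.frame` with a `system` column and one numeric column
#'   per sampling time, column names coercible to numeric times,
#'   ordered so the last time column is the final estimate.
#' @return `data.frame` with columns `time` and `bias`.
#' @export
bias_trace <- function(x) {
  stopifnot(is.data.frame(x), "system" %in% names(x))
  tcols <- setdiff(names(x), "system")
  if (length(tcols) < 2L) stop("at least two time points are required")
  times <- suppressWarnings(as.numeric(tcols))
  if (anyNA(times)) stop("time column names must be numeric")
  for (tc in tcols) {
    miss <- which(!is.finite(x[[tc]]))
    if (length(miss))
      stop(sprintf("missing value for system '%s' at time %s",
                   x$system[miss[1]], tc))
  }
  final <- x[[tcols[length(tcols)]]]
  bias <- vapply(tcols, function(tc) mean(abs(x[[tc]] - final)), numeric(1))
  data.frame(time = times, bias = unname(bias))
}

#' Pairwise method-comparison matrices
#'
#' Compares several calculation approaches (and, if supplied as a
#' column, the experimental measurement) over a shared system set in
#' terms of pairwise AUE and Pearson correlation. The diagonal is AUE 0
#' and Pearson 1 by construction.
#'
#' @param tables named list; each element a [benchmark_table()] (its
#'   `dg_calc` column is used) or a `data.frame` with columns `system`
#'   and `dg`. All elements must cover an identical system set.
#' @return list of class `method_matrix` with symmetric matrices `aue`
#'   and `pearson` (dimnames = method names) and `systems`.
#' @export
method_matrix <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L || is.null(names(tables)) ||
      any(!nzchar(names(tables))))
    stop("tables must be a named list of at least two methods")
  getcol <- function(x) {
    if (inherits(x, "benchmark_table"))
      return(setNames(x$dg_calc, x$system))
    if (is.data.frame(x) && all(c("system", "dg") %in% names(x)))
      return(setNames(x$dg, as.character(x$system)))
    stop("each table must be a benchmark_table or have columns system and dg")
  }
  vals <- lapply(tables, getcol)
  ids <- sort(names(vals[[1]]))
  for (k in seq_along(vals)) {
    idk <- sort(names(vals[[k]]))
    if (!identical(idk, ids)) {
      disjoint <- union(setdiff(ids, idk), setdiff(idk, ids))
      stop("system id mismatch between methods: ",
           paste(disjoint, collapse = ", "))
    }
    vals[[k]] <- vals[[k]][ids]
  }
  m <- length(vals)
  aue <- matrix(0, m, m, dimnames = list(names(vals), names(vals)))
  pear <- matrix(1, m, m, dimnames = list(names(vals), names(vals)))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    aue[i, j] <- mean(abs(vals[[i]] - vals[[j]]))
    pear[i, j] <- suppressWarnings(cor(vals[[i]], vals[[j]]))
  }
  structure(list(aue = aue, pearson = pear, systems = ids),
            class = "method_matrix")
}

#' @export
print.method_matrix <- function(x, ...) {
  cat("pairwise AUE:\n"); print(round(x$aue, 4))
  cat("pairwise Pearson:\n"); print(round(x$pearson, 4))
  invisible(x)
}
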