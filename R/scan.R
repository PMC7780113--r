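# Environment-radius scans and environment-model comparisons.

#' Scan the environment inclusion radius
#'
#' Runs the full embed + SCF + CI pipeline once per radius, selecting the
#' point charges within each `R` from a fixed candidate superset, and
#' records lambda_1 and f_1 of the S0->S1 transition.  The vacuum point
#' (R = 0) is always included.  A failing radius is recorded as a missing
#' row with a warning and the scan continues.
#'
#' @param fragment the chromophore `fragment_geometry`.
#' @param sources candidate point-charge superset (see
#'   [build_environment()]).
#' @param R_values radii in Angstrom, non-negative.
#' @param params an [indo_params()] set.
#' @param exclusions,spec passed to [build_environment()].
#' @param n_singles,include_paired_doubles CI controls.
#' @param label model label for the result.
#' @return an object of class `radius_scan` with a data frame `rows`
#'   (`R`, `lambda1_nm`, `f1`, `n_charges`).
#' @export
radius_scan <- function(fragment, sources, R_values = 0:8,
                        params = indo_params(), exclusions = NULL,
                        spec = NULL, n_singles = NULL,
                        include_paired_doubles = NULL, label = "custom") {
  stopifnot(all(R_values >= 0))
  R_values <- sort(unique(c(0, R_values)))
  rows <- lapply(R_values, function(R) {
    env <- build_environment(sources, fragment, R, exclusions = exclusions,
                             spec = spec, label = label)
    sp <- tryCatch(
      compute_spectrum(fragment, params, environment = env,
                       n_singles = n_singles,
                       include_paired_doubles = include_paired_doubles,
                       n_states = 1,
                       label = sprintf("%s R=%g", label, R)),
      error = function(e) {
        warning("radius R = ", R, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(sp)) return(NULL)
    data.frame(R = R, lambda1_nm = sp$states$wavelength_nm[1],
               f1 = sp$states$oscillator_strength[1],
               n_charges = nrow(env$charges))
  })
  rows <- do.call(rbind, rows)
  structure(list(rows = rows, model_label = label,
                 chromophore_id = fragment$label,
                 vacuum_row = rows[rows$R == 0, , drop = FALSE]),
            class = "radius_scan")
}

#' @export
print.radius_scan <- function(x, ...) {
  cat("<radius_scan> ", x$chromophore_id, " [", x$model_label, "]\n",
      sep = "")
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' @export
plot.radius_scan <- function(x, ...) {
  graphics::plot(x$rows$R, x$rows$lambda1_nm, type = "b", pch = 16,
                 xlab = "R (Angstrom)", ylab = expression(lambda[1]~(nm)),
                 main = paste0(x$chromophore_id, " [", x$model_label,
                               "]"), ...)
  invisible(x)
}

#' Detect the convergence radius of a scan
#'
#' Returns the smallest scanned radius from which all successive
#' lambda_1 steps within the look-ahead window stay below the tolerance,
#' or `NA` when the scan never settles.
#'
#' @param scan a `radius_scan` object (or its `rows` data frame).
#' @param window number of successive steps that must stay within
#'   tolerance (default 2).
#' @param tol_nm tolerance on successive lambda_1 differences (default 5
#'   nm).
#' @return the convergence radius in Angstrom, or `NA`.
#' @export
detect_convergence <- function(scan, window = 2, tol_nm = 5) {
  rows <- if (inherits(scan, "radius_scan")) scan$rows else scan
  if (is.null(rows) || nrow(rows) < 3) {
    stop("need at least 3 scan rows to detect convergence")
  }
  rows <- rows[order(rows$R), , drop = FALSE]
  lam <- rows$lambda1_nm
  steps <- abs(diff(lam))
  if (length(steps) < window) stop("scan too short for the window")
  for (i in seq_len(length(steps) - window + 1)) {
    if (all(steps[i:(i + window - 1)] <= tol_nm)) return(rows$R[i])
  }
  NA_real_
}

#' Compare environment models for one chromophore
#'
#' Runs one CI evaluation per environment and tabulates lambda_1, f_1 and
#' the shift relative to the first model.
#'
#' @param fragment the chromophore `fragment_geometry`.
#' @param environments list of `environment_charges` objects referring to
#'   the same chromophore.
#' @param params an [indo_params()] set.
#' @param n_singles,include_paired_doubles CI controls.
#' @return data frame with columns `model`, `lambda1_nm`, `f1`,
#'   `delta_lambda_nm`, `n_charges`.
#' @export
compare_models <- function(fragment, environments,
                           params = indo_params(), n_singles = NULL,
                           include_paired_doubles = NULL) {
  ids <- vapply(environments, function(e) e$chromophore_id, "")
  if (length(unique(ids)) > 1) {
    stop("environments reference different chromophores: ",
         paste(unique(ids), collapse = ", "))
  }
  rows <- lapply(environments, function(env) {
    sp <- compute_spectrum(fragment, params, environment = env,
                           n_singles = n_singles,
                           include_paired_doubles =
                             include_paired_doubles,
                           n_states = 1, label = env$model_label)
    data.frame(model = env$model_label,
               lambda1_nm = sp$states$wavelength_nm[1],
               f1 = sp$states$oscillator_strength[1],
               n_charges = nrow(env$charges),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$delta_lambda_nm <- out$lambda1_nm - out$lambda1_nm[1]
  out[, c("model", "lambda1_nm", "f1", "delta_lambda_nm", "n_charges")]
}
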