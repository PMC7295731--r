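#' Dilution series for amplification-efficiency estimation
#'
#' A standard curve is built from a serial dilution of template (e.g. a
#' fivefold series of mixed cDNA): mean Ct against log10 relative
#' concentration. Either supply relative concentrations directly, or dilution
#' step indices (0, 1, 2, ...) plus a dilution factor, in which case the
#' relative concentration of step j is `dilution_factor^-j` (most concentrated
#' point = 1).
#'
#' @param ct numeric vector of mean Ct values, one per dilution point.
#' @param concentration strictly positive, strictly decreasing relative
#'   concentrations (mutually exclusive with `step`).
#' @param step integer dilution step indices (0 = undiluted).
#' @param dilution_factor fold-dilution per step (default 5).
#' @return Object of class `dilution_series`: data.frame with columns
#'   `concentration`, `ct`, and attribute `dilution_factor`.
#' @export
dilution_series <- function(ct, concentration = NULL, step = NULL,
                            dilution_factor = 5) {
  if (is.null(concentration) && is.null(step)) {
    stop("supply either 'concentration' or 'step'")
  }
  if (is.null(concentration)) {
    concentration <- dilution_factor^(-as.numeric(step))
  }
  if (length(concentration) != length(ct)) {
    stop("'ct' and 'concentration' lengths differ")
  }
  if (length(ct) < 3L) stop("a dilution series needs at least 3 points")
  if (any(concentration <= 0)) stop("relative concentrations must be positive")
  if (any(diff(concentration) >= 0)) {
    stop("relative concentrations must be strictly decreasing")
  }
  structure(data.frame(concentration = concentration, ct = ct),
            dilution_factor = dilution_factor, class = c("dilution_series",
                                                         "data.frame"))
}

#' Read a dilution series from CSV
#'
#' Expects columns `concentration,ct`, or `step,ct` together with
#' `dilution_factor`.
#'
#' @param path CSV file path.
#' @param dilution_factor fold-dilution per step, used with a `step` column.
#' @return A [dilution_series()].
#' @export
read_dilution_series <- function(path, dilution_factor = 5) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("concentration" %in% names(raw)) {
    dilution_series(ct = raw$ct, concentration = raw$concentration,
                    dilution_factor = dilution_factor)
  } else if ("step" %in% names(raw)) {
    dilution_series(ct = raw$ct, step = raw$step,
                    dilution_factor = dilution_factor)
  } else {
    stop("need a 'concentration' or 'step' column")
  }
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 relative concentration. The
#' amplification efficiency follows the standard-curve formula
#' `E% = (10^(-1/slope) - 1) x 100`; a slope of -1/log10(2) = -3.3219 is
#' 100% efficiency (perfect doubling per cycle). A non-negative slope yields
#' a flagged fit with a warning rather than an error.
#'
#' @param series a [dilution_series()].
#' @return List of class `standard_curve_fit`: `slope` (cycles per log10
#'   concentration), `intercept` (cycles), `r_squared`,
#'   `efficiency_percent`, `efficiency` (fold change per cycle,
#'   `10^(-1/slope)`), `valid` (slope < 0).
#' @examples
#' s <- dilution_series(ct = c(20, 22.32, 24.64), concentration = c(1, .1, .01))
#' fit_standard_curve(s)
#' @export
fit_standard_curve <- function(series) {
  if (nrow(series) < 3L) stop("a dilution series needs at least 3 points")
  logc <- log10(series$concentration)
  if (stats::var(logc) == 0) stop("zero spread in log10 concentration")
  fit <- stats::lm(ct ~ logc, data = data.frame(ct = series$ct, logc = logc))
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  # suppressWarnings: summary.lm warns on exactly collinear points, a
  # legitimate (ideal) dilution series
  r2 <- suppressWarnings(summary(fit)$r.squared)
  eff_pct <- (10^(-1 / slope) - 1) * 100
  valid <- is.finite(slope) && slope < 0
  if (!valid) {
    warning("non-negative standard-curve slope (", signif(slope, 4),
            "); efficiency is not interpretable")
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency_percent = eff_pct,
                 efficiency = 10^(-1 / slope), valid = valid),
            class = "standard_curve_fit")
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat(sprintf("standard curve: slope %.4f, intercept %.2f, r^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("amplification efficiency: %.2f%% (E = %.4f per cycle)%s\n",
              x$efficiency_percent, x$efficiency,
              if (x$valid) "" else "  [flagged: slope >= 0]"))
  invisible(x)
}

#' Amplification efficiency from a slope
#'
#' `E% = (10^(-1/slope) - 1) x 100`.
#'
#' @param slope standard-curve slope (cycles per log10 concentration).
#' @return Efficiency in percent.
#' @export
efficiency_from_slope <- function(slope) {
  (10^(-1 / slope) - 1) * 100
}

#' Efficiency-corrected relative quantities
#'
#' Transforms a complete Ct matrix into relative quantities
#' `x(g, s) = E_g^(minCt_g - Ct(g, s))`, the input convention of geNorm-style
#' analyses: each gene's most abundant sample (its minimum Ct) gets quantity
#' 1 and all quantities lie in (0, 1]. The default efficiency of exactly 2
#' is the `Q = 2^dCt` doubling convention; per-gene efficiencies (fold change
#' per cycle, e.g. from [fit_standard_curve()]`$efficiency`) may override it.
#' The anchoring at the per-gene minimum cancels in all downstream ratio
#' statistics.
#'
#' @param table a [ct_table()] with a complete gene x sample matrix.
#' @param efficiency scalar or per-gene named vector of fold changes per
#'   cycle; must exceed 1.
#' @return Numeric gene x sample matrix of relative quantities with
#'   attribute `efficiency` (per-gene vector).
#' @export
relative_quantities <- function(table, efficiency = 2) {
  m <- ct_matrix(table, require_complete = TRUE)
  eff <- if (length(efficiency) == 1L) {
    stats::setNames(rep(as.numeric(efficiency), nrow(m)), rownames(m))
  } else {
    missing_e <- setdiff(rownames(m), names(efficiency))
    if (length(missing_e) > 0L) {
      stop("no efficiency for gene(s): ", paste(missing_e, collapse = ", "))
    }
    as.numeric(efficiency[rownames(m)])
  }
  if (any(eff <= 1)) stop("efficiency must be > 1 (fold change per cycle)")
  x <- eff^(apply(m, 1L, min) - m)
  attr(x, "efficiency") <- stats::setNames(eff, rownames(m))
  x
}
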