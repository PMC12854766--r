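#' Standard logarithmic concentration grid
#'
#' Builds the harmonization grid on which every concentration-response
#' curve is evaluated: `n` points uniform in log10 concentration between
#' `c_min` and `c_max`. Defaults give the standard 45-point grid from
#' 1 pM to 100 uM (concentrations in molar units).
#'
#' @param n Number of grid points (>= 2).
#' @param c_min,c_max Grid end points in molar; `0 < c_min < c_max`.
#' @return A numeric vector of class `conc_grid`, strictly increasing,
#'   log10-uniform.
#' @examples
#' g <- build_grid()
#' length(g)   # 45
#' range(g)    # 1e-12 1e-4
#' @export
build_grid <- function(n = 45, c_min = 1e-12, c_max = 1e-4) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  if (!(c_min > 0) || !(c_max > c_min)) {
    stop("grid requires 0 < c_min < c_max", call. = FALSE)
  }
  g <- 10^seq(log10(c_min), log10(c_max), length.out = n)
  g[1] <- c_min
  g[n] <- c_max
  structure(g, class = c("conc_grid", "numeric"))
}

#' @export
print.conc_grid <- function(x, ...) {
  cat(sprintf("<conc_grid> %d points, %.3g to %.3g M (log10-uniform)\n",
              length(x), x[1], x[length(x)]))
  invisible(x)
}

is_log_uniform <- function(grid, tol = 1e-12) {
  d <- diff(log10(grid))
  all(d > 0) && (max(d) - min(d)) <= tol * max(abs(log10(grid)))
}

#' Hill concentration-response function
#'
#' Signed percent response of the Hill model
#' `R(C) = Top * C^slope / (C^slope + AC50^slope)`: 0 at `C = 0`,
#' half of `Top` at `C = AC50`, approaching `Top` as `C` grows.
#' Vectorized over `conc`.
#'
#' @param conc Concentration(s), same units as `ac50`, all >= 0.
#' @param ac50 Half-maximal concentration (> 0).
#' @param slope Hill slope (> 0).
#' @param top Asymptotic signed response (percent; negative = inhibition).
#' @return Numeric vector of signed responses.
#' @examples
#' hill_response(1, ac50 = 1, slope = 1, top = 100)  # 50
#' @export
hill_response <- function(conc, ac50, slope, top) {
  if (any(conc < 0)) stop("concentration must be >= 0", call. = FALSE)
  if (ac50 <= 0 || slope <= 0) {
    stop("`ac50` and `slope` must be > 0", call. = FALSE)
  }
  # work in logs to avoid overflow at extreme conc^slope
  out <- top / (1 + exp(slope * (log(ac50) - log(conc))))
  out[conc == 0] <- 0
  out
}

#' Normalize a Hill curve onto the standard grid
#'
#' Evaluates a fitted Hill curve on the grid and rescales the baseline to
#' 0% and the curve's own Top to 100%, preserving shape. Direction is
#' kept as a flag: `"activation"` for positive Top, `"inhibition"` for
#' negative.
#'
#' @param ac50,slope,top Hill parameters (`top != 0`).
#' @param grid A `conc_grid` (or increasing numeric vector).
#' @param assay_id,chemical_id Optional source identifiers.
#' @return An object of class `normalized_curve`: list with `responses`
#'   (percent of Top, in `[0, 100]`, nondecreasing), `direction`,
#'   `assay_id`, `chemical_id`, `grid`.
#' @export
normalize_curve <- function(ac50, slope, top, grid = build_grid(),
                            assay_id = NA_character_,
                            chemical_id = NA_character_) {
  if (top == 0) stop("uninformative curve: top = 0", call. = FALSE)
  resp <- 100 * hill_response(grid, ac50, slope, top) / top
  structure(
    list(responses = resp,
         direction = if (top > 0) "activation" else "inhibition",
         assay_id = assay_id, chemical_id = chemical_id,
         grid = as.numeric(grid)),
    class = "normalized_curve")
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat(sprintf("<normalized_curve> %s | %s/%s | range [%.2f, %.2f]%%\n",
              x$direction, x$assay_id, x$chemical_id,
              min(x$responses), max(x$responses)))
  invisible(x)
}

#' Select the most reproducible replicate curve
#'
#' Given replicate normalized curves for one (assay, chemical) pair,
#' keeps the profile closest (mean squared deviation) to the pointwise
#' median of all replicates. With a single curve it is returned
#' unchanged; ties go to the earliest replicate.
#'
#' @param curves A list of `normalized_curve` objects on a common grid.
#' @return One `normalized_curve`.
#' @export
merge_replicates <- function(curves) {
  if (length(curves) == 0) stop("no curves to merge", call. = FALSE)
  if (length(curves) == 1) return(curves[[1]])
  mat <- vapply(curves, function(cv) cv$responses,
                numeric(length(curves[[1]]$responses)))
  med <- apply(mat, 1, stats::median)
  msd <- colMeans((mat - med)^2)
  curves[[which.min(msd)]]
}
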