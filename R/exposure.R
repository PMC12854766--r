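#' EC50 of a modeled concentration-response curve
#'
#' Concentration at which the curve first reaches 50% of its own
#' maximum absolute response, located by log-linear interpolation
#' between the bracketing grid points. Curves whose maximum absolute
#' response stays below `noise_floor` (1% of the 0-100 scale) have no
#' defined potency and return `NA`.
#'
#' @param responses Modeled responses over the grid (percent scale).
#' @param grid Concentration grid (molar or uM; the EC50 is returned in
#'   the same units).
#' @param noise_floor Minimum absolute response for a defined EC50.
#' @return EC50 (same units as `grid`) or `NA_real_`.
#' @export
ec50_from_curve <- function(responses, grid, noise_floor = 1) {
  if (any(!is.finite(responses))) {
    stop("responses must be finite", call. = FALSE)
  }
  stopifnot(length(responses) == length(grid))
  r <- abs(responses)
  rmax <- max(r)
  if (rmax < noise_floor) return(NA_real_)
  half <- rmax / 2
  above <- which(r >= half)
  i <- above[1]
  if (i == 1) return(as.numeric(grid[1]))
  lg <- log10(as.numeric(grid))
  f <- (half - r[i - 1]) / (r[i] - r[i - 1])
  10^(lg[i - 1] + f * (lg[i] - lg[i - 1]))
}

#' Per-layer EC50 potency table
#'
#' Extracts an EC50 for every observed (entity, chemical) fiber of a
#' layer tensor.
#'
#' @param layer A `layer_tensor` (grid in molar; EC50s reported in uM).
#' @return Tibble: `chemical_id`, `layer`, `target_id`, `ec50_um`
#'   (`NA` when the curve never crosses half-max).
#' @export
layer_potencies <- function(layer) {
  stopifnot(inherits(layer, "layer_tensor"), !is.null(layer$grid))
  grid_um <- as.numeric(layer$grid) * 1e6
  d <- dim(layer$values)
  layer_name <- layer$layer
  out <- list()
  for (ch in seq_len(d[3])) {
    for (en in seq_len(d[1])) {
      obs <- layer$mask[en, , ch]
      if (!any(obs)) next
      ec <- ec50_from_curve(layer$values[en, obs, ch], grid_um[obs])
      chem <- layer$chemical_ids[ch]
      tgt <- layer$entity_ids[en]
      out[[length(out) + 1L]] <- tibble::tibble(
        chemical_id = chem, layer = layer_name, target_id = tgt,
        ec50_um = ec)
    }
  }
  dplyr::bind_rows(out)
}

#' Read a steady-state plasma concentration table
#'
#' CSV with columns `chemical_id`, `css_p5`, `css_p50`, `css_p95`
#' (uM, modeled under a standardized 1 mg/kg/day repeated oral dose).
#' Rows violating `0 < p5 <= p50 <= p95` are dropped with a warning.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_css_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("chemical_id", "css_p5", "css_p50", "css_p95")
  miss <- setdiff(req, names(tbl))
  if (length(miss)) stop("Css table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ok <- with(tbl, css_p5 > 0 & css_p5 <= css_p50 & css_p50 <= css_p95)
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) warning(sum(!ok), " invalid Css rows dropped",
                        call. = FALSE)
  tbl[ok, req]
}

#' Exposure-relevance flags from Css vs modeled potency
#'
#' Compares each compound's 95th-percentile steady-state plasma
#' concentration (sensitive-subpopulation exposure) against its
#' modeled EC50s at each layer. A compound is exposure-relevant when
#' any EC50 falls at or below `css_p95` (modeled effects reachable at
#' in vivo concentrations). Compounds without a Css record are skipped
#' with a warning.
#'
#' @param css Tibble from [read_css_table()].
#' @param potencies Tibble from [layer_potencies()] (rows from several
#'   layers may be combined).
#' @return Tibble per (chemical, layer): `n_targets`, `median_ec50_um`,
#'   `min_ec50_um`, `n_below_css`, `frac_below_css`, `css_p95`, plus a
#'   per-chemical `exposure_relevant` flag.
#' @export
exposure_flags <- function(css, potencies) {
  if (nrow(potencies) == 0) stop("no potency records", call. = FALSE)
  missing_css <- setdiff(unique(potencies$chemical_id), css$chemical_id)
  if (length(missing_css)) {
    warning("no Css for ", length(missing_css),
            " compound(s); skipped: ",
            paste(utils::head(missing_css, 5), collapse = ", "),
            call. = FALSE)
  }
  potencies |>
    dplyr::inner_join(css[, c("chemical_id", "css_p95")],
                      by = "chemical_id") |>
    dplyr::group_by(.data$chemical_id, .data$layer) |>
    dplyr::summarise(
      n_targets = sum(is.finite(.data$ec50_um)),
      median_ec50_um = stats::median(.data$ec50_um, na.rm = TRUE),
      min_ec50_um = suppressWarnings(min(.data$ec50_um, na.rm = TRUE)),
      n_below_css = sum(.data$ec50_um <= .data$css_p95[1], na.rm = TRUE),
      frac_below_css = mean(.data$ec50_um <= .data$css_p95[1],
                            na.rm = TRUE),
      css_p95 = .data$css_p95[1], .groups = "drop_last") |>
    dplyr::mutate(exposure_relevant = any(.data$n_below_css > 0)) |>
    dplyr::ungroup() |>
    dplyr::mutate(min_ec50_um = dplyr::if_else(is.finite(.data$min_ec50_um),
                                               .data$min_ec50_um,
                                               NA_real_))
}
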