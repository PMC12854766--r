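#' Classify assay directionality from its Top range
#'
#' Assays are grouped by the sign pattern of the extreme fitted Top
#' values observed across their tested compounds: `positive` when both
#' minTop and maxTop exceed the near-zero band `eps`, `negative` when
#' both fall below `-eps`, `mixed` when the range spans both signs, and
#' `excluded` when either extreme sits inside the `+/- eps` band
#' (minimal modeled activity). Vectorized.
#'
#' @param min_top,max_top Per-assay extreme Top values (percent),
#'   `min_top <= max_top`.
#' @param eps Half-width of the near-zero exclusion band (percent).
#' @return Character vector: `"positive"`, `"negative"`, `"mixed"` or
#'   `"excluded"`.
#' @examples
#' classify_assay(37.3, 116)    # positive
#' classify_assay(-120, 120)    # mixed
#' classify_assay(-120, -16.9)  # negative
#' @export
classify_assay <- function(min_top, max_top, eps = 1.0) {
  if (any(min_top > max_top)) {
    stop("invariant violated: min_top > max_top", call. = FALSE)
  }
  dplyr::case_when(
    min_top > eps & max_top > eps ~ "positive",
    min_top < -eps & max_top < -eps ~ "negative",
    min_top < -eps & max_top > eps ~ "mixed",
    TRUE ~ "excluded"
  )
}

#' Summarize per-assay Top extremes
#'
#' Computes minTop/maxTop over all compounds tested in each assay and
#' attaches the directionality category.
#'
#' @param params A tibble with columns `assay_id`, `top` (one row per
#'   compound-assay pair; other columns ignored).
#' @param eps Near-zero band passed to [classify_assay()].
#' @return A tibble with `assay_id`, `min_top`, `max_top`, `category`,
#'   `n_compounds`.
#' @export
summarize_assay_tops <- function(params, eps = 1.0) {
  stopifnot(all(c("assay_id", "top") %in% names(params)))
  params |>
    dplyr::filter(is.finite(.data$top)) |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::summarise(min_top = min(.data$top),
                     max_top = max(.data$top),
                     n_compounds = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(category = classify_assay(.data$min_top, .data$max_top,
                                            eps = eps))
}

#' Read a Hill-parameter assay table
#'
#' Reads the per-pair curve-fit table (CSV or TSV by extension) with
#' required columns `assay_id`, `chemical_id`, `ac50`, `slope`, `top`
#' and an optional `unit` column for `ac50` (`"M"` default, `"uM"`
#' accepted and converted to molar). Rows with missing or invalid
#' parameters (`ac50 <= 0`, `slope <= 0`, non-finite) are dropped and
#' counted in the `n_dropped` attribute; duplicated (assay, chemical)
#' rows are kept for downstream replicate merging.
#'
#' @param path File path.
#' @return A tibble of validated Hill parameters (`ac50` in molar),
#'   with attribute `n_dropped`.
#' @export
read_assay_table <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  tbl <- reader(path, show_col_types = FALSE, progress = FALSE)
  req <- c("assay_id", "chemical_id", "ac50", "slope", "top")
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols)) {
    stop("assay table missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"unit" %in% names(tbl)) tbl$unit <- "M"
  tbl <- tbl |>
    dplyr::mutate(ac50 = dplyr::if_else(tolower(.data$unit) %in%
                                          c("um", "µm", "umol/l"),
                                        .data$ac50 * 1e-6, .data$ac50))
  ok <- with(tbl, is.finite(ac50) & is.finite(slope) & is.finite(top) &
               ac50 > 0 & slope > 0)
  ok[is.na(ok)] <- FALSE
  out <- tbl[ok, c(req)]
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Harmonize an assay table into the Assay layer tensor
#'
#' Evaluates every (assay, chemical) Hill fit on the grid, merges
#' replicates by median-deviation selection, rescales responses, and
#' assembles the three-way `assays x concentrations x chemicals` array
#' with an observed-entry mask (untested pairs are masked, never
#' zero-filled).
#'
#' Scales: `"assay_range"` (default) keeps signed responses relative
#' to the assay's largest absolute Top (`100 * R / max |Top|`),
#' preserving compound amplitude and direction for the factorization
#' layers; `"percent_of_top"` rescales each curve's own Top to 100%
#' (bounded 0-100, amplitude-free); `"response"` keeps raw evaluated
#' responses.
#'
#' @param params Hill-parameter tibble (see [read_assay_table()]).
#' @param grid A `conc_grid`.
#' @param assays,chemicals Optional rosters fixing axis order; defaults
#'   to sorted unique ids present in `params`.
#' @param scale Response scaling (see Details).
#' @return A [layer_tensor()] with layer name `"assay"`.
#' @export
build_assay_tensor <- function(params, grid = build_grid(),
                               assays = NULL, chemicals = NULL,
                               scale = c("assay_range", "percent_of_top",
                                         "response")) {
  scale <- match.arg(scale)
  stopifnot(all(c("assay_id", "chemical_id", "ac50", "slope", "top") %in%
                  names(params)))
  params <- dplyr::filter(params, .data$top != 0)
  if (is.null(assays)) assays <- sort(unique(params$assay_id))
  if (is.null(chemicals)) chemicals <- sort(unique(params$chemical_id))
  nc <- length(grid)
  vals <- array(NA_real_, dim = c(length(assays), nc, length(chemicals)),
                dimnames = list(assays, NULL, chemicals))
  mask <- array(FALSE, dim = dim(vals), dimnames = dimnames(vals))

  # per-row curve evaluations (rows x grid), on the requested scale
  lg <- log(as.numeric(grid))
  amp <- switch(scale,
                percent_of_top = rep(100, nrow(params)),
                assay_range = {
                  top_max <- tapply(abs(params$top), params$assay_id, max)
                  100 * params$top / top_max[params$assay_id]
                },
                response = params$top)
  amp <- as.numeric(amp)
  resp <- amp / (1 + exp(outer(log(params$ac50), lg, `-`) * params$slope))
  key <- paste(params$assay_id, params$chemical_id, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    r <- if (length(idx) == 1) resp[idx, ] else {
      m <- t(resp[idx, , drop = FALSE])
      med <- apply(m, 1, stats::median)
      m[, which.min(colMeans((m - med)^2))]
    }
    a <- params$assay_id[idx[1]]
    ch <- params$chemical_id[idx[1]]
    if (!(a %in% assays) || !(ch %in% chemicals)) next
    vals[a, , ch] <- r
    mask[a, , ch] <- TRUE
  }
  layer_tensor(vals, mask, entity_ids = assays, chemical_ids = chemicals,
               grid = grid, layer = "assay")
}
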