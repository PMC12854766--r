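#' Rank-based quartile assignment
#'
#' Stratifies compounds into Q1-Q4 by score, Q4 highest. Quartile edges
#' fall at ranks `ceiling(n/4)`, `ceiling(n/2)`, `ceiling(3n/4)`; ties
#' are broken by stable id order.
#'
#' @param scores Numeric scores (>= 4 values).
#' @param ids Identifiers used for stable tie-breaking (defaults to
#'   input position).
#' @return Character vector `"Q1"`..`"Q4"` aligned with `scores`.
#' @export
assign_quartiles <- function(scores, ids = NULL) {
  n <- length(scores)
  if (n < 4) stop("quartile assignment needs >= 4 compounds", call. = FALSE)
  if (is.null(ids)) ids <- seq_len(n)
  ord <- order(scores, ids)
  rk <- integer(n)
  rk[ord] <- seq_len(n)
  edges <- ceiling(c(n / 4, n / 2, 3 * n / 4))
  q <- 1L + (rk > edges[1]) + (rk > edges[2]) + (rk > edges[3])
  paste0("Q", q)
}

#' GHS acute-toxicity dose band
#'
#' Classifies an oral LD50 into the three-band scheme: high toxicity at
#' `LD50 <= 50` mg/kg, moderate for `50 < LD50 <= 2000`, low above
#' 2000 mg/kg. Vectorized.
#'
#' @param ld50_mg_per_kg Positive dose(s), mg/kg.
#' @return Character vector `"low"` / `"moderate"` / `"high"`.
#' @export
ghs_acute_class <- function(ld50_mg_per_kg) {
  if (any(!is.finite(ld50_mg_per_kg) | ld50_mg_per_kg <= 0)) {
    stop("LD50 must be finite and > 0", call. = FALSE)
  }
  dplyr::case_when(ld50_mg_per_kg <= 50 ~ "high",
                   ld50_mg_per_kg <= 2000 ~ "moderate",
                   TRUE ~ "low")
}

#' NOAEL dose band
#'
#' Three bands derived from NOAEL distribution percentiles: high at
#' `NOAEL <= 15` mg/kg bw/day, moderate for `15 < NOAEL <= 300`, low
#' above 1000. Doses in the unassigned gap `(300, 1000]` return
#' `"unclassified"`. Vectorized.
#'
#' @param noael_mg_per_kg_day Positive dose(s), mg/kg bw/day.
#' @return Character vector `"low"` / `"moderate"` / `"high"` /
#'   `"unclassified"`.
#' @export
noael_band_class <- function(noael_mg_per_kg_day) {
  if (any(!is.finite(noael_mg_per_kg_day) | noael_mg_per_kg_day <= 0)) {
    stop("NOAEL must be finite and > 0", call. = FALSE)
  }
  dplyr::case_when(noael_mg_per_kg_day <= 15 ~ "high",
                   noael_mg_per_kg_day <= 300 ~ "moderate",
                   noael_mg_per_kg_day > 1000 ~ "low",
                   TRUE ~ "unclassified")
}

#' Compound toxicity score table
#'
#' Collapses a fitted Tox tensor to per-compound scalar scores (mean
#' over the concentration grid), min-max-normalizes within each
#' endpoint, and attaches quartile labels (Q4 = highest predicted
#' toxicity).
#'
#' @param tox A `layer_fit` from [fit_tox_layer()] or a Tox
#'   `layer_tensor`.
#' @param stat Concentration summary passed to
#'   [summarize_over_concentration()].
#' @return Tibble: `chemical_id`, `endpoint_id`, `raw_score`,
#'   `normalized_score`, `quartile`.
#' @export
score_compounds <- function(tox, stat = "mean") {
  tensor <- if (inherits(tox, "layer_fit")) tox$latent else tox
  stopifnot(inherits(tensor, "layer_tensor"))
  m <- summarize_over_concentration(tensor, stat = stat)
  tibble::as_tibble(m, rownames = "endpoint_id") |>
    tidyr::pivot_longer(-"endpoint_id", names_to = "chemical_id",
                        values_to = "raw_score") |>
    dplyr::group_by(.data$endpoint_id) |>
    dplyr::mutate(normalized_score = minmax_normalize(.data$raw_score),
                  quartile = assign_quartiles(.data$normalized_score,
                                              .data$chemical_id)) |>
    dplyr::ungroup() |>
    dplyr::relocate("chemical_id")
}

#' Cluster-level toxicity z-score profiles
#'
#' For each (cluster, endpoint): the cluster median endpoint value
#' standardized against the mean and standard deviation of all
#' compound-level values for that endpoint. Continuous endpoints are
#' analyzed on the `-log10(dose)` scale (pass `values` already
#' transformed, or raw doses with `transform_continuous = TRUE`).
#' Binary endpoints are standardized on a reversed coding
#' (nontoxic = 1) and multiplied by -1, so higher z means more toxic
#' under either kind.
#'
#' @param clusters Tibble `chemical_id`, `cluster_id` (NA cluster ids
#'   are dropped).
#' @param endpoints Tibble `endpoint_id`, `kind`, `chemical_id`,
#'   `value`.
#' @param transform_continuous Apply [neglog10_dose()] to continuous
#'   values first.
#' @param sd_type `"population"` (n denominator, default) or
#'   `"sample"`.
#' @return Tibble: `cluster_id`, `endpoint_id`, `n`, `median_value`,
#'   `z_score`.
#' @export
cluster_z_scores <- function(clusters, endpoints,
                             transform_continuous = FALSE,
                             sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  dat <- endpoints |>
    dplyr::inner_join(dplyr::filter(clusters, !is.na(.data$cluster_id)),
                      by = "chemical_id") |>
    dplyr::filter(is.finite(.data$value))
  if (transform_continuous) {
    dat <- dat |>
      dplyr::mutate(value = dplyr::if_else(.data$kind == "continuous",
                                           neglog10_dose(.data$value),
                                           .data$value))
  }
  dat |>
    dplyr::mutate(value = dplyr::if_else(.data$kind == "binary",
                                         1 - .data$value, .data$value),
                  flip = dplyr::if_else(.data$kind == "binary", -1, 1)) |>
    dplyr::group_by(.data$endpoint_id) |>
    dplyr::mutate(g_mean = mean(.data$value),
                  g_sd = if (sd_type == "population") {
                    sqrt(mean((.data$value - mean(.data$value))^2))
                  } else {
                    stats::sd(.data$value)
                  }) |>
    dplyr::group_by(.data$cluster_id, .data$endpoint_id) |>
    dplyr::summarise(n = dplyr::n(),
                     median_value = stats::median(.data$value),
                     z_score = {
                       if (.data$g_sd[1] == 0) {
                         stop("endpoint has zero spread: z-scores undefined",
                              call. = FALSE)
                       }
                       .data$flip[1] * (stats::median(.data$value) -
                                          .data$g_mean[1]) / .data$g_sd[1]
                     },
                     .groups = "drop") |>
    dplyr::mutate(median_value = dplyr::if_else(
      .data$endpoint_id %in%
        endpoints$endpoint_id[endpoints$kind == "binary"],
      1 - .data$median_value, .data$median_value))
}

#' Quartile-by-class composition plot
#'
#' @param score_tbl Output of [score_compounds()] joined with a
#'   `tox_class` column per compound.
#' @return A ggplot of class proportions within each quartile, faceted
#'   by endpoint.
#' @export
plot_quartile_classes <- function(score_tbl) {
  stopifnot("tox_class" %in% names(score_tbl))
  ggplot2::ggplot(score_tbl,
                  ggplot2::aes(x = .data$quartile, fill = .data$tox_class)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::facet_wrap(~endpoint_id) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "toxicity-score quartile", y = "share of compounds",
                  fill = "class") +
    ggplot2::theme_minimal()
}
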