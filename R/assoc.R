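#' Potency score from a dose
#'
#' Continuous in vivo endpoints (LD50, NOAEL, in mg/kg) are analyzed as
#' `-log10(dose)` so that higher scores mean higher potency (toxicity at
#' lower doses). Vectorized.
#'
#' @param dose_mg_per_kg Positive dose(s) in mg/kg (or mg/kg bw/day).
#' @return `-log10(dose)`.
#' @examples
#' neglog10_dose(c(1, 10, 50))
#' @export
neglog10_dose <- function(dose_mg_per_kg) {
  if (any(!is.finite(dose_mg_per_kg) | dose_mg_per_kg <= 0)) {
    stop("dose must be finite and > 0", call. = FALSE)
  }
  -log10(dose_mg_per_kg)
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y Numeric vectors, length >= 3, both nonconstant.
#' @return A list with `r` and two-sided `p` (t distribution, n - 2 df).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need n >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Sample-size-dependent correlation threshold
#'
#' Minimum defensible correlation magnitude `2 / sqrt(n)` used as the
#' third retention criterion for continuous endpoints.
#'
#' @param n Number of compounds (>= 1).
#' @return `2 / sqrt(n)`.
#' @examples
#' sample_size_threshold(400)  # 0.1
#' @export
sample_size_threshold <- function(n) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  2 / sqrt(n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, `q_(i) = min_{j >= i} p_(j) * m / j`,
#' capped at 1, returned in the input order.
#'
#' @param pvals P-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Fisher z confidence interval for a correlation
#'
#' `atanh` transform, normal interval with standard error
#' `1 / sqrt(n - 3)`, mapped back by `tanh`. At `|stat| = 1` the
#' degenerate interval `(stat, stat)` is returned with a warning flag.
#'
#' @param stat Correlation (or rank-biserial) estimate in `[-1, 1]`.
#' @param n Sample size (>= 4).
#' @param level Confidence level.
#' @return List with `lo`, `hi`, `degenerate`.
#' @export
fisher_z_ci <- function(stat, n, level = 0.95) {
  stopifnot(n >= 4, abs(stat) <= 1)
  if (abs(stat) == 1) {
    return(list(lo = stat, hi = stat, degenerate = TRUE))
  }
  z <- atanh(stat)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  list(lo = tanh(z - q * se), hi = tanh(z + q * se), degenerate = FALSE)
}

#' Bootstrap percentile confidence interval for Pearson r
#'
#' Nonparametric paired bootstrap: `n_boot` resamples of the (x, y)
#' pairs, percentile interval of the resampled correlations.
#' Degenerate resamples (either margin constant) are redrawn and
#' counted.
#'
#' @param x,y Paired numeric vectors (n >= 5).
#' @param n_boot Number of resamples.
#' @param level Confidence level.
#' @param seed Seed; the interval is deterministic given the seed.
#' @return List with `lo`, `hi`, `n_degenerate`.
#' @export
bootstrap_ci <- function(x, y, n_boot = 2000, level = 0.95, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  set.seed(seed)
  n <- length(x)
  rs <- numeric(n_boot)
  n_degenerate <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) > 0 && stats::sd(y[idx]) > 0) break
      n_degenerate <- n_degenerate + 1L
    }
    rs[b] <- stats::cor(x[idx], y[idx])
  }
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(rs, c(a, 1 - a), type = 7))
  list(lo = ci[1], hi = ci[2], n_degenerate = n_degenerate)
}

# Brunner-Munzel two-sample test (tie-robust stochastic dominance),
# two-sided, Satterthwaite-type t approximation of the df.
brunner_munzel <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r_all <- rank(c(x, y))
  r1 <- r_all[seq_len(n1)]; r2 <- r_all[n1 + seq_len(n2)]
  ri1 <- rank(x); ri2 <- rank(y)
  m1 <- mean(r1); m2 <- mean(r2)
  p_hat <- (m2 - (n2 + 1) / 2) / n1  # P(X < Y) + 0.5 P(X = Y)
  v1 <- sum((r1 - ri1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - ri2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  if (n1 * v1 + n2 * v2 == 0) {
    # no variability in placements: identical-distribution degenerate case
    return(list(statistic = 0, df = n1 + n2 - 2, p = 1, p_hat = p_hat))
  }
  stat <- n1 * n2 * (m2 - m1) / (n1 + n2) / sqrt(n1 * v1 + n2 * v2)
  df <- (n1 * v1 + n2 * v2)^2 /
    ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  list(statistic = stat, df = df, p = p, p_hat = p_hat)
}

#' Two-group rank test with tie-dependent selection
#'
#' Compares pathway scores between toxic and nontoxic compounds: the
#' exact Wilcoxon rank-sum test when the pooled sample has no tied
#' values, otherwise the tie-robust Brunner-Munzel test (two-sided,
#' Satterthwaite t approximation). Ties are detected after rounding to
#' 12 significant digits. Groups of fewer than 5 trigger a warning for
#' the Brunner-Munzel approximation.
#'
#' @param toxic,nontoxic Numeric score vectors (each length >= 2).
#' @return List with `p`, `test_used` (`"wilcoxon"` or
#'   `"brunner_munzel"`), and `statistic`.
#' @export
rank_group_test <- function(toxic, nontoxic) {
  if (length(toxic) < 2 || length(nontoxic) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  pooled <- signif(c(toxic, nontoxic), 12)
  has_ties <- anyDuplicated(pooled) > 0
  if (!has_ties) {
    # exact null distribution for small samples, normal approximation
    # with continuity correction otherwise (standard practice)
    exact <- length(toxic) + length(nontoxic) < 50
    wt <- stats::wilcox.test(toxic, nontoxic, exact = exact,
                             correct = TRUE, alternative = "two.sided")
    return(list(p = wt$p.value, test_used = "wilcoxon",
                statistic = unname(wt$statistic)))
  }
  if (length(toxic) < 5 || length(nontoxic) < 5) {
    warning("Brunner-Munzel t approximation is unreliable below ",
            "5 observations per group", call. = FALSE)
  }
  bm <- brunner_munzel(nontoxic, toxic)  # p_hat = P(nontoxic < toxic)
  list(p = bm$p, test_used = "brunner_munzel", statistic = bm$statistic)
}

#' Rank-biserial correlation
#'
#' Effect size for a two-group rank comparison: `r_rb = 2A - 1` with
#' `A = (#\{toxic_i > nontoxic_j\} + 0.5 #ties) / (n1 n2)`; positive
#' when the toxic group is stochastically larger.
#'
#' @param toxic,nontoxic Nonempty numeric vectors.
#' @return `r_rb` in `[-1, 1]`.
#' @export
rank_biserial <- function(toxic, nontoxic) {
  if (length(toxic) == 0 || length(nontoxic) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  n1 <- length(toxic); n2 <- length(nontoxic)
  # tie-corrected Mann-Whitney favorable-pair count via midranks
  r_all <- rank(c(toxic, nontoxic))
  u <- sum(r_all[seq_len(n1)]) - n1 * (n1 + 1) / 2
  2 * (u / (n1 * n2)) - 1
}

#' Retention rule for one pathway-endpoint pair
#'
#' Continuous endpoints: retain iff `r >= r_min` and `q < q_max` and
#' `r >= 2 / sqrt(n)` (positive correlations only). Binary endpoints:
#' retain iff `r_rb > 0` and `q < q_max`.
#'
#' @param stat Pearson `r` (continuous) or `r_rb` (binary).
#' @param q BH-adjusted q-value.
#' @param n Compound count for the pair.
#' @param kind `"continuous"` or `"binary"`.
#' @param r_min Minimum correlation (continuous rule).
#' @param q_max Significance cutoff.
#' @param use_n_threshold Apply the `2 / sqrt(n)` criterion.
#' @return Logical.
#' @export
retain_pair <- function(stat, q, n, kind = c("continuous", "binary"),
                        r_min = 0.1, q_max = 0.05,
                        use_n_threshold = TRUE) {
  kind <- match.arg(kind)
  if (is.na(stat) || is.na(q)) return(FALSE)
  if (kind == "binary") return(stat > 0 && q < q_max)
  ok <- stat >= r_min && q < q_max
  if (use_n_threshold) ok <- ok && stat >= sample_size_threshold(n)
  ok
}

#' Pathway-endpoint association table
#'
#' Tests every pathway score vector against every endpoint: Pearson
#' correlation (with Fisher-z and, for `bootstrap_endpoints`,
#' bootstrap CIs) for continuous endpoints; rank test plus
#' rank-biserial effect size (Fisher-z CI) for binary endpoints.
#' Q-values are BH-adjusted within each endpoint across its candidate
#' pathways (set `fdr_scope = "global"` for one family across all
#' pairs), and the retention rule of [retain_pair()] is applied.
#'
#' @param path_scores Numeric matrix `pathways x chemicals` of
#'   summarized pathway scores (see [summarize_over_concentration()]).
#' @param endpoints Endpoint tibble: `endpoint_id`, `kind`
#'   (`"continuous"`/`"binary"`), `chemical_id`, `value` (continuous
#'   values already on the `-log10` dose scale; binary in 0/1).
#' @param r_min,q_max,use_n_threshold Retention thresholds.
#' @param fdr_scope `"per_endpoint"` (default) or `"global"`.
#' @param bootstrap_endpoints Endpoint ids that also get bootstrap CIs.
#' @param n_boot,seed Bootstrap settings.
#' @return A tibble with one row per (pathway, endpoint) pair:
#'   `pathway_id`, `endpoint_id`, `kind`, `n`, `stat`, `p`, `q`,
#'   `ci_lo`, `ci_hi`, `boot_lo`, `boot_hi`, `test_used`, `retained`.
#' @export
associate_pathways <- function(path_scores, endpoints, r_min = 0.1,
                               q_max = 0.05, use_n_threshold = TRUE,
                               fdr_scope = c("per_endpoint", "global"),
                               bootstrap_endpoints = character(),
                               n_boot = 2000, seed = 1L) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(is.matrix(path_scores),
            all(c("endpoint_id", "kind", "chemical_id", "value") %in%
                  names(endpoints)))
  pathways <- rownames(path_scores) %||%
    as.character(seq_len(nrow(path_scores)))
  chems <- colnames(path_scores)

  rows <- list()
  for (ep in unique(endpoints$endpoint_id)) {
    etab <- dplyr::filter(endpoints, .data$endpoint_id == ep,
                          is.finite(.data$value))
    kind <- etab$kind[1]
    idx <- match(etab$chemical_id, chems)
    etab <- etab[!is.na(idx), ]
    idx <- idx[!is.na(idx)]
    for (pw in seq_along(pathways)) {
      s <- path_scores[pw, idx]
      keep <- is.finite(s)
      s <- s[keep]; v <- etab$value[keep]
      n <- length(s)
      rec <- tibble::tibble(pathway_id = pathways[pw], endpoint_id = ep,
                            kind = kind, n = n, stat = NA_real_,
                            p = NA_real_, ci_lo = NA_real_,
                            ci_hi = NA_real_, boot_lo = NA_real_,
                            boot_hi = NA_real_, test_used = NA_character_)
      if (kind == "continuous") {
        if (n >= 3 && stats::sd(s) > 0 && stats::sd(v) > 0) {
          pr <- pearson_r(s, v)
          ci <- fisher_z_ci(pr$r, max(n, 4))
          rec$stat <- pr$r; rec$p <- pr$p
          rec$ci_lo <- ci$lo; rec$ci_hi <- ci$hi
          rec$test_used <- "pearson"
          if (ep %in% bootstrap_endpoints && n >= 5) {
            bci <- bootstrap_ci(s, v, n_boot = n_boot, seed = seed)
            rec$boot_lo <- bci$lo; rec$boot_hi <- bci$hi
          }
        }
      } else {
        tox <- s[v == 1]; non <- s[v == 0]
        if (length(tox) >= 2 && length(non) >= 2) {
          rt <- suppressWarnings(rank_group_test(tox, non))
          rec$stat <- rank_biserial(tox, non)
          rec$p <- rt$p
          rec$test_used <- rt$test_used
          ci <- fisher_z_ci(max(min(rec$stat, 1), -1), max(n, 4))
          rec$ci_lo <- ci$lo; rec$ci_hi <- ci$hi
        }
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- dplyr::bind_rows(rows)
  if (fdr_scope == "per_endpoint") {
    out <- out |>
      dplyr::group_by(.data$endpoint_id) |>
      dplyr::mutate(q = bh_fdr(.data$p)) |>
      dplyr::ungroup()
  } else {
    out$q <- bh_fdr(out$p)
  }
  out$retained <- mapply(retain_pair, out$stat, out$q, out$n, out$kind,
                         MoreArgs = list(r_min = r_min, q_max = q_max,
                                         use_n_threshold = use_n_threshold))
  dplyr::relocate(out, "q", .after = "p")
}

#' Binarized pathway-endpoint mapping from an association table
#'
#' @param assoc Association tibble from [associate_pathways()].
#' @param pathways,endpoints Optional axis orders (default: order of
#'   appearance).
#' @return A `mapping_matrix` (layer `"M3"`) with 0/1 weights: 1 iff
#'   the pair was retained.
#' @export
build_m3 <- function(assoc, pathways = NULL, endpoints = NULL) {
  if (is.null(pathways)) pathways <- unique(assoc$pathway_id)
  if (is.null(endpoints)) endpoints <- unique(assoc$endpoint_id)
  B <- matrix(0, length(pathways), length(endpoints),
              dimnames = list(pathways, endpoints))
  kept <- dplyr::filter(assoc, .data$retained)
  B[cbind(match(kept$pathway_id, pathways),
          match(kept$endpoint_id, endpoints))] <- 1
  mapping_matrix(B, B >= 0, layer = "M3", binarized = B)
}

#' Volcano-style view of a pathway-endpoint association table
#'
#' @param assoc Tibble from [associate_pathways()].
#' @return A ggplot: effect size vs `-log10(q)` faceted by endpoint,
#'   retained pairs highlighted.
#' @export
plot_associations <- function(assoc) {
  ggplot2::ggplot(dplyr::filter(assoc, is.finite(.data$q)),
                  ggplot2::aes(x = .data$stat,
                               y = -log10(pmax(.data$q, 1e-300)),
                               color = .data$retained)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::facet_wrap(~endpoint_id, scales = "free") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "grey60")) +
    ggplot2::labs(x = "effect size (r or rank-biserial)",
                  y = expression(-log[10](q)), color = "retained") +
    ggplot2::theme_minimal()
}
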