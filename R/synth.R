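#' Configuration for a synthetic study
#'
#' Defines the generating conditions of a fully synthetic study with
#' known ground truth: dimensions, mapping densities, true
#' pathway-endpoint associations, noise, and missingness. Defaults give
#' a compact study (20 assays, 8 proteins, 5 pathways, 300 chemicals,
#' 5 endpoints mirroring the acute/maternal/developmental/hepatotoxic
#' endpoint mix) sized for desk-scale validation.
#'
#' @param n_assays,n_proteins,n_pathways,n_chemicals,n_endpoints Counts
#'   (all >= 1).
#' @param endpoint_kinds Character vector (`"continuous"`/`"binary"`)
#'   of length `n_endpoints`; default: continuous except the last two
#'   (when `n_endpoints >= 4`).
#' @param grid Concentration grid for all curves.
#' @param assay_protein_density,protein_pathway_density Fractions in
#'   (0, 1] controlling structural mask sparsity (each row always keeps
#'   at least its dominant entry, and one dominant row per column is an
#'   exclusive anchor). Defaults mirror curated screening metadata,
#'   where an assay targets a single protein and proteins belong to
#'   one or two pathways.
#' @param true_assoc Tibble/data frame with columns `pathway`,
#'   `endpoint` (1-based indices) and `r_true` in (-1, 1): the planted
#'   associations. Default: pathway i drives endpoint i at r = 0.4.
#' @param noise_sd Gaussian response noise (percent units) added to
#'   sampled curves before Hill refitting.
#' @param missing_frac Fraction of (assay, chemical) pairs left
#'   untested.
#' @param binary_prevalence Target prevalence of binary endpoints.
#' @param dose_log10_mean,dose_log10_sd Location/scale of log10 dose
#'   (mg/kg) for continuous endpoints (defaults span the GHS moderate
#'   band).
#' @param seed Integer seed; the whole study is deterministic given it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_assays = 20, n_proteins = 8, n_pathways = 5,
                         n_chemicals = 300, n_endpoints = 5,
                         endpoint_kinds = NULL, grid = build_grid(),
                         assay_protein_density = 0.05,
                         protein_pathway_density = 0.25,
                         true_assoc = NULL, noise_sd = 0.05,
                         missing_frac = 0, binary_prevalence = 0.5,
                         dose_log10_mean = 2.5, dose_log10_sd = 0.8,
                         seed = 1L) {
  counts <- c(n_assays, n_proteins, n_pathways, n_chemicals, n_endpoints)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  if (assay_protein_density <= 0 || assay_protein_density > 1 ||
      protein_pathway_density <= 0 || protein_pathway_density > 1) {
    stop("densities must lie in (0, 1]", call. = FALSE)
  }
  if (missing_frac < 0 || missing_frac >= 1) {
    stop("missing_frac must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(endpoint_kinds)) {
    endpoint_kinds <- rep("continuous", n_endpoints)
    if (n_endpoints >= 4) {
      endpoint_kinds[(n_endpoints - 1):n_endpoints] <- "binary"
    }
  }
  stopifnot(length(endpoint_kinds) == n_endpoints,
            all(endpoint_kinds %in% c("continuous", "binary")))
  if (is.null(true_assoc)) {
    k <- min(n_pathways, n_endpoints)
    true_assoc <- tibble::tibble(pathway = seq_len(k),
                                 endpoint = seq_len(k),
                                 r_true = rep(0.4, k))
  }
  true_assoc <- tibble::as_tibble(true_assoc)
  if (nrow(true_assoc)) {
    stopifnot(all(c("pathway", "endpoint", "r_true") %in%
                    names(true_assoc)),
              all(true_assoc$pathway >= 1 &
                    true_assoc$pathway <= n_pathways),
              all(true_assoc$endpoint >= 1 &
                    true_assoc$endpoint <= n_endpoints))
    if (any(abs(true_assoc$r_true) >= 1)) {
      stop("r_true must lie in (-1, 1)", call. = FALSE)
    }
    tot <- tapply(true_assoc$r_true^2, true_assoc$endpoint, sum)
    if (any(tot >= 1)) {
      stop("sum of squared r_true per endpoint must be < 1", call. = FALSE)
    }
  }
  structure(list(n_assays = n_assays, n_proteins = n_proteins,
                 n_pathways = n_pathways, n_chemicals = n_chemicals,
                 n_endpoints = n_endpoints,
                 endpoint_kinds = endpoint_kinds, grid = grid,
                 assay_protein_density = assay_protein_density,
                 protein_pathway_density = protein_pathway_density,
                 true_assoc = true_assoc, noise_sd = noise_sd,
                 missing_frac = missing_frac,
                 binary_prevalence = binary_prevalence,
                 dose_log10_mean = dose_log10_mean,
                 dose_log10_sd = dose_log10_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Structural mask with one dominant entry per row; dominant columns
# round-robin so every column is covered when rows >= cols. One
# dominant row per column is reduced to an anchor (single allowed
# entry), which keeps the factorization identifiable at small sizes.
draw_mask <- function(n_row, n_col, density, row_what) {
  dominant <- rep(seq_len(n_col), length.out = n_row)[sample.int(n_row)]
  mask <- matrix(stats::runif(n_row * n_col) < density, n_row, n_col)
  mask[cbind(seq_len(n_row), dominant)] <- TRUE
  for (cc in seq_len(n_col)) {
    rows <- which(dominant == cc)
    if (length(rows)) {
      anchor <- rows[1]
      mask[anchor, ] <- FALSE
      mask[anchor, cc] <- TRUE
    }
  }
  empty <- which(rowSums(mask) == 0)
  if (length(empty)) {
    stop(sprintf("infeasible density: %s row(s) %s have no allowed entries",
                 row_what, paste(empty, collapse = ", ")), call. = FALSE)
  }
  list(mask = mask, dominant = dominant)
}

#' Generate a complete synthetic study with ground truth
#'
#' Draws sparse assay-protein and protein-pathway maps with positive
#' weights on every allowed entry, per-(pathway, chemical) Hill-shaped
#' latent pathway profiles (AC50 log-uniform over the grid interior,
#' slope in `[0.5, 3]`, log-uniform amplitudes), propagates them
#' through the true mappings (matrix products), converts each tested
#' assay-chemical profile to Hill parameters (exact when the profile
#' is a single Hill curve, i.e. one pathway; otherwise a least-squares
#' refit of the possibly noise-added sampled mixture curve), and draws
#' endpoint values whose population correlation with the planted
#' pathway's summarized score equals `r_true` (continuous) or follows
#' a logistic link (binary). Also emits a Css table and a
#' scaffold-family SMILES assignment for the clustering and exposure
#' stages. Deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @param refit_hill Refit emitted Hill parameters by least squares
#'   from (noise-added) sampled curves (default). `FALSE` emits
#'   analytic dominant-pathway parameters without refitting (no
#'   curve-level noise reaches the assay table), which is cheaper when
#'   only pathway scores and endpoints are consumed.
#' @return A list with `study` (tibbles/lists mirroring the pipeline's
#'   input files: `assay_params`, `assay_protein_map`, `gene_sets`,
#'   `endpoints`, `css`, `smiles`) and `truth` (`m1`, `m2` mapping
#'   matrices with dominant routes, `path_true` tensor, `path_scores`
#'   matrix, `endpoint_latent`, `pathway_of_assay`, `config`).
#' @export
generate_study <- function(config, refit_hill = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  nA <- config$n_assays; nP <- config$n_proteins
  nW <- config$n_pathways; nC <- config$n_chemicals
  nE <- config$n_endpoints
  grid <- config$grid
  g <- as.numeric(grid)
  lg <- log10(g)

  assay_ids <- sprintf("A%03d", seq_len(nA))
  protein_ids <- sprintf("PR%02d", seq_len(nP))
  pathway_ids <- sprintf("PW%02d", seq_len(nW))
  chem_ids <- sprintf("C%04d", seq_len(nC))
  endpoint_ids <- if (nE == 5) {
    c("acute_ld50", "maternal_noael", "developmental_noael",
      "hepatotox_human", "hepatotox_preclinical")
  } else {
    sprintf("EP%02d", seq_len(nE))
  }

  d1 <- draw_mask(nA, nP, config$assay_protein_density, "assay")
  d2 <- draw_mask(nP, nW, config$protein_pathway_density, "protein")
  dimnames(d1$mask) <- list(assay_ids, protein_ids)
  dimnames(d2$mask) <- list(protein_ids, pathway_ids)

  # positive weights on every allowed entry; inhibitory assays carry a
  # negative row sign so curve direction varies across assays
  assay_sign <- sample(c(1, -1), nA, replace = TRUE, prob = c(0.7, 0.3))
  w1 <- matrix(0, nA, nP, dimnames = list(assay_ids, protein_ids))
  w1[d1$mask] <- stats::runif(sum(d1$mask), 0.3, 1)
  w1 <- w1 * assay_sign
  w2 <- matrix(0, nP, nW, dimnames = list(protein_ids, pathway_ids))
  w2[d2$mask] <- stats::runif(sum(d2$mask), 0.3, 1)
  pathway_of_assay <- d2$dominant[d1$dominant]

  # latent pathway potencies: AC50 log-uniform over the grid interior,
  # log-uniform amplitudes
  lo <- lg[1] + 0.15 * (lg[length(lg)] - lg[1])
  hi <- lg[1] + 0.85 * (lg[length(lg)] - lg[1])
  lac50 <- matrix(stats::runif(nW * nC, lo, hi), nW, nC)
  slope <- matrix(stats::runif(nW * nC, 0.5, 3), nW, nC)
  t_amp <- matrix(10^stats::runif(nW * nC, 1, 2), nW, nC)

  # path_true[p, c, j] = amplitude * unit Hill
  path_vals <- array(0, c(nW, length(g), nC),
                     dimnames = list(pathway_ids, NULL, chem_ids))
  for (p in seq_len(nW)) {
    h <- 1 / (1 + exp(log(10) *
      outer(lg, lac50[p, ], function(a, b) -(a - b)) *
        rep(slope[p, ], each = length(lg))))
    path_vals[p, , ] <- h * rep(t_amp[p, ], each = length(lg))
  }
  path_true <- layer_tensor(path_vals, entity_ids = pathway_ids,
                            chemical_ids = chem_ids, grid = grid,
                            layer = "path")
  path_scores <- summarize_over_concentration(path_true)

  # assay-level mixture curves from the true mapping product
  w12 <- w1 %*% w2
  tested <- matrix(stats::runif(nA * nC) >= config$missing_frac, nA, nC)
  rows <- list()
  for (a in seq_len(nA)) {
    js <- which(tested[a, ])
    if (!length(js)) next
    # dominant-route analytic parameters (exact when n_pathways == 1)
    amp <- drop(w12[a, ] %*% t_amp[, js, drop = FALSE])
    p_dom <- if (nW == 1) rep(1L, length(js)) else {
      apply(abs(w12[a, ] * t_amp[, js, drop = FALSE]), 2, which.max)
    }
    ac50 <- 10^lac50[cbind(p_dom, js)]
    sl <- slope[cbind(p_dom, js)]
    tops <- amp
    needs_fit <- refit_hill && (nW > 1 || config$noise_sd > 0)
    if (needs_fit) {
      for (k in seq_along(js)) {
        mix <- drop(w12[a, ] %*% path_vals[, , js[k], drop = TRUE])
        if (nW == 1) mix <- w12[a, 1] * path_vals[1, , js[k]]
        resp <- mix + stats::rnorm(length(g), sd = config$noise_sd)
        fit <- fit_hill_ls(g, resp,
                           start = c(ac50 = ac50[k], slope = sl[k],
                                     top = tops[k]))
        ac50[k] <- fit["ac50"]; sl[k] <- fit["slope"]
        tops[k] <- fit["top"]
      }
    }
    rows[[a]] <- tibble::tibble(assay_id = assay_ids[a],
                                chemical_id = chem_ids[js],
                                ac50 = ac50, slope = sl, top = tops,
                                unit = "M")
  }
  assay_params <- dplyr::bind_rows(rows)

  # endpoints: shared latent per endpoint from planted pathways
  zscore <- function(x) (x - mean(x)) / stats::sd(x)
  ep_rows <- list()
  endpoint_latent <- matrix(stats::rnorm(nE * nC), nE, nC,
                            dimnames = list(endpoint_ids, chem_ids))
  for (e in seq_len(nE)) {
    ta <- config$true_assoc[config$true_assoc$endpoint == e, ]
    latent <- rep(0, nC); r2 <- 0
    if (nrow(ta)) {
      for (k in seq_len(nrow(ta))) {
        latent <- latent + ta$r_true[k] * zscore(path_scores[ta$pathway[k], ])
      }
      r2 <- sum(ta$r_true^2)
    }
    latent <- latent + sqrt(1 - r2) * stats::rnorm(nC)
    endpoint_latent[e, ] <- latent
    if (config$endpoint_kinds[e] == "continuous") {
      # -log10(dose) correlates with the planted pathway score at r_true
      value <- 10^(config$dose_log10_mean -
                     config$dose_log10_sd * latent)
    } else {
      beta <- if (nrow(ta)) 2 * sum(ta$r_true) else 0
      eta <- stats::qlogis(config$binary_prevalence) +
        beta * (if (nrow(ta)) zscore(latent) else latent)
      value <- as.numeric(stats::runif(nC) < stats::plogis(eta))
    }
    ep_rows[[e]] <- tibble::tibble(endpoint_id = endpoint_ids[e],
                                   kind = config$endpoint_kinds[e],
                                   chemical_id = chem_ids, value = value)
  }
  endpoints <- dplyr::bind_rows(ep_rows)

  # Css table (uM; standardized 1 mg/kg/day dosing), lognormal spread
  p50 <- 10^stats::rnorm(nC, 0, 0.5)
  spread <- 10^stats::runif(nC, 0.3, 0.8)
  css <- tibble::tibble(chemical_id = chem_ids, css_p5 = p50 / spread,
                        css_p50 = p50, css_p95 = p50 * spread,
                        dose_basis = 1)

  # scaffold-family SMILES, cycled over the packaged library
  lib <- scaffold_smiles_library()
  pick <- rep(seq_len(nrow(lib)), length.out = nC)
  smiles <- tibble::tibble(chemical_id = chem_ids,
                           smiles = lib$smiles[pick],
                           family = lib$family[pick])

  gene_sets <- lapply(seq_len(nW), function(p) {
    protein_ids[d2$mask[, p]]
  })
  names(gene_sets) <- pathway_ids
  assay_protein_map <- tibble::tibble(
    assay_id = assay_ids[row(d1$mask)[d1$mask]],
    protein_id = protein_ids[col(d1$mask)[d1$mask]]) |>
    dplyr::arrange(.data$assay_id, .data$protein_id)

  list(
    study = list(assay_params = assay_params,
                 assay_protein_map = assay_protein_map,
                 gene_sets = gene_sets, endpoints = endpoints,
                 css = css, smiles = smiles),
    truth = list(
      m1 = mapping_matrix(w1, d1$mask, layer = "M1"),
      m2 = mapping_matrix(w2, d2$mask, layer = "M2"),
      path_true = path_true, path_scores = path_scores,
      endpoint_latent = endpoint_latent,
      pathway_of_assay = stats::setNames(pathway_ids[pathway_of_assay],
                                         assay_ids),
      dominant_protein = stats::setNames(protein_ids[d1$dominant],
                                         assay_ids),
      config = config))
}

# least-squares Hill refit on the log-concentration grid
fit_hill_ls <- function(conc, resp, start) {
  lc <- log(conc)
  df <- data.frame(lc = lc, resp = resp)
  st <- list(lac50 = log(start[["ac50"]]), slope = start[["slope"]],
             top = start[["top"]])
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(resp ~ top / (1 + exp(slope * (lac50 - lc))),
                        data = df, start = st,
                        lower = c(lac50 = log(1e-15), slope = 0.05,
                                  top = -2e3),
                        upper = c(lac50 = log(1), slope = 30, top = 2e3),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(c(ac50 = start[["ac50"]], slope = start[["slope"]],
             top = start[["top"]]))
  }
  cf <- stats::coef(fit)
  c(ac50 = exp(cf[["lac50"]]), slope = cf[["slope"]], top = cf[["top"]])
}

#' Write a synthetic study to pipeline input files
#'
#' Emits the same formats the pipeline readers consume (assay CSV,
#' assay-protein CSV, GMT gene sets, endpoint CSV, Css CSV, SMILES
#' file) plus a JSON ground-truth sidecar for tests.
#'
#' @param study Output of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- study$study
  paths <- c(assay_params = file.path(dir, "assay_params.csv"),
             assay_protein_map = file.path(dir, "assay_protein_map.csv"),
             gene_sets = file.path(dir, "pathways.gmt"),
             endpoints = file.path(dir, "endpoints.csv"),
             css = file.path(dir, "css.csv"),
             smiles = file.path(dir, "chemicals.smi"),
             truth = file.path(dir, "ground_truth.json"))
  readr::write_csv(s$assay_params, paths["assay_params"])
  readr::write_csv(s$assay_protein_map, paths["assay_protein_map"])
  write_gmt(s$gene_sets, paths["gene_sets"])
  readr::write_csv(s$endpoints, paths["endpoints"])
  readr::write_csv(s$css, paths["css"])
  writeLines(paste(s$smiles$smiles, s$smiles$chemical_id),
             paths["smiles"])
  tr <- study$truth
  jsonlite::write_json(
    list(seed = tr$config$seed,
         pathway_of_assay = as.list(tr$pathway_of_assay),
         path_scores = tr$path_scores,
         m1_weights = tr$m1$weights, m2_weights = tr$m2$weights),
    paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Packaged scaffold-family SMILES library
#'
#' A synthetic library of ~100 small, valid structures organized into
#' homologous scaffold families (phenothiazines, organophosphorus
#' esters, parabens, xanthines, sulfonamides, acetanilides,
#' barbiturates, phthalate diesters) so that fingerprint clustering has
#' known family structure.
#'
#' @return Tibble with `smiles`, `family`.
#' @export
scaffold_smiles_library <- function() {
  fam <- list(
    phenothiazine = c(
      paste0("CN(C)CCCN1c2ccccc2Sc2ccc(", c("", "Cl", "F", "Br", "C",
                                            "OC", "CC", "N"), ")cc21"),
      paste0("CN(C)CCN1c2ccccc2Sc2ccc(", c("", "Cl", "C", "OC"), ")cc21")),
    organophosphate = c(
      paste0("CCOP(=S)(OCC)Oc1ccc(", c("[N+](=O)[O-]", "C", "Cl", "Br",
                                       "OC", "CC"), ")cc1"),
      paste0("COP(=S)(OC)Oc1ccc(", c("[N+](=O)[O-]", "C", "Cl", "CN"),
             ")cc1")),
    paraben = paste0(
      c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CC(C)", "CCCCCCC",
        "CC(C)C", "CCCCCCCC"), "OC(=O)c1ccc(O)cc1"),
    xanthine = c("Cn1cnc2c1c(=O)n(C)c(=O)n2C",
                 "Cn1c(=O)c2[nH]cnc2n(C)c1=O",
                 "Cn1cnc2c1c(=O)[nH]c(=O)n2C",
                 "CCn1cnc2c1c(=O)n(C)c(=O)n2C",
                 "CCn1cnc2c1c(=O)n(CC)c(=O)n2C",
                 "Cn1cnc2c1c(=O)n(CCC)c(=O)n2C",
                 "Cn1cnc2c1c(=O)n(C)c(=O)n2CC",
                 "CCCn1cnc2c1c(=O)n(C)c(=O)n2C"),
    sulfonamide = paste0(
      "NS(=O)(=O)c1ccc(", c("N", "NC", "NC(C)=O", "NCC", "C", "OC",
                            "Cl", "NC(=O)CC", "CN", "O"), ")cc1"),
    acetanilide = paste0(
      "CC(=O)Nc1ccc(", c("", "O", "C", "OC", "Cl", "F", "Br", "CC",
                         "OCC", "N"), ")cc1"),
    barbiturate = paste0(
      c("CC", "CCC", "CCCC", "CC(C)", "CCCCC", "C", "CCC(C)", "CCCCCC"),
      "C1(CC)C(=O)NC(=O)NC1=O"),
    phthalate = paste0(
      c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CC(C)", "CCCCCCCC"),
      "OC(=O)c1ccccc1C(=O)O",
      c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CC(C)", "CCCCCCCC"))
  )
  tibble::tibble(
    smiles = unlist(fam, use.names = FALSE),
    family = rep(names(fam), lengths(fam)))
}
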