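#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Read a GMT gene-set file into a protein-pathway mask
#'
#' Parses a standard tab-separated GMT file (set name, description,
#' members) and intersects members with the protein roster. Sets that
#' are empty or contain no rostered proteins are dropped with a
#' warning/count.
#'
#' @param path GMT file path.
#' @param proteins Protein roster (row order of the returned mask).
#' @return Logical matrix `proteins x pathways`; attribute `n_dropped`
#'   counts dropped sets.
#' @export
read_genesets <- function(path, proteins) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stop("fgsea is required to read GMT files", call. = FALSE)
  }
  sets <- fgsea::gmtPathways(path)
  keep <- vapply(sets, function(s) length(intersect(s, proteins)) > 0,
                 logical(1))
  if (any(!keep)) {
    warning(sum(!keep), " gene set(s) without rostered proteins dropped",
            call. = FALSE)
  }
  sets <- sets[keep]
  m <- vapply(sets, function(s) proteins %in% s,
              logical(length(proteins)))
  m <- matrix(m, nrow = length(proteins),
              dimnames = list(proteins, names(sets)))
  attr(m, "n_dropped") <- sum(!keep)
  m
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (set members).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a layer tensor as portable text
#'
#' Long-format CSV of observed entries plus a JSON sidecar with axis
#' metadata; `read_layer_tensor()` restores the tensor losslessly (12
#' significant digits).
#'
#' @param x A `layer_tensor`.
#' @param stem Output path stem (writes `<stem>.csv` and
#'   `<stem>.json`).
#' @return Invisibly, the paths.
#' @export
write_layer_tensor <- function(x, stem) {
  stopifnot(inherits(x, "layer_tensor"))
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, ".json")
  tidy(x) |>
    dplyr::mutate(response = signif(.data$response, 12)) |>
    dplyr::select("entity_id", "conc_index", "chemical_id", "response") |>
    readr::write_csv(csv)
  jsonlite::write_json(list(layer = x$layer, entity_ids = x$entity_ids,
                            chemical_ids = x$chemical_ids,
                            grid = as.numeric(x$grid)),
                       js, digits = NA)
  invisible(c(values = csv, meta = js))
}

#' @rdname write_layer_tensor
#' @export
read_layer_tensor <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  tbl <- readr::read_csv(paste0(stem, ".csv"), show_col_types = FALSE,
                         progress = FALSE)
  grid <- structure(meta$grid, class = c("conc_grid", "numeric"))
  d <- c(length(meta$entity_ids), length(meta$grid),
         length(meta$chemical_ids))
  vals <- array(NA_real_, d, dimnames = list(meta$entity_ids, NULL,
                                             meta$chemical_ids))
  mask <- array(FALSE, d, dimnames = dimnames(vals))
  idx <- cbind(match(tbl$entity_id, meta$entity_ids), tbl$conc_index,
               match(tbl$chemical_id, meta$chemical_ids))
  vals[idx] <- tbl$response
  mask[idx] <- TRUE
  layer_tensor(vals, mask, meta$entity_ids, meta$chemical_ids, grid,
               meta$layer)
}

#' Run the full hierarchical pipeline
#'
#' Executes the staged workflow on input files or in-memory tables:
#' harmonize the assay table onto the grid, fit the protein and
#' pathway layers, summarize pathway scores, statistically filter
#' pathway-endpoint associations into the binarized M3, fit the
#' toxicity layer, and score/stratify compounds; optionally cluster
#' structures and flag exposure-relevant compounds when SMILES / Css
#' inputs are present. All tables plus a machine-readable run manifest
#' are written to `out_dir`. Deterministic given `seed`.
#'
#' @param config Either a YAML file path or a named list with elements
#'   `assay_params`, `assay_protein_map`, `gene_sets`, `endpoints`
#'   (file paths or in-memory objects), optional `css` and `smiles`,
#'   and optional scalar settings `r_min`, `q_max`, `use_n_threshold`,
#'   `fdr_scope`, `cluster_threshold`, `cluster_min_size`,
#'   `summary_stat`, plus training settings `lr0`, `max_epochs`.
#' @param out_dir Output directory.
#' @param seed Seed applied to every stochastic stage.
#' @return Invisibly, a list with the fitted objects, tables and the
#'   manifest; files are written under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_get <- function(nm, default) config[[nm]] %||% default
  stages <- character()
  fail <- function(stage, e) {
    writeLines(c(stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) fail(name, e))
    stages <<- c(stages, name)
    res
  }

  grid <- build_grid(n = cfg_get("grid_n", 45),
                     c_min = cfg_get("grid_min", 1e-12),
                     c_max = cfg_get("grid_max", 1e-4))
  tcfg <- train_config(lr0 = cfg_get("lr0", 0.001),
                       max_epochs = cfg_get("max_epochs", 1000),
                       seed = seed)

  load_tbl <- function(x, reader) if (is.character(x)) reader(x) else x

  params <- load_tbl(config$assay_params, read_assay_table)
  ap_map <- load_tbl(config$assay_protein_map,
                     function(p) readr::read_csv(p, show_col_types = FALSE,
                                                 progress = FALSE))

  assay <- run_stage("harmonize", build_assay_tensor(params, grid))
  write_layer_tensor(assay, file.path(out_dir, "assay_tensor"))

  proteins <- sort(unique(ap_map$protein_id))
  m1_mask <- matrix(FALSE, length(assay$entity_ids), length(proteins),
                    dimnames = list(assay$entity_ids, proteins))
  m1_mask[cbind(match(ap_map$assay_id, assay$entity_ids),
                match(ap_map$protein_id, proteins))] <- TRUE

  gs <- config$gene_sets
  m2_mask <- if (is.character(gs)) read_genesets(gs, proteins) else {
    m <- vapply(gs, function(s) proteins %in% s, logical(length(proteins)))
    matrix(m, nrow = length(proteins),
           dimnames = list(proteins, names(gs)))
  }

  fit1 <- run_stage("protein_layer",
                    fit_protein_layer(assay, m1_mask, tcfg))
  fit2 <- run_stage("pathway_layer",
                    fit_pathway_layer(fit1$latent, m2_mask, tcfg))

  stat <- cfg_get("summary_stat", "mean")
  path_scores <- run_stage("summarize",
                           summarize_over_concentration(fit2$latent,
                                                        stat = stat))
  readr::write_csv(tibble::as_tibble(path_scores,
                                     rownames = "pathway_id"),
                   file.path(out_dir, "path_scores.csv"))

  endpoints <- load_tbl(config$endpoints,
                        function(p) readr::read_csv(p,
                                                    show_col_types = FALSE,
                                                    progress = FALSE))
  ep <- endpoints |>
    dplyr::filter(.data$kind == "binary" | .data$value > 0) |>
    dplyr::mutate(value = dplyr::if_else(.data$kind == "continuous",
                                         -log10(.data$value),
                                         .data$value))

  assoc <- run_stage("filter", {
    a <- associate_pathways(
      path_scores, ep, r_min = cfg_get("r_min", 0.1),
      q_max = cfg_get("q_max", 0.05),
      use_n_threshold = cfg_get("use_n_threshold", TRUE),
      fdr_scope = cfg_get("fdr_scope", "per_endpoint"), seed = seed)
    readr::write_csv(a, file.path(out_dir, "associations.csv"))
    a
  })
  m3 <- build_m3(assoc, pathways = fit2$latent$entity_ids)

  fit3 <- run_stage("tox_layer", {
    keep_ep <- colSums(m3$binarized) > 0
    if (!any(keep_ep)) {
      stop("no endpoint has any retained pathway", call. = FALSE)
    }
    if (any(!keep_ep)) {
      warning("endpoint(s) without retained pathways dropped: ",
              paste(colnames(m3$binarized)[!keep_ep], collapse = ", "),
              call. = FALSE)
    }
    m3_kept <- m3$binarized[, keep_ep, drop = FALSE]
    fit_tox_layer(fit2$latent, m3_kept, tcfg)
  })

  scores <- run_stage("score", score_compounds(fit3, stat = stat))
  readr::write_csv(scores, file.path(out_dir, "tox_scores.csv"))

  clusters <- NULL
  if (!is.null(config$smiles)) {
    clusters <- run_stage("cluster", {
      smi <- config$smiles
      if (is.character(smi) && length(smi) == 1 && file.exists(smi)) {
        lines <- strsplit(readLines(smi), "[ \t]+")
        smi <- tibble::tibble(smiles = vapply(lines, `[`, "", 1),
                              chemical_id = vapply(lines, `[`, "", 2))
      }
      fps <- maccs_fingerprints(smi$smiles, smi$chemical_id)
      cl <- taylor_butina(fps,
                          threshold = cfg_get("cluster_threshold", 0.7),
                          min_size = cfg_get("cluster_min_size", 5))
      readr::write_csv(cl, file.path(out_dir, "clusters.csv"))
      cl
    })
  }

  exposure <- NULL
  if (!is.null(config$css)) {
    exposure <- run_stage("exposure", {
      css <- load_tbl(config$css, read_css_table)
      pot <- dplyr::bind_rows(layer_potencies(assay),
                              layer_potencies(fit1$latent),
                              layer_potencies(fit2$latent))
      fl <- suppressWarnings(exposure_flags(css, pot))
      readr::write_csv(fl, file.path(out_dir, "exposure_flags.csv"))
      fl
    })
  }

  manifest <- list(
    package = "toxhier",
    version = as.character(utils::packageVersion("toxhier")),
    seed = seed, stages = stages,
    n_assays = length(assay$entity_ids),
    n_proteins = length(proteins),
    n_pathways = ncol(m2_mask),
    n_retained_pairs = sum(assoc$retained),
    retained_per_endpoint = as.list(
      tapply(assoc$retained, assoc$endpoint_id, sum)),
    config_hash = rlang::hash(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(assay = assay, protein_fit = fit1, pathway_fit = fit2,
                 tox_fit = fit3, path_scores = path_scores,
                 associations = assoc, m3 = m3, scores = scores,
                 clusters = clusters, exposure = exposure,
                 manifest = manifest))
}
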