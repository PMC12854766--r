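test_that("synth_config validates its inputs", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(n_assays = 0), "counts")
  expect_error(synth_config(assay_protein_density = 0), "densities")
  expect_error(synth_config(missing_frac = 1), "missing_frac")
  expect_error(synth_config(true_assoc = data.frame(pathway = 1,
                                                    endpoint = 1,
                                                    r_true = 1.2)),
               "r_true")
  expect_error(synth_config(endpoint_kinds = c("continuous", "weird"),
                            n_endpoints = 2), "endpoint_kinds")
})

test_that("generate_study is deterministic given the seed", {
  cfg <- synth_config(n_assays = 5, n_proteins = 3, n_pathways = 2,
                      n_chemicals = 25, seed = 42)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$study, b$study)
  expect_identical(a$truth$path_scores, b$truth$path_scores)
  d <- generate_study(synth_config(n_assays = 5, n_proteins = 3,
                                   n_pathways = 2, n_chemicals = 25,
                                   seed = 43))
  expect_false(identical(a$study$assay_params, d$study$assay_params))
})

test_that("noiseless single-chain curves refit exactly", {
  st <- tiny_exact_study()
  g <- as.numeric(st$truth$config$grid)
  ap <- st$study$assay_params
  w12 <- st$truth$m1$weights %*% st$truth$m2$weights
  for (i in seq_len(nrow(ap))) {
    a <- match(ap$assay_id[i], rownames(w12))
    j <- match(ap$chemical_id[i], st$truth$path_true$chemical_ids)
    gen <- drop(w12[a, ] %*% matrix(st$truth$path_true$values[, , j],
                                    nrow = 1))
    refit <- hill_response(g, ap$ac50[i], ap$slope[i], ap$top[i])
    expect_lt(max(abs(refit - gen)), 1e-6)
  }
})

test_that("endpoint correlation is calibrated to r_true at large n", {
  cfg <- synth_config(n_assays = 2, n_proteins = 2, n_pathways = 2,
                      n_chemicals = 2000, n_endpoints = 1,
                      endpoint_kinds = "continuous",
                      true_assoc = data.frame(pathway = 1, endpoint = 1,
                                              r_true = 0.5),
                      seed = 99)
  st <- generate_study(cfg, refit_hill = FALSE)
  ep <- st$study$endpoints
  r <- cor(st$truth$path_scores[1, ], -log10(ep$value))
  expect_equal(r, 0.5, tolerance = 0.05)
  # unlinked pathway stays near zero
  r0 <- cor(st$truth$path_scores[2, ], -log10(ep$value))
  expect_lt(abs(r0), 0.1)
})

test_that("binary endpoints follow prevalence and direction", {
  cfg <- synth_config(n_assays = 2, n_proteins = 2, n_pathways = 2,
                      n_chemicals = 1500, n_endpoints = 1,
                      endpoint_kinds = "binary",
                      true_assoc = data.frame(pathway = 1, endpoint = 1,
                                              r_true = 0.4),
                      seed = 7)
  st <- generate_study(cfg, refit_hill = FALSE)
  y <- st$study$endpoints$value
  expect_true(all(y %in% c(0, 1)))
  expect_equal(mean(y), 0.5, tolerance = 0.06)
  s <- st$truth$path_scores[1, ]
  expect_gt(mean(s[y == 1]), mean(s[y == 0]))
})

test_that("missingness masks assay-chemical pairs", {
  cfg <- synth_config(n_assays = 10, n_proteins = 4, n_pathways = 2,
                      n_chemicals = 60, missing_frac = 0.3, noise_sd = 0,
                      seed = 13)
  st <- generate_study(cfg, refit_hill = FALSE)
  frac <- nrow(st$study$assay_params) / (10 * 60)
  expect_equal(frac, 0.7, tolerance = 0.07)
  at <- build_assay_tensor(st$study$assay_params, cfg$grid,
                           assays = sprintf("A%03d", 1:10),
                           chemicals = sprintf("C%04d", 1:60))
  expect_equal(mean(at$mask), frac, tolerance = 1e-9)
})

test_that("write_study emits re-readable files plus a truth sidecar", {
  st <- tiny_exact_study()
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  back <- read_assay_table(paths[["assay_params"]])
  expect_equal(nrow(back), nrow(st$study$assay_params))
  sets <- fgsea::gmtPathways(paths[["gene_sets"]])
  expect_length(sets, length(st$study$gene_sets))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$seed, st$truth$config$seed)
})

test_that("the packaged SMILES library is valid and family-structured", {
  lib <- scaffold_smiles_library()
  expect_gte(nrow(lib), 70)
  expect_gte(length(unique(lib$family)), 7)
  expect_true(all(table(lib$family) >= 5))
})
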