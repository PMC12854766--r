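test_that("tanimoto has the set-overlap semantics", {
  a <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_equal(tanimoto(c(1, 1, 1, 0, 0), c(0, 1, 1, 1, 0)), 0.5)
  expect_error(tanimoto(c(0, 0), c(0, 0)), "all-zero")
  # symmetry, and 1 iff identical, on random vectors
  set.seed(3)
  for (i in 1:30) {
    x <- runif(32) < 0.4; y <- runif(32) < 0.4
    if (!any(x) || !any(y)) next
    expect_equal(tanimoto(x, y), tanimoto(y, x))
    if (tanimoto(x, y) == 1) expect_identical(x, y)
  }
})

test_that("taylor_butina forms, filters and orders clusters", {
  # one 6-clique: a single retained cluster of 6
  f6 <- clique_fps(6)
  c6 <- taylor_butina(f6)
  expect_equal(sum(!is.na(c6$cluster_id)), 6)
  expect_equal(length(unique(stats::na.omit(c6$cluster_id))), 1)
  # 4 mutually similar + dissimilar singletons: nothing retained
  c4 <- taylor_butina(clique_fps(4, n_single = 3))
  expect_true(all(is.na(c4$cluster_id)))
  # 7-clique + 5-clique: exactly two retained clusters, sizes 7 and 5
  c75 <- taylor_butina(clique_fps(c(7, 5)))
  sizes <- table(stats::na.omit(c75$cluster_id))
  expect_setequal(as.integer(sizes), c(7L, 5L))
  # order invariance up to relabeling
  f <- clique_fps(c(7, 5), n_single = 2)
  perm <- c(9, 1, 14, 3, 8, 2, 11, 5, 13, 4, 10, 6, 12, 7)
  c_orig <- taylor_butina(f)
  c_perm <- taylor_butina(f[perm, ])
  merged <- dplyr::inner_join(c_orig, c_perm, by = "chemical_id")
  tab <- table(merged$cluster_id.x, merged$cluster_id.y, useNA = "ifany")
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("retained members sit within the threshold of their centroid", {
  skip_if_not_installed("ChemmineOB")
  lib <- scaffold_smiles_library()
  fps <- maccs_fingerprints(lib$smiles, sprintf("m%02d", seq_len(nrow(lib))))
  cl <- taylor_butina(fps, threshold = 0.7, min_size = 5)
  kept <- cl[!is.na(cl$cluster_id), ]
  expect_gt(nrow(kept), 0)
  for (cid in unique(kept$cluster_id)) {
    members <- kept$chemical_id[kept$cluster_id == cid]
    ctr <- kept$chemical_id[kept$cluster_id == cid & kept$is_centroid]
    expect_length(ctr, 1)
    sims <- vapply(members, function(m) tanimoto(fps[m, ], fps[ctr, ]),
                   numeric(1))
    expect_true(all(sims >= 0.7))
  }
})

test_that("MACCS clustering recovers the scaffold families", {
  skip_if_not_installed("ChemmineOB")
  lib <- scaffold_smiles_library()
  fps <- maccs_fingerprints(lib$smiles, sprintf("m%02d", seq_len(nrow(lib))))
  expect_equal(ncol(fps), 166)
  cl <- taylor_butina(fps)
  cl$family <- lib$family
  kept <- cl[!is.na(cl$cluster_id), ]
  # every retained cluster is family-pure
  purity <- tapply(kept$family, kept$cluster_id,
                   function(f) length(unique(f)) == 1)
  expect_true(all(purity))
  # most families are recovered as clusters
  expect_gte(length(unique(kept$family)), 6)
})

test_that("invalid SMILES are dropped with a warning, not an error", {
  skip_if_not_installed("ChemmineOB")
  expect_warning(fps <- maccs_fingerprints(c("CCO", "not_a_smiles((")),
                 "dropped")
  expect_equal(nrow(fps), 1)
})

test_that("cluster MCS patterns match every member", {
  skip_if_not_installed("ChemmineR")
  # two copies of the same molecule: pattern spans the whole molecule
  r <- cluster_mcs_smarts(c("CCO", "CCO"))
  expect_equal(r$n_atoms, 3)
  expect_true(smarts_matches(r$smarts, "CCO"))
  # ethanol + ethylamine share an ethyl fragment
  r2 <- cluster_mcs_smarts(c("CCO", "CCN"))
  expect_gte(r2$n_atoms, 2)
  expect_true(smarts_matches(r2$smarts, "CCO"))
  expect_true(smarts_matches(r2$smarts, "CCN"))
  # near-disjoint structures flag an empty pattern
  r3 <- cluster_mcs_smarts(c("C", "c1ccccc1"))
  expect_true(r3$too_small)
  expect_identical(r3$smarts, "")
  # a homologous family shares its scaffold
  lib <- scaffold_smiles_library()
  par <- lib$smiles[lib$family == "paraben"]
  r4 <- cluster_mcs_smarts(par)
  expect_gte(r4$n_atoms, 8)
  expect_true(all(vapply(par, function(s) smarts_matches(r4$smarts, s),
                         logical(1))))
})

test_that("MACCS bits agree with an independent cheminformatics toolkit", {
  skip_if_not_installed("ChemmineOB")
  py <- Sys.which("python")
  skip_if(py == "", "python not available")
  smiles <- c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C")
  script <- paste(
    "from rdkit import Chem",
    "from rdkit.Chem import MACCSkeys",
    sprintf("smis = ['%s']", paste(smiles, collapse = "','")),
    "for s in smis:",
    "    fp = MACCSkeys.GenMACCSKeys(Chem.MolFromSmiles(s))",
    "    print(','.join(str(b) for b in fp.GetOnBits()))",
    sep = "\n")
  out <- tryCatch(system2(py, "-", input = script, stdout = TRUE,
                          stderr = FALSE),
                  error = function(e) NULL)
  skip_if(is.null(out) || length(out) != 3, "rdkit oracle unavailable")
  fps <- maccs_fingerprints(smiles)
  for (i in 1:3) {
    ref <- as.integer(strsplit(out[i], ",")[[1]])
    ref <- ref[ref >= 1 & ref <= 166]
    got <- which(fps[i, ])
    # implementations differ slightly in a few key definitions; demand
    # strong overlap rather than identity
    expect_gt(length(intersect(ref, got)) / length(union(ref, got)), 0.6)
  }
})
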