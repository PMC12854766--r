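test_that("classify_assay reproduces the directionality scheme", {
  expect_identical(classify_assay(37.3, 116), "positive")
  expect_identical(classify_assay(-120, 120), "mixed")
  expect_identical(classify_assay(-120, -16.9), "negative")
  expect_identical(classify_assay(0, 0), "excluded")
  expect_identical(classify_assay(-0.5, 0.5), "excluded")
  expect_error(classify_assay(5, -5), "min_top")
})

test_that("classify_assay partitions the half-plane min <= max", {
  set.seed(1)
  a <- runif(500, -150, 150)
  b <- runif(500, -150, 150)
  min_top <- pmin(a, b); max_top <- pmax(a, b)
  cls <- classify_assay(min_top, max_top)
  expect_true(all(cls %in% c("positive", "negative", "mixed", "excluded")))
  # each point maps to exactly one category, consistent with the bands
  expect_identical(cls == "positive", min_top > 1 & max_top > 1)
  expect_identical(cls == "negative", min_top < -1 & max_top < -1)
  expect_identical(cls == "mixed", min_top < -1 & max_top > 1)
})

test_that("summarize_assay_tops computes per-assay extremes", {
  params <- tibble::tibble(
    assay_id = c("a1", "a1", "a1", "a2", "a2"),
    top = c(37.3, 80, 116, -120, 120))
  s <- summarize_assay_tops(params)
  expect_identical(s$category, c("positive", "mixed"))
  expect_equal(s$min_top, c(37.3, -120))
  expect_equal(s$max_top, c(116, 120))
  expect_equal(s$n_compounds, c(3L, 2L))
})

test_that("read_assay_table validates schema and drops invalid rows", {
  tbl <- tibble::tibble(
    assay_id = c("a", "a", "b", "b"), chemical_id = c("c1", "c1", "c1", "c2"),
    ac50 = c(1e-7, 2e-7, -1, 1e-6), slope = c(1, 1.2, 1, 0),
    top = c(50, 60, 70, 80), unit = "M")
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl, f)
  got <- read_assay_table(f)
  expect_equal(nrow(got), 2)           # invalid ac50/slope rows dropped
  expect_equal(attr(got, "n_dropped"), 2)
  # duplicates kept for replicate merging
  expect_equal(sum(got$assay_id == "a" & got$chemical_id == "c1"), 2)

  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl[, -3], bad)
  expect_error(read_assay_table(bad), "ac50")

  # uM units converted to molar
  um <- tibble::tibble(assay_id = "a", chemical_id = "c", ac50 = 2,
                       slope = 1, top = 10, unit = "uM")
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(um, f2)
  expect_equal(read_assay_table(f2)$ac50, 2e-6)
})

test_that("build_assay_tensor masks untested pairs and keeps shapes", {
  g <- tiny_grid()
  params <- tidyr::expand_grid(assay_id = c("a1", "a2"),
                               chemical_id = c("c1", "c2", "c3")) |>
    dplyr::mutate(ac50 = 1e-7, slope = 1, top = 50)
  full <- build_assay_tensor(params, g)
  expect_equal(dim(full), c(2L, length(g), 3L))
  expect_true(all(full$mask))
  miss <- build_assay_tensor(params[-4, ], g)
  expect_false(any(miss$mask["a2", , "c1"]))
  expect_true(all(miss$mask["a1", , ]))
  expect_true(all(is.na(miss$values["a2", , "c1"])))
})

test_that("assay-range scaling preserves relative amplitude and sign", {
  g <- tiny_grid()
  params <- tibble::tibble(assay_id = "a", chemical_id = c("c1", "c2"),
                           ac50 = 1e-7, slope = 1, top = c(50, -100))
  at <- build_assay_tensor(params, g, scale = "assay_range")
  # c2 has the largest |Top|: plateaus toward -100; c1 toward +50
  expect_lt(min(at$values["a", , "c2"]), -90)
  expect_gt(max(at$values["a", , "c1"]), 45)
  pt <- build_assay_tensor(params, g, scale = "percent_of_top")
  expect_equal(max(pt$values["a", , "c2"]), max(pt$values["a", , "c1"]))
})

test_that("noiseless single-pathway study round-trips through the tensor", {
  st <- tiny_exact_study()
  cfg <- st$truth$config
  at <- build_assay_tensor(st$study$assay_params, cfg$grid,
                           scale = "response")
  prod <- st$truth$m1$weights %*% st$truth$m2$weights
  for (j in seq_along(st$truth$path_true$chemical_ids)) {
    rec <- prod %*% matrix(st$truth$path_true$values[, , j], nrow = 1)
    expect_lt(max(abs(at$values[, , j] - rec)), 1e-6)
  }
})
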