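quick_cfg <- function(...) train_config(max_epochs = 200, warm_sweeps = 20, ...)

test_that("summarize_over_concentration averages over the grid mask-aware", {
  v <- array(7, c(1, 45, 1))
  lt <- layer_tensor(v)
  expect_equal(unname(summarize_over_concentration(lt)[1, 1]), 7)
  v[1, , 1] <- seq(0, 100, length.out = 45)
  expect_equal(unname(summarize_over_concentration(layer_tensor(v))[1, 1]),
               50)
  m <- array(FALSE, c(1, 45, 1))
  expect_true(is.na(summarize_over_concentration(layer_tensor(v, m))[1, 1]))
  # max statistic
  expect_equal(unname(summarize_over_concentration(layer_tensor(v),
                                                   stat = "max")[1, 1]), 100)
})

test_that("minmax_normalize maps to [0,1] with midpoint for constants", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(5, 5, 5)), c(0.5, 0.5, 0.5))
  expect_equal(minmax_normalize(c(-1, 0, 3)), c(0, 0.25, 1))
  expect_error(minmax_normalize(numeric()), "finite")
})

test_that("an all-zero tensor fits to (near) zero loss", {
  z <- layer_tensor(array(0, c(3, 9, 4)))
  f <- fit_protein_layer(z, matrix(TRUE, 3, 2), quick_cfg())
  expect_lt(f$loss, 1e-8)
})

test_that("scalar factorization reproduces a single observed curve", {
  g <- tiny_grid()
  curve <- hill_response(g, 1e-7, 1.3, 90)
  lt <- layer_tensor(array(curve, c(1, length(g), 1)), grid = g)
  f <- fit_protein_layer(lt, matrix(TRUE, 1, 1), quick_cfg())
  rec <- f$mapping$weights[1, 1] * f$latent$values[1, , 1]
  expect_lt(max(abs(rec - curve)), 1e-3)
})

test_that("identity M3 makes Tox equal Path", {
  st <- tiny_exact_study()
  path <- st$truth$path_true
  n <- length(path$entity_ids)
  f <- fit_tox_layer(path, diag(1, n, n), quick_cfg())
  expect_lt(max(abs(f$latent$values - path$values)), 1e-3)
})

test_that("shared-fiber endpoints solve the least-squares system", {
  g <- tiny_grid()
  fiber <- hill_response(g, 1e-7, 1, 60)
  vals <- array(rep(fiber, each = 2), c(2, length(g), 1))
  path <- layer_tensor(vals, grid = g, layer = "path")
  m3 <- matrix(c(1, 1), nrow = 2)  # one endpoint linked to both pathways
  f <- fit_tox_layer(path, m3, quick_cfg())
  rec <- m3 %*% matrix(f$latent$values[1, , 1], nrow = 1)
  expect_lt(mean((rec - vals[, , 1])^2), 1e-4)
  # zero Path trivially fits
  f0 <- fit_tox_layer(layer_tensor(array(0, c(2, 9, 1))), m3, quick_cfg())
  expect_lt(f0$loss, 1e-8)
})

test_that("infeasible masks raise informative errors", {
  z <- layer_tensor(array(0, c(2, 5, 2)))
  bad_m1 <- rbind(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_error(fit_protein_layer(z, bad_m1, quick_cfg()), "e2")
  m3 <- matrix(c(1, 0, 0, 0), 2, 2)  # second endpoint has no pathway
  expect_error(fit_tox_layer(z, m3, quick_cfg()), "unmodelable")
})

test_that("masked entries never influence the fit", {
  st <- tiny_exact_study()
  cfg <- st$truth$config
  at <- build_assay_tensor(st$study$assay_params, cfg$grid)
  at$mask[1, , 1] <- FALSE
  f_ref <- fit_protein_layer(at, st$truth$m1$structure_mask, quick_cfg())
  at2 <- at
  at2$values[1, , 1] <- 1e6  # perturb unobserved entries only
  f_pert <- fit_protein_layer(at2, st$truth$m1$structure_mask, quick_cfg())
  expect_identical(f_ref$mapping$weights, f_pert$mapping$weights)
  expect_identical(f_ref$latent$values, f_pert$latent$values)
})

test_that("structure masks are conserved and loss does not increase", {
  st <- tiny_exact_study()
  cfg <- st$truth$config
  at <- build_assay_tensor(st$study$assay_params, cfg$grid)
  f <- fit_protein_layer(at, st$truth$m1$structure_mask, quick_cfg())
  expect_true(all(f$mapping$weights[!f$mapping$structure_mask] == 0))
  expect_lte(f$trace$loss[nrow(f$trace)], f$trace$loss[1])
})

test_that("fits are deterministic given the seed", {
  st <- tiny_exact_study()
  cfg <- st$truth$config
  at <- build_assay_tensor(st$study$assay_params, cfg$grid)
  f1 <- fit_protein_layer(at, st$truth$m1$structure_mask,
                          quick_cfg(init = "normal", seed = 5))
  f2 <- fit_protein_layer(at, st$truth$m1$structure_mask,
                          quick_cfg(init = "normal", seed = 5))
  expect_identical(f1$mapping$weights, f2$mapping$weights)
  expect_identical(f1$latent$values, f2$latent$values)
})

test_that("tidy and glance summarize fits", {
  st <- tiny_exact_study()
  at <- build_assay_tensor(st$study$assay_params, st$truth$config$grid)
  f <- fit_protein_layer(at, st$truth$m1$structure_mask, quick_cfg())
  td <- generics::tidy(f)
  expect_identical(names(td), c("row_id", "col_id", "mapping", "weight"))
  expect_equal(nrow(td), sum(f$mapping$structure_mask))
  gl <- generics::glance(f)
  expect_equal(nrow(gl), 1)
  expect_true(gl$r2 > 0.99)
  p <- ggplot2::autoplot(f)
  expect_s3_class(p, "ggplot")
})
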