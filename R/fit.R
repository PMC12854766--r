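#' Training configuration for layer fitting
#'
#' Settings for the gradient-based masked factorization: Adam with a
#' plateau-triggered learning-rate decay and early stopping on
#' converged loss.
#'
#' @param lr0 Initial Adam step size.
#' @param plateau_factor Multiplier applied to the step size when the
#'   loss plateaus.
#' @param plateau_patience Epochs without improvement before decay.
#' @param max_epochs Epoch budget.
#' @param converge_tol Relative loss improvement below which an epoch
#'   counts as converged.
#' @param converge_window Consecutive converged epochs that trigger
#'   early stopping.
#' @param init `"lstsq"` (alternating-least-squares warm start,
#'   default) or `"normal"` (zero-mean normal, sd 0.01, seeded).
#' @param warm_sweeps Alternating-least-squares sweeps used by the
#'   `"lstsq"` warm start.
#' @param seed Seed for any random initialization.
#' @param response_scale Divisor applied to responses before training so
#'   percent-scale curves train on a `[0, 1]` scale; latent tensors are
#'   returned rescaled back.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr0 = 0.001, plateau_factor = 0.1,
                         plateau_patience = 20, max_epochs = 1000,
                         converge_tol = 1e-6, converge_window = 20,
                         init = c("lstsq", "normal"), seed = 1L,
                         warm_sweeps = 30, response_scale = 100) {
  stopifnot(lr0 > 0, plateau_factor > 0, plateau_factor < 1,
            max_epochs >= 1, plateau_patience >= 1, converge_window >= 1,
            response_scale > 0)
  structure(list(lr0 = lr0, plateau_factor = plateau_factor,
                 plateau_patience = plateau_patience,
                 max_epochs = max_epochs, converge_tol = converge_tol,
                 converge_window = converge_window,
                 init = match.arg(init), seed = as.integer(seed),
                 warm_sweeps = warm_sweeps,
                 response_scale = response_scale),
            class = "train_config")
}

unfold3 <- function(a) {
  d <- dim(a)
  matrix(a, nrow = d[1], ncol = d[2] * d[3])
}

ridge_solve <- function(W, A, lambda = 1e-8) {
  G <- crossprod(W) + diag(lambda, ncol(W))
  solve(G, crossprod(W, A))
}

# masked alternating-least-squares warm start; respects the observation
# mask by grouping columns with identical observation patterns
als_warm_start <- function(target, obs, struct, W, fixed = FALSE,
                           sweeps = 30, lambda = 1e-8, nonneg = FALSE) {
  all_obs <- all(obs)
  groups <- if (all_obs) NULL else {
    key <- apply(obs, 2, function(z) paste(which(z), collapse = ","))
    split(seq_len(ncol(obs)), key)
  }
  P <- NULL
  for (it in seq_len(max(sweeps, 1))) {
    if (all_obs) {
      P <- ridge_solve(W, target, lambda)
    } else {
      P <- matrix(0, ncol(struct), ncol(target))
      for (cols in groups) {
        rows <- obs[, cols[1]]
        if (!any(rows)) next
        Wg <- W[rows, , drop = FALSE]
        P[, cols] <- solve(crossprod(Wg) + diag(lambda, ncol(Wg)),
                           crossprod(Wg, target[rows, cols,
                                                drop = FALSE]))
      }
    }
    if (fixed) break
    for (a in seq_len(nrow(W))) {
      m <- struct[a, ]
      o <- if (all_obs) rep(TRUE, ncol(target)) else obs[a, ]
      if (!any(o)) next
      Pm <- P[m, o, drop = FALSE]
      wa <- solve(tcrossprod(Pm) + diag(lambda, sum(m)),
                  Pm %*% target[a, o])
      W[a, m] <- if (nonneg) pmax(wa, 0) else wa
    }
    # rebalance factor scales (W[,k] vs P[k,]) to avoid ALS seesaw
    for (kf in seq_len(ncol(W))) {
      a_n <- sqrt(mean(W[, kf]^2)); b_n <- sqrt(mean(P[kf, ]^2))
      if (a_n > 0 && b_n > 0) {
        c_n <- sqrt(a_n * b_n)
        W[, kf] <- W[, kf] * (c_n / a_n)
        P[kf, ] <- P[kf, ] * (c_n / b_n)
      }
    }
  }
  list(W = W, P = P)
}

# Adam-trained masked factorization target ~= W %*% P over observed
# entries. `struct` masks W; when `fixed_weights` is given only P trains.
fit_masked_factorization <- function(target, obs, struct,
                                     fixed_weights = NULL,
                                     cfg = train_config(),
                                     nonneg_weights = FALSE) {
  stopifnot(identical(dim(target), dim(obs)))
  target <- target / cfg$response_scale
  target[!obs] <- 0
  n_obs <- sum(obs)
  if (n_obs == 0) stop("no observed entries to fit", call. = FALSE)
  r <- ncol(struct)
  k <- ncol(target)

  fixed <- !is.null(fixed_weights)
  if (fixed) {
    W <- fixed_weights * 1.0
  } else {
    W <- struct / pmax(rowSums(struct), 1)  # row-normalized start
  }
  if (cfg$init == "lstsq") {
    ws <- als_warm_start(target, obs, struct, W,
                         fixed = fixed, sweeps = cfg$warm_sweeps,
                         nonneg = nonneg_weights)
    W <- ws$W
    P <- ws$P
  } else {
    set.seed(cfg$seed)
    P <- matrix(stats::rnorm(r * k, sd = 0.01), r, k)
  }

  adam <- function() list(m = 0, v = 0)
  sW <- adam(); sP <- adam()
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- cfg$lr0
  best <- Inf; wait <- 0; conv <- 0
  prev_loss <- NA_real_
  best_W <- W; best_P <- P; best_loss <- Inf
  trace <- vector("list", cfg$max_epochs)

  for (epoch in seq_len(cfg$max_epochs)) {
    R <- W %*% P - target
    R[!obs] <- 0
    loss <- sum(R * R) / n_obs
    if (!is.finite(loss)) {
      stop(sprintf("training diverged (non-finite loss at epoch %d)",
                   epoch), call. = FALSE)
    }
    trace[[epoch]] <- c(epoch = epoch, loss = loss, lr = lr)
    if (loss < best_loss) {
      best_loss <- loss; best_W <- W; best_P <- P
    }

    # early stopping: converged relative improvement, or a loss at the
    # numerical floor
    if (loss < 1e-12) break
    if (!is.na(prev_loss)) {
      rel <- (prev_loss - loss) / max(abs(prev_loss), 1e-12)
      conv <- if (rel < cfg$converge_tol) conv + 1 else 0
      if (conv >= cfg$converge_window) break
    }
    prev_loss <- loss

    # plateau-triggered step decay (relative improvement threshold 1e-4)
    if (loss < best * (1 - 1e-4)) {
      best <- loss; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= cfg$plateau_patience) {
        lr <- lr * cfg$plateau_factor
        wait <- 0
      }
    }

    gP <- 2 / n_obs * crossprod(W, R)
    sP$m <- b1 * sP$m + (1 - b1) * gP
    sP$v <- b2 * sP$v + (1 - b2) * gP * gP
    P <- P - lr * (sP$m / (1 - b1^epoch)) /
      (sqrt(sP$v / (1 - b2^epoch)) + eps)
    if (!fixed) {
      gW <- 2 / n_obs * tcrossprod(R, P)
      gW[!struct] <- 0
      sW$m <- b1 * sW$m + (1 - b1) * gW
      sW$v <- b2 * sW$v + (1 - b2) * gW * gW
      W <- W - lr * (sW$m / (1 - b1^epoch)) /
        (sqrt(sW$v / (1 - b2^epoch)) + eps)
      if (nonneg_weights) W <- pmax(W, 0)
      W[!struct] <- 0
    }
  }

  # keep the best parameters seen (early-stopping semantics)
  R <- W %*% P - target
  R[!obs] <- 0
  if (sum(R * R) / n_obs > best_loss) {
    W <- best_W; P <- best_P
    R <- W %*% P - target
    R[!obs] <- 0
  }
  loss <- sum(R * R) / n_obs
  mu <- sum(target[obs]) / n_obs
  ss_tot <- sum((target[obs] - mu)^2)
  r2 <- if (ss_tot > 0) 1 - sum(R * R) / ss_tot else NA_real_

  list(W = W, P = P * cfg$response_scale, loss = loss, r2 = r2,
       trace = dplyr::bind_rows(lapply(trace[!vapply(trace, is.null,
                                                     logical(1))],
                                       function(x) tibble::as_tibble_row(x))))
}

# resolve per-factor sign indeterminacy: orient each latent row to a
# nonnegative mean, folding the flip into the mapping column
orient_latent <- function(res) {
  flip <- rowMeans(res$P) < 0
  if (any(flip)) {
    res$P[flip, ] <- -res$P[flip, ]
    res$W[, flip] <- -res$W[, flip]
  }
  res
}

new_layer_fit <- function(mapping, latent, res, cfg, target_layer) {
  structure(list(mapping = mapping, latent = latent,
                 trace = res$trace, loss = res$loss, r2 = res$r2,
                 cfg = cfg, target_layer = target_layer),
            class = "layer_fit")
}

#' @export
print.layer_fit <- function(x, ...) {
  cat(sprintf(
    "<layer_fit> %s -> %s | %d epochs | loss %.3g | R2 %.4f\n",
    x$latent$layer, x$target_layer, nrow(x$trace), x$loss, x$r2))
  invisible(x)
}

check_rows_feasible <- function(mask, ids, what) {
  bad <- which(rowSums(mask) == 0)
  if (length(bad)) {
    stop(sprintf("%s %s has no allowed entries in the mapping mask",
                 what, paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
}

#' Fit the protein layer (Assay ~ M1 . Prot)
#'
#' Jointly trains the assay-to-protein mapping `M1` (masked by the
#' curated assay-protein map) and the latent protein tensor `Prot` so
#' that `M1 %*% Prot` reconstructs the observed Assay tensor, minimizing
#' the mean squared error over observed entries only.
#'
#' @param assay Assay `layer_tensor`.
#' @param m1_mask Logical matrix `n_assays x n_proteins` of allowed
#'   assay-protein links (each assay needs >= 1 protein).
#' @param cfg A [train_config()].
#' @param protein_ids Optional protein identifiers (defaults to mask
#'   colnames).
#' @return A `layer_fit` with elements `mapping` (`M1`), `latent`
#'   (`Prot` tensor), `trace`, `loss`, `r2`.
#' @export
fit_protein_layer <- function(assay, m1_mask, cfg = train_config(),
                              protein_ids = colnames(m1_mask)) {
  stopifnot(inherits(assay, "layer_tensor"),
            nrow(m1_mask) == dim(assay)[1])
  force(protein_ids)
  m1_mask <- matrix(as.logical(m1_mask), nrow(m1_mask))
  check_rows_feasible(m1_mask, assay$entity_ids, "assay")
  if (is.null(protein_ids)) protein_ids <- paste0("P", seq_len(ncol(m1_mask)))
  res <- fit_masked_factorization(unfold3(assay$values),
                                  unfold3(assay$mask), m1_mask, NULL, cfg)
  res <- orient_latent(res)
  d <- dim(assay$values)
  prot <- layer_tensor(array(res$P, c(ncol(m1_mask), d[2], d[3])),
                       entity_ids = protein_ids,
                       chemical_ids = assay$chemical_ids,
                       grid = assay$grid, layer = "prot")
  m1 <- mapping_matrix(res$W, m1_mask, layer = "M1")
  dimnames(m1$weights) <- list(assay$entity_ids, protein_ids)
  new_layer_fit(m1, prot, res, cfg, "assay")
}

#' Fit the pathway layer (Prot ~ M2 . Path)
#'
#' Trains the protein-to-pathway mapping `M2` (masked by the gene-set
#' membership matrix) and the latent pathway tensor `Path` so that
#' `M2 %*% Path` reconstructs the modeled protein tensor.
#'
#' @param prot Protein `layer_tensor` (e.g. `fit$latent` from
#'   [fit_protein_layer()]).
#' @param m2_mask Logical matrix `n_proteins x n_pathways`.
#' @param cfg A [train_config()].
#' @param pathway_ids Optional pathway identifiers.
#' @return A `layer_fit` with `mapping` (`M2`) and `latent` (`Path`).
#' @export
fit_pathway_layer <- function(prot, m2_mask, cfg = train_config(),
                              pathway_ids = colnames(m2_mask)) {
  stopifnot(inherits(prot, "layer_tensor"), nrow(m2_mask) == dim(prot)[1])
  force(pathway_ids)
  m2_mask <- matrix(as.logical(m2_mask), nrow(m2_mask))
  check_rows_feasible(m2_mask, prot$entity_ids, "protein")
  if (is.null(pathway_ids)) pathway_ids <- paste0("W", seq_len(ncol(m2_mask)))
  res <- fit_masked_factorization(unfold3(prot$values),
                                  unfold3(prot$mask), m2_mask, NULL, cfg,
                                  nonneg_weights = TRUE)
  res <- orient_latent(res)
  d <- dim(prot$values)
  path <- layer_tensor(array(res$P, c(ncol(m2_mask), d[2], d[3])),
                       entity_ids = pathway_ids,
                       chemical_ids = prot$chemical_ids,
                       grid = prot$grid, layer = "path")
  m2 <- mapping_matrix(res$W, m2_mask, layer = "M2")
  dimnames(m2$weights) <- list(prot$entity_ids, pathway_ids)
  new_layer_fit(m2, path, res, cfg, "prot")
}

#' Fit the toxicity layer (Path ~ M3 . Tox)
#'
#' With the binarized pathway-endpoint matrix `M3` fixed by supervised
#' statistical filtering, trains only the latent toxicity tensor `Tox`
#' so that `M3 %*% Tox` reconstructs the modeled pathway tensor.
#' Pathways not linked to any endpoint have an all-zero `M3` row and
#' cannot be reconstructed; their entries are excluded from the loss.
#'
#' @param path Pathway `layer_tensor`.
#' @param m3 Binarized `mapping_matrix` (layer `"M3"`) or a 0/1 /
#'   logical matrix `n_pathways x n_endpoints`; every endpoint column
#'   needs at least one retained pathway.
#' @param cfg A [train_config()].
#' @param endpoint_ids Optional endpoint identifiers.
#' @return A `layer_fit` with fixed `mapping` and latent `Tox` tensor.
#' @export
fit_tox_layer <- function(path, m3, cfg = train_config(),
                          endpoint_ids = NULL) {
  stopifnot(inherits(path, "layer_tensor"))
  B <- if (inherits(m3, "mapping_matrix")) {
    if (!is.null(m3$binarized)) m3$binarized else (m3$weights != 0) * 1
  } else {
    matrix(as.numeric(as.logical(m3)), nrow(m3), dimnames = dimnames(m3))
  }
  stopifnot(nrow(B) == dim(path)[1])
  if (is.null(endpoint_ids)) {
    endpoint_ids <- colnames(B)
    if (is.null(endpoint_ids)) endpoint_ids <- paste0("T", seq_len(ncol(B)))
  }
  bad <- which(colSums(B) == 0)
  if (length(bad)) {
    stop("endpoint(s) unmodelable (no retained pathway): ",
         paste(endpoint_ids[bad], collapse = ", "), call. = FALSE)
  }
  # pathways linked to no endpoint are structurally unreconstructable
  # (their M3 row is all zero); exclude them from the loss
  obs <- path$mask
  obs[rowSums(B) == 0, , ] <- FALSE
  res <- fit_masked_factorization(unfold3(path$values), unfold3(obs),
                                  B > 0, fixed_weights = B, cfg = cfg)
  d <- dim(path$values)
  tox <- layer_tensor(array(res$P, c(ncol(B), d[2], d[3])),
                      entity_ids = endpoint_ids,
                      chemical_ids = path$chemical_ids,
                      grid = path$grid, layer = "tox")
  m3_out <- mapping_matrix(B, B > 0, layer = "M3", binarized = B)
  dimnames(m3_out$weights) <- list(path$entity_ids, endpoint_ids)
  new_layer_fit(m3_out, tox, res, cfg, "path")
}

#' @exportS3Method generics::tidy
tidy.layer_fit <- function(x, ...) {
  w <- x$mapping$weights
  idx <- which(x$mapping$structure_mask, arr.ind = TRUE)
  rn <- rownames(w) %||% as.character(seq_len(nrow(w)))
  cn <- colnames(w) %||% as.character(seq_len(ncol(w)))
  tibble::tibble(row_id = rn[idx[, 1]], col_id = cn[idx[, 2]],
                 mapping = x$mapping$layer, weight = w[idx])
}

#' @exportS3Method generics::glance
glance.layer_fit <- function(x, ...) {
  tibble::tibble(mapping = x$mapping$layer,
                 epochs = nrow(x$trace),
                 loss = x$loss, r2 = x$r2,
                 lr_final = x$trace$lr[nrow(x$trace)],
                 converged = nrow(x$trace) < x$cfg$max_epochs)
}

#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.layer_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$epoch,
                                             y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "masked MSE (training scale)",
                  title = sprintf("%s training loss", object$mapping$layer)) +
    ggplot2::theme_minimal()
}
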