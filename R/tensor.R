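#' Three-way activity tensor with an observed-entry mask
#'
#' Container for the Assay / Prot / Path / Tox layers: a numeric array
#' of shape `entities x concentrations x chemicals` plus a logical mask
#' of the same shape marking observed entries. Masked-out entries never
#' enter any training loss.
#'
#' @param values Numeric 3-way array.
#' @param mask Logical array, same shape; defaults to all observed.
#' @param entity_ids,chemical_ids Axis identifiers.
#' @param grid Concentration grid (length = 2nd dimension).
#' @param layer Layer name (`"assay"`, `"prot"`, `"path"`, `"tox"`, ...).
#' @return An object of class `layer_tensor`.
#' @export
layer_tensor <- function(values, mask = NULL, entity_ids = NULL,
                         chemical_ids = NULL, grid = NULL,
                         layer = "layer") {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(values))
  stopifnot(identical(dim(mask), dim(values)))
  d <- dim(values)
  if (is.null(entity_ids)) entity_ids <- paste0("e", seq_len(d[1]))
  if (is.null(chemical_ids)) chemical_ids <- paste0("c", seq_len(d[3]))
  stopifnot(length(entity_ids) == d[1], length(chemical_ids) == d[3])
  if (!is.null(grid)) stopifnot(length(grid) == d[2])
  structure(list(values = values, mask = mask, entity_ids = entity_ids,
                 chemical_ids = chemical_ids, grid = grid, layer = layer),
            class = "layer_tensor")
}

#' @export
print.layer_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<layer_tensor:%s> %d x %d x %d (%.1f%% observed)\n",
              x$layer, d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.layer_tensor <- function(x) dim(x$values)

#' Masked mapping matrix between two layers
#'
#' Weight matrix (rows x cols) with a structural sparsity mask: weights
#' are identically zero outside the mask. The tox-layer mapping (`M3`)
#' additionally carries a binarized form.
#'
#' @param weights Numeric matrix.
#' @param structure_mask Logical matrix of allowed entries.
#' @param layer One of `"M1"`, `"M2"`, `"M3"`.
#' @param binarized Optional 0/1 matrix (M3 only).
#' @return An object of class `mapping_matrix`.
#' @export
mapping_matrix <- function(weights, structure_mask = NULL,
                           layer = c("M1", "M2", "M3"), binarized = NULL) {
  layer <- match.arg(layer)
  weights <- as.matrix(weights)
  if (is.null(structure_mask)) {
    structure_mask <- matrix(TRUE, nrow(weights), ncol(weights))
  }
  structure_mask <- matrix(as.logical(structure_mask), nrow(weights),
                           dimnames = dimnames(weights))
  stopifnot(identical(dim(structure_mask), dim(weights)))
  if (any(weights[!structure_mask] != 0)) {
    stop("weights must be zero outside the structure mask", call. = FALSE)
  }
  if (!is.null(binarized)) {
    stopifnot(all(binarized %in% c(0, 1)),
              all(binarized[!structure_mask] == 0))
  }
  structure(list(weights = weights, structure_mask = structure_mask,
                 layer = layer, binarized = binarized),
            class = "mapping_matrix")
}

#' @export
print.mapping_matrix <- function(x, ...) {
  cat(sprintf("<mapping_matrix:%s> %d x %d, %d allowed entries\n",
              x$layer, nrow(x$weights), ncol(x$weights),
              sum(x$structure_mask)))
  invisible(x)
}

#' Collapse a layer tensor over the concentration axis
#'
#' Scalar per-(entity, chemical) score: the arithmetic mean (or max) of
#' the modeled responses over the concentration grid, honoring the
#' observed mask. Fully masked fibers yield `NA`.
#'
#' @param layer A `layer_tensor`.
#' @param stat `"mean"` (default) or `"max"`.
#' @return A numeric matrix `entities x chemicals` with dimnames.
#' @export
summarize_over_concentration <- function(layer, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  stopifnot(inherits(layer, "layer_tensor"), dim(layer$values)[2] >= 1)
  v <- layer$values
  v[!layer$mask] <- NA_real_
  f <- if (stat == "mean") {
    function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  } else {
    function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  }
  out <- apply(v, c(1, 3), f)
  dimnames(out) <- list(layer$entity_ids, layer$chemical_ids)
  out
}

#' Min-max rescaling to [0, 1]
#'
#' `(x - min) / (max - min)` over the finite values; a constant vector
#' maps to 0.5 everywhere (midpoint convention for a degenerate range).
#' `NA`s are preserved.
#'
#' @param x Numeric vector with at least one finite value.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0 || !any(is.finite(x))) {
    stop("minmax_normalize needs at least one finite value", call. = FALSE)
  }
  rng <- range(x, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    out <- rep(0.5, length(x))
    out[is.na(x)] <- NA_real_
    return(out)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Tidy a layer tensor into long form
#'
#' @param x A `layer_tensor`.
#' @param ... Unused.
#' @return A tibble with `entity_id`, `conc_index`, `conc`,
#'   `chemical_id`, `response` for observed entries.
#' @exportS3Method generics::tidy
tidy.layer_tensor <- function(x, ...) {
  d <- dim(x$values)
  idx <- which(x$mask, arr.ind = TRUE)
  tibble::tibble(
    entity_id = x$entity_ids[idx[, 1]],
    conc_index = idx[, 2],
    conc = if (is.null(x$grid)) NA_real_ else as.numeric(x$grid)[idx[, 2]],
    chemical_id = x$chemical_ids[idx[, 3]],
    response = x$values[idx]
  ) |> dplyr::arrange(.data$entity_id, .data$chemical_id, .data$conc_index)
}
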