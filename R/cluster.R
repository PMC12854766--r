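#' MACCS structural fingerprints from SMILES
#'
#' Computes 166-bit MACCS-type key fingerprints via OpenBabel
#' (ChemmineOB). Invalid SMILES are dropped with a warning rather than
#' an error.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Chemical identifiers (default `names(smiles)` or
#'   positions).
#' @return A logical matrix `compounds x 166` with row names `ids`,
#'   class `fingerprint_set`.
#' @export
maccs_fingerprints <- function(smiles, ids = names(smiles)) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("ChemmineOB is required for fingerprinting", call. = FALSE)
  }
  if (is.null(ids)) ids <- as.character(seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  ok <- vapply(smiles, function(s) {
    tryCatch({
      fp <- ChemmineOB::fingerprint_OB(
        ChemmineOB::forEachMol("SMILES", s, identity), "MACCS")
      if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
      fp[1, seq_len(166)]
    }, error = function(e) rep(NA_real_, 166))
  }, numeric(166))
  m <- t(ok) != 0
  bad <- apply(is.na(t(ok)), 1, any)
  if (any(bad)) {
    warning(sum(bad), " SMILES could not be parsed and were dropped",
            call. = FALSE)
    m <- m[!bad, , drop = FALSE]
    ids <- ids[!bad]
  }
  rownames(m) <- ids
  class(m) <- c("fingerprint_set", class(m))
  m
}

#' Tanimoto similarity of two bit vectors
#'
#' `|a AND b| / |a OR b|`; undefined (error) when both vectors are
#' all-zero.
#'
#' @param a,b Logical/0-1 vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) stop("Tanimoto undefined for two all-zero vectors",
                   call. = FALSE)
  sum(a & b) / u
}

# dense pairwise Tanimoto matrix via bit-count algebra
tanimoto_matrix <- function(fps) {
  m <- matrix(as.numeric(fps), nrow(fps))
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  uni <- outer(ones, ones, `+`) - inter
  s <- ifelse(uni > 0, inter / uni, NA_real_)
  dimnames(s) <- list(rownames(fps), rownames(fps))
  s
}

#' Taylor-Butina sphere-exclusion clustering
#'
#' Deterministic sphere-exclusion clustering at a fixed Tanimoto
#' threshold: compounds are ranked by neighbor count (ties by id
#' order); the top unassigned compound becomes a centroid and claims
#' its unassigned neighbors; repeat until all compounds are assigned.
#' Clusters below `min_size` are not retained (their members get an
#' `NA` cluster id so downstream joins stay total).
#'
#' @param fps A `fingerprint_set` (or logical matrix with row-name
#'   ids).
#' @param threshold Tanimoto similarity threshold.
#' @param min_size Minimum retained cluster size.
#' @return Tibble: `chemical_id`, `cluster_id` (`NA` when not in a
#'   retained cluster), `is_centroid`, `cluster_size`.
#' @export
taylor_butina <- function(fps, threshold = 0.7, min_size = 5) {
  n <- nrow(fps)
  ids <- rownames(fps) %||% as.character(seq_len(n))
  sim <- tanimoto_matrix(fps)
  nb <- sim >= threshold
  nb[is.na(nb)] <- FALSE
  diag(nb) <- FALSE
  assigned <- rep(FALSE, n)
  cluster <- rep(NA_integer_, n)
  centroid <- rep(FALSE, n)
  cl <- 0L
  repeat {
    counts <- vapply(seq_len(n), function(i) {
      if (assigned[i]) -1L else sum(nb[i, ] & !assigned)
    }, integer(1))
    if (all(counts < 0)) break
    ctr <- order(-counts, ids)[1]
    cl <- cl + 1L
    members <- c(ctr, which(nb[ctr, ] & !assigned))
    members <- unique(members)
    cluster[members] <- cl
    centroid[ctr] <- TRUE
    assigned[members] <- TRUE
  }
  out <- tibble::tibble(chemical_id = ids, cluster_id = cluster,
                        is_centroid = centroid)
  out |>
    dplyr::add_count(.data$cluster_id, name = "cluster_size") |>
    dplyr::mutate(cluster_id = dplyr::if_else(.data$cluster_size >=
                                                min_size,
                                              .data$cluster_id,
                                              NA_integer_))
}

# --- minimal SMILES molecular graph ------------------------------------

# Parses a (simple, organic-subset) SMILES into atoms/bonds via
# ChemmineR/ChemmineOB SDF conversion.
smiles_graph <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("ChemmineR is required", call. = FALSE)
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles)[[1]])
  ab <- ChemmineR::atomblock(sdf)
  bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
  elem <- gsub("_.*$", "", rownames(ab))
  if (!is.null(bb) && is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
  bonds <- if (!is.null(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  list(elem = elem, bonds = bonds)
}

#' Maximum common substructure of a compound cluster as SMARTS
#'
#' Finds a (connected) maximum common substructure across all cluster
#' members by iterated pairwise MCS on element/bond-order-labelled
#' molecular graphs (greedy multi-seed clique search on the modular
#' product graph), and encodes it as a SMARTS pattern of atomic-number
#' primitives joined by any-bond primitives (so the pattern matches
#' regardless of kekulization). The search is time-capped; the best
#' pattern found so far is returned.
#'
#' @param smiles SMILES of the cluster members (>= 2).
#' @param timeout Soft time cap in seconds for the clique search.
#' @return List with `smarts` (possibly `""`), `n_atoms`, and
#'   `too_small` flag (TRUE when no common substructure above one atom
#'   exists).
#' @export
cluster_mcs_smarts <- function(smiles, timeout = 10) {
  stopifnot(length(smiles) >= 2)
  graphs <- lapply(smiles, smiles_graph)
  t0 <- Sys.time()
  cur <- graphs[[1]]
  for (g in graphs[-1]) {
    cur <- pair_mcs(cur, g,
                    budget = timeout - as.numeric(Sys.time() - t0,
                                                  units = "secs"))
    if (length(cur$elem) <= 1) break
  }
  if (length(cur$elem) <= 1) {
    return(list(smarts = "", n_atoms = length(cur$elem), too_small = TRUE))
  }
  list(smarts = graph_to_smarts(cur), n_atoms = length(cur$elem),
       too_small = FALSE)
}

# pairwise connected MCS by maximum clique on the modular product graph
pair_mcs <- function(g1, g2, budget = 10) {
  n1 <- length(g1$elem); n2 <- length(g2$elem)
  if (n1 == 0 || n2 == 0) return(list(elem = character(),
                                      bonds = data.frame()))
  # candidate vertex pairs with matching elements
  pairs <- which(outer(g1$elem, g2$elem, `==`), arr.ind = TRUE)
  if (nrow(pairs) == 0) return(list(elem = character(),
                                    bonds = data.frame()))
  b1 <- matrix(0L, n1, n1); b2 <- matrix(0L, n2, n2)
  if (nrow(g1$bonds)) {
    b1[cbind(g1$bonds$a1, g1$bonds$a2)] <- g1$bonds$order
    b1[cbind(g1$bonds$a2, g1$bonds$a1)] <- g1$bonds$order
  }
  if (nrow(g2$bonds)) {
    b2[cbind(g2$bonds$a1, g2$bonds$a2)] <- g2$bonds$order
    b2[cbind(g2$bonds$a2, g2$bonds$a1)] <- g2$bonds$order
  }
  np <- nrow(pairs)
  if (np > 400) {  # keep the product graph tractable
    pairs <- pairs[seq_len(400), , drop = FALSE]
    np <- 400
  }
  # modular-product compatibility: same element pairing handled above;
  # two pairs are compatible when distinct in both molecules and the
  # bond orders agree (0 = absent in both)
  same1 <- outer(pairs[, 1], pairs[, 1], `==`)
  same2 <- outer(pairs[, 2], pairs[, 2], `==`)
  ord1 <- matrix(b1[cbind(rep(pairs[, 1], np),
                          rep(pairs[, 1], each = np))], np, np)
  ord2 <- matrix(b2[cbind(rep(pairs[, 2], np),
                          rep(pairs[, 2], each = np))], np, np)
  adj <- !same1 & !same2 & (ord1 == ord2)
  diag(adj) <- FALSE

  # deterministic greedy multi-seed clique search, time-capped; exact
  # search is exponential, so the best clique found so far is kept
  deadline <- Sys.time() + max(budget, 0.5)
  deg <- rowSums(adj)
  # prefer seeds whose pairs touch bonded atoms (connected growth)
  seeds <- order(-deg)
  best <- integer()
  for (v0 in seeds) {
    if (Sys.time() > deadline) break
    clique <- v0
    cand <- which(adj[v0, ])
    while (length(cand)) {
      # favor candidates bonded (in molecule 1) to the current clique
      bonded <- vapply(cand, function(u) {
        any(b1[pairs[u, 1], pairs[clique, 1]] > 0)
      }, logical(1))
      pool <- if (any(bonded)) cand[bonded] else cand
      nxt <- pool[order(-deg[pool], pool)][1]
      clique <- c(clique, nxt)
      cand <- cand[adj[nxt, cand]]
      cand <- setdiff(cand, clique)
    }
    if (length(clique) > length(best)) best <- clique
  }
  if (!length(best)) return(list(elem = character(), bonds = data.frame()))
  a1 <- pairs[best, 1]
  # keep the largest connected component of the common subgraph in g1
  sub_b <- g1$bonds[g1$bonds$a1 %in% a1 & g1$bonds$a2 %in% a1, ,
                    drop = FALSE]
  comp <- connected_component(a1, sub_b)
  sub_b <- sub_b[sub_b$a1 %in% comp & sub_b$a2 %in% comp, , drop = FALSE]
  remap <- stats::setNames(seq_along(comp), comp)
  list(elem = g1$elem[comp],
       bonds = data.frame(a1 = unname(remap[as.character(sub_b$a1)]),
                          a2 = unname(remap[as.character(sub_b$a2)]),
                          order = sub_b$order))
}

connected_component <- function(verts, bonds) {
  if (length(verts) <= 1 || nrow(bonds) == 0) return(verts[1])
  adj <- split(c(bonds$a2, bonds$a1), c(bonds$a1, bonds$a2))
  comps <- list(); seen <- character()
  for (v in verts) {
    if (as.character(v) %in% seen) next
    q <- v; comp <- integer()
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      if (as.character(u) %in% seen) next
      seen <- c(seen, as.character(u))
      comp <- c(comp, u)
      q <- c(q, setdiff(adj[[as.character(u)]], comp))
    }
    comps[[length(comps) + 1]] <- comp
  }
  comps[[which.max(lengths(comps))]]
}

ELEMENT_Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
               Cl = 17, Br = 35, I = 53)

# SMARTS string via depth-first traversal of the common subgraph
graph_to_smarts <- function(g) {
  n <- length(g$elem)
  adj <- vector("list", n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[k]; b <- g$bonds$a2[k]; o <- g$bonds$order[k]
      adj[[a]] <- rbind(adj[[a]], c(b, o))
      adj[[b]] <- rbind(adj[[b]], c(a, o))
    }
  }
  # bond orders constrain the correspondence search, but the emitted
  # pattern uses the any-bond primitive so kekulized rings still match
  # aromatic perception in downstream SMARTS engines
  bond_sym <- function(o) "~"
  atom_sym <- function(e) {
    z <- ELEMENT_Z[[e]]
    if (is.null(z) || is.na(z)) "[*]" else sprintf("[#%d]", z)
  }
  visited <- rep(FALSE, n)
  used_edge <- matrix(FALSE, n, n)
  dfs <- function(v) {
    visited[v] <<- TRUE
    out <- atom_sym(g$elem[v])
    branches <- character()
    if (!is.null(adj[[v]])) {
      for (k in seq_len(nrow(adj[[v]]))) {
        w <- adj[[v]][k, 1]; o <- adj[[v]][k, 2]
        if (visited[w] || used_edge[v, w]) next
        used_edge[v, w] <<- TRUE; used_edge[w, v] <<- TRUE
        branches <- c(branches, paste0(bond_sym(o), dfs(w)))
      }
    }
    if (length(branches) > 1) {
      out <- paste0(out,
                    paste0("(", branches[-length(branches)], ")",
                           collapse = ""),
                    branches[length(branches)])
    } else if (length(branches) == 1) {
      out <- paste0(out, branches)
    }
    out
  }
  # start from a terminal atom for a tidy linear pattern
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a),
                integer(1))
  start <- which(deg == min(deg))[1]
  dfs(start)
}

#' Check a SMARTS pattern against a SMILES structure
#'
#' Substructure match via OpenBabel SMARTS search; used to validate
#' extracted common-substructure patterns.
#'
#' @param smarts SMARTS pattern.
#' @param smiles SMILES string.
#' @return TRUE when the pattern matches the structure.
#' @export
smarts_matches <- function(smarts, smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("ChemmineOB is required", call. = FALSE)
  }
  if (!nzchar(smarts)) return(FALSE)
  res <- ChemmineOB::smartsSearch_OB(
    ChemmineOB::forEachMol("SMILES", smiles, identity), smarts)
  as.numeric(res)[1] > 0
}
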