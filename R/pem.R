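#' Build the influence matrix of a rooted tree
#'
#' The influence matrix B is the binary tips-by-edges matrix with
#' `B[i, j] = 1` iff edge j lies on the path from the root to tip i. It is
#' the combinatorial skeleton of a phylogenetic eigenvector map: with
#' branch-length weighting (see [compute_edge_weights()]) its weighted
#' cross-product recovers the Brownian-motion phylogenetic covariance.
#'
#' Edges are ordered by preorder (cladewise) traversal and named
#' `"<parent>-><child>"` using node numbers; the edge table is attached as
#' attribute `"edge"` together with the matching branch lengths
#' (`"edge_length"`).
#'
#' @param tree A `phylo` object with >= 2 tips.
#' @return Binary matrix (tips x edges) with tip labels as row names.
#' @export
build_influence <- function(tree) {
  validate_tree(tree)
  tree <- stats::reorder(tree, "cladewise")
  n <- ape::Ntip(tree)
  m <- nrow(tree$edge)
  parent_of <- integer(n + tree$Nnode)
  edge_of <- integer(n + tree$Nnode)      # edge row whose child is this node
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_of[tree$edge[, 2L]] <- seq_len(m)
  root <- n + 1L
  B <- matrix(0L, n, m,
              dimnames = list(tree$tip.label,
                              paste0(tree$edge[, 1L], "->", tree$edge[, 2L])))
  for (i in seq_len(n)) {
    node <- i
    while (node != root) {
      B[i, edge_of[node]] <- 1L
      node <- parent_of[node]
    }
  }
  attr(B, "edge") <- tree$edge
  attr(B, "edge_length") <- tree$edge.length
  B
}

#' Power-weighted edge weights for a PEM
#'
#' Each edge of length b (Ma) receives weight `w = psi * b^((1 - a)/2)`.
#' The steepness `a` in `[0, 1]` controls how trait divergence scales with
#' branch length: `a = 0` gives square-root weighting, whose weighted
#' influence cross-product equals the Brownian-motion covariance matrix;
#' `a = 1` removes branch-length dependence altogether (`w = psi` on every
#' edge). `psi > 0` is an overall evolution-rate scale, fixed to 1 by
#' default since regression coefficients absorb it.
#'
#' @param tree A `phylo` object.
#' @param a Steepness, in `[0, 1]`.
#' @param psi Rate scale, > 0.
#' @return An `edge_weights` list: `a`, `psi`, and per-edge `w` (preorder).
#' @export
compute_edge_weights <- function(tree, a = 0, psi = 1) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1)
    stop("steepness `a` must be a single value in [0, 1]")
  if (!is.numeric(psi) || length(psi) != 1L || is.na(psi) || psi <= 0)
    stop("rate scale `psi` must be > 0")
  tree <- stats::reorder(tree, "cladewise")
  b <- tree$edge.length
  # 0^0 == 1 in R, so a = 1 gives w = psi on zero-length edges as required
  w <- psi * b^((1 - a) / 2)
  structure(list(a = a, psi = psi, w = w), class = "edge_weights")
}

#' Build a phylogenetic eigenvector map basis
#'
#' Scales the influence-matrix columns by the edge weights, centers each
#' column on its mean over the (training) tips, and takes the thin singular
#' value decomposition. The left singular vectors U are the phylogenetic
#' eigenvectors used as regression covariates; the stored column means and
#' right singular vectors V allow out-of-sample tips to be projected into
#' the same basis ([target_scores()]).
#'
#' Singular values below `1e-10 * max(d)` are dropped (explicit numerical
#' rank decision). Each eigenvector's sign is fixed so its first nonzero
#' entry (in tip order) is positive, making bases reproducible across
#' platforms.
#'
#' @param B Influence matrix from [build_influence()]. May contain rows for
#'   tips that are not part of the training set (e.g. grafted fossils).
#' @param W Edge weights from [compute_edge_weights()] on the same tree.
#' @param tips Row names of `B` to build the basis on (default: all rows).
#'   Edges lying only on excluded tips' paths simply contribute all-zero
#'   (constant) columns, which centering removes.
#' @return A `pem_basis` object with elements `U` (n x r, orthonormal,
#'   column sums 0), `d` (descending positive singular values), `V` (m x r),
#'   `col_means` (length m), `weights`, `tips`, `edge_names`.
#' @export
build_pem <- function(B, W, tips = rownames(B)) {
  stopifnot(inherits(W, "edge_weights"))
  if (ncol(B) != length(W$w))
    stop("influence matrix and edge weights disagree on edge count")
  missing_tips <- setdiff(tips, rownames(B))
  if (length(missing_tips))
    stop("tips not in influence matrix: ", paste(missing_tips, collapse = ", "))
  if (length(tips) < 2L) stop("PEM basis needs at least 2 tips")
  Bw <- B[tips, , drop = FALSE] * rep(W$w, each = length(tips))
  cm <- colMeans(Bw)
  Bc <- sweep(Bw, 2L, cm)
  sv <- svd(Bc)
  keep <- sv$d > 1e-10 * max(sv$d, 0)
  if (!any(keep))
    stop("PEM basis has rank 0 after centering (all tips identical)")
  U <- sv$u[, keep, drop = FALSE]
  d <- sv$d[keep]
  V <- sv$v[, keep, drop = FALSE]
  # sign convention: first nonzero entry of each eigenvector positive
  for (k in seq_along(d)) {
    nz <- which(abs(U[, k]) > 1e-12)[1L]
    if (!is.na(nz) && U[nz, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  rownames(U) <- tips
  colnames(U) <- paste0("V", seq_along(d))
  structure(list(U = U, d = d, V = V, col_means = cm, weights = W,
                 tips = tips, edge_names = colnames(B)),
            class = "pem_basis")
}

#' @export
print.pem_basis <- function(x, ...) {
  cat("PEM basis:", length(x$tips), "tips,", length(x$d), "eigenvectors,",
      "a =", x$weights$a, ", psi =", x$weights$psi, "\n")
  invisible(x)
}

#' Project out-of-sample tips into a PEM basis
#'
#' Computes the eigenvector scores of target tips (e.g. grafted fossils)
#' that were not part of the training basis: the target's raw influence row
#' over the same edge set is weighted with the stored edge weights, centered
#' on the stored training column means, and projected,
#' `s = (row_w - col_means) V diag(1/d)`. A target whose weighted row equals
#' a training tip's reproduces that tip's row of U exactly.
#'
#' @param basis A `pem_basis`.
#' @param target_rows Raw (binary) influence row(s) for the target tip(s),
#'   over the same edges as the basis: a vector or a (targets x edges)
#'   matrix, e.g. rows of [build_influence()] on the full analysis tree.
#' @return Matrix of scores (targets x retained eigenvectors).
#' @export
target_scores <- function(basis, target_rows) {
  stopifnot(inherits(basis, "pem_basis"))
  if (is.null(dim(target_rows)))
    target_rows <- matrix(target_rows, nrow = 1L)
  if (ncol(target_rows) != length(basis$col_means))
    stop("target rows have ", ncol(target_rows), " edges; basis has ",
         length(basis$col_means))
  rw <- target_rows * rep(basis$weights$w, each = nrow(target_rows))
  sc <- sweep(rw, 2L, basis$col_means) %*% basis$V %*% diag(1 / basis$d,
                                                            length(basis$d))
  dimnames(sc) <- list(rownames(target_rows), colnames(basis$U))
  sc
}

#' Export a PEM basis as plain-text matrices (debugging aid)
#'
#' Writes `U.csv` (tips x eigenvectors), `V.csv` (edges x eigenvectors),
#' `d.csv` (singular values) and `col_means.csv` into `dir`. Column order
#' follows decreasing singular value, matching the in-memory basis.
#'
#' @param basis A `pem_basis`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
export_pem_basis <- function(basis, dir) {
  stopifnot(inherits(basis, "pem_basis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(basis$U, file.path(dir, "U.csv"))
  V <- basis$V
  rownames(V) <- basis$edge_names
  utils::write.csv(V, file.path(dir, "V.csv"))
  utils::write.csv(data.frame(d = basis$d), file.path(dir, "d.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(edge = basis$edge_names,
                              col_mean = basis$col_means),
                   file.path(dir, "col_means.csv"), row.names = FALSE)
  invisible(dir)
}
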