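#' Brownian-motion ancestral state reconstruction
#'
#' Maximum-likelihood internal-node states under Brownian motion, equivalent
#' to generalized least squares with the node-to-tip BM covariance
#' structure. Tip values (observed responses for extant species, PEM
#' predictions for fossils, both on the log10 scale in the standard
#' workflow) are treated as known. Internal estimates are convex
#' combinations of the tip values, so they always lie within the tip range.
#'
#' Zero-length internal edges are collapsed into polytomies for this
#' computation (the estimate is otherwise undefined at a node coincident
#' with its parent); collapsed nodes inherit their parent's estimate in the
#' output so every node of the original tree is covered. Constant tip values
#' are a valid degenerate case: every node gets that value with variance 0.
#'
#' @param tree A `phylo` object.
#' @param tip_values Named numeric vector, one value per tip.
#' @return An `ancestral_states` list: `node` (data.frame of node id, label,
#'   type, value, variance covering all tips and internal nodes of `tree`)
#'   and `sigma2` (the ML BM rate used for the variances).
#' @export
bm_ancestral_states <- function(tree, tip_values) {
  validate_tree(tree)
  n <- ape::Ntip(tree)
  if (is.null(names(tip_values)))
    stop("tip_values must be named by tip label")
  missing_tips <- setdiff(tree$tip.label, names(tip_values))
  if (length(missing_tips))
    stop("missing values for tip(s): ", paste(missing_tips, collapse = ", "))
  x <- tip_values[tree$tip.label]
  if (anyNA(x) || any(!is.finite(x))) stop("tip values must be finite")

  node_ids <- seq_len(n + tree$Nnode)
  out <- data.frame(
    node = node_ids,
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
    type = rep(c("tip", "internal"), c(n, tree$Nnode)),
    value = NA_real_, variance = NA_real_
  )
  out$value[seq_len(n)] <- x
  out$variance[seq_len(n)] <- 0

  if (max(x) - min(x) < .Machine$double.eps * max(1, abs(x[1]))) {
    out$value[] <- x[1]
    out$variance[] <- 0
    return(structure(list(node = out, sigma2 = 0), class = "ancestral_states"))
  }

  # collapse zero-length internal edges, then re-binarize (the re-rooting
  # estimator requires a bifurcating tree); original nodes are matched to
  # working-tree nodes via their descendant tip sets
  work <- ape::multi2di(ape::di2multi(tree, tol = 1e-12))
  anc <- phytools::fastAnc(work, x, vars = TRUE)
  est <- as.numeric(anc$ace)
  vars <- as.numeric(anc$var)
  work_key <- internal_keys(work)
  names(est) <- names(vars) <- work_key

  orig_key <- internal_keys(tree)
  idx <- match(orig_key, work_key)
  # nodes collapsed away: walk up to the nearest surviving ancestor
  for (j in which(is.na(idx))) {
    node <- n + j
    repeat {
      node <- tree$edge[tree$edge[, 2L] == node, 1L]
      k <- match(key_of_node(tree, node), work_key)
      if (!is.na(k)) { idx[j] <- k; break }
    }
  }
  out$value[(n + 1):(n + tree$Nnode)] <- est[idx]
  out$variance[(n + 1):(n + tree$Nnode)] <- vars[idx]

  # ML rate: quadratic form of GLS residuals in the BM tip covariance
  sigma2 <- tryCatch({
    C <- ape::vcv(work)
    xw <- x[colnames(C)]
    Ci <- solve(C)
    a_root <- sum(Ci %*% xw) / sum(Ci)
    drop(t(xw - a_root) %*% Ci %*% (xw - a_root)) / length(xw)
  }, error = function(e) NA_real_)
  structure(list(node = out, sigma2 = sigma2), class = "ancestral_states")
}

# one canonical key per internal node: sorted descendant tip labels
internal_keys <- function(tree) {
  n <- ape::Ntip(tree)
  vapply((n + 1):(n + tree$Nnode), key_of_node, "", tree = tree)
}

key_of_node <- function(tree, node) {
  tips <- ape::extract.clade(tree, node)$tip.label
  paste(sort(tips), collapse = "|")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat("BM ancestral states:", sum(x$node$type == "tip"), "tips,",
      sum(x$node$type == "internal"), "internal nodes\n")
  invisible(x)
}

#' Export node values and edge gradients for tree colour maps
#'
#' Produces the two tables a plotting layer needs for a colour-coded tree:
#' per-node values (with node heights, i.e. time from the root) and per-edge
#' linear interpolation samples between the parent and child values, for
#' continuous colour mapping along branches. Values are exported on the
#' reconstruction (log10) scale and back-transformed (`10^value`).
#'
#' @param tree The `phylo` object the states were computed on.
#' @param states An `ancestral_states` object from [bm_ancestral_states()].
#' @param n_samples Interpolation points per edge (including both endpoints).
#' @return A list of data.frames: `nodes` (node, label, type, height, value,
#'   value_natural) and `edges` (parent, child, s in \[0, 1\], height, value,
#'   value_natural).
#' @export
export_tree_map <- function(tree, states, n_samples = 10) {
  stopifnot(inherits(states, "ancestral_states"), n_samples >= 2)
  heights <- ape::node.depth.edgelength(tree)
  nd <- states$node
  if (nrow(nd) != length(heights)) stop("states do not cover all nodes")
  nodes <- data.frame(node = nd$node, label = nd$label, type = nd$type,
                      height = heights[nd$node], value = nd$value,
                      value_natural = 10^nd$value)
  s <- seq(0, 1, length.out = n_samples)
  edges <- do.call(rbind, lapply(seq_len(nrow(tree$edge)), function(e) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    vp <- nd$value[p]; vc <- nd$value[ch]
    data.frame(parent = p, child = ch, s = s,
               height = heights[p] + s * (heights[ch] - heights[p]),
               value = vp + s * (vc - vp),
               value_natural = 10^(vp + s * (vc - vp)))
  }))
  list(nodes = nodes, edges = edges)
}
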