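#' Read a rooted, time-calibrated tree from Newick text
#'
#' Parses a Newick string (or a file containing one) into an [ape::phylo]
#' object and validates it for use in downstream PEM analyses: the tree must
#' be rooted, every non-root edge must carry a finite, non-negative branch
#' length (interpreted as Ma), and tip labels must be unique and non-empty.
#' Trees need not be ultrametric -- fossil tips end before the present.
#'
#' @param text A Newick string (must end in ";").
#' @param file Alternatively, path to a file whose first line holds the tree.
#' @return A validated `phylo` object.
#' @seealso [write_newick()], [graft_tips()], [round_branch_lengths()]
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) {
    if (!file.exists(file)) stop("tree file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick: could not parse a tree from input")
  validate_tree(tree)
  tree
}

#' Validate a phylogeny for PEM analysis
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly, if valid; otherwise an error naming the problem.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (ape::Ntip(tree) < 2) stop("tree must have at least 2 tips")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (any(!nzchar(tree$tip.label))) stop("empty tip label")
  if (is.null(tree$edge.length))
    stop("missing branch lengths: tree has no edge lengths at all")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    bad <- which(!is.finite(tree$edge.length))[1L]
    stop("missing or non-finite branch length on edge to node ",
         node_token(tree, tree$edge[bad, 2L]))
  }
  if (any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1L]
    stop("negative branch length on edge to node ",
         node_token(tree, tree$edge[bad, 2L]))
  }
  # exactly one root: every node except one has one parent
  kids <- tree$edge[, 2L]
  if (anyDuplicated(kids)) stop("node with more than one parent")
  nnode <- ape::Ntip(tree) + tree$Nnode
  roots <- setdiff(seq_len(nnode), kids)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  invisible(tree)
}

# human-readable token for error messages: tip label or node number
node_token <- function(tree, node) {
  if (node <= ape::Ntip(tree)) sQuote(tree$tip.label[node]) else paste0("#", node)
}

#' Write a tree as canonical Newick
#'
#' Labels are emitted unquoted when alphanumeric (ape's convention) and branch
#' lengths with up to 6 significant digits, so that write-then-read
#' round-trips exactly on such trees.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 6) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Round branch lengths to the nearest integer (half-up)
#'
#' Time-calibrated analysis trees are discretised to whole Ma before PEM
#' construction. Rounding is half-up on the Ma value (2.5 -> 3). Branches
#' that round to zero are retained, with a warning: the PEM weight function
#' maps them to weight 0 whenever steepness < 1.
#'
#' @param tree A `phylo` object.
#' @return The tree with integer branch lengths; topology unchanged.
#' @export
round_branch_lengths <- function(tree) {
  validate_tree(tree)
  rounded <- floor(tree$edge.length + 0.5)
  zeroed <- which(rounded == 0 & tree$edge.length > 0)
  if (length(zeroed))
    warning(length(zeroed), " branch length(s) rounded to zero (edges to: ",
            paste(vapply(tree$edge[zeroed, 2L], node_token, "", tree = tree),
                  collapse = ", "), ")")
  tree$edge.length <- rounded
  tree
}

#' Specify a fossil graft
#'
#' Describes the attachment of one new pendant tip (typically a fossil) onto
#' an existing edge. The edge is identified by its child node: either a tip
#' label, or a character vector of two or more tip labels whose most recent
#' common ancestor is the child node. `at` is the attachment distance (Ma)
#' measured from the child node towards the root along that edge.
#'
#' @param label New tip name (must not collide with existing labels).
#' @param child Tip label, or character vector of tip labels (MRCA), naming
#'   the child node of the attachment edge.
#' @param at Distance from the child node along the edge, in `[0, edge length]`.
#' @param pendant Pendant branch length of the new tip (Ma, >= 0). A fossil's
#'   pendant length is chosen so its tip ends at the fossil's age.
#' @return A `graft_spec` list.
#' @export
graft_spec <- function(label, child, at, pendant) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.character(child), length(child) >= 1L,
            is.numeric(at), length(at) == 1L, is.finite(at),
            is.numeric(pendant), length(pendant) == 1L, is.finite(pendant))
  if (at < 0) stop("attachment distance must be >= 0")
  if (pendant < 0) stop("pendant branch length must be >= 0")
  structure(list(label = label, child = child, at = at, pendant = pendant),
            class = "graft_spec")
}

resolve_child_node <- function(tree, child) {
  missing_tips <- setdiff(child, tree$tip.label)
  if (length(missing_tips))
    stop("unknown tip label(s) in graft attachment: ",
         paste(missing_tips, collapse = ", "))
  if (length(child) == 1L) match(child, tree$tip.label)
  else ape::getMRCA(tree, child)
}

#' Graft pendant tips onto a tree
#'
#' Each graft splits one edge in two and adds one pendant tip, leaving every
#' pre-existing root-to-tip path length unchanged. Grafts are applied in list
#' order, so later grafts may attach to edges created by earlier ones (name
#' the child by the tip labels that subtend it).
#'
#' @param tree A `phylo` object.
#' @param grafts A single [graft_spec()] or a list of them.
#' @return The grafted tree.
#' @export
graft_tips <- function(tree, grafts) {
  validate_tree(tree)
  if (inherits(grafts, "graft_spec")) grafts <- list(grafts)
  for (g in grafts) {
    if (!inherits(g, "graft_spec")) stop("grafts must be graft_spec objects")
    if (g$label %in% tree$tip.label)
      stop("duplicate new tip label: ", g$label)
    node <- resolve_child_node(tree, g$child)
    edge_row <- which(tree$edge[, 2L] == node)
    if (!length(edge_row))
      stop("attachment child node has no parent edge (is it the root?)")
    len <- tree$edge.length[edge_row]
    if (g$at > len + 1e-12)
      stop("attachment distance ", g$at, " exceeds edge length ", len,
           " (edge to ", node_token(tree, node), ")")
    tree <- phytools::bind.tip(tree, tip.label = g$label,
                               edge.length = g$pendant,
                               where = node, position = min(g$at, len))
    validate_tree(tree)
  }
  tree
}

#' Remove tips from a tree
#'
#' Inverse of grafting: dropping a grafted tip restores the original tree
#' (the degree-two node left by the graft is collapsed and its two half-edges
#' merged).
#'
#' @param tree A `phylo` object.
#' @param labels Tip labels to remove.
#' @return The pruned tree.
#' @export
prune_tips <- function(tree, labels) {
  validate_tree(tree)
  missing_tips <- setdiff(labels, tree$tip.label)
  if (length(missing_tips))
    stop("cannot prune unknown tip(s): ", paste(missing_tips, collapse = ", "))
  ape::drop.tip(tree, labels, collapse.singles = TRUE)
}

#' Root-to-tip path lengths
#'
#' @param tree A `phylo` object.
#' @return Named numeric vector of root-to-tip distances (Ma), in tip order.
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  d
}
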