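# Independent oracles used to cross-check the package's fast paths.
# These deliberately avoid the implementation's own machinery: paths are
# enumerated with ape's nodepath, covariances built by explicit matrix
# algebra, and AICc evaluated through stats::AIC on an lm fit.

# Brute-force Brownian-motion covariance: entry (i, j) is the summed length
# of the edges shared by the root-to-tip paths of tips i and j.
oracle_shared_path_cov <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  paths <- lapply(seq_len(n), function(i) {
    nodes <- ape::nodepath(tree, root, i)
    # edges as "parent:child" strings with their lengths
    keys <- paste(nodes[-length(nodes)], nodes[-1L], sep = ":")
    lens <- vapply(seq_along(keys), function(k) {
      e <- which(tree$edge[, 1L] == nodes[k] & tree$edge[, 2L] == nodes[k + 1L])
      tree$edge.length[e]
    }, numeric(1))
    stats::setNames(lens, keys)
  })
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(names(paths[[i]]), names(paths[[j]]))
    C[i, j] <- sum(paths[[i]][shared])
  }
  C
}

# Full-likelihood Gaussian AICc via stats::AIC, for comparison with the
# profile form (they differ by the additive constant n * (log(2*pi) + 1)).
oracle_aicc_lm <- function(X, y) {
  fit <- stats::lm(y ~ X - 1)
  k <- ncol(X) + 1          # coefficients + residual variance
  n <- length(y)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

# Explicit-covariance GLS ancestral states under BM: for internal node h,
# a_h = mu + c_h' C^{-1} (x - mu), with mu the GLS root mean, C the tip
# covariance and c_h the node-to-tip shared path lengths (height of the
# MRCA of h and each tip).
oracle_gls_ancestral <- function(tree, x) {
  n <- ape::Ntip(tree)
  x <- x[tree$tip.label]
  C <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- drop(one %*% Ci %*% x) / drop(one %*% Ci %*% one)
  heights <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)
  internal <- (n + 1L):(n + tree$Nnode)
  vapply(internal, function(h) {
    ch <- heights[mr[h, seq_len(n)]]
    mu + drop(ch %*% Ci %*% (x - mu))
  }, numeric(1))
}

# Delete-one-species refit oracle: rebuilds everything from serialized
# Newick/CSV files and predicts the held-out species as a target.
oracle_loocv <- function(tree, traits, a = 0, selection = "forward") {
  training <- traits$species[traits$role == "training"]
  dir <- withr::local_tempdir()
  write_newick(tree, file.path(dir, "t.nwk"), digits = 15)
  utils::write.csv(traits, file.path(dir, "tr.csv"), row.names = FALSE)
  vapply(training, function(sp) {
    tr2 <- read_newick(file = file.path(dir, "t.nwk"))
    tab <- read_trait_table(file.path(dir, "tr.csv"))
    i <- match(sp, tab$species)
    tab$role[i] <- "target"
    tab$response[i] <- NA_real_
    f <- fit_pem_regression(tr2, tab, a = a, selection = selection)
    predict_fossil(f, species = sp)$log_point
  }, numeric(1))
}

# Rasterize a disc onto an integer matrix (test-side, independent of the
# generator's loop).
rasterize_disc <- function(mask, cy, cx, r, label = 2L) {
  rows <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  cols <- t(matrix(seq_len(ncol(mask)), ncol(mask), nrow(mask)))
  mask[(rows - cy)^2 + (cols - cx)^2 <= r^2] <- label
  mask
}

random_tree <- function(n, seed = NULL) simulate_tree(n = n, seed = seed)
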