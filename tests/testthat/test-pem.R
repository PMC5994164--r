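test_that("influence matrix marks exactly the root-to-tip edges", {
  B <- build_influence(read_newick("(A:1,B:1);"))
  expect_equal(dim(B), c(2, 2))
  expect_equal(unname(rowSums(B)), c(1, 1))
  expect_true(all(B %in% 0:1))

  t3 <- read_newick("((A:1,B:1):1,C:2);")
  B3 <- build_influence(t3)
  # preorder edges: root->X, X->A, X->B, root->C
  expect_equal(unname(B3["A", ]), c(1, 1, 0, 0))
  expect_equal(unname(B3["B", ]), c(1, 0, 1, 0))
  expect_equal(unname(B3["C", ]), c(0, 0, 0, 1))

  tr <- simulate_tree(n = 12, seed = 3)
  B12 <- build_influence(tr)
  depth_in_edges <- vapply(seq_len(12), function(i)
    length(ape::nodepath(tr, 13, i)) - 1L, integer(1))
  expect_equal(unname(rowSums(B12)), depth_in_edges)
  expect_true(all(colSums(B12) > 0))
})

test_that("edge weights follow the power law in branch length", {
  one_edge <- function(b, a, psi) {
    tr <- read_newick(sprintf("(A:%g,B:1);", b))
    W <- compute_edge_weights(tr, a, psi)
    W$w[stats::reorder(tr, "cladewise")$edge[, 2] == match("A", tr$tip.label)]
  }
  expect_equal(one_edge(4, 0, 1), 2)       # sqrt weighting
  expect_equal(one_edge(9, 1, 1), 1)       # length-independent limit
  expect_equal(one_edge(0, 0.5, 1), 0)     # zero branch, a < 1
  expect_equal(one_edge(0, 1, 1), 1)       # zero branch, a = 1
  expect_equal(one_edge(4, 0, 3), 6)       # psi scaling

  tr <- read_newick("(A:1,B:1);")
  expect_error(compute_edge_weights(tr, a = -0.1), "steepness")
  expect_error(compute_edge_weights(tr, a = 1.1), "steepness")
  expect_error(compute_edge_weights(tr, a = 0, psi = 0), "psi")
})

test_that("weighted influence cross-product equals hand-computed shared path lengths", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  B <- build_influence(tr)
  W <- compute_edge_weights(tr, a = 0, psi = 1)
  Bw <- B * rep(W$w, each = nrow(B))
  expect_equal(unname(Bw %*% t(Bw)),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3), tolerance = 1e-12)
})

test_that("Brownian-motion limit holds on random trees against the path oracle", {
  set.seed(10)
  for (rep in 1:20) {
    tr <- simulate_tree(n = sample(2:16, 1))
    B <- build_influence(tr)
    W <- compute_edge_weights(tr, a = 0, psi = 1)
    Bw <- B * rep(W$w, each = nrow(B))
    expect_lt(max(abs(Bw %*% t(Bw) - oracle_shared_path_cov(tr))), 1e-10)
  }
})

test_that("PEM basis is orthonormal, centered, rank-limited, sign-fixed", {
  set.seed(11)
  for (n in c(3, 8, 20)) {
    tr <- simulate_tree(n = n)
    basis <- build_pem(build_influence(tr), compute_edge_weights(tr, 0.3, 1))
    U <- basis$U
    r <- length(basis$d)
    expect_lte(r, n - 1)
    expect_lt(max(abs(crossprod(U) - diag(r))), 1e-10)
    expect_lt(max(abs(colSums(U))), 1e-10)
    expect_true(all(diff(basis$d) <= 1e-12))     # descending
    firsts <- apply(U, 2, function(u) u[which(abs(u) > 1e-12)[1]])
    expect_true(all(firsts > 0))
  }
})

test_that("scaling psi scales singular values and leaves eigenvectors unchanged", {
  tr <- simulate_tree(n = 9, seed = 2)
  B <- build_influence(tr)
  b1 <- build_pem(B, compute_edge_weights(tr, 0.2, 1))
  b2 <- build_pem(B, compute_edge_weights(tr, 0.2, 3.7))
  expect_equal(b2$d, 3.7 * b1$d, tolerance = 1e-10)
  expect_equal(b2$U, b1$U, tolerance = 1e-10)    # signs fixed by convention
})

test_that("target scoring reproduces training rows and zeroes the mean row", {
  tr <- simulate_tree(n = 7, seed = 4)
  B <- build_influence(tr)
  basis <- build_pem(B, compute_edge_weights(tr, 0, 1))
  sc <- target_scores(basis, B)
  expect_lt(max(abs(sc - basis$U)), 1e-10)

  # a raw row whose weighted version equals the stored column means
  w <- basis$weights$w
  mean_raw <- ifelse(w > 0, basis$col_means / w, 0)
  expect_lt(max(abs(target_scores(basis, mean_raw))), 1e-10)
})

test_that("degenerate bases are rejected", {
  expect_error(build_pem(build_influence(read_newick("(A:1,B:1);")),
                         compute_edge_weights(read_newick("(A:1,B:1);"), 0, 1),
                         tips = "A"),
               "at least 2 tips")
  tr0 <- read_newick("(A:0,B:0);")
  expect_error(build_pem(build_influence(tr0),
                         compute_edge_weights(tr0, 0, 1)),
               "rank 0")
})

test_that("training-only basis over the full grafted edge set scores fossils consistently", {
  tr <- simulate_tree(n = 10, seed = 9)
  full <- graft_tips(tr, graft_spec("fossil", tr$tip.label[2], at = 0.05,
                                    pendant = 0.3))
  B <- build_influence(full)
  basis <- build_pem(B, compute_edge_weights(full, 0, 1),
                     tips = tr$tip.label)
  sc <- target_scores(basis, B["fossil", , drop = FALSE])
  expect_equal(dim(sc), c(1L, length(basis$d)))
  expect_true(all(is.finite(sc)))
  # training tips still reproduce their own eigenvector rows
  expect_lt(max(abs(target_scores(basis, B[tr$tip.label, ]) - basis$U)), 1e-10)
})
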