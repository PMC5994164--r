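#' Simulate a pure-birth (Yule) time tree
#'
#' Generates a rooted binary tree with branch lengths in Ma, either
#' conditioned on a number of tips `n` or stopped at elapsed time `time`.
#' The default birth rate of 1 per lineage per Ma gives tree depths of a
#' few Ma for a few dozen tips, so that with the default Brownian rate of
#' the trait generator, simulated log10 traits span roughly the two orders
#' of magnitude seen in real amniote metabolic-rate data.
#'
#' @param n Number of tips (use exactly one of `n`, `time`).
#' @param time Stop time (Ma); the number of tips is then random.
#' @param birth Speciation rate per lineage per Ma.
#' @param seed Optional integer; when given, output is fully reproducible.
#' @return A `phylo` object.
#' @export
simulate_tree <- function(n = NULL, time = NULL, birth = 1, seed = NULL) {
  if (is.null(n) == is.null(time))
    stop("supply exactly one of `n` or `time`")
  stopifnot(birth > 0)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(n)) {
    stopifnot(n >= 2)
    tree <- phytools::pbtree(b = birth, n = n, type = "continuous",
                             quiet = TRUE)
  } else {
    tree <- phytools::pbtree(b = birth, t = time, type = "continuous",
                             quiet = TRUE)
  }
  tree
}

#' Simulate traits with phylogenetic signal and a linear predictor effect
#'
#' Emulates the statistical structure the PEM analysis assumes: for each tip,
#' log10 primary osteon density is drawn uniformly between the log10 bounds
#' of `density_range`, and the log10 response is
#' `beta0 + beta1 * log10(density) + BM + e`, where BM is a Brownian-motion
#' deviation on the tree with rate `s2_bm` (variance per Ma) and `e` is iid
#' Gaussian noise with s.d. `sigma_e`. All latent values (BM deviations,
#' noise, true coefficients) are returned as a truth record so recovery can
#' be tested exactly.
#'
#' @param tree A `phylo` object.
#' @param beta0,beta1 Intercept and slope of the log-log relationship.
#' @param s2_bm BM variance rate per Ma (0 switches phylogenetic signal off).
#' @param sigma_e Residual noise s.d. on the log10 scale.
#' @param density_range Predictor bounds as density fractions in (0, 1).
#' @param seed Optional integer for reproducibility.
#' @return A `sim_traits` list: `traits` (natural-scale trait table, all
#'   roles `"training"`) and `truth` (named list of every latent quantity).
#' @export
simulate_traits <- function(tree, beta0 = 0, beta1 = 1, s2_bm = 0.5,
                            sigma_e = 0.1, density_range = c(0.01, 0.5),
                            seed = NULL) {
  validate_tree(tree)
  stopifnot(s2_bm >= 0, sigma_e >= 0,
            length(density_range) == 2L, density_range[1] > 0,
            density_range[2] < 1, density_range[1] < density_range[2])
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  logx <- stats::runif(n, log10(density_range[1]), log10(density_range[2]))
  bm <- if (s2_bm > 0)
    ape::rTraitCont(tree, model = "BM", sigma = sqrt(s2_bm), root.value = 0)
  else stats::setNames(rep(0, n), tree$tip.label)
  eps <- stats::rnorm(n, 0, sigma_e)
  logy <- beta0 + beta1 * logx + as.numeric(bm[tree$tip.label]) + eps
  traits <- data.frame(species = tree$tip.label,
                       density = 10^logx, response = 10^logy,
                       role = "training", stringsAsFactors = FALSE)
  structure(list(
    traits = traits,
    truth = list(beta0 = beta0, beta1 = beta1, s2_bm = s2_bm,
                 sigma_e = sigma_e, seed = seed,
                 log_density = stats::setNames(logx, tree$tip.label),
                 bm_deviation = stats::setNames(as.numeric(bm[tree$tip.label]),
                                                tree$tip.label),
                 noise = stats::setNames(eps, tree$tip.label),
                 log_response = stats::setNames(logy, tree$tip.label))
  ), class = "sim_traits")
}

#' Turn simulated training species into prediction targets
#'
#' Synthetic "fossils" are made by switching known tips to the target role
#' and hiding their response; the generator's truth record still holds the
#' hidden value, giving an exact ground truth for prediction-recovery and
#' interval-calibration tests.
#'
#' @param traits A trait table (e.g. `sim$traits`).
#' @param species Species to convert to targets.
#' @return The modified trait table.
#' @export
as_target <- function(traits, species) {
  unknown <- setdiff(species, traits$species)
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "))
  i <- match(species, traits$species)
  traits$role[i] <- "target"
  traits$response[i] <- NA_real_
  traits
}

#' Simulate a labelled bone-section mask with known osteon density
#'
#' Builds a circular compact-bone field (label 1) surrounded by a
#' background ring (label 0) and places non-overlapping rasterized discs of
#' primary osteon (label 2) at random until the osteon pixel fraction of
#' the bone area first reaches `target_density`. The achieved fraction
#' (which overshoots the target by at most one disc) is recorded and equals
#' [osteon_density()] of the full mask exactly, since both count the same
#' pixels.
#'
#' @param target_density Desired osteon area fraction, in (0, 0.6).
#' @param radius_range Disc radius bounds in pixels.
#' @param size Mask side length in pixels.
#' @param seed Optional integer for reproducibility.
#' @param max_attempts Consecutive failed placements tolerated before
#'   declaring the target unreachable.
#' @return A `sim_mask` list: `mask` (a [section_mask()]), `achieved`
#'   (realised fraction), `n_discs`, and the call parameters.
#' @export
simulate_section_mask <- function(target_density, radius_range = c(3, 8),
                                  size = 200, seed = NULL,
                                  max_attempts = 20000) {
  stopifnot(target_density >= 0, target_density < 0.6,
            length(radius_range) == 2L, radius_range[1] >= 1,
            radius_range[1] <= radius_range[2], size >= 16)
  if (!is.null(seed)) set.seed(seed)
  ctr <- (size + 1) / 2
  bone_r <- 0.45 * size
  rows <- matrix(seq_len(size), size, size)
  cols <- t(rows)
  dist2 <- (rows - ctr)^2 + (cols - ctr)^2
  mask <- matrix(0L, size, size)
  mask[dist2 <= bone_r^2] <- 1L
  bone_px <- sum(mask == 1L)

  centers <- matrix(numeric(0), 0, 3)  # row, col, radius
  n_discs <- 0L
  fails <- 0L
  while (bone_px > 0 && sum(mask == 2L) / bone_px < target_density) {
    # as consecutive failures accumulate the section is getting crowded, so
    # bias the sampled radius towards the small end of the allowed range
    r_hi <- max(radius_range[1], radius_range[2] * exp(-fails / 300))
    r <- stats::runif(1, radius_range[1], r_hi)
    max_off <- bone_r - r - 1
    if (max_off <= 0) stop("disc radius too large for the bone field")
    repeat {
      cy <- ctr + stats::runif(1, -max_off, max_off)
      cx <- ctr + stats::runif(1, -max_off, max_off)
      if ((cy - ctr)^2 + (cx - ctr)^2 <= max_off^2) break
    }
    ok <- !nrow(centers) ||
      all((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2 >
            (centers[, 3] + r)^2)
    if (!ok) {
      fails <- fails + 1L
      if (fails >= max_attempts)
        stop("target density ", target_density,
             " unreachable with the given disc geometry (",
             max_attempts, " consecutive failed placements)")
      next
    }
    fails <- 0L
    mask[(rows - cy)^2 + (cols - cx)^2 <= r^2] <- 2L
    centers <- rbind(centers, c(cy, cx, r))
    n_discs <- n_discs + 1L
  }
  achieved <- if (bone_px > 0) sum(mask == 2L) / bone_px else 0
  structure(list(mask = section_mask(mask), achieved = achieved,
                 n_discs = n_discs, target = target_density,
                 radius_range = radius_range, size = size, seed = seed),
            class = "sim_mask")
}

#' Write a simulated dataset in the pipeline's input formats
#'
#' Emits `tree.nwk`, `traits.csv` and `truth.json` into `dir`, the same
#' Newick/CSV formats [run_analysis()] reads; the truth record (including
#' the seed) supports exact end-to-end recovery checks.
#'
#' @param tree A `phylo` object.
#' @param sim A `sim_traits` object simulated on `tree`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(tree, sim, dir) {
  stopifnot(inherits(sim, "sim_traits"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(tree, file.path(dir, "tree.nwk"))
  utils::write.csv(sim$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
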