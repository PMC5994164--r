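#' Read / validate a trait table
#'
#' A trait table has one row per species with columns `species`, `density`
#' (primary osteon density, a fraction in (0, 1)), `response` (resting
#' metabolic rate in mL O2 h^-1 g^-0.67, or bone apposition rate in um/day;
#' empty/NA for targets) and `role` (`"training"` for extant species with a
#' measured response, `"target"` for fossils to be predicted).
#'
#' @param file CSV path with columns `species,density,response,role`.
#' @return A validated data.frame.
#' @export
read_trait_table <- function(file) {
  if (!file.exists(file)) stop("trait table not found: ", file)
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_trait_table(tab)
}

#' @rdname read_trait_table
#' @param table A data.frame to validate in place of a file.
#' @export
validate_trait_table <- function(table) {
  need <- c("species", "density", "response", "role")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("trait table lacks column(s): ", paste(missing_cols, collapse = ", "))
  table$species <- as.character(table$species)
  table$role <- as.character(table$role)
  if (anyDuplicated(table$species))
    stop("duplicate species in trait table: ",
         paste(unique(table$species[duplicated(table$species)]), collapse = ", "))
  if (!all(table$role %in% c("training", "target")))
    stop("role must be 'training' or 'target'")
  bad <- table$species[!is.finite(table$density) |
                         table$density <= 0 | table$density >= 1]
  if (length(bad))
    stop("density must be a fraction in (0, 1); offending species: ",
         paste(bad, collapse = ", "))
  tr <- table$role == "training"
  bad <- table$species[tr & (!is.finite(table$response) | table$response <= 0)]
  if (length(bad))
    stop("training species must have a positive response; offending: ",
         paste(bad, collapse = ", "))
  if (any(tr) && any(!tr)) {
    has_resp <- !is.na(table$response) & nzchar(as.character(table$response))
    if (any(!tr & is.finite(table$response)))
      warning("target species carry response values; they are ignored")
  }
  table
}

#' Log-transform a trait table (base 10)
#'
#' Both predictor (primary osteon density) and response are analysed on the
#' log10 scale, accommodating the several-orders-of-magnitude range of
#' metabolic and growth rates across amniotes. Back-transformation is plain
#' base-10 exponentiation, without bias correction.
#'
#' @param table A trait table (natural scale).
#' @return The table with `density` and `response` replaced by their log10
#'   values; attribute `scale` set to `"log10"`; roles preserved.
#' @export
log_transform <- function(table) {
  table <- validate_trait_table(table)
  bad <- table$species[is.finite(table$density) & table$density <= 0]
  if (length(bad)) stop("non-positive density for: ", paste(bad, collapse = ", "))
  bad <- table$species[is.finite(table$response) & table$response <= 0]
  if (length(bad)) stop("non-positive response for: ", paste(bad, collapse = ", "))
  table$density <- log10(table$density)
  table$response <- ifelse(is.finite(table$response), log10(table$response), NA_real_)
  attr(table, "scale") <- "log10"
  table
}

#' @rdname log_transform
#' @export
back_transform <- function(table) {
  table$density <- 10^table$density
  table$response <- 10^table$response
  attr(table, "scale") <- "natural"
  table
}

# Gaussian AICc with k counting all estimated parameters: the p regression
# coefficients plus the residual variance. NA when the correction term's
# denominator is not positive (candidate infeasible, not an error).
gaussian_aicc <- function(rss, n, p) {
  k <- p + 1
  if (n - k - 1 <= 0) return(NA_real_)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# AICc comparison with the explicit tie-break: a is "better" than b when it
# is smaller by more than 1e-9, or equal within 1e-9 (including both -Inf,
# the zero-residual case) with fewer parameters.
aicc_better <- function(a, ka, b, kb, tol = 1e-9) {
  if (is.na(a)) return(FALSE)
  if (is.na(b)) return(TRUE)
  tie <- (is.infinite(a) && is.infinite(b) && a < 0 && b < 0) ||
    (is.finite(a) && is.finite(b) && abs(a - b) <= tol)
  if (tie) return(ka < kb)
  a < b
}

# OLS on a fixed design; returns NULL for singular designs.
ols_fit <- function(X, y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) return(NULL)
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% beta
  list(coef = drop(beta), rss = sum(res^2), qr = qr_x, n = length(y),
       p = ncol(X))
}

# Forward selection of eigenvectors in singular-value order with AICc stop;
# `selection` is one of forward | all | none. Returns NULL when even the
# base model is infeasible for this sample size.
select_eigenvectors <- function(U, logx, logy, selection) {
  n <- length(logy)
  base_X <- cbind(`(Intercept)` = 1, log_density = logx)
  fit0 <- ols_fit(base_X, logy)
  if (is.null(fit0)) return(NULL)
  aicc0 <- gaussian_aicc(fit0$rss, n, fit0$p)
  if (is.na(aicc0)) return(NULL)
  r <- ncol(U)
  sel <- integer(0)
  if (selection == "none" || r == 0L)
    return(list(sel = sel, aicc = aicc0, fit = fit0))
  if (selection == "all") {
    # all eigenvectors that keep AICc defined (k <= n - 2)
    max_p <- n - 3          # p + 1 <= n - 2
    sel <- seq_len(min(r, max(0, max_p - 2)))
    X <- cbind(1, U[, sel, drop = FALSE], logx)
    colnames(X) <- c("(Intercept)", colnames(U)[sel], "log_density")
    fit <- ols_fit(X, logy)
    if (is.null(fit)) return(list(sel = integer(0), aicc = aicc0, fit = fit0))
    return(list(sel = sel, aicc = gaussian_aicc(fit$rss, n, fit$p), fit = fit))
  }
  best <- list(sel = sel, aicc = aicc0, fit = fit0)
  for (j in seq_len(r)) {
    cand_sel <- c(best$sel, j)
    X <- cbind(1, U[, cand_sel, drop = FALSE], logx)
    colnames(X) <- c("(Intercept)", colnames(U)[cand_sel], "log_density")
    fit <- ols_fit(X, logy)
    if (is.null(fit)) break                       # singular candidate: stop
    aicc <- gaussian_aicc(fit$rss, n, fit$p)
    if (is.na(aicc)) break                        # out of degrees of freedom
    if (aicc_better(aicc, fit$p + 1, best$aicc, best$fit$p + 1))
      best <- list(sel = cand_sel, aicc = aicc, fit = fit)
    else break                                    # AICc no longer decreases
  }
  best
}

#' Fit a PEM trait-prediction model
#'
#' Ordinary least squares of the log10 response on an intercept, a subset of
#' PEM eigenvectors, and log10 primary osteon density, fitted on the
#' training species of the analysis tree (extant tips; grafted fossil tips
#' contribute edges but no training rows). Model selection is by Gaussian
#' AICc: eigenvectors enter by forward selection in order of decreasing
#' singular value, stopping when AICc no longer decreases, and the steepness
#' `a` of the edge-weight function is chosen on a grid by minimum AICc of
#' the selected model. Ties within 1e-9 go to the model with fewer
#' parameters, then to the smaller steepness.
#'
#' @param tree Analysis tree (`phylo`) whose tip set equals the trait
#'   table's species set (training + target).
#' @param traits Trait table on the natural scale (see [read_trait_table()]).
#' @param a Either the string `"grid"` (default: `a` in `{0, 0.01, ..., 1}`)
#'   or a fixed numeric steepness in `[0, 1]`.
#' @param selection Eigenvector selection strategy: `"forward"` (default),
#'   `"all"`, or `"none"`.
#' @param psi Evolution-rate scale of the edge weights (default 1).
#' @param interval Default interval type for predictions: `"prediction"`
#'   (new-observation interval, includes residual variance) or
#'   `"confidence"` (interval for the conditional mean).
#' @return A `pem_fit` object: coefficients, selected steepness and
#'   eigenvector indices, residual variance, AICc, and the PEM basis and
#'   influence matrix needed to score targets.
#' @export
fit_pem_regression <- function(tree, traits, a = "grid",
                               selection = c("forward", "all", "none"),
                               psi = 1,
                               interval = c("prediction", "confidence")) {
  selection <- match.arg(selection)
  interval <- match.arg(interval)
  validate_tree(tree)
  traits <- validate_trait_table(traits)
  check_species_match(tree, traits)
  training <- traits$species[traits$role == "training"]
  if (length(training) < 4L)
    stop("need at least 4 training species; got ", length(training))
  logt <- log_transform(traits)
  logx <- logt$density[match(training, logt$species)]
  logy <- logt$response[match(training, logt$species)]

  a_values <- if (identical(a, "grid")) seq(0, 1, by = 0.01) else {
    if (!is.numeric(a)) stop("`a` must be \"grid\" or a numeric steepness")
    a
  }
  infl <- build_influence(tree)
  best <- NULL
  for (av in a_values) {
    W <- compute_edge_weights(tree, a = av, psi = psi)
    basis <- build_pem(infl, W, tips = training)
    # reorder logx/logy to basis tip order (= training order used above)
    cand <- select_eigenvectors(basis$U, logx, logy, selection)
    if (is.null(cand)) next
    cand$a <- av
    cand$basis <- basis
    if (is.null(best) ||
        aicc_better(cand$aicc, cand$fit$p + 1, best$aicc, best$fit$p + 1))
      best <- cand
  }
  if (is.null(best)) {
    # sample too small for the AICc correction term (n - k - 1 <= 0 for even
    # the base model): fall back to the base regression at the smallest
    # steepness, with AICc undefined
    av <- a_values[1]
    basis <- build_pem(infl, compute_edge_weights(tree, a = av, psi = psi),
                       tips = training)
    X <- cbind(`(Intercept)` = 1, log_density = logx)
    fit0 <- ols_fit(X, logy)
    if (is.null(fit0)) stop("base design is singular")
    best <- list(sel = integer(0), aicc = NA_real_, fit = fit0, a = av,
                 basis = basis)
  }

  fit <- best$fit
  df <- fit$n - fit$p
  sigma2 <- if (df > 0) fit$rss / df else 0
  XtX_inv <- chol2inv(qr.R(fit$qr))
  structure(list(
    a = best$a, psi = psi, selection = selection, interval = interval,
    selected = best$sel, coef = fit$coef, rss = fit$rss, sigma2 = sigma2,
    df = df, n = fit$n, p = fit$p, aicc = best$aicc,
    XtX_inv = XtX_inv, basis = best$basis, influence = infl,
    training = training, log_traits = logt, tree = tree
  ), class = "pem_fit")
}

check_species_match <- function(tree, traits) {
  extra <- setdiff(traits$species, tree$tip.label)
  missing_sp <- setdiff(tree$tip.label, traits$species)
  if (length(extra) || length(missing_sp))
    stop("species/tree mismatch:",
         if (length(extra)) paste0(" in table but not tree: ",
                                   paste(extra, collapse = ", ")) else "",
         if (length(missing_sp)) paste0(" in tree but not table: ",
                                        paste(missing_sp, collapse = ", ")) else "")
  invisible(TRUE)
}

#' @export
print.pem_fit <- function(x, ...) {
  cat("PEM regression fit\n")
  cat("  training species:", x$n, "\n")
  cat("  steepness a:", x$a, " (", x$selection, " eigenvector selection)\n",
      sep = "")
  cat("  selected eigenvectors:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "none",
      "\n")
  cat("  AICc:", format(x$aicc), "  residual variance:", format(x$sigma2), "\n")
  cat("  coefficients (log10 scale):\n")
  print(x$coef)
  invisible(x)
}

# Point prediction + interval for one design row h (already on log scale).
predict_row <- function(fit, h, level = 0.95, interval = fit$interval) {
  if (fit$df <= 0) stop("no residual degrees of freedom for intervals")
  point <- drop(h %*% fit$coef)
  lev <- drop(h %*% fit$XtX_inv %*% h)
  var_term <- if (interval == "prediction") 1 + lev else lev
  se <- sqrt(fit$sigma2 * var_term)
  tq <- stats::qt(1 - (1 - level) / 2, fit$df)
  c(point = point, lwr = point - tq * se, upr = point + tq * se)
}

#' Predict responses for fossil target tips
#'
#' Each target tip's influence row on the full analysis tree is projected
#' into the training PEM basis ([target_scores()]) and its log10 response
#' predicted from the fitted regression; 95% intervals use the t
#' distribution with the fit's residual degrees of freedom. With
#' `interval = "prediction"` (default) the interval is for a new
#' observation, `point +/- t * sqrt(sigma2 * (1 + h' (X'X)^-1 h))`;
#' `"confidence"` drops the `1 +` (interval for the mean). Natural-scale
#' values are the base-10 exponentials of point and bounds.
#'
#' @param fit A `pem_fit`.
#' @param species Target species to predict (default: all `role == "target"`
#'   rows of the fit's trait table).
#' @param level Interval level (default 0.95).
#' @param interval `"prediction"` or `"confidence"`; defaults to the fit's.
#' @return A data.frame: `species`, `log_point`, `log_lwr`, `log_upr`,
#'   `point`, `lwr`, `upr` (natural units).
#' @export
predict_fossil <- function(fit, species = NULL, level = 0.95,
                           interval = NULL) {
  stopifnot(inherits(fit, "pem_fit"))
  if (is.null(interval)) interval <- fit$interval
  logt <- fit$log_traits
  if (is.null(species))
    species <- logt$species[logt$role == "target"]
  if (!length(species)) {
    return(data.frame(species = character(0), log_point = numeric(0),
                      log_lwr = numeric(0), log_upr = numeric(0),
                      point = numeric(0), lwr = numeric(0), upr = numeric(0)))
  }
  unknown <- setdiff(species, rownames(fit$influence))
  if (length(unknown))
    stop("target species not on the analysis tree: ",
         paste(unknown, collapse = ", "))
  scores <- target_scores(fit$basis, fit$influence[species, , drop = FALSE])
  out <- lapply(seq_along(species), function(i) {
    sp <- species[i]
    logx <- logt$density[match(sp, logt$species)]
    h <- c(1, scores[i, fit$selected], logx)
    predict_row(fit, h, level = level, interval = interval)
  })
  out <- do.call(rbind, out)
  data.frame(species = species,
             log_point = out[, "point"], log_lwr = out[, "lwr"],
             log_upr = out[, "upr"],
             point = 10^out[, "point"], lwr = 10^out[, "lwr"],
             upr = 10^out[, "upr"], row.names = NULL)
}

#' Leave-one-out cross-validation of the PEM model
#'
#' Each training species is in turn removed from the training set (its role
#' switched to target, its response hidden), the PEM basis and regression
#' are refit from scratch on the remaining species -- including steepness
#' and eigenvector re-selection -- and the held-out species is scored as a
#' target and predicted. PRESS is the sum of squared log10 prediction errors
#' over completed folds; folds whose refit fails are flagged and excluded.
#'
#' @inheritParams fit_pem_regression
#' @param level Interval level for per-fold predictions.
#' @return A `pem_loocv` list: `folds` (data.frame with `species`,
#'   `observed_log`, `predicted_log`, `error_log`, `ok`), `press`, `n_ok`.
#' @export
loocv <- function(tree, traits, a = "grid",
                  selection = c("forward", "all", "none"), psi = 1,
                  level = 0.95) {
  selection <- match.arg(selection)
  traits <- validate_trait_table(traits)
  training <- traits$species[traits$role == "training"]
  if (length(training) < 5L)
    stop("LOOCV needs at least 5 training species; got ", length(training))
  folds <- lapply(training, function(sp) {
    held <- traits
    i <- match(sp, held$species)
    held$role[i] <- "target"
    held$response[i] <- NA_real_
    pred <- tryCatch({
      f <- fit_pem_regression(tree, held, a = a, selection = selection,
                              psi = psi)
      predict_fossil(f, species = sp, level = level)
    }, error = function(e) NULL)
    obs <- log10(traits$response[match(sp, traits$species)])
    if (is.null(pred))
      data.frame(species = sp, observed_log = obs, predicted_log = NA_real_,
                 error_log = NA_real_, ok = FALSE)
    else
      data.frame(species = sp, observed_log = obs,
                 predicted_log = pred$log_point,
                 error_log = obs - pred$log_point, ok = TRUE)
  })
  folds <- do.call(rbind, folds)
  structure(list(folds = folds,
                 press = sum(folds$error_log[folds$ok]^2),
                 n_ok = sum(folds$ok)),
            class = "pem_loocv")
}

#' @export
print.pem_loocv <- function(x, ...) {
  cat("PEM leave-one-out cross-validation:", x$n_ok, "of", nrow(x$folds),
      "folds completed\n")
  cat("  PRESS (log10 scale):", format(x$press), "\n")
  invisible(x)
}
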