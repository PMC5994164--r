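#' Read a run configuration file
#'
#' Plain-text `key = value` lines (`#` starts a comment). Recognised keys:
#' `tree` (Newick path), `traits` (CSV path), `out_dir`, `round_branches`
#' (true/false, default true), `a` (`grid` or a number), `selection`
#' (`forward`/`all`/`none`), `interval` (`prediction`/`confidence`),
#' `level`, `seed`, `response_label`, `response_units`. The parsed config
#' is echoed in full into the run report for provenance.
#'
#' @param file Path to the config file.
#' @return A named list.
#' @export
read_run_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3L) stop("cannot parse config line: ", ln)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (tolower(val) %in% c("true", "false"))
      as.logical(toupper(val) == "TRUE")
    else if (!is.na(num) && key != "response_label" && key != "response_units")
      num
    else val
  }
  cfg
}

default_config <- function() {
  list(round_branches = TRUE, a = "grid", selection = "forward",
       interval = "prediction", level = 0.95, seed = 1,
       response_label = "response", response_units = "")
}

#' Run the full trait-inference pipeline
#'
#' Orchestrates the study workflow end to end: read the analysis tree and
#' trait table, round branch lengths to whole Ma, build the PEM and fit the
#' AICc-selected regression on the training species, run leave-one-out
#' cross-validation, predict each fossil target with 95% intervals (log10
#' and natural units), reconstruct BM ancestral states over the complete
#' sample set (observed responses at training tips, predicted values at
#' fossil tips), and write a deterministic report bundle into
#' `config$out_dir`: `fit.json`, `loocv.csv`, `predictions.csv`,
#' `ancestral_nodes.csv`, `ancestral_edges.csv` and `run.log` (every
#' decision taken: rounding warnings, selected steepness and eigenvectors,
#' fold failures).
#'
#' @param config A named list (see [read_run_config()]) or a config file
#'   path. `tree` and `traits` are required; other keys default as in
#'   [read_run_config()]. When `out_dir` is `NULL` nothing is written and
#'   the results are only returned.
#' @return Invisibly, a list: `fit`, `loocv`, `predictions` (ranked),
#'   `ancestral`, `tree_map`, `log` (character vector).
#' @export
run_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$tree) || is.null(cfg$traits))
    stop("config must provide `tree` and `traits`")
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))
  # echo every analysis option (out_dir excluded: it does not affect results,
  # and reports rerun into different directories must stay byte-identical)
  echo <- cfg[setdiff(names(cfg), "out_dir")]
  say("config: ", paste(names(echo), vapply(echo, function(v)
    paste(format(v), collapse = " "), ""), sep = "=", collapse = "; "))
  set.seed(as.integer(cfg$seed))

  tree <- if (inherits(cfg$tree, "phylo")) cfg$tree else read_newick(file = cfg$tree)
  traits <- if (is.data.frame(cfg$traits)) validate_trait_table(cfg$traits)
            else read_trait_table(cfg$traits)
  say("tree: ", ape::Ntip(tree), " tips; traits: ",
      sum(traits$role == "training"), " training, ",
      sum(traits$role == "target"), " target species")
  check_species_match(tree, traits)

  if (isTRUE(cfg$round_branches)) {
    tree <- withCallingHandlers(
      round_branch_lengths(tree),
      warning = function(w) {
        say("rounding: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    say("branch lengths rounded to the nearest Ma (half-up)")
  }

  a_opt <- if (identical(cfg$a, "grid")) "grid" else as.numeric(cfg$a)
  fit <- fit_pem_regression(tree, traits, a = a_opt,
                            selection = cfg$selection,
                            interval = cfg$interval)
  say("selected steepness a = ", fit$a, "; eigenvectors: ",
      if (length(fit$selected)) paste(fit$selected, collapse = ", ") else "none",
      "; AICc = ", format(fit$aicc))

  cv <- NULL
  if (sum(traits$role == "training") >= 5L) {
    cv <- loocv(tree, traits, a = a_opt, selection = cfg$selection,
                level = cfg$level)
    say("LOOCV: ", cv$n_ok, "/", nrow(cv$folds), " folds, PRESS = ",
        format(cv$press))
    failed <- cv$folds$species[!cv$folds$ok]
    if (length(failed)) say("LOOCV folds failed for: ",
                            paste(failed, collapse = ", "))
  } else say("LOOCV skipped: fewer than 5 training species")

  preds <- predict_fossil(fit, level = cfg$level)
  preds <- report_ordering(preds)

  logt <- fit$log_traits
  tip_vals <- stats::setNames(logt$response, logt$species)
  if (nrow(preds))
    tip_vals[preds$species] <- preds$log_point
  anc <- bm_ancestral_states(tree, tip_vals[tree$tip.label])
  tmap <- export_tree_map(tree, anc)
  say("ancestral states reconstructed on ", tree$Nnode,
      " internal nodes (log10 ", cfg$response_label, ")")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- list(
      config = cfg[setdiff(names(cfg), c("tree", "traits", "out_dir"))],
      response = list(label = cfg$response_label, units = cfg$response_units),
      model = list(a = fit$a, psi = fit$psi, selection = fit$selection,
                   selected_eigenvectors = fit$selected,
                   coefficients = as.list(fit$coef),
                   sigma2 = fit$sigma2, rss = fit$rss,
                   n_training = fit$n, aicc = fit$aicc),
      loocv = if (!is.null(cv)) list(press = cv$press, n_ok = cv$n_ok),
      predictions = preds
    )
    jsonlite::write_json(report, file.path(cfg$out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    if (!is.null(cv))
      utils::write.csv(cv$folds, file.path(cfg$out_dir, "loocv.csv"),
                       row.names = FALSE)
    utils::write.csv(preds, file.path(cfg$out_dir, "predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(tmap$nodes, file.path(cfg$out_dir, "ancestral_nodes.csv"),
                     row.names = FALSE)
    utils::write.csv(tmap$edges, file.path(cfg$out_dir, "ancestral_edges.csv"),
                     row.names = FALSE)
    writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  }
  invisible(list(fit = fit, loocv = cv, predictions = preds,
                 ancestral = anc, tree_map = tmap, log = log_lines))
}

#' Rank predictions by point estimate
#'
#' Orders a prediction table by increasing point estimate, breaking ties
#' alphabetically by species, and adds a `rank` column.
#'
#' @param predictions A data.frame from [predict_fossil()].
#' @return The same data.frame, ordered, with `rank` prepended.
#' @export
report_ordering <- function(predictions) {
  if (!nrow(predictions)) {
    predictions$rank <- integer(0)
    return(predictions[, c("rank", setdiff(names(predictions), "rank"))])
  }
  o <- order(predictions$point, predictions$species)
  out <- predictions[o, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
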