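# End-to-end pipeline: tree assembly -> prune -> per-flora metrics ->
# age structure -> between-landform tests -> landform-only and full
# regression models with spatial diagnostics.

#' Pipeline configuration
#'
#' Collects the input paths and engine options for [run_pipeline()]. Paths
#' may be `NULL` where a stage is optional (sister map, age constraints).
#'
#' @param tree Path to the backbone Newick tree.
#' @param matrix Path to the site-by-species CSV.
#' @param predictors Path to the per-site predictor CSV (must contain
#'   `site_id` and `landform`; `lon`/`lat` enable the spatial stage).
#' @param checklist Optional path to a species checklist CSV
#'   (`species`, `genus`, `family`) of species to bind into the tree.
#' @param sister_map Optional CSV (`missing_genus`, `sister_genus`) of
#'   genera to graft before binding.
#' @param out_dir Output directory (created if needed).
#' @param response Response column for the regression stage (default
#'   `"SR"`, modelled as log SR).
#' @param engine,n_rand,seed,knn_k,include_root Engine options recorded in
#'   every output's metadata sidecar.
#' @param sites_in_rows Orientation of the matrix CSV.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(tree, matrix, predictors,
                            checklist = NULL, sister_map = NULL,
                            out_dir = "floralith_out",
                            response = "SR",
                            engine = "auto", n_rand = 999L, seed = 1L,
                            knn_k = 8L, include_root = FALSE,
                            sites_in_rows = TRUE) {
  structure(list(tree = tree, matrix = matrix, predictors = predictors,
                 checklist = checklist, sister_map = sister_map,
                 out_dir = out_dir, response = response,
                 engine = engine, n_rand = as.integer(n_rand),
                 seed = assert_seed(seed), knn_k = as.integer(knn_k),
                 include_root = include_root,
                 sites_in_rows = sites_in_rows),
            class = "pipeline_config")
}

stage_msg <- function(stage, t0) {
  message(sprintf("[floralith] %-12s %.2fs", stage,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — tree assembly (graft missing genera,
#' bind checklist species at genus midpoints), pruning to the matrix
#' species, per-flora metrics (SR, PD, PDI, NRI, NTI, MDT and quartile
#' MDTs), pairwise between-landform t tests, and the regression stage
#' (landform-only and full Gaussian GLMs on the chosen response, Moran's I
#' of the residuals, and a spatial error model when coordinates are
#' available) — writing a CSV plus a metadata sidecar per stage into the
#' output directory. Reruns with the same config are bitwise reproducible.
#'
#' @param config A [pipeline_config()] object.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config object", call. = FALSE)
  for (p in c("tree", "matrix", "predictors", "checklist", "sister_map")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      stop(sprintf("input path for `%s` does not exist: %s", p, config[[p]]),
           call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta0 <- list(seed = config$seed, engine = config$engine,
                n_rand = config$n_rand, knn_k = config$knn_k,
                include_root = config$include_root)
  t0 <- proc.time()[3]

  tree <- read_newick(config$tree)
  comm <- read_matrix(config$matrix, sites_in_rows = config$sites_in_rows)
  pred <- utils::read.csv(config$predictors, stringsAsFactors = FALSE)
  if (!all(c("site_id", "landform") %in% names(pred)))
    stop("predictor table needs `site_id` and `landform` columns", call. = FALSE)
  pred <- pred[match(rownames(comm), pred$site_id), , drop = FALSE]
  if (anyNA(pred$site_id))
    stop("predictor table is missing rows for some matrix sites", call. = FALSE)
  stage_msg("read", t0); t0 <- proc.time()[3]

  if (!is.null(config$sister_map)) {
    sm <- utils::read.csv(config$sister_map, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sm)))
      tree <- graft_missing_genus(tree, sm$missing_genus[i], sm$sister_genus[i])
  }
  if (!is.null(config$checklist)) {
    cl <- utils::read.csv(config$checklist, stringsAsFactors = FALSE)
    to_bind <- cl[!(cl$species %in% tree$tip.label), , drop = FALSE]
    if (nrow(to_bind) > 0) tree <- bind_species_midpoint(tree, to_bind)
  }
  tree <- prune_to_pool(tree, colnames(comm), drop_unknown = FALSE)
  write_newick(tree, file.path(config$out_dir, "tree_pruned.nwk"))
  stage_msg("tree", t0); t0 <- proc.time()[3]

  metrics <- flora_metrics(tree, comm, engine = config$engine,
                           n_rand = config$n_rand, seed = config$seed,
                           include_root = config$include_root)
  write_with_sidecar(metrics, file.path(config$out_dir, "metrics.csv"), meta0)
  stage_msg("metrics", t0); t0 <- proc.time()[3]

  test_cols <- intersect(c("SR", "PD", "PDI", "NRI", "NTI",
                           "MDT", "MDT_oldest", "MDT_youngest"),
                         names(metrics))
  tests <- do.call(rbind, lapply(test_cols, function(cn) {
    tt <- tryCatch(pairwise_group_tests(metrics[[cn]], pred$landform),
                   error = function(e) NULL)
    if (is.null(tt)) return(NULL)
    cbind(metric = cn, tt)
  }))
  if (!is.null(tests))
    write_with_sidecar(tests, file.path(config$out_dir, "landform_tests.csv"),
                       meta0)
  stage_msg("tests", t0); t0 <- proc.time()[3]

  dat <- cbind(metrics, pred[, setdiff(names(pred), "site_id"), drop = FALSE])
  dat$landform <- factor(dat$landform)
  resp <- config$response
  dat$.y <- if (resp == "SR") log(dat$SR) else dat[[resp]]
  covars <- setdiff(names(pred),
                    c("site_id", "landform", "tectonic", "lon", "lat"))
  keep <- stats::complete.cases(dat$.y)
  dat <- dat[keep, , drop = FALSE]
  lf_fit <- fit_glm(.y ~ landform, dat)
  full_terms <- c("landform",
                  if ("tectonic" %in% names(pred)) "tectonic", covars)
  full_fit <- fit_glm(stats::as.formula(
    paste(".y ~", paste(full_terms, collapse = " + "))), dat)
  summary_rows <- data.frame(
    model = c("landform", "full"),
    deviance_explained = c(lf_fit$deviance_explained,
                           full_fit$deviance_explained),
    aic = c(lf_fit$aic, full_fit$aic))
  if (all(c("lon", "lat") %in% names(pred))) {
    w <- knn_weights(dat[, c("lon", "lat")], k = config$knn_k)
    summary_rows$moran_i <- c(morans_i(residuals(lf_fit), w)$I,
                              morans_i(residuals(full_fit), w)$I)
    sem <- fit_sem_ml(stats::formula(full_fit$fit), dat, w)
    summary_rows <- rbind(summary_rows,
      data.frame(model = "full_sem",
                 deviance_explained = sem$deviance_explained,
                 aic = sem$aic,
                 moran_i = if (is.null(sem$moran)) NA_real_ else sem$moran$I))
  }
  write_with_sidecar(summary_rows, file.path(config$out_dir, "model_summary.csv"),
                     meta0)
  cf <- stats::coef(full_fit$fit)
  write_with_sidecar(data.frame(term = names(cf), estimate = unname(cf)),
                     file.path(config$out_dir, "full_model_coefficients.csv"),
                     meta0)
  stage_msg("models", t0)
  invisible(config$out_dir)
}
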