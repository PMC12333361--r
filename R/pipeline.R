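#' Run the screening pipeline end to end
#'
#' Chains the analysis stages over a per-site feature table: `simulate`
#' (or load a CSV), `validate`, `rank` (argmax concordance per predictor),
#' `stats` (trend fits, PCA, ANOVA/Tukey across SNE classes), `classify`
#' (repeated-split logistic classification) and `regress` (repeated-split
#' regression suite). Each stage writes its outputs as CSV into `out_dir`;
#' a run manifest (config hash, seed, stages, output files) is written on
#' exit, on success or failure. All randomness derives from the single
#' config seed.
#'
#' @param config A [pipeline_config()] or path to a YAML config file.
#' @param stages Character subset of
#'   `c("simulate","validate","rank","stats","classify","regress")`.
#' @param input Optional path to a feature-table CSV; required unless
#'   "simulate" is among the stages.
#' @param out_dir Output directory (created if absent).
#' @param params [generator_params()] for the simulate stage.
#' @return The run manifest (named list), invisibly; stage results in
#'   element `results`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "validate", "rank",
                                    "stats", "classify", "regress"),
                         input = NULL,
                         out_dir = tempfile("cidnp_run_"),
                         params = NULL) {
  if (is.character(config)) config <- read_config(config)
  all_stages <- c("simulate", "validate", "rank", "stats", "classify",
                  "regress")
  stages <- all_stages[all_stages %in% stages]
  if (!length(stages)) stop("no known stage requested")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(params)) params <- generator_params(seed = config$random_seed)

  manifest <- list(
    tool = paste("cidnpscreen", as.character(utils::packageVersion("cidnpscreen"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$random_seed,
    config_hash = sprintf("%08x", sum(utf8ToInt(paste(
      vapply(config, function(v) paste(format(v, digits = 15),
                                       collapse = ","), character(1)),
      collapse = ";")) * 7L) %% 4294967291),
    stages = stages, input = input %||% "simulated",
    outputs = character(0), status = "failed")
  write_manifest <- function() {
    yaml::write_yaml(manifest[setdiff(names(manifest), "results")],
                     file.path(out_dir, "manifest.yaml"))
  }
  on.exit(write_manifest())

  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, name)
  }
  results <- list()

  tb <- if ("simulate" %in% stages) {
    lib <- generate_library(params, config)
    write_feature_table(lib$table, file.path(out_dir, "feature_table.csv"))
    manifest$outputs <- c(manifest$outputs, "feature_table.csv")
    emit(lib$ground_truth, "ground_truth.csv")
    results$simulate <- lib
    lib$table
  } else {
    if (is.null(input)) {
      stop("dependency error: no input table; run the 'simulate' stage ",
           "first or pass `input`")
    }
    load_feature_table(input, config)
  }

  if ("validate" %in% stages) {
    rep <- validate_dataset(tb)
    emit(rep$violations, "validation_violations.csv")
    if (!rep$clean) warning(nrow(rep$violations), " validation violation(s)")
    results$validate <- rep
  }
  if ("rank" %in% stages) {
    preds <- intersect(c("fukui", "a_iso", "q_value", "hirshfeld_charge",
                         "spin_density"), names(as.data.frame(tb)))
    cmp <- compare_predictors(tb, preds)
    emit(data.frame(
      predictor = vapply(cmp, `[[`, character(1), "predictor"),
      hits = vapply(cmp, `[[`, numeric(1), "hits"),
      n_molecules = vapply(cmp, `[[`, numeric(1), "n_molecules"),
      rate = vapply(cmp, `[[`, numeric(1), "rate")), "hit_rates.csv")
    emit(cmp[[1]]$detail, "hit_detail.csv")
    results$rank <- cmp
  }
  if ("stats" %in% stages) {
    quad <- c("ip", "nucleophilicity", "lumo_homo")
    fits <- lapply(feature_names(), function(f) {
      trend_fit(tb, f, form = if (f %in% quad) "quadratic" else "linear")
    })
    emit(data.frame(
      predictor = vapply(fits, `[[`, character(1), "predictor"),
      form = vapply(fits, `[[`, character(1), "form"),
      p_value = vapply(fits, `[[`, numeric(1), "p_value"),
      r_squared = vapply(fits, `[[`, numeric(1), "r_squared")),
      "trend_fits.csv")
    pca <- run_pca(tb, n_components = 3)
    emit(cbind(data.frame(explained = pca$explained_variance_ratio,
                          cumulative = pca$cumulative)), "pca_variance.csv")
    emit(as.data.frame(pca$loadings), "pca_loadings.csv")
    emit(as.data.frame(pca$scores), "pca_scores.csv")
    df <- as.data.frame(tb)
    df$sne_class <- as.character(classify_sne(df$sne,
                                              config$class_thresholds))
    at <- tryCatch(anova_tukey(df, "sne_class", "fukui"),
                   error = function(e) NULL)
    if (!is.null(at)) {
      emit(at$anova_table, "anova_fukui.csv")
      emit(at$pairwise_table, "tukey_fukui.csv")
    }
    results$stats <- list(trend_fits = fits, pca = pca, anova = at)
  }
  if ("classify" %in% stages) {
    conf <- repeated_split_classification(
      tb, n_runs = config$n_class_runs,
      train_fraction = config$class_train_fraction,
      seed = config$random_seed, thresholds = config$class_thresholds)
    emit(as.data.frame(conf$matrix), "confusion_matrix.csv")
    emit(data.frame(feature = names(conf$importances),
                    importance = as.numeric(conf$importances)),
         "classification_importances.csv")
    results$classify <- conf
  }
  if ("regress" %in% stages) {
    reports <- repeated_split_regression(
      tb, n_runs = config$n_regress_runs,
      fractions = config$regress_fractions, seed = config$random_seed)
    emit(data.frame(
      model = vapply(reports, `[[`, character(1), "model"),
      label = vapply(reports, `[[`, character(1), "model_label"),
      composite_r2 = vapply(reports, `[[`, numeric(1), "composite_score"),
      rmse = vapply(reports, function(r) r$mean_scores[["rmse"]], numeric(1)),
      mae = vapply(reports, function(r) r$mean_scores[["mae"]], numeric(1))),
      "regression_scores.csv")
    imp <- do.call(rbind, lapply(reports, function(r) {
      data.frame(model = r$model, feature = names(r$importances),
                 importance = as.numeric(r$importances))
    }))
    emit(imp, "regression_importances.csv")
    results$regress <- reports
  }

  manifest$status <- "ok"
  manifest$results <- results
  invisible(manifest)
}
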