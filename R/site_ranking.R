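#' Rank the proton sites of one molecule by a feature
#'
#' Stable sort of the molecule's sites by the chosen feature column, ties
#' broken by lexicographic site_id and flagged.
#'
#' @param molecule_rows Rows of a [feature_table()] belonging to one
#'   molecule.
#' @param feature Feature column to rank by.
#' @param descending Sort direction (default TRUE: most reactive first).
#' @return Character vector of site_ids in rank order, with attribute
#'   `ties` = TRUE if any feature values are tied.
#' @export
rank_sites <- function(molecule_rows, feature = "fukui", descending = TRUE) {
  df <- as.data.frame(molecule_rows)
  if (nrow(df) < 1) stop("need at least one site")
  if (!feature %in% names(df)) stop("unknown feature: ", feature)
  v <- df[[feature]]
  ord <- order(if (descending) -v else v, df$site_id, method = "radix")
  structure(df$site_id[ord], ties = anyDuplicated(v) > 0)
}

#' Within-molecule argmax concordance of a predictor with SNE
#'
#' For each molecule, checks whether the site with the maximal predictor
#' value is also the site with the maximal absolute SNE (the qualitative
#' site-prediction statistic; with the nucleophilic Fukui index as
#' predictor this is the headline "hits out of molecules" rate). A tie in
#' either argmax is flagged and conservatively counted as a miss. The rate
#' carries an exact Clopper-Pearson 95% confidence interval.
#'
#' @param table A [feature_table()].
#' @param predictor Feature column used as site predictor.
#' @return A `hit_rate_result`: list with `predictor`, `hits`,
#'   `n_molecules`, `rate`, `binomial_ci95`, and `detail` (per-molecule
#'   data.frame with predicted/true site and tie flags).
#' @export
argmax_hit_rate <- function(table, predictor = "fukui") {
  df <- as.data.frame(table)
  if (nrow(df) == 0) stop("empty table")
  if (!predictor %in% names(df)) stop("unknown feature: ", predictor)
  per_mol <- split(df, df$molecule_id)
  detail <- do.call(rbind, lapply(per_mol, function(m) {
    p <- m[[predictor]]
    s <- abs(m$sne)
    tie_p <- sum(p == max(p)) > 1
    tie_s <- sum(s == max(s)) > 1
    pred_site <- m$site_id[which.max(p)]
    true_site <- m$site_id[which.max(s)]
    data.frame(molecule_id = m$molecule_id[1],
               predicted_site = pred_site, true_site = true_site,
               tie = tie_p || tie_s,
               hit = !(tie_p || tie_s) && pred_site == true_site,
               stringsAsFactors = FALSE)
  }))
  rownames(detail) <- NULL
  hits <- sum(detail$hit)
  n <- nrow(detail)
  ci <- stats::binom.test(hits, n)$conf.int
  structure(list(predictor = predictor, hits = hits, n_molecules = n,
                 rate = hits / n, binomial_ci95 = as.numeric(ci),
                 detail = detail),
            class = "hit_rate_result")
}

#' @export
print.hit_rate_result <- function(x, ...) {
  cat(sprintf("<hit_rate_result> %s: %d/%d molecules (%.1f%%), 95%% CI [%.3f, %.3f]\n",
              x$predictor, x$hits, x$n_molecules, 100 * x$rate,
              x$binomial_ci95[1], x$binomial_ci95[2]))
  invisible(x)
}

#' Compare site predictors by argmax concordance and SNE correlation
#'
#' Evaluates several per-site quantities (e.g. Fukui index, a_iso,
#' Hirshfeld charge, spin density) as predictors of the maximal-SNE site,
#' sorted by hit rate; also reports the Pearson correlation of each
#' predictor with absolute SNE across all sites.
#'
#' @param table A [feature_table()].
#' @param predictors Character vector of feature/column names.
#' @return List of `hit_rate_result`s sorted by rate (descending), with
#'   attribute `correlations` (named vector).
#' @export
compare_predictors <- function(table, predictors = c("fukui", "a_iso")) {
  df <- as.data.frame(table)
  missing <- setdiff(predictors, names(df))
  if (length(missing)) stop("unknown predictor(s): ",
                            paste(missing, collapse = ", "))
  res <- lapply(predictors, function(p) argmax_hit_rate(table, p))
  cors <- vapply(predictors, function(p) {
    stats::cor(df[[p]], abs(df$sne))
  }, numeric(1))
  res <- res[order(vapply(res, function(r) r$rate, numeric(1)),
                   decreasing = TRUE)]
  structure(res, correlations = cors)
}
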