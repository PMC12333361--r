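#' Coarse-grain a feature table by its natural hierarchy
#'
#' The eight features live at different levels: logP is shared by a
#' substituent series, IP/N/gap/Delta g are molecule-level, and f-, a_iso
#' and Q are proton-specific. Trend analyses therefore run at three
#' levels: every proton ("site"), the maximal-SNE site of each molecule
#' ("molecule"), and the maximal-SNE molecule-site of each
#' (family, series) group ("family").
#'
#' @param table A [feature_table()].
#' @param level One of "site", "molecule", "family".
#' @return A [feature_table()] reduced to the representative rows.
#' @export
coarse_grain <- function(table, level = c("site", "molecule", "family")) {
  level <- match.arg(level)
  df <- as.data.frame(table)
  if (level == "site") return(table)
  key <- switch(level,
                molecule = df$molecule_id,
                family = paste(df$family, df$series, sep = "\r"))
  picked <- do.call(rbind, lapply(split(df, key), function(g) {
    g[which.max(abs(g$sne)), , drop = FALSE]
  }))
  rownames(picked) <- NULL
  feature_table(picked, q_scale = attr(table, "q_scale") %||% 1e21)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ordinary least-squares trend of SNE on a feature
#'
#' Fits `response ~ predictor` (linear) or `response ~ predictor +
#' predictor^2` (quadratic; appropriate for the electron-transfer-related
#' features IP, N and LUMO-HOMO, whose rate dependence is
#' Marcus-parabolic) at a chosen coarse-graining level. The p-value is the
#' overall F-test of the fitted terms, reported unadjusted.
#'
#' @param table A [feature_table()].
#' @param predictor Feature column name.
#' @param response Response column (default "sne").
#' @param form "linear" or "quadratic".
#' @param level Coarse-graining level passed to [coarse_grain()].
#' @return A `trend_fit`: list with `coefficients`, `p_value`,
#'   `r_squared`, `n`, and the fitted `lm` object.
#' @export
trend_fit <- function(table, predictor, response = "sne",
                      form = c("linear", "quadratic"), level = "site") {
  form <- match.arg(form)
  df <- as.data.frame(coarse_grain(table, level))
  if (!predictor %in% names(df)) stop("unknown feature: ", predictor)
  x <- df[[predictor]]
  y <- df[[response]]
  n_coef <- if (form == "linear") 2L else 3L
  if (length(y) < n_coef + 2L) stop("too few rows for a ", form, " fit")
  if (stats::var(x) == 0) stop("fit error: predictor has zero variance")
  fit <- if (form == "linear") {
    stats::lm(y ~ x)
  } else {
    stats::lm(y ~ x + I(x^2))
  }
  fs <- summary(fit)$fstatistic
  p <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  structure(list(predictor = predictor, response = response, form = form,
                 level = level, coefficients = stats::coef(fit),
                 p_value = unname(p), r_squared = summary(fit)$r.squared,
                 n = length(y), fit = fit),
            class = "trend_fit")
}

#' Principal component analysis of the feature space
#'
#' PCA of the eight features across sites. Because the features span
#' incomparable units (eV, MHz, dimensionless), each is z-scored before
#' decomposition (correlation-matrix PCA). Constant columns cannot be
#' z-scored and are dropped with a warning.
#'
#' @param table A [feature_table()].
#' @param n_components Number of components to retain (<= number of
#'   usable features).
#' @param standardize Z-score features first (default TRUE).
#' @param level Coarse-graining level (default "site": all protons).
#' @return A `pca_result`: list with `scores`, `loadings`,
#'   `explained_variance_ratio`, `cumulative` (both over all components),
#'   and `dropped` (constant features removed).
#' @export
run_pca <- function(table, n_components = 3, standardize = TRUE,
                    level = "site") {
  df <- as.data.frame(coarse_grain(table, level))
  X <- as.matrix(df[, feature_names()])
  const <- apply(X, 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (n_components > ncol(X)) stop("n_components exceeds usable features")
  if (nrow(X) < n_components + 1) stop("too few rows")
  pc <- stats::prcomp(X, center = TRUE, scale. = standardize)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = pc$x[, seq_len(n_components), drop = FALSE],
    loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
    explained_variance_ratio = evr,
    cumulative = cumsum(evr),
    dropped = colnames(df[, feature_names()])[const],
    n_components = n_components
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>\n")
  k <- min(length(x$cumulative), max(3, x$n_components))
  cat(sprintf("  cumulative variance: %s\n",
              paste(sprintf("PC1-%d: %.3f", seq_len(k),
                            x$cumulative[seq_len(k)]), collapse = ", ")))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Tests whether a response differs across groups (by default: a feature
#' across SNE enhancement classes), followed by Tukey honest significant
#' difference pairwise comparisons with family-wise adjusted p-values.
#'
#' @param table A [feature_table()] or data.frame.
#' @param grouping Grouping column name.
#' @param response Response column name.
#' @return List with `anova_table` (data.frame: F, df, p) and
#'   `pairwise_table` (Tukey HSD data.frame: diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(table, grouping, response) {
  df <- as.data.frame(table)
  stopifnot(grouping %in% names(df), response %in% names(df))
  g <- factor(df[[grouping]])
  sizes <- table(g)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) {
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  y <- df[[response]]
  fit <- stats::aov(y ~ g)
  at <- summary(fit)[[1]]
  anova_table <- data.frame(
    term = c(grouping, "residuals"),
    df = at$Df, sum_sq = at$`Sum Sq`, mean_sq = at$`Mean Sq`,
    f_value = at$`F value`, p_value = at$`Pr(>F)`,
    stringsAsFactors = FALSE)
  tk <- stats::TukeyHSD(fit)$g
  pairwise_table <- data.frame(
    pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
    upr = tk[, "upr"], p_adj = tk[, "p adj"],
    row.names = NULL, stringsAsFactors = FALSE)
  list(anova_table = anova_table, pairwise_table = pairwise_table)
}
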