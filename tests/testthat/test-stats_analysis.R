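test_that("coarse-graining picks max-SNE representatives per level", {
  lib <- generate_library(generator_params(seed = 2))
  tb <- lib$table
  expect_identical(as.data.frame(coarse_grain(tb, "site")),
                   as.data.frame(tb))
  mol <- coarse_grain(tb, "molecule")
  expect_equal(nrow(mol), 40)
  df <- as.data.frame(tb)
  # every representative carries its molecule's maximal SNE
  mx <- tapply(abs(df$sne), df$molecule_id, max)
  md <- as.data.frame(mol)
  expect_equal(abs(md$sne), as.numeric(mx[md$molecule_id]),
               ignore_attr = TRUE)
  fam <- coarse_grain(tb, "family")
  expect_equal(nrow(fam),
               nrow(unique(df[, c("family", "series")])))

  one <- tiny_table("M1", "1", fukui = 1, sne = 50)
  expect_equal(as.data.frame(coarse_grain(one, "molecule")),
               as.data.frame(one))
})

test_that("trend fits recover noiseless linear and quadratic laws", {
  x <- seq_len(10)
  tb <- tiny_table(sprintf("M%d", 1:10), "1", fukui = x, sne = 2 * x)
  fit <- suppressWarnings(trend_fit(tb, "fukui", form = "linear"))
  expect_equal(unname(fit$coefficients["x"]), 2, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-12)

  tb2 <- tiny_table(sprintf("M%d", 1:12), "1", fukui = 1:12,
                    sne = 3 * (1:12)^2 + 5)
  fit2 <- suppressWarnings(trend_fit(tb2, "fukui", form = "quadratic"))
  expect_equal(unname(fit2$coefficients["I(x^2)"]), 3, tolerance = 1e-9)

  const <- tiny_table(sprintf("M%d", 1:10), "1", fukui = rep(1, 10),
                      sne = runif(10))
  expect_error(trend_fit(const, "fukui"), "zero variance")
})

test_that("trend-fit slope is unbiased on simulated linear data", {
  set.seed(31)
  slopes <- replicate(200, {
    n <- 100
    x <- rnorm(n)
    tb <- tiny_table(sprintf("M%d", 1:n), "1", fukui = x,
                     sne = abs(min(x)) + 10 + x + rnorm(n))
    unname(trend_fit(tb, "fukui")$coefficients["x"])
  })
  expect_lt(abs(mean(slopes) - 1), 0.02)
})

test_that("PCA matches the eigendecomposition oracle and its invariants", {
  set.seed(8)
  lib <- generate_library(generator_params(seed = 8))
  res <- run_pca(lib$table, n_components = 3)
  X <- as.matrix(as.data.frame(lib$table)[, feature_names()])
  ev <- eigen(cor(X), symmetric = TRUE)$values  # independent oracle
  expect_equal(res$explained_variance_ratio, ev / sum(ev),
               tolerance = 1e-8)
  expect_equal(sum(res$explained_variance_ratio), 1, tolerance = 1e-9)
  expect_true(all(diff(res$cumulative) >= -1e-12))
  expect_equal(crossprod(res$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)

  # invariance: row order and per-feature affine rescaling
  df <- as.data.frame(lib$table)
  df2 <- df[sample(nrow(df)), ]
  df2$ip <- 3 * df2$ip - 5
  df2$a_iso <- df2$a_iso / 7
  res2 <- run_pca(feature_table(df2), n_components = 3)
  expect_equal(res2$explained_variance_ratio,
               res$explained_variance_ratio, tolerance = 1e-8)
})

test_that("PCA handles rank-1 data and constant features", {
  n <- 30
  t_var <- seq_len(n)
  df <- as.data.frame(tiny_table(sprintf("M%d", 1:n), "1",
                                 fukui = 0.1 * t_var, sne = t_var))
  df$a_iso <- 2 * t_var  # all variation along one direction
  df$ip <- -t_var
  rank1 <- df
  for (cn in c("nucleophilicity", "lumo_homo", "delta_g", "q_value",
               "log_p")) rank1[[cn]] <- rank1[[cn]][1]
  expect_warning(res <- run_pca(feature_table(rank1), n_components = 1),
                 "constant")
  expect_equal(res$explained_variance_ratio[1], 1, tolerance = 1e-10)
  expect_equal(res$dropped,
               c("nucleophilicity", "lumo_homo", "delta_g", "q_value",
                 "log_p"))
})

test_that("ANOVA and Tukey detect separated groups and respect preconditions", {
  set.seed(12)
  df <- data.frame(g = rep(c("a", "b"), each = 20),
                   y = c(rnorm(20, 0), rnorm(20, 10)))
  out <- anova_tukey(df, "g", "y")
  expect_lt(out$anova_table$p_value[1], 1e-6)
  expect_lt(out$pairwise_table$p_adj[1], 1e-6)

  same <- data.frame(g = rep(c("a", "b"), each = 5), y = rep(1:5, 2))
  out0 <- anova_tukey(same, "g", "y")
  expect_equal(out0$anova_table$f_value[1], 0, tolerance = 1e-12)
  expect_equal(out0$anova_table$p_value[1], 1, tolerance = 1e-10)

  single <- data.frame(g = c("a", "a", "b"), y = 1:3)
  expect_error(anova_tukey(single, "g", "y"), "singleton group")
  expect_error(anova_tukey(data.frame(g = "a", y = 1), "g", "y"),
               "2 groups")
})
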