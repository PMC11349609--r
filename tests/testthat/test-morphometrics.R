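make_table <- function(m, groups) {
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  df <- data.frame(id = rownames(m), group = groups, as.data.frame(m),
                   stringsAsFactors = FALSE, check.names = FALSE)
  morpho_table(df)
}

test_that("missingness filter drops variables first, then individuals", {
  set.seed(1)
  m <- matrix(rnorm(10 * 7, 20, 1), 10, 7,
              dimnames = list(paste0("s", 1:10), paste0("V", 1:7)))
  m[1:3, "V7"] <- NA                      # 30% missing -> variable dropped
  m["s1", "V1"] <- NA                     # 1/6 = 16.7% after drop -> removed
  tab <- make_table(m, rep(c("A", "B"), 5))
  res <- filter_missing(tab)
  expect_equal(res$removed_variables$variable, "V7")
  expect_equal(res$removed_variables$missing_fraction, 0.3)
  expect_equal(res$removed_individuals$id, "s1")
  expect_equal(res$removed_individuals$missing_fraction, 1 / 6,
               tolerance = 1e-12)
  expect_equal(res$table$id, paste0("s", 2:10))
  expect_false("V7" %in% names(res$table))
  # complete table unchanged
  full <- make_table(matrix(rexp(20, 0.1) + 1, 5, 4,
                            dimnames = list(paste0("t", 1:5), paste0("W", 1:4))),
                     rep("A", 5))
  expect_equal(filter_missing(full)$table, full, ignore_attr = TRUE)
  # hand-enumerated oracle on a messier fixture
  set.seed(2)
  m2 <- matrix(runif(60, 5, 10), 10, 6,
               dimnames = list(paste0("u", 1:10), paste0("X", 1:6)))
  holes <- rbind(c(1, 1), c(2, 1), c(3, 1),   # X1: 30% -> dropped
                 c(4, 2), c(4, 3),            # u4: 2/5 = 40% -> dropped
                 c(5, 4))                     # u5: 1/5 = 20% -> dropped
  m2[holes] <- NA
  res2 <- filter_missing(make_table(m2, rep(c("A", "B"), 5)))
  expect_equal(res2$removed_variables$variable, "X1")
  expect_setequal(res2$removed_individuals$id, c("u4", "u5"))
})

test_that("correlation pruning keeps the anchor of each high-r pair", {
  set.seed(3)
  base <- rnorm(30, 20, 2)
  m <- cbind(BL = base, COPY = base, IND = rnorm(30, 10, 1) + 5)
  rownames(m) <- paste0("s", 1:30)
  res <- prune_correlated(make_table(m, rep("A", 30)))
  expect_equal(res$removed$variable, "COPY")   # r = 1; anchor earlier column
  expect_equal(res$removed$anchor, "BL")
  expect_setequal(measurement_names(res$table), c("BL", "IND"))
  # independent noise columns both kept
  m2 <- cbind(A1 = rnorm(30, 10), A2 = rnorm(30, 10))
  rownames(m2) <- paste0("t", 1:30)
  res2 <- prune_correlated(make_table(m2 + 20, rep("A", 30)))
  expect_equal(nrow(res2$removed), 0)
  # 3-variable chain: result equals exhaustive search (no surviving pair > r)
  m3 <- cbind(P = base, Q = base + rnorm(30, 0, 0.3), R = rnorm(30, 20, 2))
  rownames(m3) <- paste0("u", 1:30)
  res3 <- prune_correlated(make_table(m3, rep("A", 30)), r_thresh = 0.90)
  surv <- measurement_matrix(res3$table)
  cc <- cor(surv); diag(cc) <- 0
  expect_true(all(abs(cc) <= 0.90))
  # anchor with fewer missing cells wins regardless of order
  m4 <- cbind(FIRST = base, SECOND = base)
  m4[1:3, "FIRST"] <- NA
  rownames(m4) <- paste0("v", 1:30)
  res4 <- prune_correlated(make_table(m4, rep("A", 30)))
  expect_equal(res4$removed$variable, "FIRST")
})

test_that("PMM imputation has the donor property and learns from correlation", {
  # complete table: identity for any seed
  full <- make_table(matrix(runif(40, 10, 20), 8, 5,
                            dimnames = list(paste0("s", 1:8), paste0("V", 1:5))),
                     rep("A", 8))
  expect_identical(pmm_impute(full, seed = 1), full)
  expect_identical(pmm_impute(full, seed = 999), full)
  # donor property: every imputed cell is an observed value of its column
  sim <- simulate_morphotable(morpho_sim_config(
    data.frame(label = "A", n = 40, size_factor = 1),
    ind_size_cv = 0.10, cv_noise = 0.03, seed = 8))
  truth <- measurement_matrix(sim$table)
  holed <- truth
  set.seed(9)
  miss <- matrix(runif(length(holed)) < 0.1, nrow(holed))
  holed[miss] <- NA
  tab <- make_table(holed, rep("A", 40))
  imp <- pmm_impute(tab, donors = 5, iterations = 20, seed = 10)
  mimp <- measurement_matrix(imp)
  expect_false(anyNA(mimp))
  for (j in seq_len(ncol(mimp))) {
    filled <- mimp[miss[, j], j]
    observed <- truth[!miss[, j], j]
    expect_true(all(filled %in% observed))
    expect_true(all(filled >= min(observed) & filled <= max(observed)))
  }
  # size correlation across variables makes imputation beat the column SD
  rmse <- sqrt(mean((mimp[miss] - truth[miss])^2))
  colsd <- mean(apply(truth, 2, sd))
  expect_lt(rmse, colsd)
  # reproducible given seed
  imp2 <- pmm_impute(tab, donors = 5, iterations = 20, seed = 10)
  expect_identical(measurement_matrix(imp2), mimp)
  # too few complete cases errors
  tiny <- make_table(rbind(c(1, 2), c(NA, 3), c(NA, 4)) + 10,
                     rep("A", 3))
  expect_error(pmm_impute(tiny, donors = 5), "complete cases")
})

test_that("univariate procedure routes variance-heterogeneous variables to Kruskal-Wallis", {
  set.seed(12)
  g <- rep(c("A", "B", "C"), each = 12)
  even <- c(rnorm(12, 10, 1), rnorm(12, 12, 1), rnorm(12, 14, 1))
  hetero <- c(rnorm(12, 10, 0.5), rnorm(12, 10, 5), rnorm(12, 10, 0.5))
  tab <- make_table(cbind(EVEN = even + 10, HET = abs(hetero) + 10),
                    g)
  res <- univariate_tests(tab)
  expect_equal(res$test[res$variable == "EVEN"], "anova")
  expect_equal(res$test[res$variable == "HET"], "kruskal_wallis")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # Tukey table present exactly for the ANOVA-path variable
  tk <- attr(res, "tukey")
  expect_equal(names(tk), "EVEN")
  expect_equal(nrow(tk$EVEN), 3)   # three pairwise comparisons
  # ANOVA-path statistics agree with direct stats:: computation
  fit <- aov(even + 10 ~ factor(g))
  expect_equal(res$statistic[res$variable == "EVEN"],
               summary(fit)[[1]][["F value"]][1], tolerance = 1e-12)
  kw <- kruskal.test(abs(hetero) + 10, factor(g))
  expect_equal(res$statistic[res$variable == "HET"],
               unname(kw$statistic), tolerance = 1e-12)
  # two identical groups: F ~ 0, p ~ 1
  tab2 <- make_table(cbind(V = rep(c(10, 11, 12, 13), 2)),
                     rep(c("A", "B"), each = 4))
  res2 <- univariate_tests(tab2)
  expect_lt(res2$statistic, 1e-20)
  expect_gt(res2$p_value, 0.999)
})

test_that("log-shape ratios remove isometric size", {
  tab <- make_table(rbind(s1 = c(4, 9), s2 = c(8, 18), s3 = c(6, 6)),
                    rep("A", 3))
  ss <- size_and_shape(tab)
  expect_equal(unname(ss$gm["s1"]), 6)
  expect_equal(unname(ss$shape["s1", ]), c(log(2 / 3), log(3 / 2)))
  # scale invariance: s2 = 2 * s1
  expect_equal(ss$shape["s2", ], ss$shape["s1", ], ignore_attr = TRUE)
  expect_equal(unname(ss$gm["s2"]), 2 * unname(ss$gm["s1"]))
  # all-equal row has a zero shape vector
  expect_equal(unname(ss$shape["s3", ]), c(0, 0))
  # property: shape rows sum to zero for random tables
  set.seed(13)
  m <- matrix(rexp(50, 0.1) + 1, 10, 5,
              dimnames = list(paste0("r", 1:10), paste0("V", 1:5)))
  ss2 <- size_and_shape(make_table(m, rep("A", 10)))
  expect_true(all(abs(rowSums(ss2$shape)) < 1e-10))
  c_scale <- 3.7
  ss3 <- size_and_shape(make_table(m * c_scale, rep("A", 10)))
  expect_equal(ss3$shape, ss2$shape, tolerance = 1e-12)
})

test_that("correlation PCA is a proper eigen-decomposition", {
  set.seed(14)
  m <- matrix(rnorm(60, 50, 5), 12, 5,
              dimnames = list(paste0("s", 1:12), paste0("V", 1:5)))
  p <- pca_correlation(m)
  expect_equal(sum(p$variance_fraction), 1)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  # reconstruction of the standardized data from all components
  z <- scale(m)
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon, z, tolerance = 1e-8, ignore_attr = TRUE)
  # rank-1 latent factor: PC1 carries everything
  f <- rnorm(12)
  m1 <- outer(f, c(1, 2, 3)) + 100
  colnames(m1) <- paste0("W", 1:3); rownames(m1) <- paste0("s", 1:12)
  p1 <- pca_correlation(m1)
  expect_equal(p1$variance_fraction[1], 1, tolerance = 1e-12)
  m2 <- cbind(m, CONST = 7)
  expect_error(pca_correlation(m2), "CONST")
})

test_that("UPGMA heights match hand computation and recover ultrametric input", {
  m <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m["a", "b"] <- m["b", "a"] <- 2
  m["a", "c"] <- m["c", "a"] <- 4
  m["b", "c"] <- m["c", "b"] <- 4
  tr <- upgma_cluster(dist_matrix(m, "euclidean"))
  cp <- ape::cophenetic.phylo(tr)[rownames(m), colnames(m)]
  expect_equal(cp, m, tolerance = 1e-12)       # ultrametric input recovered
  expect_true(ape::is.ultrametric(tr))
  # duplicate specimens merge first at height zero
  m4 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr4 <- upgma_cluster(dist_matrix(m4, "euclidean"))
  expect_equal(ape::cophenetic.phylo(tr4)["x", "y"], 0)
  # non-ultrametric: merge height is the average of merged distances
  m5 <- matrix(0, 3, 3, dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  m5["p", "q"] <- m5["q", "p"] <- 2
  m5["p", "r"] <- m5["r", "p"] <- 6
  m5["q", "r"] <- m5["r", "q"] <- 8
  tr5 <- upgma_cluster(dist_matrix(m5, "euclidean"))
  expect_equal(ape::cophenetic.phylo(tr5)["p", "r"], 7)   # (6+8)/2
})

test_that("LOO k-NN classification separates clusters and breaks ties by nearest", {
  set.seed(15)
  m <- rbind(matrix(rnorm(40, 0, 0.5), 20), matrix(rnorm(40, 8, 0.5), 20))
  rownames(m) <- paste0("s", 1:40)
  labels <- rep(c("A", "B"), each = 20)
  res <- knn_classify_loo(m, labels, k = 1)
  expect_equal(res$overall_percent, 100)
  expect_equal(res$per_group$percent_correct, c(100, 100))
  # auto-k reports an odd k and 100% here
  resa <- knn_classify_loo(m, labels, k = "auto")
  expect_true(resa$k %% 2 == 1)
  expect_equal(resa$overall_percent, 100)
  # 5-point fixture with one ambiguous point, k = 1 -> 4/5
  pts <- matrix(c(0, 1, 2, 3.5, 10), ncol = 1)
  rownames(pts) <- paste0("p", 1:5)
  res5 <- knn_classify_loo(pts, c("A", "A", "A", "B", "B"), k = 1,
                           standardize = FALSE)
  expect_equal(res5$overall_percent, 80)
  expect_equal(res5$per_group$percent_correct[res5$per_group$group == "A"], 100)
  expect_equal(res5$per_group$percent_correct[res5$per_group$group == "B"], 50)
  # twin property: duplicating every specimen gives 100% at k = 1
  twins <- rbind(m, m)
  rownames(twins) <- paste0("t", 1:80)
  rest <- knn_classify_loo(twins, rep(labels, 2), k = 1)
  expect_equal(rest$overall_percent, 100)
  expect_error(knn_classify_loo(m, labels, k = 40), "k must be")
})

test_that("descriptive stats mirror per-group hand computation", {
  m <- rbind(s1 = c(10, 20), s2 = c(12, 22), s3 = c(30, NA))
  colnames(m) <- c("BL", "ZW")
  tab <- make_table(m, c("A", "A", "B"))
  ds <- descriptive_stats(tab)
  rowA <- ds[ds$stratum == "A" & ds$variable == "BL", ]
  expect_equal(rowA$n, 2); expect_equal(rowA$mean, 11)
  expect_equal(rowA$sd, sd(c(10, 12))); expect_equal(rowA$max, 12)
  rowB <- ds[ds$stratum == "B" & ds$variable == "ZW", ]
  expect_equal(rowB$n, 0); expect_true(is.na(rowB$mean))
  rowB2 <- ds[ds$stratum == "B" & ds$variable == "BL", ]
  expect_equal(rowB2$mean, 30); expect_true(is.na(rowB2$sd))
  # by-sex stratification
  tab$sex <- c("m", "f", "m")
  ds2 <- descriptive_stats(tab, by_sex = TRUE)
  expect_true("A/m" %in% ds2$stratum)
  expect_equal(ds2$n[ds2$stratum == "A/m" & ds2$variable == "BL"], 1)
})

test_that("pipeline enforces order and separates size from shape signal", {
  # groups differing only in size (well separated): size ANOVA rejects and
  # raw k-NN is perfect, but shape-space k-NN falls to near-chance
  simsize <- simulate_morphotable(morpho_sim_config(
    data.frame(label = c("a", "b"), n = c(15, 15),
               size_factor = c(1, 1.3)),
    cv_noise = 0.03, ind_size_cv = 0.03, seed = 16))
  ss <- size_and_shape(simsize$table)
  psize <- summary(aov(ss$gm ~ factor(simsize$table$group)))[[1]][["Pr(>F)"]][1]
  expect_lt(psize, 0.001)
  shape_acc <- knn_classify_loo(ss$shape, simsize$table$group,
                                k = 1)$overall_percent
  raw_acc <- knn_classify_loo(simsize$table, k = 1)$overall_percent
  expect_equal(raw_acc, 100)
  expect_lt(shape_acc, 75)   # size removed: near-chance
  # full pipeline run on a holed table with clone variables
  simfull <- simulate_morphotable(morpho_sim_config(
    data.frame(label = c("small", "big"), n = c(15, 15),
               size_factor = c(0.85, 1)),
    missing_rate = 0.05, n_correlated_clones = 2, seed = 17))
  res <- run_morpho_pipeline(simfull$table, iterations = 10, seed = 18)
  expect_false(anyNA(measurement_matrix(res$imputed)))
  expect_lt(res$size_anova_p, 1e-4)
  expect_true(all(abs(rowSums(res$size_shape$shape)) < 1e-10))
  # clone variables were pruned
  expect_false(any(grepl("_clone", measurement_names(res$imputed))))
})
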