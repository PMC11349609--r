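# Craniodental/external morphometric pipeline: missingness filters,
# correlation pruning, chained-equations predictive-mean-matching
# imputation, univariate test procedure (Bartlett -> ANOVA/Tukey or
# Kruskal-Wallis), correlation PCA, Mosimann log-shape ratios, UPGMA
# clustering, and leave-one-out k-NN classification.
#
# The intended analysis order is: filter_missing -> prune_correlated ->
# (UPGMA on observed data) -> pmm_impute -> PCA / size_and_shape / k-NN;
# run_morpho_pipeline() enforces it.

#' Remove variables, then individuals, with excess missing data
#'
#' Variables with a missing fraction strictly above `var_thresh` are dropped
#' first; then individuals whose missing fraction over the surviving
#' variables is strictly above `ind_thresh` are dropped. Defaults mirror the
#' usual 20% variable / 15% individual rules (so an individual at 16%
#' missing is removed).
#'
#' @param table a `morpho_table`.
#' @param var_thresh,ind_thresh missing-fraction thresholds in (0, 1).
#' @return list: `table` (filtered `morpho_table`), `removed_variables` and
#'   `removed_individuals` (data frames with the offending fraction).
#' @export
filter_missing <- function(table, var_thresh = 0.20, ind_thresh = 0.15) {
  stopifnot(var_thresh > 0, var_thresh < 1, ind_thresh > 0, ind_thresh < 1)
  m <- measurement_matrix(table)
  var_frac <- colMeans(is.na(m))
  drop_vars <- names(var_frac)[var_frac > var_thresh]
  removed_variables <- data.frame(variable = drop_vars,
                                  missing_fraction = unname(var_frac[drop_vars]),
                                  stringsAsFactors = FALSE)
  m2 <- m[, setdiff(colnames(m), drop_vars), drop = FALSE]
  if (!ncol(m2)) stop("all variables removed by the missingness filter")
  ind_frac <- rowMeans(is.na(m2))
  drop_ind <- rownames(m2)[ind_frac > ind_thresh]
  removed_individuals <- data.frame(id = drop_ind,
                                    missing_fraction = unname(ind_frac[drop_ind]),
                                    stringsAsFactors = FALSE)
  keep_rows <- !(table$id %in% drop_ind)
  if (!any(keep_rows)) stop("all individuals removed by the missingness filter")
  out <- table[keep_rows, c(intersect(names(table), c("id", "group", "sex", "population")),
                            setdiff(colnames(m2), character(0))), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  list(table = out, removed_variables = removed_variables,
       removed_individuals = removed_individuals)
}

#' Drop one of each highly correlated variable pair
#'
#' Iteratively removes variables until no pair of measurements has
#' |Pearson r| above `r_thresh` (pairwise-complete observations). At each
#' step the worst pair is resolved by keeping the anchor — the variable with
#' fewer missing cells, ties broken by earlier column order — and dropping
#' the other.
#'
#' @param table a `morpho_table` with >= 2 measurement variables.
#' @param r_thresh absolute correlation threshold (default 0.90).
#' @return list: `table`, `removed` (data frame `variable`, `anchor`, `r`).
#' @export
prune_correlated <- function(table, r_thresh = 0.90) {
  m <- measurement_matrix(table)
  if (ncol(m) < 2L) stop("need >= 2 variables")
  removed <- data.frame(variable = character(0), anchor = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  repeat {
    cc <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
    diag(cc) <- 0
    cc[is.na(cc)] <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    if (max(abs(cc)) <= r_thresh) break
    i <- worst[1]; j <- worst[2]
    miss <- colSums(is.na(m))
    # anchor: fewer missing cells, then earlier column
    anchor <- if (miss[i] < miss[j]) i else if (miss[j] < miss[i]) j else min(i, j)
    victim <- if (anchor == i) j else i
    removed <- rbind(removed, data.frame(
      variable = colnames(m)[victim], anchor = colnames(m)[anchor],
      r = cc[i, j], stringsAsFactors = FALSE))
    m <- m[, -victim, drop = FALSE]
    if (ncol(m) < 2L) break
  }
  keep_cols <- c(intersect(names(table), c("id", "group", "sex", "population")),
                 colnames(m))
  out <- table[, keep_cols, drop = FALSE]
  class(out) <- class(table)
  list(table = out, removed = removed)
}

#' Predictive-mean-matching imputation (chained equations)
#'
#' Fills missing cells by chained-equations PMM: missing cells start at
#' column means; then, for a fixed number of sweeps, each variable with
#' missingness is regressed (ordinary least squares) on all other variables
#' over the rows where it is observed (other variables at their current
#' working values), predictions are computed for every row, and each missing
#' cell is replaced by the observed value of one of the `donors` rows whose
#' predictions are closest to the missing row's prediction, drawn uniformly.
#' Every imputed value is therefore an observed value of its own variable.
#' Single imputation: one completed table, reproducible given `seed`.
#'
#' @param table a `morpho_table` (typically filtered and pruned).
#' @param donors donor pool size (default 5).
#' @param iterations number of chained sweeps (default 50).
#' @param seed integer seed for donor draws.
#' @return a complete `morpho_table`; attribute `imputed_cells` lists
#'   (id, variable) of filled cells.
#' @export
pmm_impute <- function(table, donors = 5L, iterations = 50L, seed = 1L) {
  m <- measurement_matrix(table)
  miss <- is.na(m)
  if (!any(miss)) return(table)
  n_complete <- colSums(!miss)
  too_few <- colnames(m)[n_complete < donors]
  if (length(too_few))
    stop("fewer than ", donors, " complete cases for: ",
         paste(too_few, collapse = ", "))
  set.seed(as.integer(seed))
  work <- m
  for (j in seq_len(ncol(work)))
    work[miss[, j], j] <- mean(m[, j], na.rm = TRUE)
  vars_missing <- which(colSums(miss) > 0)
  for (it in seq_len(iterations)) {
    for (j in vars_missing) {
      obs <- which(!miss[, j])
      mis <- which(miss[, j])
      X <- work[, -j, drop = FALSE]
      fit <- lm.fit(cbind(1, X[obs, , drop = FALSE]), m[obs, j])
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred <- as.vector(cbind(1, X) %*% beta)
      for (r in mis) {
        gap <- abs(pred[obs] - pred[r])
        pool <- obs[order(gap, obs)][seq_len(donors)]
        donor <- pool[sample.int(donors, 1L)]
        work[r, j] <- m[donor, j]
      }
    }
  }
  out <- table
  for (j in seq_len(ncol(work))) out[[colnames(work)[j]]] <- work[, j]
  idx <- which(miss, arr.ind = TRUE)
  attr(out, "imputed_cells") <- data.frame(
    id = rownames(m)[idx[, 1]], variable = colnames(m)[idx[, 2]],
    stringsAsFactors = FALSE)
  out
}

#' Univariate test procedure per measurement
#'
#' For each variable: Bartlett's test of homogeneity of group variances; if
#' its p-value is at least `alpha_bartlett`, a one-way ANOVA with Tukey HSD
#' pairwise comparisons (family-wise studentized-range adjustment within the
#' variable); otherwise a Kruskal-Wallis rank test. This mirrors the common
#' practice of routing variance-heterogeneous measurements (e.g. ATL-like
#' variables) to the nonparametric test.
#'
#' @param table a `morpho_table`.
#' @param alpha_bartlett Bartlett rejection level (default 0.05).
#' @return data frame per variable: `variable`, `test`
#'   (`"anova"`/`"kruskal_wallis"`), `statistic`, `p_value`,
#'   `bartlett_statistic`, `bartlett_p`; attribute `tukey` holds a named
#'   list of Tukey tables for the ANOVA-path variables.
#' @export
univariate_tests <- function(table, alpha_bartlett = 0.05) {
  g <- factor(table$group)
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  vars <- measurement_names(table)
  tukey <- list()
  rows <- lapply(vars, function(v) {
    x <- table[[v]]
    ok <- !is.na(x)
    xi <- x[ok]; gi <- droplevels(g[ok])
    sizes <- table(gi)
    if (nlevels(gi) < 2L || any(sizes < 2L))
      return(data.frame(variable = v, test = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        bartlett_statistic = NA_real_, bartlett_p = NA_real_,
                        stringsAsFactors = FALSE))
    bt <- bartlett.test(xi, gi)
    if (bt$p.value >= alpha_bartlett) {
      fit <- aov(xi ~ gi)
      sm <- summary(fit)[[1]]
      tukey[[v]] <<- TukeyHSD(fit)$gi
      data.frame(variable = v, test = "anova",
                 statistic = sm[["F value"]][1], p_value = sm[["Pr(>F)"]][1],
                 bartlett_statistic = unname(bt$statistic),
                 bartlett_p = bt$p.value, stringsAsFactors = FALSE)
    } else {
      kw <- kruskal.test(xi, gi)
      data.frame(variable = v, test = "kruskal_wallis",
                 statistic = unname(kw$statistic), p_value = kw$p.value,
                 bartlett_statistic = unname(bt$statistic),
                 bartlett_p = bt$p.value, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  attr(res, "tukey") <- tukey
  res
}

#' Geometric-mean size and Mosimann log-shape ratios
#'
#' Per specimen: size = geometric mean of its p measurements; shape vector =
#' log of each measurement divided by that geometric mean. Shape vectors sum
#' to zero and are invariant to multiplying a specimen's row by a constant,
#' so isometric size is removed.
#'
#' @param table a complete `morpho_table` (positive values, no NAs).
#' @return list: `gm` (named numeric, specimen sizes), `shape` (matrix
#'   specimens x variables of log-shape ratios).
#' @export
size_and_shape <- function(table) {
  m <- measurement_matrix(table)
  if (anyNA(m)) stop("table has missing cells; impute first")
  if (any(m <= 0)) stop("non-positive measurement")
  gm <- exp(rowMeans(log(m)))
  shape <- log(m / gm)
  list(gm = gm, shape = shape)
}

#' Principal component analysis on the correlation matrix
#'
#' Eigen-decomposition of the Pearson correlation matrix of the measurements
#' (equivalently PCA of standardized variables), the usual choice for
#' linear-measurement data on different scales.
#'
#' @param x complete numeric matrix (specimens x variables) or
#'   `morpho_table`.
#' @return list: `scores` (specimens x components), `loadings` (variables x
#'   components, unit eigenvectors), `variance_fraction` (per component,
#'   sums to 1), `sdev`.
#' @export
pca_correlation <- function(x) {
  m <- if (inherits(x, "morpho_table") || is.data.frame(x))
    measurement_matrix(x) else as.matrix(x)
  if (anyNA(m)) stop("PCA input has missing cells")
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  z <- scale(m, center = TRUE, scale = TRUE)
  ev <- eigen(cor(m), symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  loadings <- ev$vectors
  rownames(loadings) <- colnames(m)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  scores <- z %*% loadings
  list(scores = scores, loadings = loadings,
       variance_fraction = lam / sum(lam),
       sdev = sqrt(lam))
}

#' UPGMA dendrogram from a Euclidean distance matrix
#'
#' Average-linkage agglomeration; the returned tree is ultrametric with
#' root-to-tip path equal to half the final merge's average distance (tips
#' at depth = merge height / 2, the standard dendrogram-to-tree convention).
#'
#' @param d a [dist_matrix()] (mode `"euclidean"`) or `dist` object.
#' @return ultrametric `phylo`.
#' @export
upgma_cluster <- function(d) {
  dd <- if (inherits(d, "dist")) d else as.dist(unclass(d))
  if (anyNA(dd)) stop("distance matrix has undefined cells")
  ape::as.phylo(hclust(dd, method = "average"))
}

#' Leave-one-out k-nearest-neighbour classification
#'
#' Each specimen is classified by the majority label among its k nearest
#' neighbours (Euclidean distance, optionally on standardized variables),
#' with itself held out; vote ties are broken by the single nearest
#' neighbour's label. `k = "auto"` picks the odd k in 1..15 with the highest
#' LOO overall accuracy (smallest k on ties).
#'
#' @param x complete numeric matrix or `morpho_table`.
#' @param labels group label per row (defaults to the table's `group`).
#' @param k neighbour count, or `"auto"`.
#' @param standardize scale variables to unit variance first (default TRUE).
#' @return list: `k`, `overall_percent`, `per_group` (data frame `group`,
#'   `n`, `percent_correct`), `predicted` (named character).
#' @export
knn_classify_loo <- function(x, labels = NULL, k = "auto", standardize = TRUE) {
  m <- if (inherits(x, "morpho_table") || is.data.frame(x)) {
    if (is.null(labels)) labels <- x$group
    measurement_matrix(x)
  } else as.matrix(x)
  if (is.null(labels)) stop("labels required")
  labels <- as.character(labels)
  n <- nrow(m)
  if (length(unique(labels)) < 2L) stop("need >= 2 groups")
  if (anyNA(m)) stop("k-NN input has missing cells")
  if (standardize) {
    sds <- apply(m, 2, sd)
    m <- scale(m, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  }
  D <- as.matrix(dist(m))
  loo_predict <- function(kk) {
    vapply(seq_len(n), function(i) {
      dd <- D[i, ]; dd[i] <- Inf
      ord <- order(dd, seq_len(n))
      nb <- ord[seq_len(kk)]
      tab <- table(labels[nb])
      winners <- names(tab)[tab == max(tab)]
      if (length(winners) == 1L) winners else labels[nb[1L]]
    }, character(1))
  }
  if (identical(k, "auto")) {
    ks <- seq(1L, min(15L, n - 1L), by = 2L)
    acc <- vapply(ks, function(kk) mean(loo_predict(kk) == labels), numeric(1))
    k <- ks[which.max(acc)]
  }
  k <- as.integer(k)
  if (k >= n) stop("k must be < number of specimens")
  pred <- loo_predict(k)
  names(pred) <- rownames(m)
  per_group <- do.call(rbind, lapply(sort(unique(labels)), function(gl) {
    idx <- labels == gl
    data.frame(group = gl, n = sum(idx),
               percent_correct = 100 * mean(pred[idx] == gl),
               stringsAsFactors = FALSE)
  }))
  list(k = k, overall_percent = 100 * mean(pred == labels),
       per_group = per_group, predicted = pred)
}

#' Per-group descriptive statistics (Table-4/6 layout)
#'
#' n, mean, SD, min and max per variable and group (optionally split by
#' sex), excluding missing cells per cell. SD is `NA` for single values.
#'
#' @param table a `morpho_table`.
#' @param by_sex split groups by the `sex` column.
#' @return long data frame: `group` (, `sex`), `variable`, `n`, `mean`,
#'   `sd`, `min`, `max`.
#' @export
descriptive_stats <- function(table, by_sex = FALSE) {
  vars <- measurement_names(table)
  key <- if (by_sex && "sex" %in% names(table))
    interaction(table$group, table$sex, sep = "/", drop = TRUE)
  else factor(table$group)
  rows <- list()
  for (lev in levels(key)) {
    sel <- key == lev
    for (v in vars) {
      x <- table[[v]][sel]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = lev, variable = v, n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) >= 2L) sd(x) else NA_real_,
        min = if (length(x)) min(x) else NA_real_,
        max = if (length(x)) max(x) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full morphometric pipeline in the canonical order
#'
#' filter_missing -> prune_correlated -> UPGMA on the observed (pre-imputation)
#' data -> PMM imputation -> correlation PCA (raw and size-corrected),
#' geometric-mean size ANOVA, and LOO k-NN classification on raw and
#' log-shape-ratio data.
#'
#' @param table a `morpho_table`.
#' @param var_thresh,ind_thresh,r_thresh,donors,iterations,seed,k pipeline
#'   parameters (see the stage functions).
#' @return list with every stage's output: `filter`, `prune`, `upgma`,
#'   `imputed`, `tests`, `pca_raw`, `pca_shape`, `size_shape`,
#'   `size_anova_p`, `knn_raw`, `knn_shape`, `descriptives`.
#' @export
run_morpho_pipeline <- function(table, var_thresh = 0.20, ind_thresh = 0.15,
                                r_thresh = 0.90, donors = 5L,
                                iterations = 50L, seed = 1L, k = "auto") {
  filt <- filter_missing(table, var_thresh, ind_thresh)
  prn <- prune_correlated(filt$table, r_thresh)
  cc_rows <- complete.cases(measurement_matrix(prn$table))
  upg <- if (sum(cc_rows) >= 3L) {
    obs <- measurement_matrix(prn$table)[cc_rows, , drop = FALSE]
    upgma_cluster(dist(obs))
  } else NULL
  imp <- pmm_impute(prn$table, donors, iterations, seed)
  tests <- univariate_tests(imp)
  ss <- size_and_shape(imp)
  av <- aov(ss$gm ~ factor(imp$group))
  size_p <- summary(av)[[1]][["Pr(>F)"]][1]
  list(filter = filt, prune = prn, upgma = upg, imputed = imp,
       tests = tests,
       pca_raw = pca_correlation(imp),
       pca_shape = pca_correlation(ss$shape),
       size_shape = ss,
       size_anova_p = size_p,
       knn_raw = knn_classify_loo(imp, k = k),
       knn_shape = knn_classify_loo(ss$shape, labels = imp$group, k = k),
       descriptives = descriptive_stats(imp))
}
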