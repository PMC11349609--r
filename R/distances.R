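# K2P distances with pairwise deletion, plus Table-2 style group summaries.
# Sites where either sequence is not plain A/C/G/T are excluded per pair;
# ambiguity codes count as missing, not as fractional matches.

#' Classify aligned site patterns between two sequences
#'
#' Compares two equal-length DNA strings column by column. Columns where
#' either sequence carries anything but A, C, G or T (gaps, `?`, `N`, IUPAC
#' ambiguity codes) are excluded — pairwise deletion. Transitions are the
#' purine pair A<->G and the pyrimidine pair C<->T; every other differing
#' ACGT pair is a transversion.
#'
#' @param seq_a,seq_b DNA strings of equal length (case-insensitive).
#' @return list with `n_valid`, `n_transitions`, `n_transversions`, and the
#'   proportions `P` (transitions) and `Q` (transversions). When no site
#'   survives deletion, proportions are `NA` and `undefined` is `TRUE`.
#' @export
count_site_patterns <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("sequences differ in length (", length(a), " vs ", length(b), ")")
  acgt <- c("A", "C", "G", "T")
  keep <- a %in% acgt & b %in% acgt
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  diff <- a != b
  purine <- c("A", "G")
  ts <- diff & ((a %in% purine) == (b %in% purine))
  n_ts <- sum(ts)
  n_tv <- sum(diff) - n_ts
  list(n_valid = n,
       n_transitions = n_ts,
       n_transversions = n_tv,
       P = if (n > 0) n_ts / n else NA_real_,
       Q = if (n > 0) n_tv / n else NA_real_,
       undefined = n == 0L)
}

#' Kimura two-parameter distance from site-pattern proportions
#'
#' `k2p_all` applies the full two-parameter correction
#' d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q); `k2p_tv` uses only the
#' transversion component d = -1/2 ln(1 - 2Q), the convention for
#' transversion-only 12S rRNA comparisons.
#'
#' @param counts result of [count_site_patterns()] (or any list with `P`,
#'   `Q`, `n_valid`).
#' @param mode `"k2p_all"` or `"k2p_tv"`.
#' @return distance in substitutions per site.
#' @export
k2p_distance <- function(counts, mode = c("k2p_all", "k2p_tv")) {
  mode <- match.arg(mode)
  if (isTRUE(counts$undefined) || is.na(counts$P) || counts$n_valid == 0L)
    stop("no comparable sites: distance undefined")
  P <- counts$P; Q <- counts$Q
  if (mode == "k2p_all") {
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0)
      stop("K2P saturation: log argument <= 0 (P=", signif(P, 4),
           ", Q=", signif(Q, 4), ")")
    d <- -0.5 * log(w1) - 0.25 * log(w2)
  } else {
    w2 <- 1 - 2 * Q
    if (w2 <= 0)
      stop("K2P saturation: log argument <= 0 (Q=", signif(Q, 4), ")")
    d <- -0.5 * log(w2)
  }
  max(d, 0)
}

#' Construct a labelled distance matrix object
#' @param values symmetric numeric matrix (NA allowed for undefined cells).
#' @param mode one of `"k2p_all"`, `"k2p_tv"`, `"hamming"`, `"patristic"`,
#'   `"euclidean"`.
#' @return a `dist_matrix`: the matrix with `mode` attribute and class.
#' @export
dist_matrix <- function(values, mode) {
  mode <- match.arg(mode, c("k2p_all", "k2p_tv", "hamming", "patristic",
                            "euclidean"))
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("distance matrix must be labelled")
  colnames(values) <- rownames(values)
  if (any(abs(values - t(values)) > 1e-12, na.rm = TRUE))
    stop("distance matrix not symmetric")
  diag(values) <- 0
  if (any(values < 0, na.rm = TRUE)) stop("negative distances")
  structure(values, mode_label = mode, class = c("dist_matrix", "matrix", "array"))
}

#' Distance mode of a `dist_matrix`
#' @param d a `dist_matrix`.
#' @export
dist_mode <- function(d) attr(d, "mode_label")

#' Pairwise K2P distance matrix for an alignment
#'
#' Computes all unordered pairs via [count_site_patterns()] and
#' [k2p_distance()]. Saturated or zero-overlap pairs become `NA` cells
#' (flagged with a warning naming the count), never silent zeros.
#'
#' @param aln an [alignment()].
#' @param mode `"k2p_all"` or `"k2p_tv"`.
#' @return a `dist_matrix` of substitutions/site.
#' @export
pairwise_matrix <- function(aln, mode = c("k2p_all", "k2p_tv")) {
  mode <- match.arg(mode)
  n <- length(aln$ids)
  if (n < 2L) stop("need >= 2 sequences")
  m <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  n_undef <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- tryCatch(
        k2p_distance(count_site_patterns(aln$seqs[[i]], aln$seqs[[j]]), mode),
        error = function(e) NA_real_)
      if (is.na(d)) n_undef <- n_undef + 1L
      m[i, j] <- m[j, i] <- d
    }
  }
  if (n_undef > 0L)
    warning(n_undef, " pair(s) undefined (saturated or no shared sites)")
  dist_matrix(m, mode)
}

#' Group-level distance summary (Table-2 layout)
#'
#' Mean, min and max pairwise distance for every ordered group pair:
#' between-group summaries over all cross pairs, within-group summaries over
#' distinct pairs (self-pairs excluded). Undefined cells are dropped from
#' summaries; groups with fewer than two members get `NA` within-group rows.
#'
#' @param d a `dist_matrix`.
#' @param groups a `group_map` covering every matrix label.
#' @param as_percent report distances multiplied by 100.
#' @return data frame with `group_a`, `group_b`, `n_pairs`, `mean`, `min`,
#'   `max`, `type` (`"within"`/`"between"`).
#' @export
group_summary <- function(d, groups, as_percent = TRUE) {
  labs <- rownames(d)
  g <- group_of(groups, labs)
  scale <- if (as_percent) 100 else 1
  glev <- unique(g)
  out <- list()
  for (i in seq_along(glev)) {
    for (j in i:length(glev)) {
      ga <- glev[i]; gb <- glev[j]
      ia <- which(g == ga); ib <- which(g == gb)
      if (ga == gb) {
        if (length(ia) < 2L) {
          vals <- numeric(0)
        } else {
          sub <- d[ia, ia, drop = FALSE]
          vals <- sub[upper.tri(sub)]
        }
        type <- "within"
      } else {
        vals <- as.vector(d[ia, ib, drop = FALSE])
        type <- "between"
      }
      vals <- vals[!is.na(vals)]
      out[[length(out) + 1L]] <- data.frame(
        group_a = ga, group_b = gb, n_pairs = length(vals),
        mean = if (length(vals)) mean(vals) * scale else NA_real_,
        min  = if (length(vals)) min(vals) * scale else NA_real_,
        max  = if (length(vals)) max(vals) * scale else NA_real_,
        type = type, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "as_percent") <- as_percent
  attr(res, "mode_label") <- dist_mode(d)
  res
}

#' Write a distance matrix (square TSV and long CSV)
#' @param d a `dist_matrix`.
#' @param path_square path for the square tab-delimited matrix (or NULL).
#' @param path_long path for long-format CSV `id_a,id_b,distance,mode` (or NULL).
#' @return invisibly, the long-format data frame.
#' @export
write_dist_matrix <- function(d, path_square = NULL, path_long = NULL) {
  if (!is.null(path_square)) {
    df <- data.frame(id = rownames(d), as.data.frame(unclass(d)),
                     check.names = FALSE)
    write.table(df, path_square, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  idx <- which(upper.tri(d), arr.ind = TRUE)
  long <- data.frame(id_a = rownames(d)[idx[, 1]],
                     id_b = colnames(d)[idx[, 2]],
                     distance = d[idx],
                     mode = dist_mode(d), stringsAsFactors = FALSE)
  if (!is.null(path_long)) write.csv(long, path_long, row.names = FALSE)
  invisible(long)
}

#' @importFrom utils write.table
NULL
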