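# Tree- and distance-based species-delimitation statistics: monophyly,
# Rosenberg's probability of monophyly under random coalescence, intra/inter
# distance ratio, and leave-one-out probability of correct identification.

#' Is a tip set monophyletic on a rooted tree?
#'
#' True iff some node's descendant tip set equals `tips` exactly. Singletons
#' and the full tip set are monophyletic by convention.
#'
#' @param tree rooted `phylo`.
#' @param tips character vector of tip labels.
#' @return logical scalar.
#' @export
is_monophyletic <- function(tree, tips) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("tips not in tree: ", paste(unknown, collapse = ", "))
  if (length(tips) <= 1L || length(tips) == length(tree$tip.label))
    return(TRUE)
  ape::is.monophyletic(tree, tips)
}

#' Rosenberg's probability of monophyly under random coalescence
#'
#' Probability that, under a null of random sequential pairwise coalescence
#' of exchangeable lineages, `a` lineages of one putative species and `b` of
#' its sister are observed as clades. The `"reciprocal"` variant requires
#' both groups monophyletic: R(1,1) = 1 and
#' R(i,j) = \[C(i,2) R(i-1,j) + C(j,2) R(i,j-1)\] / C(i+j,2).
#' The `"clade_A"` variant requires only the first group monophyletic:
#' M(1,j) = 1 and M(i,j) = \[C(i,2) M(i-1,j) + C(j,2) M(i,j-1)\] / C(i+j,2).
#' Small values reject the single-species null for the pair.
#'
#' @param a,b lineage counts (positive integers).
#' @param variant `"reciprocal"` (default; symmetric in a, b) or `"clade_A"`.
#' @return probability in \[0, 1\].
#' @export
rosenberg_pab <- function(a, b, variant = c("reciprocal", "clade_A")) {
  variant <- match.arg(variant)
  if (a < 1 || b < 1 || a != round(a) || b != round(b))
    stop("a and b must be positive integers")
  memo <- new.env(parent = emptyenv())
  recip <- variant == "reciprocal"
  f <- function(i, j) {
    if (recip && i == 1 && j == 1) return(1)
    if (!recip && i == 1) return(1)
    if (recip && (i == 0 || j == 0)) return(0)   # unreachable guard
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    tot <- choose(i + j, 2)
    p <- 0
    if (i >= 2) p <- p + choose(i, 2) * f(i - 1, j)
    if (j >= 2) p <- p + choose(j, 2) * f(i, j - 1)
    p <- p / tot
    memo[[key]] <- p
    p
  }
  # reciprocal variant: reduce boundary cases j == 1 via same recursion:
  # R(i,1) = C(i,2) R(i-1,1) / C(i+1,2); R(1,j) symmetric.
  f(a, b)
}

#' Intra/inter distance ratio for a pair of groups
#'
#' Mean of all within-group distinct-pair distances (pooling both groups)
#' divided by the mean of all cross-group distances. Small ratios indicate
#' tight, well-separated clusters.
#'
#' @param d a [dist_matrix()] (patristic or sequence distances).
#' @param ids_a,ids_b disjoint character vectors of member ids.
#' @return ratio (>= 0); `NA` with a warning if the inter mean is zero.
#' @export
intra_inter_ratio <- function(d, ids_a, ids_b) {
  if (length(intersect(ids_a, ids_b))) stop("groups must be disjoint")
  labs <- rownames(d)
  missing <- setdiff(c(ids_a, ids_b), labs)
  if (length(missing)) stop("ids not in matrix: ", paste(missing, collapse = ", "))
  within_vals <- c()
  for (ids in list(ids_a, ids_b)) {
    if (length(ids) >= 2L) {
      sub <- d[ids, ids, drop = FALSE]
      within_vals <- c(within_vals, sub[upper.tri(sub)])
    }
  }
  if (!length(within_vals))
    stop("need >= 2 members in at least one group for the intra term")
  inter_vals <- as.vector(d[ids_a, ids_b, drop = FALSE])
  intra <- mean(within_vals, na.rm = TRUE)
  inter <- mean(inter_vals, na.rm = TRUE)
  if (is.na(inter) || inter == 0) {
    warning("inter-group mean distance is zero or undefined; ratio undefined")
    return(NA_real_)
  }
  intra / inter
}

#' Leave-one-out probability of correct identification
#'
#' Each member of the focal group is scored correct when its nearest non-self
#' neighbour (smallest distance over all other individuals in the matrix) is
#' also in the focal group. Distance ties between a conspecific and a
#' non-conspecific neighbour are scored incorrect (conservative). Returns the
#' proportion with a normal-approximation 95% CI, p +/- 1.96 sqrt(p(1-p)/n),
#' truncated to \[0, 1\].
#'
#' @param d a [dist_matrix()].
#' @param groups a `group_map` covering the matrix labels.
#' @param focal focal group label (needs >= 2 members).
#' @return list with `prob`, `ci_low`, `ci_high`, `n`, `correct` (logical
#'   vector named by focal ids).
#' @export
prob_correct_id <- function(d, groups, focal) {
  labs <- rownames(d)
  g <- group_of(groups, labs)
  idx <- which(g == focal)
  if (length(idx) < 2L) stop("focal group '", focal, "' has fewer than 2 members")
  correct <- logical(length(idx))
  names(correct) <- labs[idx]
  for (k in seq_along(idx)) {
    i <- idx[k]
    dd <- d[i, ]
    dd[i] <- NA
    m <- min(dd, na.rm = TRUE)
    nearest <- which(!is.na(dd) & dd == m)
    # tie toward a non-conspecific counts as incorrect
    correct[k] <- all(g[nearest] == focal)
  }
  p <- mean(correct)
  se <- sqrt(p * (1 - p) / length(correct))
  list(prob = p,
       ci_low = max(0, p - 1.96 * se),
       ci_high = min(1, p + 1.96 * se),
       n = length(correct),
       correct = correct)
}

#' Species-delimitation report for clade pairs (Table-3 layout)
#'
#' For each pair of putative species: monophyly of each side and reciprocal
#' monophyly on the rooted tree; the intra/inter distance ratio; probability
#' of correct identification (with CI) for the first group; and Rosenberg's
#' probability. Following the convention of reporting `NA` for
#' non-monophyletic groups, `p_ab` is emitted only when the relevant
#' monophyly holds (`reciprocal` variant: both sides; `clade_A`: group A).
#'
#' @param tree rooted `phylo` whose tips cover all pair members.
#' @param d a [dist_matrix()]; by default patristic distances from `tree`
#'   are used when `d` is `NULL`.
#' @param groups a `group_map`.
#' @param pairs list of 2-element character vectors: (group A label, group B
#'   label).
#' @param pab_variant variant passed to [rosenberg_pab()].
#' @return data frame, one row per pair: `group_a`, `group_b`, `a`, `b`,
#'   `mono_a`, `mono_b`, `mono_reciprocal`, `intra_inter`, `prob_correct`,
#'   `ci_low`, `ci_high`, `p_ab`, `pab_variant`, `distance_mode`.
#' @export
delimit_report <- function(tree, d = NULL, groups, pairs,
                           pab_variant = c("reciprocal", "clade_A")) {
  pab_variant <- match.arg(pab_variant)
  if (is.null(d)) d <- patristic_distances(tree)
  rows <- lapply(pairs, function(pr) {
    ga <- pr[[1]]; gb <- pr[[2]]
    ids_a <- groups$id[groups$group == ga]
    ids_b <- groups$id[groups$group == gb]
    ids_a <- intersect(ids_a, tree$tip.label)
    ids_b <- intersect(ids_b, tree$tip.label)
    if (!length(ids_a) || !length(ids_b))
      stop("pair (", ga, ", ", gb, ") has an empty group on the tree")
    mono_a <- is_monophyletic(tree, ids_a)
    mono_b <- is_monophyletic(tree, ids_b)
    mono_rec <- mono_a && mono_b
    ii <- tryCatch(intra_inter_ratio(d, ids_a, ids_b),
                   error = function(e) NA_real_)
    sub_groups <- group_map(data.frame(
      id = c(ids_a, ids_b),
      group = c(rep(ga, length(ids_a)), rep(gb, length(ids_b))),
      stringsAsFactors = FALSE))
    pc <- tryCatch(prob_correct_id(d[c(ids_a, ids_b), c(ids_a, ids_b)] |>
                                     dist_matrix(dist_mode(d)),
                                   sub_groups, ga),
                   error = function(e) list(prob = NA_real_, ci_low = NA_real_,
                                            ci_high = NA_real_))
    relevant_mono <- if (pab_variant == "reciprocal") mono_rec else mono_a
    p_ab <- if (relevant_mono)
      rosenberg_pab(length(ids_a), length(ids_b), pab_variant)
    else NA_real_
    data.frame(group_a = ga, group_b = gb,
               a = length(ids_a), b = length(ids_b),
               mono_a = mono_a, mono_b = mono_b, mono_reciprocal = mono_rec,
               intra_inter = ii,
               prob_correct = pc$prob, ci_low = pc$ci_low, ci_high = pc$ci_high,
               p_ab = p_ab, pab_variant = pab_variant,
               distance_mode = dist_mode(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
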