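# Independent oracles, deliberately written without reference to the package
# internals they check.

# Exact probability of monophyly under random sequential pairwise
# coalescence, by full enumeration of labelled coalescent histories.
# Lineages are (n_from_A, n_from_B) pairs; every merge is uniform over the
# available pairs. A group is monophyletic iff at some point a lineage holds
# exactly all of that group and nothing else.
brute_force_pab <- function(a, b, variant = c("reciprocal", "clade_A")) {
  variant <- match.arg(variant)
  recurse <- function(lins, sawA, sawB) {
    k <- nrow(lins)
    if (k == 1L) {
      return(if (variant == "reciprocal") as.numeric(sawA && sawB)
             else as.numeric(sawA))
    }
    total <- 0
    npairs <- k * (k - 1) / 2
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      merged <- lins[i, ] + lins[j, ]
      rest <- lins[-c(i, j), , drop = FALSE]
      new_lins <- rbind(rest, merged)
      total <- total + recurse(
        new_lins,
        sawA || (merged[1] == a && merged[2] == 0),
        sawB || (merged[1] == 0 && merged[2] == b)) / npairs
    }
    total
  }
  lins <- rbind(matrix(c(1, 0), a, 2, byrow = TRUE),
                matrix(c(0, 1), b, 2, byrow = TRUE))
  recurse(lins, a == 1L, b == 1L)
}

# Per-column site-pattern classification by explicit enumeration.
oracle_site_patterns <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  n_valid <- 0L; ts <- 0L; tv <- 0L
  purines <- c("A", "G")
  for (i in seq_along(a)) {
    x <- a[i]; y <- b[i]
    if (x %in% c("A", "C", "G", "T") && y %in% c("A", "C", "G", "T")) {
      n_valid <- n_valid + 1L
      if (x != y) {
        if ((x %in% purines) == (y %in% purines)) ts <- ts + 1L
        else tv <- tv + 1L
      }
    }
  }
  list(n_valid = n_valid, ts = ts, tv = tv)
}

# K2P distance computed directly from the closed form on oracle counts.
oracle_k2p <- function(s1, s2, tv_only = FALSE) {
  cnt <- oracle_site_patterns(s1, s2)
  P <- cnt$ts / cnt$n_valid
  Q <- cnt$tv / cnt$n_valid
  if (tv_only) -0.5 * log(1 - 2 * Q)
  else -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# Random ACGT alignment with optional missing symbols, as a named vector.
random_seqs <- function(n, len, missing_prob = 0, seed = 1) {
  set.seed(seed)
  pool <- c("A", "C", "G", "T")
  miss <- c("-", "?", "N")
  vapply(seq_len(n), function(i) {
    chars <- sample(pool, len, replace = TRUE)
    if (missing_prob > 0) {
      hit <- runif(len) < missing_prob
      chars[hit] <- sample(miss, sum(hit), replace = TRUE)
    }
    paste(chars, collapse = "")
  }, character(1)) |> setNames(paste0("s", seq_len(n)))
}

# Related sequences: one uniform ancestor, each record independently
# substituted at sub_prob per site (so pairwise divergence ~ 2*sub_prob),
# far from K2P saturation.
related_seqs <- function(n, len, sub_prob = 0.05, missing_prob = 0, seed = 1) {
  set.seed(seed)
  pool <- c("A", "C", "G", "T")
  anc <- sample(pool, len, replace = TRUE)
  miss <- c("-", "?", "N")
  vapply(seq_len(n), function(i) {
    chars <- anc
    hit <- runif(len) < sub_prob
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(pool, b), 1), character(1))
    if (missing_prob > 0) {
      mhit <- runif(len) < missing_prob
      chars[mhit] <- sample(miss, sum(mhit), replace = TRUE)
    }
    paste(chars, collapse = "")
  }, character(1)) |> setNames(paste0("s", seq_len(n)))
}

# Patristic distance by explicit root-to-tip path vectors.
oracle_patristic <- function(tree, tip1, tip2) {
  edges <- tree$edge
  lens <- tree$edge.length
  path_to_root <- function(tip) {
    node <- match(tip, tree$tip.label)
    out <- numeric(0); names(out) <- character(0)
    while (TRUE) {
      e <- match(node, edges[, 2])
      if (is.na(e)) break
      out[as.character(e)] <- lens[e]
      node <- edges[e, 1]
    }
    out
  }
  p1 <- path_to_root(tip1); p2 <- path_to_root(tip2)
  shared <- intersect(names(p1), names(p2))
  sum(p1) + sum(p2) - 2 * sum(p1[shared])
}
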