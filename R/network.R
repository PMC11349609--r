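# Haplotype collapsing and parsimony-style haplotype networks.
# Columns with any gap/unknown/ambiguity in any sequence are removed
# globally before collapsing, matching the usual network-software treatment
# of missing data.

#' Drop alignment columns containing missing or ambiguous symbols
#'
#' Removes every column in which any sequence carries a symbol other than
#' plain A, C, G or T (so gaps `-`, `?`, `N`, and all IUPAC ambiguity codes).
#' Masking is global: one bad cell drops the column for all records.
#'
#' @param aln an [alignment()].
#' @return list with `alignment` (masked) and `retained_columns`
#'   (1-based indices into the original alignment).
#' @export
mask_uninformative_columns <- function(aln) {
  m <- alignment_matrix(aln)
  ok <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(ok)) stop("all columns contain missing/ambiguous symbols")
  kept <- which(ok)
  seqs <- apply(m[, kept, drop = FALSE], 1, paste, collapse = "")
  list(alignment = alignment(setNames(seqs, aln$ids), aln$locus_name),
       retained_columns = kept)
}

#' Collapse identical sequences into haplotypes
#'
#' Merges identical (masked) sequences and tallies per-group frequencies.
#' Node order is deterministic: decreasing total count, then sequence
#' lexicographic order; haplotype ids are `H1`, `H2`, ...
#'
#' @param aln a masked [alignment()] (see [mask_uninformative_columns()]).
#' @param groups a `group_map` covering the alignment ids.
#' @return data frame with `hap_id`, `sequence`, `total_count`, `member_ids`
#'   (semicolon-joined), plus one `n_<group>` count column per group label.
#' @export
collapse_haplotypes <- function(aln, groups) {
  g <- group_of(groups, aln$ids)
  glev <- sort(unique(groups$group))
  by_seq <- split(seq_along(aln$ids), unname(aln$seqs))
  seqs <- names(by_seq)
  counts <- vapply(by_seq, length, integer(1))
  ord <- order(-counts, seqs)
  by_seq <- by_seq[ord]; seqs <- seqs[ord]; counts <- counts[ord]
  df <- data.frame(hap_id = paste0("H", seq_along(seqs)),
                   sequence = seqs,
                   total_count = as.integer(counts),
                   member_ids = vapply(by_seq, function(ix)
                     paste(aln$ids[ix], collapse = ";"), character(1)),
                   stringsAsFactors = FALSE)
  for (gl in glev)
    df[[paste0("n_", gl)]] <- vapply(by_seq, function(ix)
      sum(g[ix] == gl), integer(1))
  rownames(df) <- NULL
  df
}

hamming_steps <- function(s1, s2) {
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  sum(a != b)
}

#' Build a parsimony-style haplotype network
#'
#' Minimum-spanning-network construction over haplotype Hamming distances:
#' candidate edges are sorted by mutational steps and added in nondecreasing
#' order; an edge is kept when its weight is within `epsilon` of the weight
#' at which its two endpoints' components first become connected. With
#' `epsilon = 0` this is the union of all minimum spanning trees, so tied
#' alternative connections appear as reticulations. Edges longer than
#' `max_steps` are never added (a configurable stand-in for a statistical
#' parsimony connection limit), so the network may be disconnected.
#'
#' @param haps haplotype table from [collapse_haplotypes()].
#' @param epsilon non-negative integer relaxation of the MST weight.
#' @param max_steps maximum allowed edge length in steps (`Inf` = unlimited).
#' @return list of class `haplotype_network`: `nodes` (the haplotype table)
#'   and `edges` (data frame `hap_a`, `hap_b`, `steps`).
#' @export
build_parsimony_network <- function(haps, epsilon = 0L, max_steps = Inf) {
  n <- nrow(haps)
  if (n < 1L) stop("need >= 1 haplotype")
  edges <- data.frame(hap_a = character(0), hap_b = character(0),
                      steps = integer(0), stringsAsFactors = FALSE)
  if (n >= 2L) {
    cand <- list()
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      w <- hamming_steps(haps$sequence[i], haps$sequence[j])
      cand[[length(cand) + 1L]] <- c(i, j, w)
    }
    cand <- do.call(rbind, cand)
    cand <- cand[cand[, 3] <= max_steps, , drop = FALSE]
    if (nrow(cand)) {
      cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
      # pass 1: weight class at which each node pair's components first
      # connect (bottleneck weight), via Kruskal over weight classes
      parent <- seq_len(n)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      first_connect <- matrix(Inf, n, n)
      for (w in sort(unique(cand[, 3]))) {
        roots_before <- vapply(seq_len(n), find, integer(1))
        grp <- cand[cand[, 3] == w, , drop = FALSE]
        for (k in seq_len(nrow(grp))) {
          i <- find(grp[k, 1]); j <- find(grp[k, 2])
          if (i != j) parent[i] <- j
        }
        roots_after <- vapply(seq_len(n), find, integer(1))
        newly <- outer(roots_before, roots_before, "!=") &
                 outer(roots_after, roots_after, "==")
        first_connect[newly & !is.finite(first_connect)] <- w
      }
      keep <- cand[, 3] <= first_connect[cbind(cand[, 1], cand[, 2])] + epsilon
      kept <- cand[keep, , drop = FALSE]
      if (nrow(kept))
        edges <- data.frame(hap_a = haps$hap_id[kept[, 1]],
                            hap_b = haps$hap_id[kept[, 2]],
                            steps = as.integer(kept[, 3]),
                            stringsAsFactors = FALSE)
    }
  }
  structure(list(nodes = haps, edges = edges,
                 epsilon = epsilon, max_steps = max_steps),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype_network>", nrow(x$nodes), "haplotypes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Number of connected components of a haplotype network
#' @param net a `haplotype_network`.
#' @return integer count.
#' @export
network_components <- function(net) {
  ids <- net$nodes$hap_id
  parent <- seq_along(ids)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(net$edges))) {
    i <- find(match(net$edges$hap_a[k], ids))
    j <- find(match(net$edges$hap_b[k], ids))
    if (i != j) parent[i] <- j
  }
  length(unique(vapply(seq_along(ids), find, integer(1))))
}

#' Write a haplotype network as plain-text node and edge tables
#' @param net a `haplotype_network`.
#' @param nodes_path,edges_path output CSV paths.
#' @return invisibly, `net`.
#' @export
write_network <- function(net, nodes_path, edges_path) {
  write.csv(net$nodes, nodes_path, row.names = FALSE)
  write.csv(net$edges, edges_path, row.names = FALSE)
  invisible(net)
}
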