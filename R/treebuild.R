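# Trees for delimitation without external inference: neighbor-joining,
# outgroup rooting, patristic distances. User-supplied Newick trees are
# first-class wherever a tree is consumed.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via ape). Negative branch lengths, which NJ can
#' produce on non-additive input, are clamped to zero; the total clamped
#' deficit is recorded in the `clamped_deficit` attribute.
#'
#' @param d a [dist_matrix()] with no undefined cells and >= 3 labels.
#' @return an unrooted `phylo` with all input labels as tips.
#' @export
neighbor_joining <- function(d) {
  if (nrow(d) < 3L) stop("need >= 3 labels for neighbor-joining")
  if (anyNA(d))
    stop("distance matrix has undefined cells; prune the affected labels first")
  tr <- ape::nj(as.dist(unclass(d)))
  neg <- tr$edge.length < 0
  deficit <- -sum(tr$edge.length[neg])
  tr$edge.length[neg] <- 0
  attr(tr, "clamped_deficit") <- deficit
  tr
}

#' Root a tree on the edge separating an outgroup
#'
#' Places the root on the edge that separates `outgroup_tips` from the rest,
#' splitting that edge's length equally, so the result has a degree-2 root.
#' The outgroup must be a single tip or a set forming one side of an edge of
#' the unrooted tree.
#'
#' @param tree a `phylo` (rooted input is unrooted first).
#' @param outgroup_tips character vector of tip labels.
#' @return rooted `phylo`.
#' @export
root_by_outgroup <- function(tree, outgroup_tips) {
  missing <- setdiff(outgroup_tips, tree$tip.label)
  if (length(missing))
    stop("outgroup tips not in tree: ", paste(missing, collapse = ", "))
  utree <- ape::unroot(tree)
  ntip <- ape::Ntip(utree)
  tipset <- function(node) {
    if (node <= ntip) utree$tip.label[node]
    else ape::extract.clade(utree, node)$tip.label
  }
  # the separating edge is the one whose child-side tip set equals the
  # outgroup or its complement
  sep <- NA_integer_
  for (e in seq_len(nrow(utree$edge))) {
    ts <- tipset(utree$edge[e, 2])
    if (setequal(ts, outgroup_tips) ||
        setequal(ts, setdiff(utree$tip.label, outgroup_tips))) {
      sep <- e
      break
    }
  }
  if (is.na(sep)) stop("outgroup not monophyletic in unrooted tree")
  phytools::reroot(utree, utree$edge[sep, 2],
                   position = utree$edge.length[sep] / 2)
}

#' Patristic (path-length) distances between all tips
#' @param tree a `phylo` with branch lengths.
#' @return a `dist_matrix` with mode `"patristic"`.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  dist_matrix(ape::cophenetic.phylo(tree), "patristic")
}
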