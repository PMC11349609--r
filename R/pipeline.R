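# Orchestration: run every stage of the analysis from a single config list
# (or YAML file) and write tables plus a reproducibility manifest.

#' Run the full delimitation + morphometrics analysis
#'
#' Drives the whole pipeline from a configuration: per-locus K2P distance
#' matrices and group summaries, divergence dating, haplotype networks,
#' neighbor-joining (or user-supplied) trees with a delimitation report, and
#' the morphometric pipeline. Stages whose inputs are absent from the config
#' are skipped with a notice. All outputs are plain-text tables under
#' `out_dir`; a `manifest.yaml` records parameters and seeds.
#'
#' @param config list (or path to a YAML file) with optional blocks:
#'   \describe{
#'     \item{loci}{named list: locus -> FASTA path (or `alignment` objects).}
#'     \item{groups}{path to a group table, or a `group_map`.}
#'     \item{tree}{optional Newick path or `phylo`; otherwise NJ is built
#'       from the first locus.}
#'     \item{outgroup}{optional tip labels used to root the tree.}
#'     \item{dist_mode}{`"k2p_all"` (default) or `"k2p_tv"` per locus
#'       (named vector recycled).}
#'     \item{dating}{list: `mode` ("rate"/"springer"), `rate`.}
#'     \item{pairs}{list of 2-vectors of group labels for delimitation.}
#'     \item{network}{list: `epsilon`, `max_steps`.}
#'     \item{morpho}{path to a measurement CSV or a `morpho_table`, plus
#'       optional `params` passed to [run_morpho_pipeline()].}
#'     \item{seed}{integer master seed (default 1).}
#'   }
#' @param out_dir output directory.
#' @return invisibly, a list of all in-memory results.
#' @export
run_full_analysis <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  results <- list()
  note <- function(...) message("[run_full_analysis] ", ...)

  groups <- NULL
  if (!is.null(config$groups)) {
    groups <- if (inherits(config$groups, "group_map")) config$groups
              else read_group_map(config$groups)
  }

  if (!is.null(config$loci)) {
    if (is.null(groups)) stop("sequence analyses need a 'groups' block")
    dmodes <- config$dist_mode
    if (is.null(dmodes)) dmodes <- "k2p_all"
    loci <- names(config$loci)
    results$loci <- list()
    for (i in seq_along(loci)) {
      locus <- loci[i]
      aln <- config$loci[[i]]
      if (!inherits(aln, "alignment"))
        aln <- read_fasta_alignment(aln, locus_name = locus)
      mode <- if (length(dmodes) >= i) dmodes[[i]] else dmodes[[1]]
      d <- pairwise_matrix(aln, mode)
      summ <- group_summary(d, groups, as_percent = TRUE)
      write_dist_matrix(d,
        file.path(out_dir, paste0(locus, "_dist.tsv")),
        file.path(out_dir, paste0(locus, "_dist_long.csv")))
      write.csv(summ, file.path(out_dir, paste0(locus, "_group_summary.csv")),
                row.names = FALSE)
      dating_cfg <- config$dating
      dmode <- if (!is.null(dating_cfg$mode)) dating_cfg$mode
               else if (mode == "k2p_tv") "springer" else "rate"
      rate <- if (!is.null(dating_cfg$rate)) dating_cfg$rate else 2.1
      dated <- date_group_summary(summ, dmode, rate)
      write.csv(dated, file.path(out_dir, paste0(locus, "_dating.csv")),
                row.names = FALSE)
      net_cfg <- config$network
      masked <- tryCatch(mask_uninformative_columns(aln),
                         error = function(e) { note(locus, ": network skipped (",
                                                    conditionMessage(e), ")"); NULL })
      net <- NULL
      if (!is.null(masked)) {
        haps <- collapse_haplotypes(masked$alignment, groups)
        net <- build_parsimony_network(
          haps,
          epsilon = if (is.null(net_cfg$epsilon)) 0L else net_cfg$epsilon,
          max_steps = if (is.null(net_cfg$max_steps)) Inf else net_cfg$max_steps)
        write_network(net,
          file.path(out_dir, paste0(locus, "_hap_nodes.csv")),
          file.path(out_dir, paste0(locus, "_hap_edges.csv")))
      }
      results$loci[[locus]] <- list(alignment = aln, dist = d, summary = summ,
                                    dating = dated, network = net)
    }

    first <- results$loci[[1]]
    tree <- config$tree
    if (is.null(tree)) {
      tree <- neighbor_joining(first$dist)
      if (!is.null(config$outgroup))
        tree <- root_by_outgroup(tree, config$outgroup)
      else
        tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
    } else if (is.character(tree)) {
      tree <- read_newick(tree)
    }
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    results$tree <- tree
    if (!is.null(config$pairs)) {
      report <- delimit_report(tree, d = NULL, groups = groups,
                               pairs = config$pairs)
      write.csv(report, file.path(out_dir, "delimitation_report.csv"),
                row.names = FALSE)
      results$delimitation <- report
    }
  } else note("no 'loci' block: sequence analyses skipped")

  if (!is.null(config$morpho)) {
    mt <- config$morpho
    if (is.character(mt)) mt <- read_morpho_table(mt)
    params <- config$morpho_params
    if (is.null(params)) params <- list()
    params$table <- mt
    if (is.null(params$seed)) params$seed <- seed
    mres <- do.call(run_morpho_pipeline, params)
    write.csv(mres$tests, file.path(out_dir, "morpho_tests.csv"),
              row.names = FALSE)
    write.csv(data.frame(component = seq_along(mres$pca_raw$variance_fraction),
                         variance_fraction = mres$pca_raw$variance_fraction),
              file.path(out_dir, "morpho_pca_variance.csv"), row.names = FALSE)
    write.csv(mres$knn_raw$per_group,
              file.path(out_dir, "morpho_knn_raw.csv"), row.names = FALSE)
    write.csv(mres$knn_shape$per_group,
              file.path(out_dir, "morpho_knn_shape.csv"), row.names = FALSE)
    write.csv(mres$descriptives, file.path(out_dir, "morpho_descriptives.csv"),
              row.names = FALSE)
    if (!is.null(mres$upgma))
      write_newick(mres$upgma, file.path(out_dir, "morpho_upgma.nwk"))
    results$morpho <- mres
  } else note("no 'morpho' block: morphometrics skipped")

  manifest <- list(
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("specdelim")),
    config = rapply(config, function(x)
      if (is.character(x) || is.numeric(x) || is.logical(x)) x else
        paste(class(x), collapse = "/"), how = "replace"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(results)
}
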