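# Seeded generators for sequence alignments under a K2P substitution
# process on a species tree, and morphometric tables with multiplicative
# group size factors — the statistical structure the delimitation and
# morphometric analyses assume.

#' Species tree for a two-clade, four-population study design
#'
#' Four populations (WA, NT in one clade; Qld, PNG in the other) with a deep
#' split between the clades and shallow splits within. Branch lengths are in
#' million years on the pairwise scale: the patristic distance between two
#' population tips equals their pairwise divergence time.
#'
#' @param deep_time pairwise divergence time between the clades (My).
#' @param shallow_time pairwise divergence time within each clade (My).
#' @return `phylo` with tips WA, NT, Qld, PNG.
#' @export
two_clade_species_tree <- function(deep_time = 3.9, shallow_time = 1.0) {
  stopifnot(deep_time > shallow_time, shallow_time >= 0)
  half_deep <- deep_time / 2
  half_shal <- shallow_time / 2
  txt <- sprintf("((WA:%g,NT:%g):%g,(Qld:%g,PNG:%g):%g);",
                 half_shal, half_shal, half_deep - half_shal,
                 half_shal, half_shal, half_deep - half_shal)
  ape::read.tree(text = txt)
}

#' Configuration for the sequence simulator
#'
#' @param groups data frame with `label` and `n` (samples per group); labels
#'   must match the species-tree tips.
#' @param species_tree `phylo` on the group labels, branch lengths in My;
#'   patristic distance = pairwise divergence time.
#' @param pairwise_rate pairwise divergence rate, percent per My
#'   (default 2.1).
#' @param within_group_time pairwise divergence time between conspecific
#'   samples (My); each sample sits on a star branch of half this time.
#' @param length alignment columns.
#' @param kappa transition/transversion rate ratio (default 4).
#' @param seed integer seed.
#' @return list of class `seq_sim_config`.
#' @export
seq_sim_config <- function(groups, species_tree, pairwise_rate = 2.1,
                           within_group_time = 0.3, length = 1000L,
                           kappa = 4, seed = 1L) {
  stopifnot(all(c("label", "n") %in% names(groups)),
            pairwise_rate > 0, within_group_time >= 0,
            length >= 1L, kappa > 0)
  if (!setequal(groups$label, species_tree$tip.label))
    stop("group labels must match species-tree tips")
  structure(list(groups = groups, species_tree = species_tree,
                 pairwise_rate = pairwise_rate,
                 within_group_time = within_group_time,
                 length = as.integer(length), kappa = kappa,
                 seed = as.integer(seed)),
            class = "seq_sim_config")
}

# K80 transition-probability matrix for branch length d (expected
# substitutions/site) and transition/transversion rate ratio kappa.
k2p_prob_matrix <- function(d, kappa) {
  beta <- 1 / (kappa + 2)          # rates scaled so alpha + 2 beta = 1
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1         # each of the two transversion targets
  bases <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", C = "T", G = "A", T = "C")
  P <- matrix(p_tv, 4, 4, dimnames = list(bases, bases))
  diag(P) <- p_same
  for (b in bases) P[b, ts_partner[b]] <- p_ts
  P
}

evolve_states <- function(states, d, kappa) {
  if (d <= 0) return(states)
  P <- k2p_prob_matrix(d, kappa)
  bases <- c("A", "C", "G", "T")
  out <- states
  for (b in bases) {
    idx <- which(states == b)
    if (length(idx))
      out[idx] <- sample(bases, length(idx), replace = TRUE, prob = P[b, ])
  }
  out
}

#' Simulate a multi-population alignment under a K2P process
#'
#' Evolves each site independently along the species tree and then along
#' per-sample star branches. Branch lengths are converted so that the
#' expected pairwise K2P distance between two samples equals
#' `pairwise_rate/100` times their pairwise divergence time: a between-group
#' pair diverges `rate x T_split` and a within-group pair
#' `rate x within_group_time`. Root states are uniform on ACGT; output is
#' deterministic given the seed.
#'
#' @param cfg a [seq_sim_config()].
#' @return list: `alignment` (an [alignment()]), `groups` (a `group_map`
#'   with `population` = group), `truth` (generating parameters).
#' @export
simulate_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "seq_sim_config"))
  set.seed(cfg$seed)
  tr <- stats::reorder(cfg$species_tree, "cladewise")  # parents before children
  per_my <- cfg$pairwise_rate / 100   # pairwise substitutions/site per My
  w_half <- cfg$within_group_time / 2
  # subtract the star half-time from terminal edges so cross-group pairwise
  # expectation stays rate x patristic time
  edge_my <- tr$edge.length
  tip_edges <- match(seq_along(tr$tip.label), tr$edge[, 2])
  if (any(edge_my[tip_edges] < w_half))
    stop("within_group_time too large for the species tree's terminal edges")
  edge_my[tip_edges] <- edge_my[tip_edges] - w_half
  L <- cfg$length
  n_node <- ape::Ntip(tr) + tr$Nnode
  states <- vector("list", n_node)
  root <- ape::Ntip(tr) + 1L
  states[[root]] <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    states[[child]] <- evolve_states(states[[par]], edge_my[e] * per_my,
                                     cfg$kappa)
  }
  seqs <- character(0); ids <- character(0); grp <- character(0)
  for (r in seq_len(nrow(cfg$groups))) {
    lab <- cfg$groups$label[r]
    anc <- states[[match(lab, tr$tip.label)]]
    for (s in seq_len(cfg$groups$n[r])) {
      tip_states <- evolve_states(anc, w_half * per_my, cfg$kappa)
      ids <- c(ids, sprintf("%s_%02d", lab, s))
      seqs <- c(seqs, paste(tip_states, collapse = ""))
      grp <- c(grp, lab)
    }
  }
  names(seqs) <- ids
  list(alignment = alignment(seqs, locus_name = "simulated"),
       groups = group_map(data.frame(id = ids, group = grp,
                                     population = grp,
                                     stringsAsFactors = FALSE)),
       truth = list(pairwise_rate = cfg$pairwise_rate,
                    within_group_time = cfg$within_group_time,
                    kappa = cfg$kappa, seed = cfg$seed,
                    species_tree = ape::write.tree(tr)))
}

#' Configuration for the morphometric simulator
#'
#' @param groups data frame with `label`, `n`, `size_factor` (multiplicative
#'   group size, 1 = baseline).
#' @param variable_base_means positive baseline means (mm) per variable;
#'   names become variable names (default: 8 skull-like measurements).
#' @param cv_noise per-cell lognormal noise CV (default 0.03).
#' @param ind_size_cv per-individual lognormal size-deviate CV
#'   (default 0.05).
#' @param missing_rate MCAR cell deletion probability (default 0).
#' @param n_correlated_clones near-duplicate variables appended (for
#'   correlation-pruning exercises; default 0).
#' @param seed integer seed.
#' @return list of class `morpho_sim_config`.
#' @export
morpho_sim_config <- function(groups,
                              variable_base_means = c(BL = 25, NL = 10,
                                                      FL = 9, RWP = 7,
                                                      IOW = 5.5, ZW = 15,
                                                      UIL = 2.5, PML = 5.8),
                              cv_noise = 0.03, ind_size_cv = 0.05,
                              missing_rate = 0, n_correlated_clones = 0L,
                              seed = 1L) {
  stopifnot(all(c("label", "n", "size_factor") %in% names(groups)),
            all(groups$size_factor > 0), all(variable_base_means > 0),
            cv_noise >= 0, ind_size_cv >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(list(groups = groups, variable_base_means = variable_base_means,
                 cv_noise = cv_noise, ind_size_cv = ind_size_cv,
                 missing_rate = missing_rate,
                 n_correlated_clones = as.integer(n_correlated_clones),
                 seed = as.integer(seed)),
            class = "morpho_sim_config")
}

#' Simulate a morphometric measurement table
#'
#' Cell value = base mean x group size factor x individual lognormal size
#' deviate x independent lognormal noise. Optional near-clone variables are
#' appended (each a fresh low-noise copy of the first variable), and cells
#' are deleted completely at random at `missing_rate`. Deterministic given
#' the seed.
#'
#' @param cfg a [morpho_sim_config()].
#' @return list: `table` (a `morpho_table`), `truth` (generating
#'   parameters).
#' @export
simulate_morphotable <- function(cfg) {
  stopifnot(inherits(cfg, "morpho_sim_config"))
  set.seed(cfg$seed)
  mu <- cfg$variable_base_means
  p <- length(mu)
  vnames <- names(mu)
  if (is.null(vnames)) vnames <- paste0("V", seq_len(p))
  sd_noise <- sqrt(log(1 + cfg$cv_noise^2))
  sd_size <- sqrt(log(1 + cfg$ind_size_cv^2))
  rows <- list(); ids <- character(0); grp <- character(0)
  for (r in seq_len(nrow(cfg$groups))) {
    lab <- cfg$groups$label[r]
    for (s in seq_len(cfg$groups$n[r])) {
      size_dev <- exp(rnorm(1, -sd_size^2 / 2, sd_size))
      noise <- exp(rnorm(p, -sd_noise^2 / 2, sd_noise))
      vals <- mu * cfg$groups$size_factor[r] * size_dev * noise
      rows[[length(rows) + 1L]] <- vals
      ids <- c(ids, sprintf("%s_%02d", lab, s))
      grp <- c(grp, lab)
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- vnames
  if (cfg$n_correlated_clones > 0L) {
    for (ci in seq_len(cfg$n_correlated_clones)) {
      clone <- m[, 1] * exp(rnorm(nrow(m), 0, 0.002))
      m <- cbind(m, clone)
      colnames(m)[ncol(m)] <- paste0(vnames[1], "_clone", ci)
    }
  }
  if (cfg$missing_rate > 0) {
    del <- matrix(runif(length(m)) < cfg$missing_rate, nrow(m))
    m[del] <- NA
  }
  df <- data.frame(id = ids, group = grp, as.data.frame(m),
                   stringsAsFactors = FALSE, check.names = FALSE)
  list(table = morpho_table(df),
       truth = list(groups = cfg$groups, cv_noise = cfg$cv_noise,
                    ind_size_cv = cfg$ind_size_cv,
                    missing_rate = cfg$missing_rate, seed = cfg$seed))
}

#' Write the canonical synthetic study to disk
#'
#' A small end-to-end fixture mirroring a two-clade, four-population design:
#' a FASTA alignment and group TSV with a deep split between {WA, NT} and
#' {Qld, PNG} and shallow splits within, and a morphometric CSV with one
#' small-bodied group and two equal-sized groups. True generating parameters
#' go to a flat YAML.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed.
#' @param length alignment columns (default 2000).
#' @param n_per_group samples per population (default 8).
#' @return named list of file paths, invisibly; also returns the simulated
#'   objects in `$objects`.
#' @export
write_fixture_set <- function(out_dir, seed = 1L, length = 2000L,
                              n_per_group = 8L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- seq_sim_config(
    groups = data.frame(label = c("WA", "NT", "Qld", "PNG"),
                        n = rep(n_per_group, 4), stringsAsFactors = FALSE),
    species_tree = two_clade_species_tree(3.9, 1.0),
    pairwise_rate = 2.1, within_group_time = 0.3,
    length = length, kappa = 4, seed = seed)
  sim <- simulate_alignment(scfg)
  # short, shallow "network locus": population structure is recent enough
  # that haplotype sharing between populations of the same clade occurs;
  # one cross-population identical pair per clade is built in directly,
  # emulating the shared haplotypes real shallow loci show
  ncfg <- seq_sim_config(
    groups = scfg$groups, species_tree = two_clade_species_tree(3.9, 0.2),
    pairwise_rate = 2.1, within_group_time = 0.1,
    length = 400L, kappa = 4, seed = seed + 2L)
  nsim <- simulate_alignment(ncfg)
  net_seqs <- nsim$alignment$seqs
  net_seqs[paste0("NT_", formatC(1, width = 2, flag = "0"))] <-
    net_seqs[paste0("WA_", formatC(1, width = 2, flag = "0"))]
  net_seqs[paste0("PNG_", formatC(1, width = 2, flag = "0"))] <-
    net_seqs[paste0("Qld_", formatC(1, width = 2, flag = "0"))]
  net_aln <- alignment(net_seqs, locus_name = "network_locus")
  mcfg <- morpho_sim_config(
    groups = data.frame(label = c("small", "bigA", "bigB"),
                        n = c(19, 7, 7),
                        size_factor = c(0.85, 1.0, 1.0),
                        stringsAsFactors = FALSE),
    # 6% per-variable noise keeps inter-variable correlations below the
    # 0.90 pruning threshold (only the deliberate clones exceed it)
    cv_noise = 0.06,
    missing_rate = 0.05, n_correlated_clones = 1L, seed = seed + 1L)
  msim <- simulate_morphotable(mcfg)
  paths <- list(
    fasta = file.path(out_dir, "alignment.fasta"),
    fasta_network = file.path(out_dir, "network_locus.fasta"),
    groups = file.path(out_dir, "groups.tsv"),
    morpho = file.path(out_dir, "morpho.csv"),
    truth = file.path(out_dir, "truth.yaml"))
  write_fasta_alignment(sim$alignment, paths$fasta)
  write_fasta_alignment(net_aln, paths$fasta_network)
  write.table(as.data.frame(sim$groups), paths$groups, sep = "\t",
              quote = FALSE, row.names = FALSE)
  mm <- msim$table
  write.csv(mm, paths$morpho, row.names = FALSE, na = "")
  yaml::write_yaml(list(
    seed = seed,
    deep_split_my = 3.9, shallow_split_my = 1.0,
    pairwise_rate_percent_per_my = 2.1, within_group_time_my = 0.3,
    alignment_length = length, kappa = 4,
    morpho_size_factors = setNames(as.list(mcfg$groups$size_factor),
                                   mcfg$groups$label)), paths$truth)
  paths$objects <- list(seq = sim, network = list(alignment = net_aln,
                                                  groups = nsim$groups),
                        morpho = msim)
  invisible(paths)
}
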