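test_that("monophyly is exact descendant-set equality", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  expect_true(is_monophyletic(tr, c("a", "b")))
  expect_false(is_monophyletic(tr, c("a", "c")))
  expect_true(is_monophyletic(tr, c("a", "b", "c")))   # full set = root
  expect_true(is_monophyletic(tr, "c"))                # singleton
  expect_error(is_monophyletic(tr, "zz"), "not in tree")
})

test_that("Rosenberg probabilities equal brute-force coalescent enumeration", {
  expect_equal(rosenberg_pab(1, 1), 1)
  expect_equal(rosenberg_pab(2, 1), 1 / 3)
  expect_equal(rosenberg_pab(2, 2), 1 / 9)
  expect_equal(rosenberg_pab(2, 2, "clade_A"), 2 / 9)
  for (a in 1:6) for (b in 1:(7 - a)) {
    expect_equal(rosenberg_pab(a, b), brute_force_pab(a, b),
                 tolerance = 1e-12,
                 label = sprintf("reciprocal a=%d b=%d", a, b))
    expect_equal(rosenberg_pab(a, b, "clade_A"),
                 brute_force_pab(a, b, "clade_A"),
                 tolerance = 1e-12,
                 label = sprintf("clade_A a=%d b=%d", a, b))
  }
})

test_that("Rosenberg probability is monotone and variant-ordered", {
  grid <- expand.grid(a = 1:8, b = 1:8)
  p <- matrix(mapply(rosenberg_pab, grid$a, grid$b), 8, 8)
  expect_true(all(diff(p) <= 1e-14))        # non-increasing in a
  expect_true(all(diff(t(p)) <= 1e-14))     # non-increasing in b
  expect_equal(p, t(p), tolerance = 1e-14)  # reciprocal variant symmetric
  pa <- matrix(mapply(function(a, b) rosenberg_pab(a, b, "clade_A"),
                      grid$a, grid$b), 8, 8)
  expect_true(all(p <= pa + 1e-14))
  expect_error(rosenberg_pab(0, 2), "positive")
})

test_that("intra/inter ratio matches hand and brute-force computation", {
  # intra all 1, inter all 2 -> 0.5
  m <- matrix(2, 4, 4, dimnames = list(c("a1", "a2", "b1", "b2"),
                                       c("a1", "a2", "b1", "b2")))
  m["a1", "a2"] <- m["a2", "a1"] <- 1
  m["b1", "b2"] <- m["b2", "b1"] <- 1
  diag(m) <- 0
  d <- dist_matrix(m, "patristic")
  expect_equal(intra_inter_ratio(d, c("a1", "a2"), c("b1", "b2")), 0.5)
  # identical within-group sequences -> ratio 0
  m0 <- m; m0["a1", "a2"] <- m0["a2", "a1"] <- 0
  m0["b1", "b2"] <- m0["b2", "b1"] <- 0
  expect_equal(intra_inter_ratio(dist_matrix(m0, "patristic"),
                                 c("a1", "a2"), c("b1", "b2")), 0)
  # random fixture vs explicit enumeration
  set.seed(21)
  n <- 7
  rm <- matrix(runif(n * n), n)
  rm <- rm + t(rm); diag(rm) <- 0
  rownames(rm) <- colnames(rm) <- paste0("x", 1:n)
  drm <- dist_matrix(rm, "euclidean")
  ia <- paste0("x", 1:3); ib <- paste0("x", 4:7)
  within <- c(rm[cbind(c("x1","x1","x2"), c("x2","x3","x3"))],
              rm[cbind(c("x4","x4","x4","x5","x5","x6"),
                       c("x5","x6","x7","x6","x7","x7"))])
  inter <- as.vector(rm[ia, ib])
  expect_equal(intra_inter_ratio(drm, ia, ib), mean(within) / mean(inter),
               tolerance = 1e-12)
  expect_error(intra_inter_ratio(drm, c("x1", "x2"), c("x1", "x4")),
               "disjoint")
})

test_that("probability of correct identification is LOO nearest-neighbour", {
  # two tight, well-separated clusters -> 1.0
  pts <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  ids <- paste0("p", 1:6)
  m <- as.matrix(dist(pts)); rownames(m) <- colnames(m) <- ids
  gm <- group_map(data.frame(id = ids, group = rep(c("A", "B"), each = 3)))
  d <- dist_matrix(m, "euclidean")
  res <- prob_correct_id(d, gm, "A")
  expect_equal(res$prob, 1)
  expect_equal(res$ci_high, 1)
  # 8-specimen fixture, one focal individual nearest the other group -> 5/6
  pts2 <- c(0, 1, 2, 3, 4, 19, 20, 21)
  ids2 <- paste0("q", 1:8)
  m2 <- as.matrix(dist(pts2)); rownames(m2) <- colnames(m2) <- ids2
  gm2 <- group_map(data.frame(id = ids2,
                              group = c(rep("F", 6), rep("O", 2))))
  res2 <- prob_correct_id(dist_matrix(m2, "euclidean"), gm2, "F")
  expect_equal(res2$prob, 5 / 6)
  p <- 5 / 6
  expect_equal(res2$ci_low, p - 1.96 * sqrt(p * (1 - p) / 6), tolerance = 1e-12)
  expect_equal(res2$ci_high, min(1, p + 1.96 * sqrt(p * (1 - p) / 6)),
               tolerance = 1e-12)
  expect_error(prob_correct_id(d, gm, "Z"), "fewer than 2|focal")
})

test_that("delimitation report wires monophyly, ratios and P_AB together", {
  sim <- simulate_alignment(seq_sim_config(
    data.frame(label = c("WA", "NT", "Qld", "PNG"), n = rep(5, 4)),
    two_clade_species_tree(3.9, 1.0), length = 2000, seed = 5))
  d <- pairwise_matrix(sim$alignment)
  g <- sim$groups
  g$group <- ifelse(g$population %in% c("WA", "NT"), "west", "east")
  gm <- group_map(as.data.frame(g)[, c("id", "group")])
  tr <- neighbor_joining(d)
  west <- gm$id[gm$group == "west"]
  tr <- root_by_outgroup(tr, west)
  rep <- delimit_report(tr, d = NULL, groups = gm,
                        pairs = list(c("west", "east")))
  expect_true(rep$mono_reciprocal)
  expect_lt(rep$intra_inter, 0.5)
  expect_equal(rep$prob_correct, 1)
  expect_lt(rep$p_ab, 0.05)
  expect_equal(rep$p_ab, rosenberg_pab(10, 10))
  # sequence-distance variant also works
  rep2 <- delimit_report(tr, d = d, groups = gm,
                         pairs = list(c("west", "east")))
  expect_equal(rep2$distance_mode, "k2p_all")
  expect_true(rep2$mono_reciprocal)
  # shuffled labels: monophyly collapses and P_AB becomes NA
  set.seed(99)
  gm_shuf <- gm
  gm_shuf$group <- sample(gm$group)
  rep3 <- delimit_report(tr, d = NULL, groups = gm_shuf,
                         pairs = list(c("west", "east")))
  expect_false(rep3$mono_reciprocal)
  expect_true(is.na(rep3$p_ab))
})
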