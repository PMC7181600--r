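test_that("GTOM closed forms and oracle equivalence", {
  # triangle: all off-diagonal (1+1)/(2+1-1) = 1
  t_tri <- gtom(bone_network(complete_graph(3)))
  expect_true(all(t_tri == 1))
  # path: t(a,b) = 1, t(a,c) = 0.5
  t_path <- gtom(bone_network(path_graph()))
  expect_equal(t_path["a_M", "b_M"], 1)
  expect_equal(t_path["a_M", "c_M"], 0.5)
  # complete graph: all ones
  expect_true(all(gtom(bone_network(complete_graph(6))) == 1))
  # brute-force shared-neighbour oracle on graphs up to 12 nodes
  set.seed(3)
  for (rep in 1:25) {
    m <- random_connected_adj(sample(4:12, 1))
    t1 <- gtom(bone_network(m))
    expect_equal(unname(t1[, ]), oracle_gtom1(m), ignore_attr = TRUE)
    expect_true(all(t1 >= 0 & t1 <= 1))
    expect_equal(t1, t(t1), ignore_attr = TRUE)
  }
})

test_that("higher-order GTOM uses m-step neighbourhoods", {
  # path a-b-c-d-e: with m=2 the ends a,e reach {b,c} and {c,d}
  m <- path_graph(sprintf("p%d_M", 1:5))
  t2 <- gtom(bone_network(m), m = 2)
  # a: N2={b,c}, c: N2={a,b,d,e}; shared {b}, a_ac=0 -> 1/(2+1) = 1/3
  expect_equal(t2["p1_M", "p3_M"], 1 / 3)
  expect_error(gtom(bone_network(m), m = 0))
})

test_that("isolated nodes make GTOM degenerate", {
  m <- adj(3)
  m[1, 2] <- m[2, 1] <- 1
  expect_error(gtom(bone_network(m, require_connected = FALSE)),
               "isolated")
})

test_that("ward clustering merges cliques before bridges", {
  m <- two_cliques(3)
  net <- bone_network(m)
  d <- 1 - gtom(net)
  h <- ward_cluster(d)
  # every merge before the final one stays within a single clique, so the
  # two-cluster cut is exactly the two cliques
  cut2 <- cutree(h, k = 2)
  expect_equal(length(unique(cut2[rownames(m)[1:3]])), 1)
  expect_equal(length(unique(cut2[rownames(m)[4:6]])), 1)
  expect_false(cut2[[1]] == cut2[[6]])
  expect_true(all(diff(h$height) >= -1e-12))
  expect_error(ward_cluster(matrix(c(0, NA, NA, 0), 2)), "symmetric|NA")
})

test_that("Q-optimal cut maximizes Newman modularity over all cuts", {
  # two disconnected 3-cliques: Q_max = 2 * (3/6 - (6/12)^2) = 0.5
  net <- bone_network(two_cliques(3, bridge = FALSE),
                      require_connected = FALSE)
  qm <- q_modules(net)
  expect_equal(qm$q, 0.5)
  expect_equal(qm$n_modules, 2)

  # single clique: 1 module, Q_max = 0
  qc <- q_modules(bone_network(complete_graph(5)))
  expect_equal(qc$q, 0)
  expect_equal(qc$n_modules, 1)

  # every <=10-node graph: Q at the returned cut equals the brute-force
  # recomputation, and is >= Q of every other dendrogram cut
  set.seed(21)
  for (rep in 1:20) {
    m <- random_connected_adj(sample(5:10, 1))
    net <- bone_network(m)
    dendro <- ward_cluster(1 - gtom(net))
    qm <- q_modules(net, dendro)
    expect_equal(qm$q, oracle_newman_q(m, qm$assignment))
    labs <- rownames(m)
    for (k in seq_len(nrow(m))) {
      mem <- cutree(dendro, k = k)[labs]
      expect_lte(oracle_newman_q(m, mem), qm$q + 1e-12)
    }
  }
})

test_that("S-modules: cliques significant, complete graph not", {
  # two 5-cliques joined by one bridge: both cliques significant
  net <- bone_network(two_cliques(5))
  s <- s_modules(net)
  expect_equal(s$count, 2)
  # complete graph: no S-modules at all
  s0 <- s_modules(bone_network(complete_graph(8)))
  expect_equal(s0$count, 0)
  expect_true(all(s0$p_values >= 0.05))
})

test_that("planted modules are recovered as S-modules across seeds", {
  hits <- 0
  n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    sk <- make_skull(skull_template(n_pairs = 12, n_midline = 3,
                                    n_modules = 3, p_in = 0.9,
                                    p_out = 0.05, seed = seed))
    s <- s_modules(sk)
    if (s$count == 3) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("planted partitions are recovered by the Q-optimal cut", {
  skip_if_not_installed("mclust")
  hits <- 0
  n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    tpl <- skull_template(n_pairs = 13, n_midline = 4, n_modules = 3,
                          p_in = 0.9, p_out = 0.03, seed = seed)
    sk <- make_skull(tpl)
    qm <- q_modules(sk)
    truth <- tpl$module_plan[names(qm$assignment)]
    ari <- mclust::adjustedRandIndex(qm$assignment, truth)
    if (ari == 1) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("parcellation closed forms and bounds", {
  expect_equal(parcellation(rep(1, 7)), 0)
  expect_equal(parcellation(rep(1:2, each = 5)), 0.5)
  expect_equal(parcellation(rep(1:3, c(6, 3, 1))), 0.54)
  # relabeling invariance and upper bound
  set.seed(2)
  for (rep in 1:10) {
    mem <- sample(1:4, 20, replace = TRUE)
    relab <- c(9, 5, 7, 3)[mem]
    expect_equal(parcellation(mem), parcellation(relab))
    k <- length(unique(mem))
    expect_lte(parcellation(mem), 1 - 1 / k + 1e-12)
    expect_gte(parcellation(mem), 0)
  }
})

test_that("asymmetry counts split left/right pairs", {
  labels <- parse_bone_labels(c("pmx_L", "pmx_R", "max_L", "max_R", "pa_M"))
  same <- c(pmx_L = 1, pmx_R = 1, max_L = 2, max_R = 2, pa_M = 1)
  expect_equal(asymmetry_score(same, labels), 0)
  split <- c(pmx_L = 1, pmx_R = 2, max_L = 2, max_R = 2, pa_M = 1)
  expect_equal(asymmetry_score(split, labels), 1)
})

test_that("unpaired-bone deletion yields a mirror-consistent partition", {
  # the deletion experiment: after removing midline bones from a
  # mirror-symmetric skull, the module distribution is identical on the
  # left and right sides (the partition maps onto itself under L<->R)
  for (seed in c(4, 11, 23)) {
    sk <- make_skull(skull_template(n_pairs = 12, n_midline = 4,
                                    n_modules = 3, p_in = 0.9,
                                    p_out = 0.03, seed = seed))
    d <- suppressWarnings(drop_unpaired(sk))
    mod <- skull_modules(d)
    expect_true(partition_mirror_consistent(mod, d))
  }
})
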