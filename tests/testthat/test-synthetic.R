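test_that("generated skulls are connected, mirror-symmetric, deterministic", {
  tpl <- skull_template(n_pairs = 10, n_midline = 4, n_modules = 3,
                        seed = 1)
  sk <- make_skull(tpl)
  g <- igraph::graph_from_adjacency_matrix(sk$adjacency,
                                           mode = "undirected")
  expect_true(igraph::is_connected(g))
  perm <- cranionet:::mirror_label(rownames(sk$adjacency))
  expect_true(all(sk$adjacency[perm, perm] == sk$adjacency))
  # same seed twice: identical adjacency
  expect_identical(make_skull(tpl)$adjacency, sk$adjacency)
  # different seed: different draw (overwhelmingly)
  tpl2 <- skull_template(n_pairs = 10, n_midline = 4, n_modules = 3,
                         seed = 2)
  expect_false(identical(make_skull(tpl2)$adjacency, sk$adjacency))
})

test_that("pure within-module wiring yields one-sided cliques", {
  tpl <- skull_template(n_pairs = 9, n_midline = 0, n_modules = 3,
                        p_in = 1, p_out = 1e-9, p_cross = 0, seed = 3)
  tpl$p_out <- 0                      # exact zero between modules
  sk <- make_skull(tpl, connect = FALSE)
  plan <- tpl$module_plan
  left <- paste0(tpl$pair_names, "_L")
  for (mod in unique(plan[left])) {
    members <- left[plan[left] == mod]
    block <- sk$adjacency[members, members]
    expect_true(all(block[upper.tri(block)] == 1))
  }
  # no contacts between left-side modules
  for (a in left) for (b in left)
    if (plan[[a]] != plan[[b]]) expect_equal(sk$adjacency[a, b], 0)
})

test_that("ontogenetic fusion series shrinks monotonically", {
  tpl <- skull_template(n_pairs = 12, n_midline = 4, seed = 6)
  hatch <- make_skull(tpl)
  sched <- make_fusion_schedule(hatch, 5, seed = 2)
  expect_equal(nrow(sched), 5)
  expect_true(all(diff(sched$stage) > 0))

  series <- simulate_ontogeny(hatch, sched, c(0.2, 0.5, 1))
  ns <- vapply(series, function(s) nrow(s$network$adjacency), numeric(1))
  expect_true(all(diff(ns) <= 0))
  expect_equal(ns[3], nrow(hatch$adjacency) - 5)    # all fusions applied
  expect_equal(vapply(series, `[[`, numeric(1), "relative_size"),
               c(20, 50, 100))
  # every stage stays connected: edge contraction cannot disconnect
  for (s in series) {
    g <- igraph::graph_from_adjacency_matrix(s$network$adjacency,
                                             mode = "undirected")
    expect_true(igraph::is_connected(g))
  }

  # empty schedule: identical networks at all stages
  empty <- make_fusion_schedule(hatch, 0)
  still <- simulate_ontogeny(hatch, empty, c(0.3, 1))
  expect_identical(still[[1]]$network$adjacency, hatch$adjacency)
  expect_identical(still[[2]]$network$adjacency, hatch$adjacency)
})

test_that("bone count declines with relative size across a series", {
  # the ontogenetic signal the study design rests on: N falls as the
  # skull grows and sutures close
  tpl <- skull_template(n_pairs = 14, n_midline = 5, seed = 9)
  hatch <- make_skull(tpl)
  sched <- make_fusion_schedule(hatch, 12, seed = 4)
  stages <- seq(0.1, 1, by = 0.1)
  series <- simulate_ontogeny(hatch, sched, stages)
  n <- vapply(series, function(s) nrow(s$network$adjacency), numeric(1))
  size <- vapply(series, `[[`, numeric(1), "relative_size")
  f <- ols_fit(size, n)
  expect_lt(f$slope, 0)
  expect_lt(f$p_slope, 0.01)
})

test_that("BM tree simulation has the right moments and structure", {
  sim <- simulate_bm_tree(10, sigma2 = 0, root_value = 3, seed = 1)
  expect_true(all(sim$tip_values == 3))
  expect_true(ape::is.ultrametric(sim$tree, tol = 1e-8))

  # tip variance across seeds matches sigma^2 * depth
  sigma2 <- 0.7
  vals <- vapply(1:400, function(seed) {
    sim <- simulate_bm_tree(5, sigma2 = sigma2, seed = seed)
    depth <- max(ape::node.depth.edgelength(sim$tree))
    sim$tip_values[[1]] / sqrt(depth)
  }, numeric(1))
  expect_equal(var(vals), sigma2, tolerance = 0.2 * sigma2)

  # determinism
  a <- simulate_bm_tree(8, seed = 5)
  b <- simulate_bm_tree(8, seed = 5)
  expect_identical(a$tip_values, b$tip_values)
  expect_identical(a$tree$edge.length, b$tree$edge.length)
})

test_that("the full synthetic study is coherent and deterministic", {
  st <- simulate_study(n_species = 5, seed = 11)
  expect_equal(length(st$nets), 10)
  expect_equal(nrow(st$meta), 10)
  expect_setequal(st$tree$tip.label, unique(st$meta$taxon))
  # juvenile N >= adult N within each species
  for (sp in st$tree$tip.label) {
    nj <- nrow(st$nets[[paste0(sp, "_juv")]]$adjacency)
    na <- nrow(st$nets[[paste0(sp, "_ad")]]$adjacency)
    expect_gte(nj, na)
  }
  st2 <- simulate_study(n_species = 5, seed = 11)
  expect_identical(st2$nets[[3]]$adjacency, st$nets[[3]]$adjacency)

  # round trip through the on-disk formats
  dir <- file.path(tempdir(), "study_rt")
  write_study(st, dir)
  back <- cranionet:::read_study_dir(dir)
  expect_identical(back$nets[["sp01_juv"]]$adjacency,
                   st$nets[["sp01_juv"]]$adjacency)
  expect_equal(back$meta$specimen_id, st$meta$specimen_id)
  expect_true(ape::all.equal.phylo(back$tree, st$tree,
                                   use.edge.length = FALSE))
})
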