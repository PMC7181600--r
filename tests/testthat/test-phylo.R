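worked_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

test_that("consensus_edges averages branch lengths over same topologies", {
  t1 <- worked_tree()
  # identical trees -> identical output
  same <- consensus_edges(list(t1, t1))
  expect_equal(same$edge.length, t1$edge.length)

  # lengths 1 and 3 on an edge average to 2
  t2 <- worked_tree()
  t2$edge.length[t2$edge[, 2] == which(t2$tip.label == "A")] <- 3
  avg <- consensus_edges(list(t1, t2))
  eA <- avg$edge.length[avg$edge[, 2] == which(avg$tip.label == "A")]
  expect_equal(eA, 2)

  # 100 jittered trees: consensus edge equals the sample mean
  set.seed(17)
  base <- ape::rphylo(8, 1, 0)
  jit <- lapply(1:100, function(i) {
    tr <- base
    tr$edge.length <- tr$edge.length * exp(rnorm(length(tr$edge.length),
                                                 0, 0.2))
    tr
  })
  cons <- consensus_edges(jit, topology = base)
  mean_len <- Reduce(`+`, lapply(jit, `[[`, "edge.length")) / 100
  expect_equal(cons$edge.length, mean_len, tolerance = 1e-12)

  # permutation invariance over the tree set
  cons2 <- consensus_edges(rev(jit), topology = base)
  expect_equal(cons$edge.length, cons2$edge.length)
  # idempotence
  expect_equal(consensus_edges(list(cons), topology = base)$edge.length,
               cons$edge.length)

  # topology mismatch names the offending split
  other <- ape::read.tree(text = "((A:1,C:1):1,B:2);")
  expect_error(consensus_edges(list(t1, other)), "split")
})

test_that("tip splitting builds juvenile/adult cherries", {
  tr <- worked_tree()
  sp <- split_ontogenetic_tips(tr, "A", pendant = 0.5)
  expect_equal(sort(sp$tip.label), c("A_ad", "A_juv", "B", "C"))
  # cherry pendant lengths are the requested 0.5
  for (tip in c("A_juv", "A_ad")) {
    i <- which(sp$tip.label == tip)
    expect_equal(sp$edge.length[sp$edge[, 2] == i], 0.5)
  }
  expect_true(ape::is.ultrametric(sp, tol = 1e-8))

  # a slower-growing outgroup gets its own, longer pendant
  big <- ape::read.tree(text = "((A:20,B:20):20,Croc:40);")
  sp2 <- split_ontogenetic_tips(big, c("A", "Croc"), pendant = c(1, 10))
  i <- which(sp2$tip.label == "Croc_juv")
  expect_equal(sp2$edge.length[sp2$edge[, 2] == i], 10)

  # splitting all tips doubles the tip count
  all_split <- split_ontogenetic_tips(big, big$tip.label,
                                      pendant = c(1, 1, 10))
  expect_equal(length(all_split$tip.label), 6)

  expect_error(split_ontogenetic_tips(tr, "nope"), "not found")
  expect_error(split_ontogenetic_tips(tr, "A", pendant = 5), "pendant")
})

test_that("asr_bm reproduces the GLS closed form", {
  tr <- worked_tree()
  res <- asr_bm(tr, c(A = 0, B = 0, C = 3))
  expect_equal(res$root, 9 / 7, tolerance = 1e-12)

  # constant tips reconstruct as constant, SD proxy 0
  resc <- asr_bm(tr, c(A = 2, B = 2, C = 2))
  expect_equal(unname(resc$node_values), c(2, 2), tolerance = 1e-12)
  expect_equal(resc$sd_proxy, 0)

  # independent oracle: ape's ML reconstruction, trees up to 6 tips
  for (seed in 1:5) {
    sim <- simulate_bm_tree(6, sigma2 = 1, seed = seed)
    mine <- asr_bm(sim$tree, sim$tip_values)
    ref <- ape::ace(sim$tip_values[sim$tree$tip.label], sim$tree,
                    type = "continuous", method = "ML")
    expect_equal(unname(mine$node_values), unname(ref$ace),
                 tolerance = 1e-4)
    # closed-form phylogenetic mean at the root
    V <- ape::vcv(sim$tree)
    x <- sim$tip_values[sim$tree$tip.label]
    one <- rep(1, length(x))
    mu <- c(one %*% solve(V) %*% x) / c(one %*% solve(V) %*% one)
    expect_equal(mine$root, mu, tolerance = 1e-12)
    # root value within the tip range (ultrametric BM)
    expect_gte(mine$root, min(x))
    expect_lte(mine$root, max(x))
  }

  expect_error(asr_bm(tr, c(A = 1, B = 2)), "missing")
})

test_that("asr_bm clade values sit at the configured MRCAs", {
  sim <- simulate_bm_tree(12, seed = 2)
  tips <- sim$tree$tip.label
  res <- asr_bm(sim$tree, sim$tip_values,
                clades = list(all = tips, pair = tips[1:2]))
  nt <- length(tips)
  expect_equal(unname(res$clade_values["all"]), res$root)
  mrca <- ape::getMRCA(sim$tree, tips[1:2])
  expect_equal(unname(res$clade_values["pair"]),
               unname(res$node_values[as.character(mrca)]))
})

test_that("BM root estimates are unbiased over many seeds", {
  errs <- vapply(1:300, function(seed) {
    sim <- simulate_bm_tree(15, sigma2 = 1, root_value = 5, seed = seed)
    asr_bm(sim$tree, sim$tip_values)$root - 5
  }, numeric(1))
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)) + 0.05)
})

test_that("pfda at lambda 0 on a star tree equals ordinary LDA", {
  set.seed(10)
  star <- ape::stree(24, "star")
  star$edge.length <- rep(2, 24)
  X <- matrix(rnorm(48), 24, 2)
  g <- rep(c("a", "b"), each = 12)
  X[g == "b", 1] <- X[g == "b", 1] + 4
  rownames(X) <- star$tip.label
  itest <- c(1, 2, 23, 24)
  res <- pfda(X[-itest, ], g[-itest], X[itest, , drop = FALSE], star,
              lambda_grid = 0)
  plain <- MASS::lda(X[-itest, ], grouping = g[-itest])
  expect_equal(unname(res$predictions),
               as.character(predict(plain, X[itest, ])$class))
  plain_cv <- MASS::lda(X[-itest, ], grouping = g[-itest], CV = TRUE)
  expect_equal(unname(res$confusion),
               unname(table(g[-itest], plain_cv$class)))
  expect_equal(rowSums(res$posteriors), rep(1, 4), ignore_attr = TRUE)
})

test_that("pfda separates well-separated groups perfectly", {
  set.seed(14)
  sim <- simulate_bm_tree(20, sigma2 = 0.1, seed = 3)
  X <- cbind(rnorm(20, 0, 0.5), rnorm(20, 0, 0.5))
  g <- rep(c("a", "b"), each = 10)
  X[g == "b", 1] <- X[g == "b", 1] + 10   # 10 within-group SDs apart
  rownames(X) <- sim$tree$tip.label
  res <- pfda(X[1:16, ], g[1:16], X[17:20, ], sim$tree)
  expect_equal(res$error, 0)
  expect_true(all(res$posteriors[, "b"] > 0.99))
  expect_true(res$lambda >= 0 && res$lambda <= 1)
})

test_that("pfda recovers group membership on BM traits with a mean shift", {
  hits <- 0; total <- 0
  for (seed in 1:10) {
    sim <- simulate_bm_tree(40, sigma2 = 0.3, seed = 20 + seed)
    tips <- sim$tree$tip.label
    set.seed(seed)
    g <- rep(c("a", "b"), each = 20)[sample(40)]
    X <- cbind(sim$tip_values + ifelse(g == "b", 4, 0) + rnorm(40, 0, 0.3),
               rnorm(40))
    rownames(X) <- tips
    hold <- sample(40, 6)
    res <- pfda(X[-hold, ], g[-hold], X[hold, , drop = FALSE], sim$tree)
    hits <- hits + sum(res$predictions == g[hold])
    total <- total + 6
  }
  expect_gte(hits / total, 0.9)
})

test_that("juvenile substitution turns juveniles into hatchlings", {
  # all at the minimum size already: adjustment is the identity
  s <- c(a = 10, b = 10, c = 10, d = 10)
  tr <- c(a = 1.2, b = 0.7, c = 1.9, d = 0.4)
  expect_error(juvenile_substitute(tr, s), "constant")

  # perfectly linear trait in size: all adjusted to the fit at s_min
  s2 <- c(a = 10, b = 20, c = 30, d = 40)
  tr2 <- 2 + 0.5 * s2
  adj <- juvenile_substitute(tr2, s2, youngest_id = "a")
  expect_equal(unname(adj), rep(2 + 0.5 * 10, 4))

  # youngest_id must carry the minimum size
  expect_error(juvenile_substitute(tr2, s2, youngest_id = "c"), "minimum")

  # noisy ontogeny: adjusted values recover hatchling values within noise
  set.seed(30)
  n <- 60
  hatch <- rnorm(n, 5, 1)
  size <- runif(n, 10, 80)
  slope <- 0.2
  obs <- hatch + slope * (size - 10) + rnorm(n, 0, 0.05)
  names(obs) <- paste0("t", 1:n)
  adj2 <- juvenile_substitute(obs, size)
  expect_lt(sqrt(mean((adj2 - hatch)^2)), 1)   # within the hatchling SD
  expect_gt(cor(adj2, hatch), 0.9)
})

test_that("parsimony proxies compare reconstructions sensibly", {
  sim <- simulate_bm_tree(15, seed = 8)
  a1 <- asr_bm(sim$tree, sim$tip_values)
  expect_equal(parsimony_proxies(a1, a1)$sd_difference, 0)
  expect_equal(a1$sd_proxy, sd(a1$node_values))   # arithmetic oracle
  expect_equal(a1$logprod_proxy, sum(log(abs(a1$node_values))))
  expect_identical(a1$logprod_valid, all(a1$node_values > 0))

  # a smooth trend vs the same tips with one large clade jump
  het <- simulate_heterochrony_traits(n_tips = 25, shift = 8, seed = 5)
  smooth <- asr_bm(het$tree, het$substituted_values)
  jumpy <- asr_bm(het$tree, het$adult_values)
  pp <- parsimony_proxies(jumpy, smooth)
  expect_lt(pp$sd_substituted, pp$sd_adult)
  expect_equal(pp$more_parsimonious, "substituted")
})
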