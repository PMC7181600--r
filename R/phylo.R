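edge_lengths_by_split <- function(tree) {
  # edge lengths keyed by the sorted tip set below each edge
  n <- length(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  keys <- vapply(seq_len(nrow(tree$edge)), function(e)
    paste(sort(desc[[tree$edge[e, 2]]]), collapse = "|"), character(1))
  stats::setNames(tree$edge.length, keys)
}

#' Temporal consensus of same-topology trees
#'
#' Averages branch lengths across a set of trees that all share one
#' topology (e.g. a posterior sample of relaxed-clock trees): each edge of
#' the consensus gets the arithmetic mean of that edge's lengths across the
#' set, edges being matched by the tip set they subtend.
#'
#' @param trees a list (or \code{multiPhylo}) of trees with identical
#'   topologies and tip labels.
#' @param topology tree supplying the output topology; defaults to the
#'   first tree.
#' @return the topology with mean edge lengths.
#' @export
consensus_edges <- function(trees, topology = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1)
  if (is.null(topology)) topology <- trees[[1]]
  ref <- edge_lengths_by_split(topology)
  acc <- stats::setNames(numeric(length(ref)), names(ref))
  for (tr in trees) {
    el <- edge_lengths_by_split(tr)
    extra <- setdiff(names(el), names(ref))
    missing <- setdiff(names(ref), names(el))
    if (length(extra) || length(missing)) {
      off <- c(extra, missing)[1]
      stop("topology mismatch at split {",
           gsub("\\|", ", ", off), "}")
    }
    acc <- acc + el[names(ref)]
  }
  out <- topology
  out$edge.length <- unname(acc / length(trees))
  out
}

#' Split tips into juvenile/adult OTU pairs
#'
#' Replaces each listed tip by a cherry of \code{<tip>_juv} and
#' \code{<tip>_ad}, each with the given pendant branch length (one year for
#' birds; ten for slower-growing archosaurs such as crocodylians, whose
#' ontogeny is much longer). The cherry tips end at the original tip's
#' depth, so an ultrametric input stays ultrametric.
#'
#' @param tree a \code{phylo} tree with branch lengths.
#' @param species tip labels to split.
#' @param pendant pendant branch length(s), recycled along \code{species}.
#' @param suffixes juvenile/adult label suffixes.
#' @return the tree with each listed tip replaced by a two-tip cherry.
#' @export
split_ontogenetic_tips <- function(tree, species, pendant = 1,
                                   suffixes = c("_juv", "_ad")) {
  stopifnot(inherits(tree, "phylo"), length(suffixes) == 2)
  pendant <- rep_len(pendant, length(species))
  for (i in seq_along(species)) {
    sp <- species[i]
    bl <- pendant[i]
    tipi <- match(sp, tree$tip.label)
    if (is.na(tipi)) stop("species not found in tree: ", sp)
    edge_len <- tree$edge.length[tree$edge[, 2] == tipi]
    if (edge_len <= bl)
      stop("tip edge of ", sp, " (", edge_len,
           ") is not longer than the pendant length ", bl)
    cherry <- ape::read.tree(text = sprintf(
      "(%s:%.10f,%s:%.10f);", paste0(sp, suffixes[1]), bl,
      paste0(sp, suffixes[2]), bl))
    tree <- ape::bind.tree(tree, cherry, where = tipi, position = bl)
    tree <- ape::drop.tip(tree, sp)
  }
  tree
}

matrix_inv_sqrt <- function(V, floor = 1e-10) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
}

#' Phylogenetic flexible discriminant analysis
#'
#' Linear discriminant analysis after phylogenetic whitening controlled by
#' Pagel's lambda. For each lambda on a grid, the phylogenetic covariance
#' of all involved tips has its off-diagonal elements scaled by lambda, the
#' predictors are whitened by the inverse square root of that matrix, an
#' LDA is fitted on the training tips and scored by leave-one-out
#' misclassification. The lambda minimizing the training error is chosen
#' (ties toward the smallest lambda, i.e. the weakest phylogenetic
#' correction), and test tips are classified under it.
#'
#' @param train_x numeric matrix of predictors, rows named by tree tips.
#' @param train_groups group label per training row (>= 2 groups).
#' @param test_x optional predictor matrix for tips to classify.
#' @param tree \code{phylo} tree containing every training and test tip.
#' @param lambda_grid candidate lambda values in [0, 1].
#' @param eig_floor eigenvalue floor for the matrix inverse square root.
#' @return list of class \code{pfda_result}: \code{lambda}, \code{error}
#'   (leave-one-out training misclassification fraction), \code{confusion}
#'   (true x predicted table), \code{posteriors} (test tips x groups, rows
#'   summing to 1), \code{predictions}, \code{error_curve}.
#' @export
pfda <- function(train_x, train_groups, test_x = NULL, tree,
                 lambda_grid = seq(0, 1, by = 0.01), eig_floor = 1e-10) {
  train_x <- as.matrix(train_x)
  train_groups <- factor(train_groups)
  if (nlevels(train_groups) < 2) stop("need at least 2 groups")
  if (!is.null(test_x)) test_x <- as.matrix(test_x)
  taxa <- c(rownames(train_x), rownames(test_x))
  if (anyDuplicated(taxa)) stop("duplicate tip names across train and test")
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("tips absent from tree: ", paste(missing, collapse = ", "))
  V <- ape::vcv(tree)[taxa, taxa]
  X <- rbind(train_x, test_x)[taxa, , drop = FALSE]
  itrain <- seq_len(nrow(train_x))
  whiten <- function(lambda) {
    Vl <- V * lambda
    diag(Vl) <- diag(V)
    matrix_inv_sqrt(Vl, floor = eig_floor) %*% X
  }
  loo_error <- function(Xw) {
    fit <- tryCatch(
      MASS::lda(Xw[itrain, , drop = FALSE], grouping = train_groups,
                CV = TRUE),
      error = function(e) stop(
        "LDA failed (", conditionMessage(e),
        "); the within-group covariance may be singular - reduce the ",
        "number of predictor axes", call. = FALSE))
    mean(fit$class != train_groups)
  }
  errs <- vapply(lambda_grid, function(l) loo_error(whiten(l)), numeric(1))
  best <- which(errs == min(errs))[1]  # smallest lambda on ties
  lambda <- lambda_grid[best]
  Xw <- whiten(lambda)
  cvfit <- MASS::lda(Xw[itrain, , drop = FALSE], grouping = train_groups,
                     CV = TRUE)
  confusion <- table(true = train_groups, predicted = cvfit$class)
  fit <- MASS::lda(Xw[itrain, , drop = FALSE], grouping = train_groups)
  posteriors <- NULL
  predictions <- NULL
  if (!is.null(test_x)) {
    pr <- stats::predict(fit, Xw[-itrain, , drop = FALSE])
    posteriors <- pr$posterior
    rownames(posteriors) <- taxa[-itrain]
    predictions <- stats::setNames(as.character(pr$class), taxa[-itrain])
  }
  structure(
    list(lambda = lambda, error = errs[best], confusion = confusion,
         posteriors = posteriors, predictions = predictions,
         error_curve = data.frame(lambda = lambda_grid, error = errs),
         fit = fit),
    class = "pfda_result")
}

#' @export
print.pfda_result <- function(x, ...) {
  cat("pfda_result: lambda =", x$lambda,
      " leave-one-out error =", format(x$error, digits = 3), "\n")
  print(x$confusion)
  invisible(x)
}

#' Brownian-motion ancestral state reconstruction
#'
#' Maximum-likelihood (GLS) ancestral values at every internal node under a
#' constant-rate Brownian motion model. The value at node k is the BLUP
#' \deqn{\hat a_k = \hat\mu + c_k' V^{-1} (x - \hat\mu 1)}
#' where V is the tip phylogenetic covariance, \eqn{c_k} the shared path
#' lengths between node k and each tip, and \eqn{\hat\mu} the GLS
#' phylogenetic mean \eqn{(1'V^{-1}x) / (1'V^{-1}1)} (the root estimate).
#'
#' Two parsimony proxies summarize the reconstruction: the standard
#' deviation of all ancestral values (less variation = a smoother, "more
#' parsimonious" history) and the log-product \eqn{\sum \log |a_k|}, which
#' is only meaningful when every ancestral value is positive — a validity
#' flag is set accordingly.
#'
#' @param tree \code{phylo} tree with positive branch lengths.
#' @param tip_values named numeric vector covering every tip.
#' @param clades optional named list of tip-label vectors; each clade's
#'   ancestral value is read at the most recent common ancestor of its
#'   tips.
#' @return list of class \code{asr_result}: \code{node_values} (named by
#'   internal node number), \code{root} (the phylogenetic mean),
#'   \code{sd_proxy}, \code{logprod_proxy}, \code{logprod_valid},
#'   \code{clade_values}.
#' @export
asr_bm <- function(tree, tip_values, clades = NULL) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  if (is.null(names(tip_values)))
    stop("tip_values must be named by tip labels")
  missing <- setdiff(tree$tip.label, names(tip_values))
  if (length(missing))
    stop("missing tip value(s): ", paste(missing, collapse = ", "))
  if (any(tree$edge.length <= 0)) stop("branch lengths must be positive")
  x <- tip_values[tree$tip.label]
  V <- ape::vcv(tree)
  Vi <- solve(V)
  one <- rep(1, nt)
  mu <- as.numeric(one %*% Vi %*% x) / as.numeric(one %*% Vi %*% one)
  depth <- ape::node.depth.edgelength(tree)
  dn <- ape::dist.nodes(tree)
  nodes <- nt + seq_len(tree$Nnode)
  wres <- Vi %*% (x - mu)
  vals <- vapply(nodes, function(k) {
    ck <- (depth[k] + depth[seq_len(nt)] - dn[k, seq_len(nt)]) / 2
    mu + as.numeric(ck %*% wres)
  }, numeric(1))
  names(vals) <- as.character(nodes)
  clade_values <- NULL
  if (!is.null(clades)) {
    clade_values <- vapply(clades, function(tips) {
      bad <- setdiff(tips, tree$tip.label)
      if (length(bad))
        stop("clade tip(s) not in tree: ", paste(bad, collapse = ", "))
      node <- if (length(tips) == 1) match(tips, tree$tip.label)
        else ape::getMRCA(tree, tips)
      if (node <= nt) unname(x[tree$tip.label[node]])
      else unname(vals[as.character(node)])
    }, numeric(1))
  }
  structure(
    list(node_values = vals,
         root = mu,
         sd_proxy = stats::sd(vals),
         logprod_proxy = sum(log(abs(vals))),
         logprod_valid = all(vals > 0),
         clade_values = clade_values),
    class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat("asr_result:", length(x$node_values), "internal nodes, root =",
      format(x$root, digits = 4), ", SD of ancestral values =",
      format(x$sd_proxy, digits = 4), "\n")
  invisible(x)
}

#' Standardize juvenile traits to hypothetical hatchlings
#'
#' Juvenile specimens are sampled at unequal ontogenetic stages, so their
#' trait values carry an ontogenetic signal. This regresses the trait on
#' relative skull size and shifts every residual to the fitted value at the
#' youngest individual's relative size, turning all juveniles into
#' hypothetical hatchlings of a common stage:
#' \deqn{adj_i = e_i + (\hat\alpha + \hat\beta s_{min}).}
#'
#' @param traits named numeric vector of juvenile trait values.
#' @param rel_sizes relative skull sizes (percent), same order/names.
#' @param youngest_id optional id that must carry the minimum relative
#'   size (a consistency check on the intended reference individual).
#' @return adjusted trait vector (same names).
#' @export
juvenile_substitute <- function(traits, rel_sizes, youngest_id = NULL) {
  stopifnot(length(traits) == length(rel_sizes))
  if (stats::var(rel_sizes) == 0) stop("relative sizes are constant")
  s_min <- min(rel_sizes)
  if (!is.null(youngest_id)) {
    idx <- match(youngest_id, names(traits))
    if (is.na(idx)) stop("youngest_id not found: ", youngest_id)
    if (rel_sizes[idx] > s_min + 1e-12)
      stop("youngest_id does not have the minimum relative size")
  }
  fit <- stats::lm(traits ~ rel_sizes)
  adj <- stats::resid(fit) +
    unname(stats::coef(fit)[1] + stats::coef(fit)[2] * s_min)
  stats::setNames(as.numeric(adj), names(traits))
}

#' Compare the parsimony proxies of two reconstructions
#'
#' Reports the standard-deviation proxy of an adult-tip reconstruction and
#' a juvenile-substituted reconstruction on the same tree: the smaller SD
#' marks the smoother — "more parsimonious" — evolutionary history. The
#' log-product proxies are reported with their validity flags (they are
#' undefined in sign whenever an ancestral value is non-positive).
#'
#' @param asr_adult,asr_substituted \code{\link{asr_bm}} results on the
#'   same tree.
#' @return list: \code{sd_adult}, \code{sd_substituted},
#'   \code{sd_difference} (adult minus substituted; positive means the
#'   substituted history is more parsimonious), \code{more_parsimonious},
#'   log-product proxies and flags.
#' @export
parsimony_proxies <- function(asr_adult, asr_substituted) {
  stopifnot(inherits(asr_adult, "asr_result"),
            inherits(asr_substituted, "asr_result"))
  if (length(asr_adult$node_values) != length(asr_substituted$node_values))
    stop("reconstructions are not on the same tree")
  list(sd_adult = asr_adult$sd_proxy,
       sd_substituted = asr_substituted$sd_proxy,
       sd_difference = asr_adult$sd_proxy - asr_substituted$sd_proxy,
       more_parsimonious = if (asr_substituted$sd_proxy < asr_adult$sd_proxy)
         "substituted" else "adult",
       logprod_adult = asr_adult$logprod_proxy,
       logprod_substituted = asr_substituted$logprod_proxy,
       logprod_valid = asr_adult$logprod_valid &&
         asr_substituted$logprod_valid)
}
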