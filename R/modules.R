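#' Generalized topological overlap matrix (GTOM)
#'
#' Node-pair similarity based on shared neighbourhoods: bones connecting to
#' the same other bones more likely belong to the same module. For order
#' \code{m = 1},
#' \deqn{t_{ij} = (|N(i) \cap N(j)| + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})}
#' with \eqn{t_{ii} = 1}. Higher orders replace the neighbour sets by
#' m-step neighbourhoods (all nodes reachable within m steps, excluding the
#' node itself) in both numerator and denominator.
#'
#' @param net a \code{\link{bone_network}} without isolated nodes.
#' @param m neighbourhood order (positive integer, default 1).
#' @return a symmetric matrix in [0, 1] with unit diagonal, bone labels as
#'   dimnames, and attribute \code{"order"}.
#' @examples
#' tri <- matrix(1, 3, 3) - diag(3)
#' dimnames(tri) <- list(letters[1:3], letters[1:3])
#' gtom(bone_network(tri))   # all off-diagonal entries 1
#' @export
gtom <- function(net, m = 1) {
  stopifnot(inherits(net, "bone_network"), m >= 1, m == round(m))
  A <- net$adjacency
  n <- nrow(A)
  deg <- rowSums(A)
  if (any(deg == 0))
    stop("isolated node (degree 0): ",
         rownames(A)[which(deg == 0)[1]],
         "; GTOM is degenerate for isolated nodes")
  B <- A
  if (m > 1) {
    reach <- A
    P <- A
    for (step in seq_len(m - 1)) {
      P <- P %*% A
      reach <- reach + P
    }
    B <- (reach > 0) * 1
    diag(B) <- 0
  }
  shared <- B %*% B
  bdeg <- rowSums(B)
  minb <- outer(bdeg, bdeg, pmin)
  t <- (shared + A) / (minb + 1 - A)
  diag(t) <- 1
  dimnames(t) <- dimnames(A)
  attr(t, "order") <- m
  t
}

#' Ward.D2 hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering under the Ward.D2 criterion (inputs treated as
#' distances, not squared distances), the variance-minimizing method used to
#' group bones by GTOM similarity. The dissimilarity fed in is normally
#' \code{1 - gtom(net)}.
#'
#' @param dissimilarity symmetric matrix with zero diagonal (or a
#'   \code{dist}); \code{NA}/\code{NaN} entries are rejected.
#' @return an \code{\link[stats]{hclust}} dendrogram.
#' @export
ward_cluster <- function(dissimilarity) {
  if (!inherits(dissimilarity, "dist")) {
    dissimilarity <- as.matrix(dissimilarity)
    if (anyNA(dissimilarity)) stop("NA/NaN in dissimilarity")
    if (any(abs(dissimilarity - t(dissimilarity)) > 1e-12))
      stop("dissimilarity must be symmetric")
    if (any(abs(diag(dissimilarity)) > 1e-12))
      stop("dissimilarity must have a zero diagonal")
    dissimilarity <- stats::as.dist(dissimilarity)
  }
  if (anyNA(dissimilarity)) stop("NA/NaN in dissimilarity")
  stats::hclust(dissimilarity, method = "ward.D2")
}

#' Newman modularity of a partition
#'
#' \deqn{Q = \sum_s [ l_s/K - (d_s / 2K)^2 ]}
#' where \eqn{l_s} is the number of edges inside module s and \eqn{d_s} the
#' summed degree of its nodes: observed within-module connections minus the
#' expectation under random edge placement with the same degrees.
#'
#' @param adjacency symmetric 0/1 matrix (or a \code{\link{bone_network}}).
#' @param membership module assignment, one entry per node.
#' @return the modularity Q (a number in [-0.5, 1]).
#' @export
newman_q <- function(adjacency, membership) {
  if (inherits(adjacency, "bone_network")) adjacency <- adjacency$adjacency
  A <- as.matrix(adjacency)
  stopifnot(length(membership) == nrow(A))
  K <- sum(A) / 2
  if (K == 0) return(0)
  deg <- rowSums(A)
  q <- 0
  for (s in unique(membership)) {
    inS <- membership == s
    l_s <- sum(A[inS, inS]) / 2
    d_s <- sum(deg[inS])
    q <- q + l_s / K - (d_s / (2 * K))^2
  }
  q
}

#' Modularity-optimal dendrogram cut (Q-modules)
#'
#' Cuts the GTOM/Ward dendrogram at every possible number of clusters
#' k = 1..N, scores each cut with Newman modularity Q on the bone-contact
#' graph, and returns the partition that maximizes Q (\code{Qmax}). Ties are
#' broken toward fewer modules.
#'
#' @param net a \code{\link{bone_network}}.
#' @param dendro an \code{hclust} whose leaves are the bone labels; computed
#'   from \code{1 - gtom(net, m)} when omitted.
#' @param m GTOM order used when \code{dendro} is omitted.
#' @return a list of class \code{module_partition}: \code{assignment}
#'   (named integer vector), \code{q} (the maximized Q), \code{n_modules},
#'   and \code{q_curve} (data frame of Q at every cut k).
#' @export
q_modules <- function(net, dendro = NULL, m = 1) {
  stopifnot(inherits(net, "bone_network"))
  if (is.null(dendro)) dendro <- ward_cluster(1 - gtom(net, m))
  labs <- net$labels$label
  if (!setequal(dendro$labels, labs))
    stop("dendrogram leaves do not match the network's bone labels")
  n <- length(labs)
  qs <- numeric(n)
  cuts <- vector("list", n)
  for (k in seq_len(n)) {
    mem <- stats::cutree(dendro, k = k)[labs]
    cuts[[k]] <- mem
    qs[k] <- newman_q(net$adjacency, mem)
  }
  best <- which.max(qs)  # first maximum = fewest modules on ties
  structure(
    list(assignment = cuts[[best]],
         q = qs[best],
         n_modules = length(unique(cuts[[best]])),
         q_curve = data.frame(k = seq_len(n), q = qs)),
    class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition:", x$n_modules, "Q-modules, Qmax =",
      format(x$q, digits = 4), "\n")
  invisible(x)
}

hclust_clusters <- function(dendro) {
  # leaf sets under each internal merge node, in merge order
  n <- length(dendro$labels)
  sets <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    members <- integer()
    for (j in dendro$merge[i, ]) {
      members <- c(members, if (j < 0) -j else sets[[j]])
    }
    sets[[i]] <- members
  }
  lapply(sets, function(ix) dendro$labels[sort(ix)])
}

#' Significant connectivity modules (S-modules)
#'
#' Tests every candidate cluster of the dendrogram (each internal node with
#' at least \code{min_size} leaves, excluding the full tree) for significant
#' internal cohesion: a one-sided two-sample Wilcoxon rank-sum test of each
#' member bone's count of internal contacts against its count of external
#' contacts (internal > external). The exact distribution is used for small
#' untied samples; otherwise the normal approximation with tie correction.
#' The S-module count is the number of significant clusters that are not
#' nested inside another significant cluster; the nested (total) count is
#' also reported.
#'
#' @param net a \code{\link{bone_network}}.
#' @param dendro an \code{hclust} over the bone labels; computed from
#'   \code{1 - gtom(net, m)} when omitted.
#' @param alpha significance level for counting (default 0.05). P-values
#'   themselves are reported so stricter levels (0.01, 0.001) can be read
#'   off directly.
#' @param min_size smallest cluster size tested (default 3).
#' @param max_frac largest tested cluster size as a fraction of the
#'   network (default 0.5): a candidate spanning more than half the skull
#'   would out-count its complement by size alone, so it is not a
#'   meaningful module candidate.
#' @param m GTOM order used when \code{dendro} is omitted.
#' @return list with \code{count} (non-nested significant clusters),
#'   \code{count_nested} (all significant clusters), \code{p_values}, and
#'   \code{clusters} (the tested leaf sets).
#' @export
s_modules <- function(net, dendro = NULL, alpha = 0.05, min_size = 3,
                      max_frac = 0.5, m = 1) {
  stopifnot(inherits(net, "bone_network"))
  if (is.null(dendro)) dendro <- ward_cluster(1 - gtom(net, m))
  A <- net$adjacency
  labs <- rownames(A)
  all_sets <- hclust_clusters(dendro)
  keep <- vapply(all_sets, function(s)
    length(s) >= min_size && length(s) <= max_frac * length(labs),
    logical(1))
  sets <- all_sets[keep]
  pv <- vapply(sets, function(s) {
    inside <- labs %in% s
    internal <- rowSums(A[inside, inside, drop = FALSE])
    external <- rowSums(A[inside, !inside, drop = FALSE])
    if (all(internal == external)) return(1)
    suppressWarnings(
      stats::wilcox.test(internal, external,
                         alternative = "greater")$p.value)
  }, numeric(1))
  sig <- which(pv < alpha)
  nested <- vapply(sig, function(i) {
    any(vapply(sig, function(j)
      i != j && all(sets[[i]] %in% sets[[j]]) &&
        length(sets[[j]]) > length(sets[[i]]), logical(1)))
  }, logical(1))
  list(count = sum(!nested),
       count_nested = length(sig),
       p_values = pv,
       clusters = sets)
}

#' Parcellation of a module partition
#'
#' \eqn{P = 1 - \sum_s (N_s / N)^2}: the probability that two randomly drawn
#' bones lie in different modules. 0 for a single module; approaches 1 for
#' many balanced modules.
#'
#' @param assignment module assignment vector (or a
#'   \code{module_partition}).
#' @return the parcellation P in [0, 1).
#' @examples
#' parcellation(c(1, 1, 1, 2, 2, 2))        # 0.5
#' parcellation(rep(1:3, c(6, 3, 1)))       # 0.54
#' @export
parcellation <- function(assignment) {
  if (inherits(assignment, "module_partition"))
    assignment <- assignment$assignment
  sizes <- table(assignment)
  1 - sum((sizes / sum(sizes))^2)
}

#' Left-right module asymmetry
#'
#' Counts the paired bones whose left and right copies are assigned to
#' different modules — the asymmetry imposed when the dichotomous cluster
#' analysis splits a bilaterally equivalent pair.
#'
#' @param partition a \code{module_partition} (or a bare assignment vector
#'   named by bone labels).
#' @param labels a \code{\link{parse_bone_labels}} data frame, or a
#'   \code{bone_network} to take it from.
#' @return integer count of split pairs.
#' @export
asymmetry_score <- function(partition, labels) {
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  if (inherits(labels, "bone_network")) labels <- labels$labels
  pairs <- 0L
  for (nm in unique(labels$name)) {
    l <- labels$label[labels$name == nm & labels$side == "left"]
    r <- labels$label[labels$name == nm & labels$side == "right"]
    if (length(l) == 1 && length(r) == 1 &&
        assignment[[l]] != assignment[[r]])
      pairs <- pairs + 1L
  }
  pairs
}

#' Is a module partition mirror-consistent?
#'
#' Checks whether a partition is invariant under the left/right
#' relabeling: mapping every bone to its antimere must map each module
#' onto a module (possibly itself). This is the sense in which the module
#' distribution of a bilaterally symmetric skull can be "identical on the
#' left and right side" even when left and right copies occupy different
#' (mirrored) modules.
#'
#' @param partition a \code{module_partition} or named assignment vector.
#' @param labels a \code{\link{parse_bone_labels}} data frame or a
#'   \code{bone_network}.
#' @return TRUE if the mirrored partition equals the partition.
#' @export
partition_mirror_consistent <- function(partition, labels) {
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  if (inherits(labels, "bone_network")) labels <- labels$labels
  mirrored <- mirror_label(labels$label)
  mirrored_assignment <- assignment[mirrored]
  # the mirror map must induce a consistent bijection between module ids
  map <- tapply(mirrored_assignment, assignment[labels$label],
                function(v) length(unique(v)))
  all(map == 1) &&
    length(unique(tapply(mirrored_assignment, assignment[labels$label],
                         unique))) == length(map)
}

#' Full connectivity-module analysis of one specimen
#'
#' Convenience wrapper running the whole module stage: GTOM similarity,
#' Ward.D2 dendrogram, Q-optimal cut, S-module significance, parcellation
#' and left-right asymmetry.
#'
#' @param net a \code{\link{bone_network}}.
#' @param gtom_order GTOM neighbourhood order.
#' @param alpha significance level for the S-module count.
#' @return a \code{module_partition} with extra elements \code{s_pvalues},
#'   \code{n_s_modules}, \code{n_s_modules_nested}, \code{parcellation},
#'   \code{asymmetry}, \code{gtom} and \code{dendrogram}.
#' @export
skull_modules <- function(net, gtom_order = 1, alpha = 0.05) {
  t <- gtom(net, gtom_order)
  dendro <- ward_cluster(1 - t)
  part <- q_modules(net, dendro)
  s <- s_modules(net, dendro, alpha = alpha)
  part$s_pvalues <- s$p_values
  part$n_s_modules <- s$count
  part$n_s_modules_nested <- s$count_nested
  part$parcellation <- parcellation(part)
  part$asymmetry <- asymmetry_score(part, net)
  part$gtom <- t
  part$dendrogram <- dendro
  part
}
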