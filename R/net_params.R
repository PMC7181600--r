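#' Primary network parameters of a skull graph
#'
#' Computes the six primary anatomical-network descriptors of one specimen:
#' \describe{
#'   \item{N}{number of bones (nodes).}
#'   \item{K}{number of bone contacts (edges).}
#'   \item{D}{density of connections, \eqn{2K / (N(N-1))}.}
#'   \item{C}{mean clustering coefficient: the arithmetic mean over nodes of
#'     the fraction of a node's neighbour pairs that are themselves in
#'     contact. Nodes of degree < 2 contribute 0 by default.}
#'   \item{L}{mean shortest path length over all unordered node pairs.}
#'   \item{H}{degree heterogeneity: the standard deviation of node degrees
#'     divided by the mean degree (often called, loosely, the "variance of
#'     connectivity"; it is in fact a normalized dispersion, not a variance).}
#' }
#'
#' @param net a connected \code{\link{bone_network}} with at least 2 bones.
#' @param heterogeneity \code{"sample"} (default) uses the n-1 denominator
#'   for the degree standard deviation, \code{"population"} uses n.
#' @param clustering_isolates \code{"zero"} (default) counts degree-<2 nodes
#'   as 0 in the clustering mean, \code{"exclude"} drops them.
#' @return a one-row data frame with columns \code{N, K, D, C, L, H}.
#' @examples
#' g <- matrix(0, 3, 3, dimnames = list(c("a_M","b_M","c_M"),
#'                                      c("a_M","b_M","c_M")))
#' g["a_M","b_M"] <- g["b_M","a_M"] <- 1
#' g["b_M","c_M"] <- g["c_M","b_M"] <- 1
#' compute_params(bone_network(g))   # path graph: D = 2/3, L = 4/3
#' @export
compute_params <- function(net,
                           heterogeneity = c("sample", "population"),
                           clustering_isolates = c("zero", "exclude")) {
  stopifnot(inherits(net, "bone_network"))
  heterogeneity <- match.arg(heterogeneity)
  clustering_isolates <- match.arg(clustering_isolates)
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n < 2) stop("need at least 2 bones")
  if (!igraph::is_connected(g))
    stop("graph is disconnected: mean path length is undefined")
  k <- igraph::ecount(g)
  deg <- igraph::degree(g)
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc <- if (clustering_isolates == "zero") mean(loc) else
    mean(loc[deg >= 2])
  l <- igraph::mean_distance(g)
  sdd <- stats::sd(deg)
  if (heterogeneity == "population")
    sdd <- sdd * sqrt((n - 1) / n)
  data.frame(N = n, K = k, D = 2 * k / (n * (n - 1)),
             C = cc, L = l, H = sdd / mean(deg))
}

#' All ten anatomical-network parameters of one specimen
#'
#' Extends \code{\link{compute_params}} with the connectivity-module
#' descriptors: the number of significant S-modules, the number of Q-modules
#' at the modularity-optimal dendrogram cut, the maximized Newman modularity
#' \code{Qmax}, and the parcellation \code{P}.
#'
#' @param net a connected \code{\link{bone_network}}.
#' @param gtom_order neighbourhood order for the GTOM similarity
#'   (see \code{\link{gtom}}).
#' @param ... passed on to \code{\link{compute_params}}.
#' @return a one-row data frame with columns
#'   \code{N, K, D, C, L, H, S, Q, Qmax, P}.
#' @seealso \code{\link{skull_modules}} for the underlying partition.
#' @export
skull_params <- function(net, gtom_order = 1, ...) {
  base <- compute_params(net, ...)
  mod <- skull_modules(net, gtom_order = gtom_order)
  cbind(base,
        data.frame(S = mod$n_s_modules, Q = mod$n_modules,
                   Qmax = mod$q, P = mod$parcellation))
}
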