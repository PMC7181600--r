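#' Variables entering the morphospace
#'
#' The nine network parameters ordinated by PCoA. Parcellation (P) is kept
#' in the parameter table for the group tests but excluded from the
#' ordination variable set.
#' @export
pcoa_variables <- c("N", "K", "D", "C", "L", "H", "S", "Q", "Qmax")

#' Build the specimen-by-parameter table
#'
#' Runs \code{\link{skull_params}} on each specimen and stacks the rows,
#' naming them by \code{meta$specimen_id} (or the list names).
#'
#' @param nets named list of \code{\link{bone_network}} objects.
#' @param gtom_order GTOM order passed through to \code{skull_params}.
#' @param ... further arguments for \code{skull_params}.
#' @return data frame with one row per specimen and the ten parameter
#'   columns \code{N, K, D, C, L, H, S, Q, Qmax, P}.
#' @export
build_param_table <- function(nets, gtom_order = 1, ...) {
  rows <- lapply(nets, skull_params, gtom_order = gtom_order, ...)
  tab <- do.call(rbind, rows)
  ids <- vapply(seq_along(nets), function(i) {
    id <- nets[[i]]$meta$specimen_id
    if (is.null(id)) id <- names(nets)[i]
    if (is.null(id) || !nzchar(id)) id <- paste0("specimen_", i)
    id
  }, character(1))
  rownames(tab) <- ids
  tab
}

#' Log-transform the parameter table
#'
#' Natural logs of the nine ordination variables. Parameters that can be 0
#' in degenerate graphs (C on triangle-free skulls, Qmax on single-module
#' graphs) are offset by \code{eps} with a warning.
#'
#' @param tab a parameter table (rows = specimens); only the
#'   \code{\link{pcoa_variables}} columns are used.
#' @param eps offset added to non-positive cells before logging.
#' @return the log-transformed nine-column table.
#' @export
log_params <- function(tab, eps = 1e-6) {
  x <- as.matrix(tab[, pcoa_variables, drop = FALSE])
  if (any(x < 0)) stop("negative parameter value; cannot log-transform")
  nz <- x <= 0
  if (any(nz)) {
    warning(sum(nz), " zero cell(s) offset by eps = ", eps,
            " before log transform")
    x[nz] <- x[nz] + eps
  }
  log(x)
}

#' Gower distance between specimens
#'
#' Range-normalized Manhattan distance:
#' \deqn{d_{ij} = (1/p) \sum_v |x_{iv} - x_{jv}| / range_v.}
#' A zero-range column cannot discriminate and contributes 0 (with a
#' warning); the divisor p stays the full column count.
#'
#' @param x numeric matrix or data frame, rows = specimens.
#' @return a symmetric distance matrix with zero diagonal, bounded by 1.
#' @export
gower_distance <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  n <- nrow(x)
  rng <- apply(x, 2, function(col) diff(range(col)))
  if (any(rng == 0)) {
    warning("zero-range column(s) contribute 0 to the Gower distance: ",
            paste(colnames(x)[rng == 0], collapse = ", "))
  }
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (v in seq_len(p)) {
    if (rng[v] == 0) next
    d <- d + abs(outer(x[, v], x[, v], "-")) / rng[v]
  }
  d / p
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared distance matrix (\eqn{-\frac12 J D^2 J}),
#' eigendecomposes it, and returns coordinates scaled by the square roots of
#' the positive eigenvalues. Negative eigenvalues — possible because Gower
#' distances need not be Euclidean — are dropped and their summed magnitude
#' reported. Axis signs are fixed so each axis's largest-magnitude loading
#' is positive, making results reproducible across platforms.
#'
#' @param d symmetric distance matrix (or \code{dist}) with zero diagonal.
#' @param eig_tol relative tolerance below which eigenvalues count as zero.
#' @return an object of class \code{pcoa_result}: \code{coordinates}
#'   (specimens x axes, columns PCo1, PCo2, ...), \code{eigenvalues}
#'   (positive, non-increasing), \code{variance_fractions} (shares of the
#'   positive eigenvalue sum), and \code{negative_magnitude}.
#' @export
pcoa <- function(d, eig_tol = 1e-8) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-10))
    stop("distance matrix must be square and symmetric")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- eig_tol * max(abs(e$values), 1e-300)
  pos <- e$values > tol
  vals <- e$values[pos]
  vecs <- e$vectors[, pos, drop = FALSE]
  coords <- sweep(vecs, 2, sqrt(vals), "*")
  for (a in seq_len(ncol(coords))) {
    top <- which.max(abs(coords[, a]))
    if (coords[top, a] < 0) coords[, a] <- -coords[, a]
  }
  dimnames(coords) <- list(rownames(d), paste0("PCo", seq_len(ncol(coords))))
  structure(
    list(coordinates = coords,
         eigenvalues = vals,
         variance_fractions = vals / sum(vals),
         negative_magnitude = sum(abs(e$values[e$values < -tol]))),
    class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("pcoa_result:", nrow(x$coordinates), "specimens,",
      ncol(x$coordinates), "axes\n")
  vf <- round(100 * x$variance_fractions[seq_len(min(3, length(
    x$variance_fractions)))], 1)
  cat("  variance:",
      paste(paste0("PCo", seq_along(vf), "=", vf, "%"), collapse = ", "),
      "\n")
  if (x$negative_magnitude > 0)
    cat("  dropped negative eigenvalue magnitude:",
        format(x$negative_magnitude, digits = 3), "\n")
  invisible(x)
}

#' Morphospace from a parameter table
#'
#' One-call wrapper: log-transform the nine ordination variables, compute
#' Gower distances, and run PCoA.
#'
#' @param tab parameter table from \code{\link{build_param_table}}.
#' @param eps log offset for zero cells (see \code{\link{log_params}}).
#' @return a \code{\link{pcoa}} result.
#' @export
morphospace <- function(tab, eps = 1e-6) {
  pcoa(gower_distance(log_params(tab, eps = eps)))
}
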