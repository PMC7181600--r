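#' Parse bone labels into name and side
#'
#' Bone labels follow the convention \code{<name>_L}, \code{<name>_R} or
#' \code{<name>_M} (case-insensitive suffix) for left, right and midline
#' elements. A label without a side suffix is treated as a midline element.
#' Paired bones share the same \code{name} with opposite left/right sides.
#'
#' @param labels character vector of bone labels.
#' @return A data frame with columns \code{label}, \code{name} and
#'   \code{side} (one of \code{"left"}, \code{"right"}, \code{"midline"}).
#' @examples
#' parse_bone_labels(c("premaxilla_L", "premaxilla_R", "parietal_M", "vomer"))
#' @export
parse_bone_labels <- function(labels) {
  stopifnot(is.character(labels))
  suffix <- toupper(sub("^.*_([LRMlrm])$", "\\1", labels))
  has_suffix <- grepl("_[LRMlrm]$", labels)
  side <- rep("midline", length(labels))
  side[has_suffix & suffix == "L"] <- "left"
  side[has_suffix & suffix == "R"] <- "right"
  name <- ifelse(has_suffix, sub("_[LRMlrm]$", "", labels), labels)
  data.frame(label = labels, name = name, side = side,
             stringsAsFactors = FALSE)
}

#' Construct a bone-contact network
#'
#' A \code{bone_network} holds one specimen's skull scored as an undirected,
#' unweighted graph: nodes are bones (or fused bone units) and edges are
#' sutures or articulations. The adjacency matrix must be square, binary,
#' symmetric, zero on the diagonal and carry unique bone labels as both row
#' and column names.
#'
#' @param adjacency square 0/1 matrix with identical row and column labels.
#' @param meta optional named list of specimen metadata (see
#'   \code{\link{read_specimen_meta}}); typical fields are
#'   \code{specimen_id}, \code{taxon}, \code{stage}, \code{group},
#'   \code{skull_box} and \code{relative_size}.
#' @param require_connected reject disconnected graphs? Mean path length is
#'   undefined on disconnected graphs, so they are refused by default;
#'   pass \code{FALSE} to override (e.g. for deliberately split test graphs).
#' @return An object of class \code{bone_network} with elements
#'   \code{labels} (a \code{\link{parse_bone_labels}} data frame),
#'   \code{adjacency} and \code{meta}.
#' @export
bone_network <- function(adjacency, meta = NULL, require_connected = TRUE) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be square, got ", nrow(adjacency), " x ",
         ncol(adjacency))
  labs <- rownames(adjacency)
  if (is.null(labs) || is.null(colnames(adjacency)))
    stop("adjacency must carry bone labels as row and column names")
  if (!identical(labs, colnames(adjacency)))
    stop("row and column labels differ or are ordered differently")
  dup <- labs[duplicated(labs)]
  if (length(dup))
    stop("duplicate bone label(s): ", paste(unique(dup), collapse = ", "))
  mode(adjacency) <- "numeric"
  bad <- which(!(adjacency %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(adjacency)) + 1
    j <- ((bad[1] - 1) %/% nrow(adjacency)) + 1
    stop("non-binary cell at (", labs[i], ", ", labs[j], "): ",
         adjacency[i, j])
  }
  asym <- which(adjacency != t(adjacency), arr.ind = TRUE)
  if (nrow(asym))
    stop("asymmetric adjacency: cell (", labs[asym[1, 1]], ", ",
         labs[asym[1, 2]], ") disagrees with its transpose")
  if (any(diag(adjacency) != 0))
    stop("diagonal must be zero (self-contact at ",
         labs[which(diag(adjacency) != 0)[1]], ")")
  net <- structure(
    list(labels = parse_bone_labels(labs),
         adjacency = adjacency,
         meta = meta),
    class = "bone_network")
  if (require_connected && !is_connected(net))
    stop("graph is disconnected; pass require_connected = FALSE to override")
  net
}

#' @export
print.bone_network <- function(x, ...) {
  cat("bone_network:", nrow(x$adjacency), "bones,",
      sum(x$adjacency) / 2, "contacts\n")
  tab <- table(x$labels$side)
  cat("  sides:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$meta$specimen_id))
    cat("  specimen:", x$meta$specimen_id,
        if (!is.null(x$meta$stage)) paste0("(", x$meta$stage, ")"), "\n")
  invisible(x)
}

#' @export
as.matrix.bone_network <- function(x, ...) x$adjacency

#' Convert a bone network to an igraph graph
#'
#' @param net a \code{\link{bone_network}}.
#' @return an undirected \code{igraph} graph with bone labels as vertex names.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "bone_network"))
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

is_connected <- function(net) {
  igraph::is_connected(as_igraph(net))
}

#' Read a bone-adjacency CSV
#'
#' Expects a comma-separated file whose first row and first column hold the
#' same bone labels in the same order, with every cell 0 or 1 (1 = the two
#' bones share a suture or articulation). Format violations (non-square,
#' asymmetric, non-binary cells, duplicate labels) raise errors naming the
#' offending cell or label.
#'
#' @param path path to the CSV file.
#' @param meta optional specimen metadata list attached to the network.
#' @param require_connected see \code{\link{bone_network}}.
#' @return a validated \code{\link{bone_network}}.
#' @export
read_adjacency <- function(path, meta = NULL, require_connected = TRUE) {
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  bone_network(as.matrix(raw), meta = meta,
               require_connected = require_connected)
}

#' Write a bone-adjacency CSV
#'
#' Inverse of \code{\link{read_adjacency}}: writing then reading returns an
#' identical adjacency matrix and label order.
#'
#' @param net a \code{\link{bone_network}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_adjacency <- function(net, path) {
  stopifnot(inherits(net, "bone_network"))
  utils::write.csv(net$adjacency, path, quote = FALSE)
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Tab-separated, one row per specimen, with columns \code{specimen_id},
#' \code{taxon}, \code{stage} (juvenile/adult), \code{group},
#' \code{box_length}, \code{box_width}, \code{box_height} and
#' \code{clade_tags} (semicolon-joined). Box dimensions may be missing.
#'
#' @param path path to the TSV file.
#' @return a data frame with an added \code{box_volume} column
#'   (length x width x height) where dimensions are present.
#' @export
read_specimen_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "taxon", "stage", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$specimen_id))
    stop("duplicate specimen_id in metadata")
  bad_stage <- setdiff(unique(meta$stage), c("juvenile", "adult"))
  if (length(bad_stage))
    stop("unknown stage value(s): ", paste(bad_stage, collapse = ", "))
  dims <- c("box_length", "box_width", "box_height")
  if (all(dims %in% names(meta))) {
    for (d in dims)
      if (any(!is.na(meta[[d]]) & meta[[d]] <= 0))
        stop("non-positive ", d)
    meta$box_volume <- meta$box_length * meta$box_width * meta$box_height
  }
  meta
}

#' Fuse two bones into a single unit
#'
#' Ontogenetic suture closure joins neighbouring bones into one unit: the
#' fused node inherits the union of both neighbour sets (minus the pair
#' itself), the bone count drops by exactly one, and no self-loop is created.
#'
#' @param net a \code{\link{bone_network}}.
#' @param a,b labels of the two distinct bones to fuse.
#' @param new_name label of the fused unit; its side is parsed from the
#'   usual suffix convention. Defaults to joining the two names (keeping a
#'   common side suffix when both parents share one).
#' @return a new \code{bone_network} with \code{a} and \code{b} replaced by
#'   \code{new_name} at \code{a}'s position.
#' @export
fuse_bones <- function(net, a, b, new_name = NULL) {
  stopifnot(inherits(net, "bone_network"))
  labs <- net$labels$label
  for (lab in c(a, b))
    if (!lab %in% labs) stop("unknown bone label: ", lab)
  if (a == b) stop("cannot fuse a bone with itself: ", a)
  if (is.null(new_name)) {
    pa <- parse_bone_labels(c(a, b))
    stem <- paste(unique(pa$name), collapse = ".")
    suf <- if (pa$side[1] == pa$side[2])
      c(left = "_L", right = "_R", midline = "_M")[[pa$side[1]]] else "_M"
    new_name <- paste0(stem, suf)
  }
  if (new_name %in% setdiff(labs, c(a, b)))
    stop("new_name collides with existing label: ", new_name)
  A <- net$adjacency
  merged <- pmin(A[a, ] + A[b, ], 1)
  keep <- setdiff(labs, b)
  B <- A[keep, keep, drop = FALSE]
  B[a, ] <- merged[keep]
  B[, a] <- merged[keep]
  B[a, a] <- 0
  rownames(B)[rownames(B) == a] <- new_name
  colnames(B)[colnames(B) == a] <- new_name
  bone_network(B, meta = net$meta, require_connected = FALSE)
}

#' Delete all unpaired (midline) bones
#'
#' Reproduces the unpaired-element deletion experiment: every midline-side
#' bone is removed together with its incident contacts, leaving only the
#' paired left/right elements. If the result is empty or disconnected a
#' warning is recorded (the deletion can legitimately split the graph).
#'
#' @param net a \code{\link{bone_network}}.
#' @return a \code{bone_network} containing only paired bones; a
#'   \code{"validation"} attribute carries any warnings raised.
#' @export
drop_unpaired <- function(net) {
  stopifnot(inherits(net, "bone_network"))
  keep <- net$labels$label[net$labels$side != "midline"]
  if (!length(keep)) stop("no paired bones would remain")
  notes <- character()
  out <- bone_network(net$adjacency[keep, keep, drop = FALSE],
                      meta = net$meta, require_connected = FALSE)
  if (!is_connected(out)) {
    notes <- c(notes, "result is disconnected")
    warning("drop_unpaired: result is disconnected")
  }
  attr(out, "validation") <- notes
  out
}
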