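#' Template for a synthetic skull network
#'
#' Describes a bilaterally symmetric skull: \code{n_pairs} left/right bone
#' pairs plus \code{n_midline} unpaired midline bones, with a planted,
#' mirror-symmetric assignment of bones to connectivity modules. Contacts
#' are drawn with probability \code{p_in} within a module and \code{p_out}
#' between modules.
#'
#' @param n_pairs number of L/R bone pairs.
#' @param n_midline number of midline bones.
#' @param n_modules number of planted modules.
#' @param p_in,p_out within-/between-module contact probabilities
#'   (\code{p_in > p_out}).
#' @param p_cross probability that a pair's left and right copies contact
#'   each other across the midline (as the premaxillae, frontals or
#'   dentaries do in real skulls); such an edge is its own mirror image.
#' @param seed RNG seed making the generated skull deterministic.
#' @param specimen_id id attached to generated networks.
#' @return a list of class \code{skull_template} including
#'   \code{module_plan}, a bone-to-module map that is identical for the
#'   two sides of each pair.
#' @export
skull_template <- function(n_pairs = 12, n_midline = 4, n_modules = 3,
                           p_in = 0.9, p_out = 0.05, p_cross = 0.3,
                           seed = 1, specimen_id = "synthetic") {
  stopifnot(n_pairs >= 1, n_midline >= 0, n_modules >= 1,
            p_in > p_out, p_in <= 1, p_out >= 0,
            p_cross >= 0, p_cross <= 1)
  pair_names <- sprintf("bone%02d", seq_len(n_pairs))
  mid_names <- if (n_midline > 0)
    sprintf("mid%02d_M", seq_len(n_midline)) else character()
  pair_mod <- ((seq_len(n_pairs) - 1) %% n_modules) + 1
  mid_mod <- if (n_midline > 0)
    ((seq_len(n_midline) - 1) %% n_modules) + 1 else integer()
  plan <- c(
    stats::setNames(rep(pair_mod, 2),
                    c(paste0(pair_names, "_L"), paste0(pair_names, "_R"))),
    stats::setNames(mid_mod, mid_names))
  structure(
    list(n_pairs = n_pairs, n_midline = n_midline, n_modules = n_modules,
         p_in = p_in, p_out = p_out, p_cross = p_cross, seed = seed,
         specimen_id = specimen_id,
         pair_names = pair_names, mid_names = mid_names,
         module_plan = plan),
    class = "skull_template")
}

mirror_label <- function(lab) {
  out <- lab
  out[grepl("_L$", lab)] <- sub("_L$", "_R", lab[grepl("_L$", lab)])
  out[grepl("_R$", lab)] <- sub("_R$", "_L", lab[grepl("_R$", lab)])
  out
}

#' Generate a mirror-symmetric skull network
#'
#' Draws contacts within the left side from the planted module plan
#' (probability \code{p_in} inside a module, \code{p_out} between), mirrors
#' them exactly onto the right side, draws midline-midline contacts, and
#' wires each midline bone to the two sides symmetrically (one draw per
#' midline-left pair, copied to the matching midline-right pair). If the
#' result is disconnected, minimal bridging contacts are added in
#' mirror-symmetric pairs until it is connected. Deterministic given the
#' template seed.
#'
#' @param template a \code{\link{skull_template}}.
#' @param connect enforce connectivity by adding bridging edges
#'   (default TRUE). With \code{FALSE} the raw draw is returned (validated
#'   without the connectivity requirement).
#' @return a \code{\link{bone_network}} whose adjacency is exactly
#'   invariant under the left/right relabeling.
#' @export
make_skull <- function(template, connect = TRUE) {
  stopifnot(inherits(template, "skull_template"))
  set.seed(template$seed)
  left <- paste0(template$pair_names, "_L")
  right <- paste0(template$pair_names, "_R")
  mids <- template$mid_names
  labs <- c(left, right, mids)
  plan <- template$module_plan
  n <- length(labs)
  A <- matrix(0, n, n, dimnames = list(labs, labs))
  p_of <- function(a, b)
    if (plan[[a]] == plan[[b]]) template$p_in else template$p_out
  # left-left contacts, mirrored to right-right
  for (i in seq_along(left)) for (j in seq_along(left)) {
    if (i >= j) next
    if (stats::runif(1) < p_of(left[i], left[j])) {
      A[left[i], left[j]] <- A[left[j], left[i]] <- 1
      A[right[i], right[j]] <- A[right[j], right[i]] <- 1
    }
  }
  # midline-midline contacts
  if (length(mids) > 1)
    for (i in seq_along(mids)) for (j in seq_along(mids)) {
      if (i >= j) next
      if (stats::runif(1) < p_of(mids[i], mids[j]))
        A[mids[i], mids[j]] <- A[mids[j], mids[i]] <- 1
    }
  # midline-side contacts, one draw shared by both sides
  for (m in mids) for (i in seq_along(left)) {
    if (stats::runif(1) < p_of(m, left[i])) {
      A[m, left[i]] <- A[left[i], m] <- 1
      A[m, right[i]] <- A[right[i], m] <- 1
    }
  }
  # antimere contacts across the midline (self-mirroring edges)
  for (i in seq_along(left)) {
    if (stats::runif(1) < template$p_cross)
      A[left[i], right[i]] <- A[right[i], left[i]] <- 1
  }
  if (connect) {
    repeat {
      g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
      comp <- igraph::components(g)
      if (comp$no == 1) break
      main <- which(comp$membership == comp$membership[1])
      other <- which(comp$membership != comp$membership[1])
      u <- labs[other[1]]
      v <- labs[main[1]]
      A[u, v] <- A[v, u] <- 1
      A[mirror_label(u), mirror_label(v)] <- 1
      A[mirror_label(v), mirror_label(u)] <- 1
    }
  }
  meta <- list(specimen_id = template$specimen_id,
               planted_modules = plan)
  bone_network(A, meta = meta, require_connected = connect)
}

#' Random ontogenetic fusion schedule
#'
#' Simulates suture closure forward from a starting skull: at each step a
#' random remaining contact is chosen and its two bones are marked for
#' fusion, at evenly spaced stage fractions ending at 1. Contracting a
#' contact can never disconnect the graph, so any schedule built this way
#' is safe to apply. Deterministic given the seed.
#'
#' @param net the starting \code{\link{bone_network}}.
#' @param n_fusions number of fusion events.
#' @param seed RNG seed.
#' @return data frame of class \code{fusion_schedule} with columns
#'   \code{stage} (fraction in (0, 1], increasing), \code{bone_a},
#'   \code{bone_b}, \code{new_name}.
#' @export
make_fusion_schedule <- function(net, n_fusions, seed = 1) {
  stopifnot(inherits(net, "bone_network"), n_fusions >= 0)
  set.seed(seed)
  cur <- net
  rows <- list()
  for (i in seq_len(n_fusions)) {
    edges <- which(upper.tri(cur$adjacency) & cur$adjacency == 1,
                   arr.ind = TRUE)
    if (nrow(edges) == 0) stop("no contacts left to fuse at step ", i)
    pick <- edges[sample.int(nrow(edges), 1), ]
    a <- rownames(cur$adjacency)[pick[1]]
    b <- rownames(cur$adjacency)[pick[2]]
    nxt <- fuse_bones(cur, a, b)
    new_name <- setdiff(nxt$labels$label, cur$labels$label)
    rows[[i]] <- data.frame(stage = i / n_fusions, bone_a = a, bone_b = b,
                            new_name = new_name)
    cur <- nxt
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stage = numeric(), bone_a = character(),
               bone_b = character(), new_name = character())
  class(out) <- c("fusion_schedule", class(out))
  out
}

#' Simulate an ontogenetic series of skulls
#'
#' Applies a fusion schedule cumulatively: the network returned for a stage
#' carries every fusion whose schedule fraction is at or below that stage,
#' so the bone count is non-increasing along the series. Relative size is
#' attached as \code{stage * 100} percent.
#'
#' @param net the starting (hatchling) \code{\link{bone_network}}.
#' @param schedule a \code{\link{make_fusion_schedule}} data frame.
#' @param stages increasing vector of size fractions in (0, 1].
#' @return list with one element per stage: \code{network},
#'   \code{relative_size}, \code{stage}.
#' @export
simulate_ontogeny <- function(net, schedule, stages) {
  stopifnot(inherits(net, "bone_network"), all(diff(stages) > 0),
            all(stages > 0), all(stages <= 1))
  cur <- net
  applied <- 0
  out <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    while (applied < nrow(schedule) &&
           schedule$stage[applied + 1] <= stages[s]) {
      row <- schedule[applied + 1, ]
      cur <- fuse_bones(cur, row$bone_a, row$bone_b, row$new_name)
      applied <- applied + 1
    }
    out[[s]] <- list(network = cur, relative_size = 100 * stages[s],
                     stage = stages[s])
  }
  out
}

#' Simulate a clock tree with a Brownian trait
#'
#' Pure-birth (Yule) ultrametric tree with a Brownian-motion trait recorded
#' at every node, so ancestral-state estimates can be checked against the
#' simulated truth. Deterministic given the seed.
#'
#' @param n_tips number of tips (>= 3).
#' @param birth speciation rate of the pure-birth process.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param root_value trait value at the root.
#' @param seed RNG seed.
#' @return list: \code{tree}, \code{tip_values} (named), \code{node_values}
#'   (internal nodes, named by node number), \code{root_value}.
#' @export
simulate_bm_tree <- function(n_tips, birth = 1, sigma2 = 1, root_value = 0,
                             seed = 1) {
  stopifnot(n_tips >= 3)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = 0)
  nt <- length(tree$tip.label)
  vals <- numeric(nt + tree$Nnode)
  vals[nt + 1] <- root_value
  for (e in seq_len(nrow(tree$edge))) {   # cladewise order: parents first
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    vals[child] <- vals[parent] +
      stats::rnorm(1, 0, sqrt(sigma2 * tree$edge.length[e]))
  }
  list(tree = tree,
       tip_values = stats::setNames(vals[seq_len(nt)], tree$tip.label),
       node_values = stats::setNames(vals[nt + seq_len(tree$Nnode)],
                                     as.character(nt + seq_len(tree$Nnode))),
       root_value = root_value)
}

#' Simulate adult/juvenile trait pairs with a clade-localized adult shift
#'
#' Builds the trait scenario behind the heterochrony comparison: on one
#' clock tree, "adult" tip values follow a smooth Brownian background plus
#' a large shift confined to one clade (the abrupt evolutionary jump),
#' while the "substituted" (hypothetical-hatchling) values carry only the
#' smooth background. Reconstructing both with \code{\link{asr_bm}} should
#' find a smaller ancestral-value standard deviation for the substituted
#' set.
#'
#' @param n_tips tips on the simulated clock tree.
#' @param shift trait shift added to the selected clade's adults.
#' @param sigma2 Brownian background rate.
#' @param seed RNG seed.
#' @return list: \code{tree}, \code{adult_values},
#'   \code{substituted_values}, \code{clade_tips} (the shifted clade).
#' @export
simulate_heterochrony_traits <- function(n_tips = 30, shift = 10,
                                         sigma2 = 0.5, seed = 1) {
  sim <- simulate_bm_tree(n_tips, sigma2 = sigma2, seed = seed)
  tree <- sim$tree
  nt <- length(tree$tip.label)
  # pick the internal node whose clade is closest to a third of the tips
  sizes <- vapply((nt + 2):(nt + tree$Nnode), function(node)
    length(tip_descendants(tree, node)), integer(1))
  node <- ((nt + 2):(nt + tree$Nnode))[which.min(abs(sizes - nt / 3))]
  clade <- tree$tip.label[tip_descendants(tree, node)]
  adult <- sim$tip_values + shift * (tree$tip.label %in% clade)
  names(adult) <- tree$tip.label
  list(tree = tree, adult_values = adult,
       substituted_values = sim$tip_values, clade_tips = clade)
}

tip_descendants <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  out <- integer()
  for (k in kids) out <- c(out, tip_descendants(tree, k))
  out
}

#' Simulate a full ontogenetic study
#'
#' Generates the complete synthetic analogue of an ontogenetic AnNA study:
#' for each of \code{n_species}, a hatchling skull from a common template
#' size (independent contact draws per species), a species-specific fusion
#' schedule, a juvenile sampled at a random intermediate stage and an adult
#' at the final stage, skull-box volumes scaling with stage, and an
#' ultrametric species tree. Juvenile bone counts therefore decrease with
#' relative skull size across species, the adult condition being the most
#' fused.
#'
#' @param n_species number of species (each contributes a juvenile and an
#'   adult specimen).
#' @param seed RNG seed governing every draw.
#' @param n_pairs,n_midline,n_modules,p_in,p_out skull template parameters
#'   shared by all species.
#' @param n_fusions central number of fusion events per species schedule;
#'   each species draws a count within 2 of it so adult bone counts vary
#'   across species, as they do in real samples.
#' @return list of class \code{synthetic_study}: \code{nets} (named list of
#'   \code{bone_network}s, ids \code{<species>_juv}/\code{<species>_ad}),
#'   \code{meta} (specimen metadata incl. box dimensions), \code{tree}
#'   (species-level clock tree), \code{truth} (planted modules, schedules
#'   and sampled stages).
#' @export
simulate_study <- function(n_species = 10, seed = 1,
                           n_pairs = 14, n_midline = 5, n_modules = 3,
                           p_in = 0.85, p_out = 0.04, n_fusions = 10) {
  stopifnot(n_species >= 3)
  set.seed(seed)
  species <- sprintf("sp%02d", seq_len(n_species))
  stage_j <- stats::runif(n_species, 0.15, 0.7)
  adult_len <- stats::runif(n_species, 40, 120)    # mm skull box edges
  n_fus <- pmax(1, n_fusions + sample(-2:2, n_species, replace = TRUE))
  sub_seeds <- sample.int(1e6, n_species + 1)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  tree$tip.label <- species
  min_tip <- min(tree$edge.length[tree$edge[, 2] <= n_species])
  tree$edge.length <- tree$edge.length * max(1, 5 / min_tip)
  nets <- list()
  meta_rows <- list()
  truth <- list(stage_juvenile = stats::setNames(stage_j, species),
                schedules = list(), module_plan = NULL)
  for (i in seq_len(n_species)) {
    tpl <- skull_template(n_pairs, n_midline, n_modules,
                          p_in = p_in, p_out = p_out,
                          seed = sub_seeds[i],
                          specimen_id = species[i])
    hatch <- make_skull(tpl)
    if (is.null(truth$module_plan)) truth$module_plan <- tpl$module_plan
    sched <- make_fusion_schedule(hatch, n_fus[i],
                                  seed = sub_seeds[i] + 1)
    truth$schedules[[species[i]]] <- sched
    series <- simulate_ontogeny(hatch, sched, c(stage_j[i], 1))
    for (s in 1:2) {
      st <- if (s == 1) "juvenile" else "adult"
      id <- paste0(species[i], if (s == 1) "_juv" else "_ad")
      net <- series[[s]]$network
      frac <- if (s == 1) stage_j[i]^(1 / 3) else 1
      net$meta <- list(specimen_id = id, taxon = species[i], stage = st,
                       group = "crown_bird")
      nets[[id]] <- net
      meta_rows[[id]] <- data.frame(
        specimen_id = id, taxon = species[i], stage = st,
        group = "crown_bird",
        box_length = adult_len[i] * frac,
        box_width = 0.6 * adult_len[i] * frac,
        box_height = 0.5 * adult_len[i] * frac,
        clade_tags = "")
    }
  }
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  meta$box_volume <- meta$box_length * meta$box_width * meta$box_height
  structure(list(nets = nets, meta = meta, tree = tree, truth = truth,
                 seed = seed),
            class = "synthetic_study")
}

#' Write a synthetic study to disk in pipeline input formats
#'
#' Emits one adjacency CSV per specimen, the metadata TSV, the species tree
#' in Newick, and a JSON truth file (planted module plan and sampled
#' juvenile stages) into a directory.
#'
#' @param study a \code{\link{simulate_study}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(study$nets))
    write_adjacency(study$nets[[id]], file.path(dir, paste0(id, ".csv")))
  meta <- study$meta
  meta$box_volume <- NULL
  utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(
    list(seed = study$seed,
         module_plan = as.list(study$truth$module_plan),
         stage_juvenile = as.list(study$truth$stage_juvenile)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
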