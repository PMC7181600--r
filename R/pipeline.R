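#' Assemble and validate a pipeline run configuration
#'
#' The configuration can come from a YAML file or be given as a list. Known
#' fields (all optional unless noted):
#' \describe{
#'   \item{input_dir}{directory of adjacency CSVs plus \code{meta.tsv} and
#'     optionally \code{tree.nwk}. Omitted when \code{synthetic} is given.}
#'   \item{synthetic}{list of \code{\link{simulate_study}} arguments; the
#'     study is generated into \code{<out_dir>/inputs} and then read back
#'     through the normal input path.}
#'   \item{out_dir}{output directory (required).}
#'   \item{gtom_order}{GTOM order, default 1.}
#'   \item{nperm}{PERMANOVA permutations, default 10000.}
#'   \item{perm_seed}{seed for the PERMANOVA permutations, default 1.}
#'   \item{lambda_grid}{pFDA lambda grid, default \code{seq(0, 1, 0.01)}.}
#'   \item{pfda_axes}{number of leading PCo axes fed to the pFDA,
#'     default 4.}
#'   \item{pendant_juvenile}{pendant branch length when splitting tree tips
#'     into juvenile/adult OTUs, default 1.}
#'   \item{clades}{named list of tip-label vectors whose ancestral values
#'     are reported.}
#' }
#'
#' @param config a list or the path to a YAML file.
#' @return validated config list of class \code{run_config}.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(gtom_order = 1, nperm = 10000, perm_seed = 1,
                   lambda_grid = seq(0, 1, by = 0.01), pfda_axes = 4,
                   pendant_juvenile = 1, clades = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  if (is.null(config$input_dir) && is.null(config$synthetic))
    stop("config needs either input_dir or synthetic")
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir))
    stop("input_dir does not exist: ", config$input_dir)
  structure(config, class = "run_config")
}

read_study_dir <- function(dir) {
  meta_path <- file.path(dir, "meta.tsv")
  if (!file.exists(meta_path)) stop("missing ", meta_path)
  meta <- read_specimen_meta(meta_path)
  nets <- list()
  for (i in seq_len(nrow(meta))) {
    id <- meta$specimen_id[i]
    path <- file.path(dir, paste0(id, ".csv"))
    if (!file.exists(path)) stop("missing adjacency file for ", id)
    nets[[id]] <- read_adjacency(
      path, meta = as.list(meta[i, , drop = FALSE]))
  }
  tree <- NULL
  tree_path <- file.path(dir, "tree.nwk")
  if (file.exists(tree_path)) tree <- ape::read.tree(tree_path)
  list(nets = nets, meta = meta, tree = tree)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
}

#' Run the full anatomical-network study pipeline
#'
#' Executes every stage in order on one dataset: per-specimen network
#' parameters, connectivity-module partitions, the Gower/PCoA morphospace,
#' stage-group comparison tests, allometric regressions with ANCOVA,
#' PERMANOVA on the morphospace, pFDA of juveniles vs adults on the
#' ontogenetically split tree, and Brownian ancestral-state reconstruction
#' of PCo1 for adult tips and for juvenile-substituted (hypothetical
#' hatchling) tips. All outputs are plain CSV/JSON/Newick files under
#' \code{out_dir}; a manifest records files, md5 digests and seeds, so a
#' rerun with the same config reproduces identical digests (the PERMANOVA
#' permutation seed is part of the config).
#'
#' @param config a \code{\link{run_config}} (or list / YAML path for one).
#' @return the run manifest, invisibly (list: stages, files, digests,
#'   seeds).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  fail <- function(stage, e, id = NULL)
    stop("pipeline stage '", stage, "' failed",
         if (!is.null(id)) paste0(" at specimen ", id), ": ",
         conditionMessage(e), call. = FALSE)

  # stage 1: inputs
  input_dir <- config$input_dir
  if (is.null(input_dir)) {
    input_dir <- file.path(out_dir, "inputs")
    study <- tryCatch(do.call(simulate_study, config$synthetic),
                      error = function(e) fail("synthesize", e))
    write_study(study, input_dir)
  }
  data <- tryCatch(read_study_dir(input_dir),
                   error = function(e) fail("read", e))
  stages <- c(stages, "inputs")
  meta <- data$meta

  # stage 2: network parameters
  tab <- NULL
  for (id in names(data$nets)) {
    row <- tryCatch(
      skull_params(data$nets[[id]], gtom_order = config$gtom_order),
      error = function(e) fail("params", e, id))
    tab <- rbind(tab, row)
  }
  rownames(tab) <- names(data$nets)
  utils::write.csv(cbind(specimen_id = rownames(tab), tab),
                   file.path(out_dir, "params.csv"), row.names = FALSE)
  stages <- c(stages, "params")

  # stage 3: module partitions
  part_dir <- file.path(out_dir, "partitions")
  dir.create(part_dir, showWarnings = FALSE)
  for (id in names(data$nets)) {
    mod <- tryCatch(
      skull_modules(data$nets[[id]], gtom_order = config$gtom_order),
      error = function(e) fail("modules", e, id))
    write_json_out(
      list(specimen_id = id,
           assignment = as.list(mod$assignment),
           q_max = mod$q, n_modules = mod$n_modules,
           q_curve = mod$q_curve,
           s_pvalues = mod$s_pvalues,
           n_s_modules = mod$n_s_modules,
           parcellation = mod$parcellation,
           asymmetry = mod$asymmetry),
      file.path(part_dir, paste0(id, ".json")))
  }
  stages <- c(stages, "modules")

  # stage 4: morphospace
  ord <- tryCatch(morphospace(tab), error = function(e) fail("pcoa", e))
  coords <- ord$coordinates
  utils::write.csv(cbind(specimen_id = rownames(coords),
                         as.data.frame(coords)),
                   file.path(out_dir, "pcoa.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(axis = paste0("PCo", seq_along(ord$eigenvalues)),
               eigenvalue = ord$eigenvalues,
               variance_fraction = ord$variance_fractions),
    file.path(out_dir, "pcoa_eigenvalues.csv"), row.names = FALSE)
  stages <- c(stages, "pcoa")

  # stage 5: group statistics
  stage_f <- meta$stage[match(rownames(tab), meta$specimen_id)]
  both <- cbind(tab, as.data.frame(coords))
  t1 <- tryCatch(compare_groups(both, stage_f),
                 error = function(e) fail("group_tests", e))
  utils::write.csv(t1, file.path(out_dir, "table1.csv"), row.names = FALSE)
  meta_rs <- tryCatch(relative_skull_size(meta),
                      error = function(e) fail("relative_size", e))
  size <- meta_rs$relative_size[match(rownames(tab), meta_rs$specimen_id)]
  t2 <- tryCatch(regression_table(both, size, stage_f),
                 error = function(e) fail("regressions", e))
  utils::write.csv(t2, file.path(out_dir, "table2.csv"), row.names = FALSE)
  stages <- c(stages, "group_stats")

  # stage 6: PERMANOVA on the morphospace (Euclidean on PCo scores)
  perm <- tryCatch(
    permanova(stats::dist(coords), stage_f, nperm = config$nperm,
              seed = config$perm_seed, pairwise = TRUE),
    error = function(e) fail("permanova", e))
  write_json_out(list(F = perm$statistic, p = perm$p, n = perm$n,
                      nperm = perm$nperm, seed = config$perm_seed),
                 file.path(out_dir, "permanova.json"))
  stages <- c(stages, "permanova")

  # stages 7-8 need a tree
  if (!is.null(data$tree)) {
    taxa <- unique(meta$taxon)
    split_tree <- tryCatch(
      split_ontogenetic_tips(data$tree, intersect(data$tree$tip.label, taxa),
                             pendant = config$pendant_juvenile),
      error = function(e) fail("tree_split", e))
    id_of <- function(tax, st)
      meta$specimen_id[meta$taxon == tax & meta$stage == st]
    n_axes <- min(config$pfda_axes, ncol(coords))
    X <- coords[, seq_len(n_axes), drop = FALSE]
    tip_ids <- rownames(X)
    tip_names <- vapply(tip_ids, function(id) {
      st <- meta$stage[meta$specimen_id == id]
      tax <- meta$taxon[meta$specimen_id == id]
      paste0(tax, if (st == "juvenile") "_juv" else "_ad")
    }, character(1))
    Xs <- X[tip_names %in% split_tree$tip.label, , drop = FALSE]
    rownames(Xs) <- tip_names[tip_names %in% split_tree$tip.label]
    groups <- stage_f[tip_names %in% split_tree$tip.label]
    fda <- tryCatch(
      pfda(Xs, groups, test_x = NULL, tree = split_tree,
           lambda_grid = config$lambda_grid),
      error = function(e) fail("pfda", e))
    write_json_out(
      list(lambda = fda$lambda, error = fda$error,
           confusion = as.data.frame(fda$confusion)),
      file.path(out_dir, "pfda.json"))
    stages <- c(stages, "pfda")

    # ASR of PCo1: adult tips vs juvenile-substituted tips
    sp <- data$tree$tip.label
    adult_vals <- stats::setNames(
      coords[match(vapply(sp, function(s) id_of(s, "adult"), character(1)),
                   rownames(coords)), "PCo1"], sp)
    juv_ids <- vapply(sp, function(s) id_of(s, "juvenile"), character(1))
    juv_vals <- stats::setNames(
      coords[match(juv_ids, rownames(coords)), "PCo1"], sp)
    juv_size <- meta_rs$relative_size[match(juv_ids, meta_rs$specimen_id)]
    subst <- tryCatch(juvenile_substitute(juv_vals, juv_size),
                      error = function(e) fail("substitute", e))
    asr_a <- tryCatch(asr_bm(data$tree, adult_vals, clades = config$clades),
                      error = function(e) fail("asr", e))
    asr_s <- tryCatch(asr_bm(data$tree, subst, clades = config$clades),
                      error = function(e) fail("asr", e))
    prox <- parsimony_proxies(asr_a, asr_s)
    write_json_out(
      list(adult = list(root = asr_a$root, sd = asr_a$sd_proxy,
                        node_values = as.list(asr_a$node_values),
                        clade_values = as.list(asr_a$clade_values)),
           substituted = list(root = asr_s$root, sd = asr_s$sd_proxy,
                              node_values = as.list(asr_s$node_values),
                              clade_values = as.list(asr_s$clade_values)),
           proxies = prox),
      file.path(out_dir, "asr.json"))
    stages <- c(stages, "asr")
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  digests <- tools::md5sum(files)
  names(digests) <- sub(paste0("^", out_dir, "/?"), "", names(digests))
  manifest <- list(
    package_version = as.character(utils::packageVersion("cranionet")),
    stages = stages,
    seeds = list(perm_seed = config$perm_seed,
                 synthetic_seed = config$synthetic$seed),
    files = as.list(digests))
  write_json_out(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
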