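#' Read a ligand-receptor database CSV
#'
#' Expects columns `ligand,receptor,pathway[,limit]` (UTF-8, header
#' required); complexes use `_`-joined subunits by default.
#'
#' @param path CSV path.
#' @param subunit_separator see [parse_lr_database()].
#' @return an [lr_database][parse_lr_database].
#' @export
read_lr_database <- function(path, subunit_separator = "_") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  parse_lr_database(tb, subunit_separator = subunit_separator)
}

read_triplet_expression <- function(expr_path, genes_path, spots_path) {
  tr <- readr::read_csv(expr_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("row", "col", "value") %in% names(tr)))
    abort("triplet expression file must have columns row,col,value")
  genes <- readr::read_lines(genes_path, progress = FALSE)
  spots <- readr::read_lines(spots_path, progress = FALSE)
  # triplets are 1-based on disk (MTX convention): row = spot, col = gene
  if (any(tr$row < 1 | tr$row > length(spots)) || any(tr$col < 1 | tr$col > length(genes)))
    abort("triplet indices out of range for the genes/spots sidecars")
  X <- matrix(0, length(spots), length(genes), dimnames = list(spots, genes))
  X[cbind(tr$row, tr$col)] <- tr$value
  X
}

#' Read spatial expression with coordinates (and optional labels)
#'
#' Supports two expression layouts: a dense CSV (first column spot IDs,
#' header row of gene names) and a 1-based sparse triplet CSV
#' (`row,col,value`) with `genes.txt` / `spots.txt` sidecars. Coordinates
#' come from a `spot,x,y[,z]` CSV; every expression spot must have a
#' coordinate (extra coordinate rows are dropped with a warning). Spot order
#' follows the expression file.
#'
#' @param expr_path dense or triplet expression CSV.
#' @param coords_path coordinates CSV (`spot,x,y[,z]`).
#' @param labels_path optional cluster-label CSV (`spot,label`).
#' @param genes_path,spots_path sidecar paths for the triplet layout;
#'   default `genes.txt` / `spots.txt` next to `expr_path`.
#' @return a [spatial_expression].
#' @export
read_spatial_expression <- function(expr_path, coords_path, labels_path = NULL,
                                    genes_path = NULL, spots_path = NULL) {
  for (p in c(expr_path, coords_path, labels_path))
    if (!is.null(p) && !file.exists(p)) abort(paste0("file not found: ", p))
  header <- strsplit(readr::read_lines(expr_path, n_max = 1), ",")[[1]]
  if (identical(sort(header), c("col", "row", "value"))) {
    genes_path <- genes_path %||% file.path(dirname(expr_path), "genes.txt")
    spots_path <- spots_path %||% file.path(dirname(expr_path), "spots.txt")
    X <- read_triplet_expression(expr_path, genes_path, spots_path)
  } else {
    tb <- readr::read_csv(expr_path, show_col_types = FALSE, progress = FALSE)
    X <- as.matrix(tb[, -1])
    rownames(X) <- as.character(tb[[1]])
  }
  co <- readr::read_csv(coords_path, show_col_types = FALSE, progress = FALSE)
  if (!"spot" %in% names(co)) names(co)[1] <- "spot"
  missing <- setdiff(rownames(X), as.character(co$spot))
  if (length(missing) > 0)
    abort(paste0("coordinates missing for spot(s): ",
                 paste(utils::head(missing, 10), collapse = ", ")))
  extra <- setdiff(as.character(co$spot), rownames(X))
  if (length(extra) > 0)
    warn(sprintf("%d coordinate row(s) without expression dropped", length(extra)))
  co <- co[match(rownames(X), as.character(co$spot)), ]
  coord_cols <- intersect(c("x", "y", "z"), names(co))
  labels <- NULL
  if (!is.null(labels_path)) {
    lb <- readr::read_csv(labels_path, show_col_types = FALSE, progress = FALSE)
    if (!"spot" %in% names(lb)) names(lb)[1] <- "spot"
    lab_col <- setdiff(names(lb), "spot")[1]
    labels <- lb[[lab_col]][match(rownames(X), as.character(lb$spot))]
    if (anyNA(labels)) abort("labels missing for some spots")
  }
  spatial_expression(X, as.matrix(co[, coord_cols]), labels = labels)
}

pair_file_name <- function(nm) paste0(gsub("[^A-Za-z0-9._-]", "_", nm), ".csv")

#' Write a coupling tensor to per-pair triplet CSVs
#'
#' Writes one `sender,receiver,weight` CSV per ligand-receptor pair (nonzero
#' entries only, sorted by sender then receiver), a `spots.txt` sidecar
#' fixing the spot universe, and a `manifest.json` with package version,
#' seed, configuration hash and solver diagnostics. Output is byte-stable:
#' identical inputs produce identical files.
#'
#' @param tensor a `ccc_tensor`.
#' @param outdir output directory (created if needed).
#' @param seed seed to record in the manifest.
#' @param config configuration list to hash into the manifest.
#' @return the manifest, invisibly.
#' @export
write_coupling <- function(tensor, outdir, seed = NULL, config = NULL) {
  stopifnot(inherits(tensor, "ccc_tensor"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spots <- tensor$spots %||% as.character(seq_len(tensor$n_s))
  readr::write_lines(spots, file.path(outdir, "spots.txt"))
  files <- character(0)
  for (nm in names(tensor$S)) {
    tr <- as(tensor$S[[nm]], "TsparseMatrix")
    tb <- tibble(sender = spots[tr@i + 1L], receiver = spots[tr@j + 1L],
                 weight = tr@x)
    tb <- dplyr::arrange(tb, .data$sender, .data$receiver)
    f <- pair_file_name(nm)
    readr::write_csv(tb, file.path(outdir, f), progress = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    package = "spatialcot",
    version = as.character(utils::packageVersion("spatialcot")),
    seed = seed,
    config_hash = rlang::hash(config),
    n_spots = tensor$n_s,
    pairs = names(tensor$S),
    files = files,
    eps = tensor$eps, rho = tensor$rho,
    diagnostics = tensor$diagnostics[c("iterations", "converged", "dual_change",
                                       "max_ligand_excess", "max_receptor_excess",
                                       "total_mass")]
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a coupling tensor written by [write_coupling()]
#'
#' @param outdir directory holding `manifest.json`, `spots.txt` and the
#'   per-pair CSVs.
#' @return a `ccc_tensor` (couplings, spot universe and diagnostics; the
#'   marginals and coordinates are not stored on disk).
#' @export
read_coupling <- function(outdir) {
  mf <- jsonlite::read_json(file.path(outdir, "manifest.json"), simplifyVector = TRUE)
  spots <- readr::read_lines(file.path(outdir, "spots.txt"), progress = FALSE)
  n_s <- length(spots)
  S <- setNames(vector("list", length(mf$pairs)), mf$pairs)
  for (p in seq_along(mf$pairs)) {
    tb <- readr::read_csv(file.path(outdir, mf$files[p]),
                          show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            sender = readr::col_character(),
                            receiver = readr::col_character(),
                            weight = readr::col_double()))
    S[[p]] <- Matrix::sparseMatrix(
      i = match(tb$sender, spots), j = match(tb$receiver, spots),
      x = tb$weight, dims = c(n_s, n_s), dimnames = list(spots, spots))
  }
  structure(list(S = S, n_s = n_s, spots = spots, eps = mf$eps, rho = mf$rho,
                 diagnostics = mf$diagnostics),
            class = "ccc_tensor")
}

default_config <- function() {
  list(
    cost = list(phi = "linear", dis_thr = NULL),
    solver = list(eps_frac = 0.01, rho_frac = 10, eps = NULL, rho = NULL,
                  tol = 1e-8, max_iter = 10000),
    downstream = list(k_neighbors = 5, n_perm = 999, fdr_alpha = 0.05,
                      n_top_corr = 20, n_trees = 500),
    filters = list(min_pct = 0.005),
    seed = 1
  )
}

#' Read (and validate) a run configuration YAML
#'
#' Unset keys fall back to the package defaults; numeric fields are range
#' checked. Coordinates and spatial limits are assumed to share one length
#' unit: no unit conversion is ever attempted.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("config file not found: ", path))
    user <- yaml::read_yaml(path)
    for (sec in intersect(names(user), names(cfg))) {
      if (is.list(cfg[[sec]])) cfg[[sec]][names(user[[sec]])] <- user[[sec]]
      else cfg[[sec]] <- user[[sec]]
    }
  }
  s <- cfg$solver
  if (s$eps_frac <= 0 || s$rho_frac <= 0 || s$tol <= 0 || s$max_iter < 1)
    abort("solver config out of range")
  if (!is.null(cfg$cost$dis_thr) && cfg$cost$dis_thr <= 0)
    abort("cost.dis_thr must be positive")
  if (cfg$filters$min_pct < 0 || cfg$filters$min_pct > 1)
    abort("filters.min_pct must be in [0, 1]")
  cfg
}

#' Run the full inference pipeline on files
#'
#' Reads expression, coordinates and the ligand-receptor database, solves
#' the collective transport problem and writes per-pair couplings plus a
#' manifest to `out_dir`. The run is deterministic: identical inputs,
#' configuration and seed yield byte-identical outputs.
#'
#' @param expr_path,coords_path,lr_db_path,labels_path input files, see
#'   [read_spatial_expression()] and [read_lr_database()].
#' @param out_dir output directory.
#' @param config configuration list from [read_run_config()] (or NULL for
#'   defaults).
#' @param dis_thr global spatial limit; overrides `config$cost$dis_thr`.
#' @param seed recorded in the manifest (the solver itself is deterministic).
#' @return the `ccc_tensor`, invisibly.
#' @export
run_pipeline <- function(expr_path, coords_path, lr_db_path, out_dir,
                         labels_path = NULL, config = NULL, dis_thr = NULL,
                         seed = NULL) {
  cfg <- config %||% read_run_config(NULL)
  dis_thr <- dis_thr %||% cfg$cost$dis_thr
  seed <- seed %||% cfg$seed
  expr <- read_spatial_expression(expr_path, coords_path, labels_path)
  db <- read_lr_database(lr_db_path)
  tensor <- infer_communication(
    expr, db, dis_thr = dis_thr, phi = cfg$cost$phi,
    eps = cfg$solver$eps, rho = cfg$solver$rho,
    eps_frac = cfg$solver$eps_frac, rho_frac = cfg$solver$rho_frac,
    tol = cfg$solver$tol, max_iter = cfg$solver$max_iter,
    min_pct = cfg$filters$min_pct
  )
  write_coupling(tensor, out_dir, seed = seed,
                 config = c(cfg, list(dis_thr = dis_thr)))
  jsonlite::write_json(
    as.list(glance(tensor)), file.path(out_dir, "diagnostics.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(tensor)
}

#' Write a simulated tissue to CSVs consumable by [run_pipeline()]
#'
#' Writes `expr.csv` (dense spots x genes), `coords.csv`, `lr_db.csv` and the
#' ground-truth fluxes under `ground_truth/` as per-pair triplet CSVs.
#'
#' @param sim a [simulated_tissue][simulate_tissue].
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "simulated_tissue"))
  dir.create(file.path(outdir, "ground_truth"), recursive = TRUE, showWarnings = FALSE)
  expr_tb <- as_tibble(sim$expr$X, rownames = "spot")
  readr::write_csv(expr_tb, file.path(outdir, "expr.csv"), progress = FALSE)
  co <- tibble(spot = sim$expr$spots, x = sim$expr$coords[, 1],
               y = sim$expr$coords[, 2])
  readr::write_csv(co, file.path(outdir, "coords.csv"), progress = FALSE)
  write_lr_database(sim$db, file.path(outdir, "lr_db.csv"))
  for (nm in names(sim$ground_truth)) {
    G <- sim$ground_truth[[nm]]
    idx <- which(G > 0, arr.ind = TRUE)
    tb <- tibble(sender = sim$expr$spots[idx[, 1]],
                 receiver = sim$expr$spots[idx[, 2]],
                 weight = G[idx])
    tb <- dplyr::arrange(tb, .data$sender, .data$receiver)
    readr::write_csv(tb, file.path(outdir, "ground_truth", pair_file_name(nm)),
                     progress = FALSE)
  }
  invisible(outdir)
}
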