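# Plain-text readers and writers shared by all modules, run configuration,
# and the top-level pipeline.  All formats are tab-delimited text with a
# documented header line plus JSON sidecars; no imaging formats.

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop(what, " table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d
}

#' Write / read a parcellation TSV
#'
#' Columns `parcel_id`, `hemisphere`, `x`, `y`, `z` plus one column per
#' annotation.
#'
#' @param parc a [parcellation()].
#' @param path file path.
#' @return `path` (writer) or a [parcellation()] (reader).
#' @export
write_parcellation_tsv <- function(parc, path) {
  d <- data.frame(parcel_id = parc$parcel_id, hemisphere = parc$hemisphere,
                  parc$centroid, stringsAsFactors = FALSE)
  for (nm in names(parc$annotations)) d[[nm]] <- as.character(parc$annotations[[nm]])
  write_tsv(d, path)
}

#' @rdname write_parcellation_tsv
#' @export
read_parcellation_tsv <- function(path) {
  d <- read_tsv_checked(path, c("parcel_id", "hemisphere", "x", "y", "z"),
                        "parcellation")
  ann_cols <- setdiff(names(d), c("parcel_id", "hemisphere", "x", "y", "z"))
  parcellation(d$parcel_id, d$hemisphere, as.matrix(d[, c("x", "y", "z")]),
               annotations = as.list(d[, ann_cols, drop = FALSE]))
}

#' Write / read one donor's sample tables
#'
#' A directory with four TSVs: `samples.tsv` (sample_id, x, y, z,
#' structure), `probes.tsv` (probe_id, gene), `expression.tsv` (probe_id x
#' sample_id intensity matrix) and `pa_calls.tsv` (matching logical matrix
#' of above-background calls), plus a `donor.json` sidecar with the donor
#' id.
#'
#' @param donor a [donor_sample_table()].
#' @param dir directory to create/read.
#' @return `dir` (writer) or a [donor_sample_table()] (reader).
#' @export
write_donor_dir <- function(donor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(donor$samples, file.path(dir, "samples.tsv"))
  write_tsv(donor$probes, file.path(dir, "probes.tsv"))
  write_tsv(data.frame(probe_id = rownames(donor$expr), donor$expr,
                       check.names = FALSE, stringsAsFactors = FALSE),
            file.path(dir, "expression.tsv"))
  write_tsv(data.frame(probe_id = rownames(donor$pa), donor$pa,
                       check.names = FALSE, stringsAsFactors = FALSE),
            file.path(dir, "pa_calls.tsv"))
  jsonlite::write_json(list(donor_id = donor$donor_id),
                       file.path(dir, "donor.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_donor_dir
#' @export
read_donor_dir <- function(dir) {
  samples <- read_tsv_checked(file.path(dir, "samples.tsv"),
                              c("sample_id", "x", "y", "z"), "samples")
  probes <- read_tsv_checked(file.path(dir, "probes.tsv"),
                             c("probe_id", "gene"), "probes")
  ex <- read_tsv_checked(file.path(dir, "expression.tsv"), "probe_id",
                         "expression")
  pa <- read_tsv_checked(file.path(dir, "pa_calls.tsv"), "probe_id",
                         "background calls")
  expr <- as.matrix(ex[, -1, drop = FALSE])
  pam <- as.matrix(pa[, -1, drop = FALSE])
  if (is.character(pam)) pam <- pam == "TRUE"
  mode(pam) <- "logical"
  rownames(expr) <- ex$probe_id
  rownames(pam) <- pa$probe_id
  meta <- jsonlite::read_json(file.path(dir, "donor.json"))
  donor_sample_table(meta$donor_id, samples, probes,
                     expr[probes$probe_id, samples$sample_id, drop = FALSE],
                     pam[probes$probe_id, samples$sample_id, drop = FALSE])
}

#' Write / read a brain map TSV
#'
#' Columns `parcel_id`, `value`.
#'
#' @param m a [brain_map()].
#' @param path file path.
#' @param name,kind metadata used by the reader.
#' @return `path` (writer) or a [brain_map()] (reader).
#' @export
write_map_tsv <- function(m, path) {
  write_tsv(data.frame(parcel_id = m$parcels, value = unname(m$values),
                       stringsAsFactors = FALSE), path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path, name = "map", kind = "mean") {
  d <- read_tsv_checked(path, c("parcel_id", "value"), "map")
  brain_map(d$parcel_id, d$value, name = name, kind = kind)
}

#' Write / read a spin ensemble
#'
#' Permutation rows as a TSV of 1-based parcel indices plus a JSON sidecar
#' recording seed, kind and rotation count.
#'
#' @param ens a [spin_permutations()] ensemble.
#' @param prefix path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return `prefix` (writer) or a `spin_ensemble` (reader).
#' @export
write_spin_ensemble <- function(ens, prefix) {
  utils::write.table(ens$perms, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(n_rot = ens$n_rot, seed = ens$seed,
                            kind = ens$kind, parcel_id = ens$parcel_id),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_spin_ensemble
#' @export
read_spin_ensemble <- function(prefix) {
  perms <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(perms) <- NULL
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(list(perms = perms, n_rot = meta$n_rot, seed = meta$seed,
                 parcel_id = meta$parcel_id, kind = meta$kind),
            class = "spin_ensemble")
}

#' Write a complete set of synthetic pipeline inputs
#'
#' Materializes one synthetic cohort (parcellation, donor directories, gene
#' sets, developmental dataset, stage table) in the exact file formats the
#' pipeline reads, plus the planted ground truth under `truth/`.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory.
#' @return invisibly, a list of the generated objects.
#' @export
write_synthetic_inputs <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- make_donor_tables(spec)
  write_parcellation_tsv(cohort$parc, file.path(dir, "parcellation.tsv"))
  for (d in cohort$donors) {
    write_donor_dir(d, file.path(dir, "donors", d$donor_id))
  }
  write_geneset_tsv(cohort$genesets, file.path(dir, "genesets.tsv"))
  life <- make_lifespan_dataset(spec, cohort$genesets)
  ds <- life$dataset
  write_tsv(ds$samples[, c("sample_id", "donor_id", "region", "age_pcd")],
            file.path(dir, "lifespan_samples.tsv"))
  write_tsv(data.frame(gene = rownames(ds$expr), ds$expr, check.names = FALSE,
                       stringsAsFactors = FALSE),
            file.path(dir, "lifespan_expression.tsv"))
  write_tsv(ds$stage_table, file.path(dir, "stage_table.tsv"))
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_tsv(data.frame(parcel_id = rownames(cohort$truth), cohort$truth,
                       check.names = FALSE, stringsAsFactors = FALSE),
            file.path(dir, "truth", "parcel_patterns.tsv"))
  jsonlite::write_json(life$truth, file.path(dir, "truth", "stage_effects.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(list(cohort = cohort, lifespan = life))
}

#' Read a developmental expression dataset from TSVs
#'
#' @param samples_path TSV with columns `sample_id`, `donor_id`, `region`,
#'   `age_pcd`.
#' @param expr_path TSV with column `gene` followed by one column per
#'   sample.
#' @param stage_table stage table (default [default_stage_table()]).
#' @return a [lifespan_dataset()].
#' @export
read_lifespan_tsv <- function(samples_path, expr_path,
                              stage_table = default_stage_table()) {
  samples <- read_tsv_checked(samples_path,
                              c("sample_id", "donor_id", "region", "age_pcd"),
                              "lifespan samples")
  ex <- read_tsv_checked(expr_path, "gene", "lifespan expression")
  expr <- as.matrix(ex[, -1, drop = FALSE])
  rownames(expr) <- ex$gene
  lifespan_dataset(samples, expr[, samples$sample_id, drop = FALSE],
                   stage_table)
}

#' Validate and resolve a pipeline run configuration
#'
#' Checks that every referenced input exists, that numeric parameters are in
#' range, and fills defaults (10000 rotations, DS threshold 0.1, 2 mm
#' assignment tolerance, RPKM filter variant).  Idempotent: validating a
#' validated configuration returns it unchanged.
#'
#' @param cfg list with fields `input_dir` (a directory produced by
#'   [write_synthetic_inputs()] or laid out the same way), `out_dir`, `seed`
#'   and optionally `n_rot`, `ds_threshold`, `tol_mm`, `filter`, `span`.
#' @return validated configuration of class `run_config`.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  defaults <- list(n_rot = 10000, ds_threshold = 0.1, tol_mm = 2,
                   filter = "rpkm", span = 0.75)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  for (nm in c("input_dir", "out_dir", "seed")) {
    if (is.null(cfg[[nm]])) stop("config is missing '", nm, "'", call. = FALSE)
  }
  if (!dir.exists(cfg$input_dir)) {
    stop("input directory not found: ", cfg$input_dir, call. = FALSE)
  }
  needed <- c("parcellation.tsv", "genesets.tsv", "lifespan_samples.tsv",
              "lifespan_expression.tsv", "stage_table.tsv")
  for (f in needed) {
    if (!file.exists(file.path(cfg$input_dir, f))) {
      stop("missing input file: ", file.path(cfg$input_dir, f), call. = FALSE)
    }
  }
  if (!dir.exists(file.path(cfg$input_dir, "donors"))) {
    stop("missing donors directory under ", cfg$input_dir, call. = FALSE)
  }
  if (cfg$ds_threshold < -1 || cfg$ds_threshold > 1) {
    stop("ds_threshold must lie in [-1, 1]", call. = FALSE)
  }
  if (cfg$tol_mm <= 0) stop("tol_mm must be positive", call. = FALSE)
  if (cfg$n_rot < 1) stop("n_rot must be >= 1", call. = FALSE)
  if (!cfg$filter %in% c("rpkm", "log2signal")) {
    stop("filter must be 'rpkm' or 'log2signal'", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg <- cfg[sort(names(cfg))]
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Chains curation inputs through map building, spin inference and the
#' developmental trajectories: read gene sets, assemble the donor-averaged
#' parcel-by-gene matrix, build pathway mean / z-scored / PC1 maps, build
#' the spin ensemble, test all pairwise map correlations (BH-FDR across
#' pairs) and per-annotation class enrichment, then clean, transform,
#' normalize and summarize the developmental dataset per pathway.  Every
#' artifact is written as TSV under `out_dir` along with a
#' `manifest.json` recording the seed, resolved configuration and an MD5
#' checksum per file; rerunning with the same configuration and seed
#' reproduces byte-identical outputs.
#'
#' @param cfg a configuration accepted by [validate_config()].
#' @return invisibly, a list with the in-memory results (`expr`, `maps`,
#'   `ensemble`, `correlations`, `enrichment`, `trajectories`, `curves`,
#'   `manifest`).
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  parc <- read_parcellation_tsv(file.path(cfg$input_dir, "parcellation.tsv"))
  genesets <- load_energy_genesets(file.path(cfg$input_dir, "genesets.tsv"))
  donor_dirs <- list.dirs(file.path(cfg$input_dir, "donors"),
                          recursive = FALSE)
  donors <- lapply(sort(donor_dirs), read_donor_dir)

  expr <- assemble_expression(donors, parc, ds_threshold = cfg$ds_threshold,
                              tol_mm = cfg$tol_mm)
  utils::write.table(
    data.frame(parcel_id = expr$parcels, expr$values, check.names = FALSE),
    file.path(cfg$out_dir, "expression_matrix.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(data.frame(gene = expr$genes, ds = unname(expr$ds)),
            file.path(cfg$out_dir, "differential_stability.tsv"))

  usable <- Filter(function(g) any(g$genes %in% expr$genes), genesets)
  maps <- lapply(usable, function(g) {
    mm <- pathway_mean_map(expr, g)
    zm <- zscore_map(mm)
    pm <- if (sum(g$genes %in% expr$genes) >= 2) {
      pathway_pc1_map(expr, g)
    }
    write_map_tsv(mm, file.path(cfg$out_dir, paste0("map_mean_", g$name, ".tsv")))
    write_map_tsv(zm, file.path(cfg$out_dir, paste0("map_z_", g$name, ".tsv")))
    if (!is.null(pm)) {
      write_map_tsv(pm, file.path(cfg$out_dir, paste0("map_pc1_", g$name, ".tsv")))
    }
    list(mean = mm, z = zm, pc1 = pm)
  })

  ens <- spin_permutations(parc, n_rot = cfg$n_rot, seed = cfg$seed)
  write_spin_ensemble(ens, file.path(cfg$out_dir, "spin_ensemble"))

  nms <- names(maps)
  cors <- NULL
  if (length(nms) >= 2) {
    pairs <- utils::combn(nms, 2)
    cors <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      ct <- spin_correlation_test(maps[[a]]$mean, maps[[b]]$mean, ens)
      data.frame(map_a = a, map_b = b, rho = ct$rho, p_spin = ct$p_spin,
                 stringsAsFactors = FALSE)
    }))
    cors$p_spin_fdr <- bh_fdr(cors$p_spin)
    write_tsv(cors, file.path(cfg$out_dir, "map_correlations.tsv"))
  }

  enrich <- do.call(rbind, lapply(names(parc$annotations), function(ann) {
    do.call(rbind, lapply(nms, function(nm) {
      et <- class_enrichment_test(maps[[nm]]$z, parc$annotations[[ann]], ens)
      if (is.null(et)) return(NULL)
      data.frame(annotation = ann, pathway = nm, et, stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(enrich)) {
    write_tsv(enrich, file.path(cfg$out_dir, "class_enrichment.tsv"))
  }

  life <- read_lifespan_tsv(file.path(cfg$input_dir, "lifespan_samples.tsv"),
                            file.path(cfg$input_dir, "lifespan_expression.tsv"),
                            validate_stage_table(utils::read.delim(
                              file.path(cfg$input_dir, "stage_table.tsv"))))
  life <- lifespan_cleanup(life, filter = cfg$filter)
  life$expr <- log2_transform(life$expr)
  life$expr <- upper_quartile_normalize(life$expr, life$samples$donor_id)
  usable_l <- Filter(function(g) any(g$genes %in% rownames(life$expr)),
                     genesets)
  trajectories <- do.call(rbind, lapply(usable_l, function(g) {
    tr <- stage_trajectory(life, g)
    data.frame(pathway = g$name, tr, stringsAsFactors = FALSE)
  }))
  if (!is.null(trajectories)) {
    write_tsv(trajectories, file.path(cfg$out_dir, "stage_trajectories.tsv"))
  }
  curves <- do.call(rbind, lapply(usable_l, function(g) {
    present <- intersect(g$genes, rownames(life$expr))
    sm <- colMeans(life$expr[present, , drop = FALSE])
    cv <- loess_trajectory(life$samples$age_pcd, sm, span = cfg$span)
    data.frame(pathway = g$name, cv, stringsAsFactors = FALSE)
  }))
  if (!is.null(curves)) {
    write_tsv(curves, file.path(cfg$out_dir, "loess_curves.tsv"))
  }

  cfg_path <- file.path(cfg$out_dir, "run_config.json")
  # analytic parameters only: machine-specific paths would break
  # byte-identical reproduction across working directories
  cfg_echo <- unclass(cfg)[setdiff(names(cfg), c("input_dir", "out_dir"))]
  jsonlite::write_json(cfg_echo, cfg_path, auto_unbox = TRUE, digits = NA)
  files <- sort(setdiff(list.files(cfg$out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("energymaps")),
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(cfg$out_dir, f))),
           bytes = file.size(file.path(cfg$out_dir, f)))
    }))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(config = cfg, expr = expr, maps = maps, ensemble = ens,
                 correlations = cors, enrichment = enrich,
                 trajectories = trajectories, curves = curves,
                 manifest = manifest))
}
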