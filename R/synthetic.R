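#' Specification for synthetic pipeline inputs
#'
#' Collects every knob of the synthetic-data generators in one validated
#' list.  Defaults give a small but structurally faithful cohort: 100
#' parcels per hemisphere, 6 donors of which 2 carry right-hemisphere
#' samples, 60 genes organized into 5 pathway-like gene sets, exponential
#' spatial covariance with a 0.3 rad correlation length, and lifespan stage
#' effects emulating the canonical energy-pathway trajectories.
#'
#' @param n_parcels_per_hemisphere parcels per hemisphere (>= 10).
#' @param n_donors number of donors (>= 1).
#' @param n_genes total number of genes (gene-set genes plus background).
#' @param correlation_length angular scale (radians) of the exponential
#'   spatial covariance kernel (> 0).
#' @param class_effects data.frame with columns `geneset`, `annotation`,
#'   `class`, `effect` planting per-class mean shifts (in SD units of the
#'   spatial field) on the genes of a set.
#' @param noise_sd within-donor sample noise SD (intensity units).
#' @param share_weight weight of the shared pathway factor in each gene's
#'   spatial pattern (in [0, 1]).
#' @param fraction_unsampled fraction of parcels left unsampled per donor.
#' @param right_hemisphere_donors how many donors carry right-hemisphere
#'   samples (default 2 of 6).
#' @param decoy_fraction fraction of genes given a second, unstable decoy
#'   probe.
#' @param background_fraction fraction of probe-sample pairs flagged as
#'   below background.
#' @param sample_jitter_mm SD of the sample-coordinate jitter about parcel
#'   centroids (mm).
#' @param n_regions,n_per_cell lifespan design: cortical regions and donors
#'   per stage (each donor contributes one sample per region).
#' @param stage_effects named list: gene set -> numeric vector of per-stage
#'   log2 mean shifts (length = number of stages).
#' @param lifespan_noise_sd between-sample noise SD on the log2 scale.
#' @param seed integer seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_parcels_per_hemisphere = 100,
                           n_donors = 6,
                           n_genes = 60,
                           correlation_length = 0.3,
                           class_effects = NULL,
                           noise_sd = 0.5,
                           share_weight = 0.7,
                           fraction_unsampled = 0.15,
                           right_hemisphere_donors = 2,
                           decoy_fraction = 0.3,
                           background_fraction = 0.05,
                           sample_jitter_mm = 0.5,
                           n_regions = 6,
                           n_per_cell = 4,
                           stage_effects = default_stage_effects(),
                           lifespan_noise_sd = 0.5,
                           seed = 1) {
  stopifnot(n_parcels_per_hemisphere >= 10, n_donors >= 1,
            correlation_length > 0, n_genes >= 1,
            share_weight >= 0, share_weight <= 1,
            fraction_unsampled >= 0, fraction_unsampled < 1,
            right_hemisphere_donors >= 0,
            right_hemisphere_donors <= n_donors)
  structure(list(n_parcels_per_hemisphere = n_parcels_per_hemisphere,
                 n_donors = n_donors, n_genes = n_genes,
                 correlation_length = correlation_length,
                 class_effects = class_effects, noise_sd = noise_sd,
                 share_weight = share_weight,
                 fraction_unsampled = fraction_unsampled,
                 right_hemisphere_donors = right_hemisphere_donors,
                 decoy_fraction = decoy_fraction,
                 background_fraction = background_fraction,
                 sample_jitter_mm = sample_jitter_mm,
                 n_regions = n_regions, n_per_cell = n_per_cell,
                 stage_effects = stage_effects,
                 lifespan_noise_sd = lifespan_noise_sd,
                 seed = seed),
            class = "synthetic_spec")
}

#' Default planted stage-effect profiles
#'
#' Log2 mean shifts over the eight developmental stages emulating the
#' canonical trajectories: the ATP-producing pathways rise from the fetal
#' stages, peak in childhood and settle to adult levels, while the anabolic
#' pentose-phosphate-like set is highest prenatally and declines
#' monotonically through life.
#'
#' @return named list of numeric vectors of length 8.
#' @export
default_stage_effects <- function() {
  list(glycolysis = c(-1.2, -0.9, -0.4, 0.5, 1.0, 0.9, 0.6, 0.4),
       ppp        = c(1.6, 1.2, 0.8, 0.2, -0.2, -0.5, -0.8, -1.1),
       tca        = c(-1.1, -0.8, -0.3, 0.5, 0.9, 0.8, 0.5, 0.3),
       oxphos     = c(-1.4, -1.0, -0.4, 0.5, 1.0, 1.1, 0.7, 0.5),
       lactate    = c(-1.0, -0.7, -0.2, 0.6, 0.9, 0.8, 0.6, 0.4))
}

#' Synthetic pathway-like gene sets
#'
#' Five gene sets of 8-12 synthetic gene symbols each, named after the five
#' energy pathways so planted effects can be keyed by set.
#'
#' @param sizes integer vector of set sizes.
#' @return named list of [pathway_geneset()]s.
#' @export
make_synthetic_genesets <- function(sizes = c(glycolysis = 12, ppp = 8,
                                              tca = 10, oxphos = 12,
                                              lactate = 8)) {
  out <- lapply(seq_along(sizes), function(i) {
    nm <- names(sizes)[i]
    genes <- sprintf("%s%02d", toupper(substr(nm, 1, 3)), seq_len(sizes[i]))
    pathway_geneset(nm, genes)
  })
  names(out) <- names(sizes)
  out
}

#' Synthetic spherical parcellation
#'
#' Each hemisphere is modelled as its own full sphere of parcel centroids
#' (near-uniform Fibonacci lattice with seeded jitter, scaled to a
#' brain-like hemisphere radius and offset laterally from the midline); the
#' right hemisphere is the exact sagittal mirror of the left.  Two
#' categorical annotations (`class`, `network`) are built from spatially
#' contiguous k-means clusters of the left-hemisphere lattice and mirrored
#' to the right.
#'
#' @param n_per_hemisphere parcels per hemisphere.
#' @param n_classes clusters for the `class` annotation (default 7).
#' @param n_networks clusters for the `network` annotation (default 7).
#' @param seed integer seed.
#' @param radius_mm hemisphere sphere radius in mm (default 35).
#' @param offset_mm lateral offset of each hemisphere centre from the
#'   midline (default 45; must exceed `radius_mm` so the sign of x encodes
#'   hemisphere).
#' @param jitter_sd angular jitter SD (default 0.02).
#' @return a [parcellation()].
#' @export
make_parcellation <- function(n_per_hemisphere = 100, n_classes = 7,
                              n_networks = 7, seed = 1, radius_mm = 35,
                              offset_mm = 45, jitter_sd = 0.02) {
  stopifnot(offset_mm > radius_mm)
  set.seed(seed)
  n <- n_per_hemisphere
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n)
  zc <- 1 - 2 * (i - 0.5) / n
  theta <- 2 * pi * ((i * golden) %% 1)
  r <- sqrt(pmax(1 - zc^2, 0))
  u <- cbind(x = r * cos(theta), y = r * sin(theta), z = zc)
  u <- u + matrix(stats::rnorm(3 * n, sd = jitter_sd), n, 3)
  u <- u / sqrt(rowSums(u^2))
  left <- sweep(u * radius_mm, 2, c(-offset_mm, 0, 0), "+")
  right <- left
  right[, 1] <- -right[, 1]
  centroid <- rbind(left, right)
  cl <- stats::kmeans(u, centers = n_classes, nstart = 5)$cluster
  nw <- stats::kmeans(u[, c("y", "z")], centers = n_networks,
                      nstart = 5)$cluster
  parcellation(parcel_id = c(sprintf("L%03d", i), sprintf("R%03d", i)),
               hemisphere = rep(c("L", "R"), each = n),
               centroid = centroid,
               annotations = list(class = paste0("class", c(cl, cl)),
                                  network = paste0("net", c(nw, nw))))
}

#' Gaussian-process maps on the parcellated sphere
#'
#' Zero-mean Gaussian fields with covariance exp(-d/lambda) between parcel
#' centroids, where d is the great-circle distance on a common unit sphere
#' (each hemisphere normalized about its own centre, the right hemisphere
#' reflected so homotopic parcels align), via Cholesky factorization of the
#' jittered covariance matrix.  With `bilateral = "independent"` (the
#' default) the two hemispheres carry independent fields (block-diagonal
#' kernel), the appropriate null for per-hemisphere permutation studies;
#' with `bilateral = "mirrored"` homotopic parcels are maximally correlated,
#' emulating the near-symmetry of real cortical maps.
#'
#' @param parc a [parcellation()].
#' @param correlation_length lambda, in radians (> 0).
#' @param n number of independent maps (default 1).
#' @param seed optional integer seed.
#' @param jitter diagonal jitter (default 1e-8).
#' @param bilateral `"independent"` or `"mirrored"` (see above).
#' @return numeric P x n matrix of map values.
#' @export
gp_maps <- function(parc, correlation_length, n = 1, seed = NULL,
                    jitter = 1e-8,
                    bilateral = c("independent", "mirrored")) {
  stopifnot(correlation_length > 0, n >= 1)
  bilateral <- match.arg(bilateral)
  if (!is.null(seed)) set.seed(seed)
  u <- common_sphere(parc)
  d <- acos(pmin(pmax(tcrossprod(u), -1), 1))
  C <- exp(-d / correlation_length)
  if (bilateral == "independent") {
    C[outer(parc$hemisphere, parc$hemisphere, "!=")] <- 0
  }
  diag(C) <- diag(C) + jitter
  L <- tryCatch(chol(C), error = function(e) {
    stop("spatial covariance is not positive definite after jitter",
         call. = FALSE)
  })
  Z <- matrix(stats::rnorm(nrow(u) * n), nrow(u), n)
  out <- crossprod(L, Z)
  rownames(out) <- parc$parcel_id
  out
}

# Planted parcel-by-gene ground-truth patterns: per gene set a shared
# spatial factor plus gene-specific fields, with optional class effects.
# Patterns are bilaterally symmetric (right = mirrored left), the working
# assumption behind mirroring tissue samples across hemispheres.
make_truth_patterns <- function(spec, parc, genesets) {
  set_genes <- lapply(genesets, function(g) g$genes)
  genes <- unlist(set_genes, use.names = FALSE)
  n_bg <- max(0, spec$n_genes - length(genes))
  if (n_bg > 0) genes <- c(genes, sprintf("BG%03d", seq_len(n_bg)))
  P <- n_parcels(parc)
  w <- spec$share_weight
  shared <- gp_maps(parc, spec$correlation_length, n = length(genesets),
                    bilateral = "mirrored")
  own <- gp_maps(parc, spec$correlation_length, n = length(genes),
                 bilateral = "mirrored")
  truth <- matrix(NA_real_, P, length(genes),
                  dimnames = list(parc$parcel_id, genes))
  for (j in seq_along(genes)) {
    set_idx <- which(vapply(set_genes, function(g) genes[j] %in% g,
                            logical(1)))
    truth[, j] <- if (length(set_idx)) {
      w * shared[, set_idx[1]] + sqrt(1 - w^2) * own[, j]
    } else {
      own[, j]
    }
  }
  # bilateral symmetry: copy each left parcel's value to its mirror twin
  idx_l <- which(parc$hemisphere == "L")
  idx_r <- which(parc$hemisphere == "R")
  if (length(idx_l) == length(idx_r)) {
    mirror_of <- match_mirror(parc, idx_l, idx_r)
    truth[idx_r[mirror_of], ] <- truth[idx_l, , drop = FALSE]
  }
  ce <- spec$class_effects
  if (!is.null(ce) && nrow(ce)) {
    for (k in seq_len(nrow(ce))) {
      ann <- parc$annotations[[ce$annotation[k]]]
      mask <- which(as.character(ann) == ce$class[k])
      cols <- set_genes[[ce$geneset[k]]]
      truth[mask, cols] <- truth[mask, cols] + ce$effect[k]
    }
  }
  truth
}

# For each left parcel, the index (into idx_r) of the right parcel nearest
# to its sagittal mirror image.
match_mirror <- function(parc, idx_l, idx_r) {
  lm <- parc$centroid[idx_l, , drop = FALSE]
  lm[, 1] <- -lm[, 1]
  rc <- parc$centroid[idx_r, , drop = FALSE]
  vapply(seq_len(nrow(lm)), function(i) {
    which.min(colSums((t(rc) - lm[i, ])^2))
  }, integer(1))
}

#' Synthetic donor sample tables
#'
#' Emulates a multi-donor microarray cohort: per donor, one tissue sample at
#' a jittered centroid of each sampled parcel (a configurable fraction of
#' parcels is left unsampled; only the first `right_hemisphere_donors`
#' donors carry right-hemisphere samples).  Gene intensities follow shared
#' spatial patterns (Gaussian-process fields per gene set plus gene-specific
#' fields and planted class effects) with donor-level noise.  A configurable
#' fraction of genes receives a second decoy probe whose regional profile is
#' independently shuffled per donor (so its cross-donor stability is low);
#' faithful probes carry the suffix `_2` and decoys `_1`, so a naive
#' lexicographic choice would pick the decoy.  A configurable fraction of
#' probe-sample pairs is flagged below background.
#'
#' @param spec a [synthetic_spec()].
#' @param parc a [parcellation()] (defaults to one generated from `spec`).
#' @param genesets named list of [pathway_geneset()]s (defaults to
#'   [make_synthetic_genesets()]).
#' @return list with elements `donors` (list of [donor_sample_table()]s),
#'   `truth` (parcels x genes ground-truth pattern matrix), `parc`,
#'   `genesets`, `decoy_genes`.
#' @export
make_donor_tables <- function(spec, parc = NULL, genesets = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  if (is.null(parc)) {
    parc <- make_parcellation(spec$n_parcels_per_hemisphere,
                              seed = spec$seed)
  }
  if (is.null(genesets)) genesets <- make_synthetic_genesets()
  truth <- make_truth_patterns(spec, parc, genesets)
  genes <- colnames(truth)
  P <- n_parcels(parc)
  n_decoy <- round(spec$decoy_fraction * length(genes))
  decoy_genes <- if (n_decoy > 0) sort(sample(genes, n_decoy)) else character()
  probes <- data.frame(
    probe_id = c(paste0(genes, "_2"),
                 if (length(decoy_genes)) paste0(decoy_genes, "_1")),
    gene = c(genes, decoy_genes),
    stringsAsFactors = FALSE)
  baseline <- 8
  donors <- lapply(seq_len(spec$n_donors), function(d) {
    hemis <- if (d <= spec$right_hemisphere_donors) c("L", "R") else "L"
    cand <- which(parc$hemisphere %in% hemis)
    n_drop <- floor(spec$fraction_unsampled * length(cand))
    sampled <- sort(if (n_drop > 0) {
      setdiff(cand, sample(cand, n_drop))
    } else cand)
    xyz <- parc$centroid[sampled, , drop = FALSE] +
      matrix(stats::rnorm(3 * length(sampled), sd = spec$sample_jitter_mm),
             length(sampled), 3)
    samples <- data.frame(sample_id = sprintf("D%d_S%03d", d,
                                              seq_along(sampled)),
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          structure = parc$parcel_id[sampled],
                          stringsAsFactors = FALSE)
    faithful <- baseline + t(truth[sampled, , drop = FALSE]) +
      matrix(stats::rnorm(length(genes) * length(sampled),
                          sd = spec$noise_sd),
             length(genes), length(sampled))
    rownames(faithful) <- paste0(genes, "_2")
    expr <- faithful
    if (length(decoy_genes)) {
      shuffle <- sample.int(P)  # donor-specific parcel shuffle
      decoy <- baseline +
        t(truth[shuffle, decoy_genes, drop = FALSE][seq_along(sampled), ,
                                                    drop = FALSE]) +
        matrix(stats::rnorm(length(decoy_genes) * length(sampled),
                            sd = spec$noise_sd),
               length(decoy_genes), length(sampled))
      rownames(decoy) <- paste0(decoy_genes, "_1")
      expr <- rbind(faithful, decoy)
    }
    expr <- expr[probes$probe_id, , drop = FALSE]
    pa <- matrix(stats::runif(length(expr)) >= spec$background_fraction,
                 nrow(expr), ncol(expr))
    donor_sample_table(paste0("donor", d), samples, probes, expr, pa)
  })
  list(donors = donors, truth = truth, parc = parc, genesets = genesets,
       decoy_genes = decoy_genes)
}

#' Synthetic developmental expression dataset
#'
#' Emulates a lifespan RNA-seq cohort: for every stage of the stage table,
#' `n_per_cell` donors with ages drawn uniformly within the stage interval,
#' each contributing one cortical sample per region.  RPKM values are
#' log-normal about per-gene baselines; genes belonging to a set listed in
#' `spec$stage_effects` have their log2 means shifted by the set's
#' per-stage profile.  The dataset plants one always-low gene (`ALWAYSLOW`,
#' RPKM < 1 everywhere) to exercise the expression filter and duplicates
#' one gene symbol to exercise deduplication.
#'
#' @param spec a [synthetic_spec()].
#' @param genesets named list of [pathway_geneset()]s (defaults to
#'   [make_synthetic_genesets()]).
#' @param stage_table stage table (default [default_stage_table()]).
#' @return list with elements `dataset` (a [lifespan_dataset()]), `truth`
#'   (named list of planted per-stage log2 profiles) and `duplicated_gene`.
#' @export
make_lifespan_dataset <- function(spec, genesets = NULL,
                                  stage_table = default_stage_table()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  if (is.null(genesets)) genesets <- make_synthetic_genesets()
  effects <- spec$stage_effects
  stopifnot(all(names(effects) %in% names(genesets)))
  tab <- stage_table[order(stage_table$index), ]
  n_stage <- nrow(tab)
  for (e in effects) stopifnot(length(e) == n_stage)
  regions <- sprintf("region%02d", seq_len(spec$n_regions))
  genes <- unlist(lapply(genesets, function(g) g$genes), use.names = FALSE)
  genes <- c(genes, sprintf("LBG%03d", seq_len(max(0, spec$n_genes -
                                                     length(genes)))))
  donors <- expand.grid(rep = seq_len(spec$n_per_cell),
                        stage_idx = seq_len(n_stage))
  donors$donor_id <- sprintf("ld%02d_%d", donors$stage_idx, donors$rep)
  donors$age_pcd <- stats::runif(nrow(donors),
                                 tab$min_pcd[donors$stage_idx],
                                 tab$max_pcd[donors$stage_idx])
  samples <- do.call(rbind, lapply(seq_len(nrow(donors)), function(i) {
    data.frame(sample_id = paste0(donors$donor_id[i], "_", regions),
               donor_id = donors$donor_id[i], region = regions,
               age_pcd = donors$age_pcd[i], stringsAsFactors = FALSE)
  }))
  baseline <- stats::runif(length(genes), 2, 6)
  names(baseline) <- genes
  shift <- matrix(0, length(genes), n_stage, dimnames = list(genes, tab$stage))
  for (nm in names(effects)) {
    shift[genesets[[nm]]$genes, ] <-
      matrix(effects[[nm]], nrow = length(genesets[[nm]]$genes),
             ncol = n_stage, byrow = TRUE)
  }
  stage_idx <- match(stage_of_age(samples$age_pcd, tab), tab$stage)
  log2mean <- baseline + shift[, stage_idx, drop = FALSE]
  lognoise <- matrix(stats::rnorm(length(log2mean),
                                  sd = spec$lifespan_noise_sd),
                     nrow(log2mean), ncol(log2mean))
  expr <- 2^(log2mean + lognoise)
  rownames(expr) <- genes
  # planted always-low gene and a duplicated symbol
  low <- matrix(stats::runif(ncol(expr), 0, 0.5), 1, ncol(expr),
                dimnames = list("ALWAYSLOW", NULL))
  dup_gene <- genes[1]
  dup <- expr[dup_gene, , drop = FALSE] *
    2^stats::rnorm(ncol(expr), sd = spec$lifespan_noise_sd)
  rownames(dup) <- dup_gene
  expr <- rbind(expr, low, dup)
  ds <- lifespan_dataset(samples, expr, tab)
  list(dataset = ds, truth = effects, duplicated_gene = dup_gene)
}
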