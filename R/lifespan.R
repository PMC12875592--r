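#' Default developmental stage table
#'
#' Eight major developmental stages with age bounds in post-conception days
#' (pcd; birth = 280 pcd): early/mid/late fetal, infancy, early and late
#' childhood, adolescence and adulthood.  Intervals are ordered,
#' non-overlapping and cover the study range; a sample belongs to the stage
#' whose interval contains its age (lower bound inclusive).
#'
#' @return data.frame with columns `stage`, `min_pcd`, `max_pcd`, `index`.
#' @export
default_stage_table <- function() {
  path <- system.file("extdata", "stage_table.tsv", package = "energymaps")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_stage_table(tab)
  tab
}

validate_stage_table <- function(tab) {
  stopifnot(all(c("stage", "min_pcd", "max_pcd", "index") %in% names(tab)))
  tab <- tab[order(tab$index), ]
  if (any(tab$min_pcd >= tab$max_pcd)) {
    stop("stage intervals must have min < max", call. = FALSE)
  }
  if (nrow(tab) > 1 && any(tab$min_pcd[-1] != tab$max_pcd[-nrow(tab)])) {
    stop("stage intervals must be contiguous and non-overlapping",
         call. = FALSE)
  }
  invisible(tab)
}

#' Stage of an age in post-conception days
#'
#' @param age_pcd numeric ages (> 0) in post-conception days.
#' @param stage_table a stage table as from [default_stage_table()].
#' @return character vector of stage labels (`NA` outside the covered range).
#' @export
stage_of_age <- function(age_pcd, stage_table = default_stage_table()) {
  tab <- stage_table[order(stage_table$index), ]
  breaks <- c(tab$min_pcd, tab$max_pcd[nrow(tab)])
  idx <- findInterval(age_pcd, breaks, rightmost.closed = TRUE)
  out <- rep(NA_character_, length(age_pcd))
  ok <- idx >= 1 & idx <= nrow(tab)
  out[ok] <- tab$stage[idx[ok]]
  out
}

#' Construct a developmental expression dataset
#'
#' @param samples data.frame with columns `sample_id`, `donor_id`, `region`,
#'   `age_pcd` (and optionally `stage`; recomputed from the stage table when
#'   absent).
#' @param expr numeric genes x samples matrix of RPKM-scale nonnegative
#'   values; rownames are gene symbols (duplicates allowed until
#'   [lifespan_cleanup()]).
#' @param stage_table stage table used to bin ages.
#' @return object of class `lifespan_dataset`.
#' @export
lifespan_dataset <- function(samples, expr, stage_table = default_stage_table()) {
  stopifnot(all(c("sample_id", "donor_id", "region", "age_pcd") %in%
                  names(samples)),
            ncol(expr) == nrow(samples),
            all(is.finite(expr)), all(expr >= 0), all(samples$age_pcd > 0))
  samples$sample_id <- as.character(samples$sample_id)
  colnames(expr) <- samples$sample_id
  samples$stage <- stage_of_age(samples$age_pcd, stage_table)
  if (anyNA(samples$stage)) {
    stop("sample age(s) outside the stage table range", call. = FALSE)
  }
  structure(list(samples = samples, expr = expr, stage_table = stage_table),
            class = "lifespan_dataset")
}

#' @export
print.lifespan_dataset <- function(x, ...) {
  cat(sprintf("<lifespan_dataset> %d genes x %d samples, %d regions, %d stages\n",
              nrow(x$expr), ncol(x$expr), length(unique(x$samples$region)),
              length(unique(x$samples$stage))))
  invisible(x)
}

#' Clean up a developmental expression dataset
#'
#' Three filters, applied in order: (1) regions lacking a sample in any
#' stage of the stage table are dropped; (2) duplicate gene symbols are
#' collapsed to their first occurrence; (3) a gene is retained iff, within
#' every retained region-by-stage cell, at least `min_fraction` of that
#' cell's samples express it (RPKM >= `min_rpkm` for the RNA-seq variant;
#' log2 signal >= `log2_threshold` for the microarray variant).  The 80%
#' boundary is inclusive.  Idempotent.
#'
#' @param ds a [lifespan_dataset()].
#' @param min_rpkm expression threshold on the RPKM scale (default 1).
#' @param min_fraction required fraction of expressing samples per cell
#'   (default 0.8).
#' @param filter `"rpkm"` (RNA-seq rule) or `"log2signal"` (microarray
#'   rule).
#' @param log2_threshold threshold for the microarray variant (default 6).
#' @return the filtered `lifespan_dataset`; errors if no region survives.
#' @export
lifespan_cleanup <- function(ds, min_rpkm = 1, min_fraction = 0.8,
                             filter = c("rpkm", "log2signal"),
                             log2_threshold = 6) {
  stopifnot(inherits(ds, "lifespan_dataset"))
  filter <- match.arg(filter)
  stages <- ds$stage_table$stage
  # (1) regions with >= 1 sample in every stage
  tab <- table(ds$samples$region, factor(ds$samples$stage, levels = stages))
  keep_regions <- rownames(tab)[apply(tab > 0, 1, all)]
  if (length(keep_regions) == 0L) {
    stop("no region has samples in every developmental stage", call. = FALSE)
  }
  keep_s <- ds$samples$region %in% keep_regions
  samples <- ds$samples[keep_s, , drop = FALSE]
  expr <- ds$expr[, keep_s, drop = FALSE]
  # (2) duplicate gene symbols -> first occurrence
  first <- !duplicated(rownames(expr))
  expr <- expr[first, , drop = FALSE]
  # (3) expression filter per region x stage cell
  expressed <- if (filter == "rpkm") {
    expr >= min_rpkm
  } else {
    log2(expr + 1) >= log2_threshold
  }
  cell <- interaction(samples$region, samples$stage, drop = TRUE)
  ok <- rep(TRUE, nrow(expr))
  for (cl in levels(cell)) {
    cols <- which(cell == cl)
    ok <- ok & (rowMeans(expressed[, cols, drop = FALSE]) >= min_fraction)
  }
  expr <- expr[ok, , drop = FALSE]
  out <- ds
  out$samples <- samples
  out$expr <- expr
  out
}

#' Log2 transform with unit offset
#'
#' `log2(x + 1)` elementwise; the +1 offset keeps the transform total on
#' zero entries.
#'
#' @param x nonnegative numeric vector or matrix.
#' @return transformed values.
#' @export
log2_transform <- function(x) {
  if (any(x < 0)) stop("negative expression values", call. = FALSE)
  log2(x + 1)
}

#' Upper-quartile normalization across donors
#'
#' Each donor's expression is divided by that donor's 75th percentile
#' (type-7 quantile over all its entries) and multiplied by the mean 75th
#' percentile across donors, so that afterwards every donor's upper
#' quartile equals the pre-normalization mean.
#'
#' @param expr numeric genes x samples matrix.
#' @param donor per-sample donor ids (length = ncol(expr)).
#' @return the normalized matrix.
#' @export
upper_quartile_normalize <- function(expr, donor) {
  stopifnot(length(donor) == ncol(expr))
  donor <- as.character(donor)
  q75 <- vapply(split(seq_len(ncol(expr)), donor), function(cols) {
    stats::quantile(expr[, cols, drop = FALSE], 0.75, type = 7, names = FALSE)
  }, numeric(1))
  if (any(q75 == 0)) {
    stop("zero 75th percentile for donor(s): ",
         paste(names(q75)[q75 == 0], collapse = ", "), call. = FALSE)
  }
  target <- mean(q75)
  scale_by <- target / q75[donor]
  expr * rep(scale_by, each = nrow(expr))
}

#' Per-stage median trajectory of a pathway
#'
#' Per sample, the unweighted mean over the pathway's available genes; per
#' stage, the median over samples, ordered by stage index.
#'
#' @param ds a [lifespan_dataset()] (typically cleaned, log2-transformed and
#'   upper-quartile normalized).
#' @param gs a [pathway_geneset()] with at least one gene in the dataset.
#' @return data.frame with columns `stage`, `index`, `n`, `median`; stages
#'   with zero samples are omitted with a warning.
#' @export
stage_trajectory <- function(ds, gs) {
  stopifnot(inherits(ds, "lifespan_dataset"), inherits(gs, "pathway_geneset"))
  present <- intersect(gs$genes, rownames(ds$expr))
  if (length(present) == 0L) {
    stop("no genes of pathway '", gs$name, "' present in the dataset",
         call. = FALSE)
  }
  sample_mean <- colMeans(ds$expr[present, , drop = FALSE])
  tab <- ds$stage_table[order(ds$stage_table$index), ]
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    sel <- ds$samples$stage == tab$stage[i]
    if (!any(sel)) {
      warning("stage with zero samples omitted: ", tab$stage[i], call. = FALSE)
      return(NULL)
    }
    data.frame(stage = tab$stage[i], index = tab$index[i], n = sum(sel),
               median = stats::median(sample_mean[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' LOESS trajectory against log10 age
#'
#' Locally weighted linear regression (tricube kernel, degree 1) of the
#' values on log10(age in post-conception days), evaluated on an evenly
#' spaced grid over the observed range.  Fitting uses the exact (direct)
#' local-regression surface.
#'
#' @param age_pcd ages in post-conception days (> 0), length >= 10.
#' @param values response values, same length.
#' @param span smoothing span in (0, 1] (default 0.75).
#' @param n_grid number of grid points (default 100).
#' @return data.frame with columns `log10_age`, `fitted`.
#' @export
loess_trajectory <- function(age_pcd, values, span = 0.75, n_grid = 100) {
  stopifnot(length(age_pcd) == length(values), all(age_pcd > 0),
            span > 0, span <= 1)
  if (length(age_pcd) < 10) stop("need at least 10 points", call. = FALSE)
  lx <- log10(age_pcd)
  if (length(unique(lx)) < 3) {
    stop("need at least 3 distinct ages", call. = FALSE)
  }
  fit <- stats::loess(values ~ lx, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(lx), max(lx), length.out = n_grid)
  data.frame(log10_age = grid,
             fitted = stats::predict(fit, newdata = data.frame(lx = grid)))
}
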