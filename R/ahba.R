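#' Construct a donor sample table
#'
#' One donor's tissue samples: coordinates (mm, x > 0 = right hemisphere),
#' structure labels, and probe-by-sample intensities with above-background
#' calls.
#'
#' @param donor_id donor identifier.
#' @param samples data.frame with columns `sample_id`, `x`, `y`, `z`,
#'   `structure`.
#' @param probes data.frame with columns `probe_id`, `gene`.
#' @param expr numeric probes x samples intensity matrix (dimnames set from
#'   `probes$probe_id` and `samples$sample_id`).
#' @param pa logical probes x samples matrix of above-background calls.
#' @return object of class `donor_sample_table`.
#' @export
donor_sample_table <- function(donor_id, samples, probes, expr, pa) {
  stopifnot(nrow(samples) >= 1,
            all(c("sample_id", "x", "y", "z") %in% names(samples)),
            all(c("probe_id", "gene") %in% names(probes)),
            nrow(expr) == nrow(probes), ncol(expr) == nrow(samples),
            identical(dim(expr), dim(pa)),
            all(is.finite(as.matrix(samples[, c("x", "y", "z")]))))
  if (!"structure" %in% names(samples)) samples$structure <- NA_character_
  samples$sample_id <- as.character(samples$sample_id)
  probes$probe_id <- as.character(probes$probe_id)
  probes$gene <- toupper(trimws(as.character(probes$gene)))
  dimnames(expr) <- list(probes$probe_id, samples$sample_id)
  dimnames(pa) <- list(probes$probe_id, samples$sample_id)
  structure(list(donor_id = as.character(donor_id), samples = samples,
                 probes = probes, expr = expr, pa = pa),
            class = "donor_sample_table")
}

#' @export
print.donor_sample_table <- function(x, ...) {
  cat(sprintf("<donor_sample_table> donor %s: %d samples, %d probes (%d genes)\n",
              x$donor_id, nrow(x$samples), nrow(x$probes),
              length(unique(x$probes$gene))))
  invisible(x)
}

#' Intensity-based probe filter
#'
#' A probe is retained iff the fraction of samples -- pooled across donors --
#' in which its intensity falls below background is strictly less than
#' `max_below_fraction`.  With the default 0.5 this discards probes below
#' background in at least half of all samples (the boundary case is
#' discarded).
#'
#' @param pa logical probes x samples matrix of above-background calls, with
#'   samples pooled across donors, or a list of `donor_sample_table`s whose
#'   `pa` matrices are pooled column-wise.
#' @param max_below_fraction proportion in (0, 1]; default 0.5.
#' @return character vector of retained probe ids, with attribute
#'   `below_fraction` holding the per-probe below-background fraction.
#' @export
filter_probes <- function(pa, max_below_fraction = 0.5) {
  stopifnot(max_below_fraction > 0, max_below_fraction <= 1)
  if (is.list(pa) && !is.matrix(pa)) {
    stopifnot(all(vapply(pa, inherits, logical(1), "donor_sample_table")))
    ids <- lapply(pa, function(d) d$probes$probe_id)
    if (length(unique(lapply(ids, sort))) != 1L) {
      stop("donors must share the same probe set", call. = FALSE)
    }
    ref <- ids[[1]]
    pa <- do.call(cbind, lapply(pa, function(d) d$pa[ref, , drop = FALSE]))
  }
  if (ncol(pa) == 0L) stop("probes have zero samples", call. = FALSE)
  frac_below <- rowMeans(!pa)
  keep <- frac_below < max_below_fraction
  out <- rownames(pa)[keep]
  attr(out, "below_fraction") <- frac_below
  out
}

#' Robust sigmoid normalization
#'
#' Outlier-robust scaling through a logistic function centred at the median
#' with scale IQR/1.35 (the IQR-to-sigma conversion for a normal
#' distribution), followed by min-max rescaling to the unit interval.
#' Strictly monotone and invariant to positive affine transforms of the
#' input.
#'
#' @param x numeric vector, length >= 2.
#' @param rescale rescale the sigmoid output to [0, 1] (default TRUE).
#' @return normalized vector.  A zero-IQR input yields a constant 0.5 vector
#'   (rescale skipped) flagged with attribute `degenerate = TRUE`.
#' @export
robust_sigmoid <- function(x, rescale = TRUE) {
  stopifnot(is.numeric(x), length(x) >= 2, all(is.finite(x)))
  med <- stats::median(x)
  iqr <- stats::IQR(x, type = 7)
  if (iqr == 0) {
    y <- rep(0.5, length(x))
    attr(y, "degenerate") <- TRUE
    return(y)
  }
  y <- 1 / (1 + exp(-(x - med) / (iqr / 1.35)))
  if (rescale) y <- (y - min(y)) / (max(y) - min(y))
  y
}

#' Differential stability of a regional expression profile
#'
#' Mean Spearman correlation of one gene's (or probe's) regional profile over
#' all donor pairs, computed on parcels sampled in both donors of a pair.
#' Donor pairs where either profile has zero rank variance (or fewer than 3
#' shared parcels) are undefined and excluded from the mean with a warning.
#'
#' @param profiles numeric parcels x donors matrix; `NA` marks parcels not
#'   sampled in a donor.
#' @return mean pairwise Spearman correlation in [-1, 1], or `NA` if every
#'   pair is undefined.
#' @export
differential_stability <- function(profiles) {
  profiles <- as.matrix(profiles)
  nd <- ncol(profiles)
  if (nd < 2) stop("differential stability requires >= 2 donors", call. = FALSE)
  vals <- numeric(0)
  dropped <- 0L
  for (i in seq_len(nd - 1)) {
    for (j in seq(i + 1, nd)) {
      ok <- stats::complete.cases(profiles[, c(i, j)])
      xi <- profiles[ok, i]
      xj <- profiles[ok, j]
      if (sum(ok) < 3 || stats::sd(xi) == 0 || stats::sd(xj) == 0) {
        dropped <- dropped + 1L
        next
      }
      vals <- c(vals, stats::cor(xi, xj, method = "spearman"))
    }
  }
  if (dropped > 0L) {
    warning(dropped, " donor pair(s) with undefined correlation excluded",
            call. = FALSE)
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

# Batch differential stability for many probes sharing the same parcel
# coverage per donor.  profiles_list: per-donor parcels x probes matrices
# with identical dimnames; returns a named per-probe DS vector.
ds_batch <- function(profiles_list) {
  nd <- length(profiles_list)
  stopifnot(nd >= 2)
  np <- ncol(profiles_list[[1]])
  acc <- matrix(NA_real_, nrow = np, ncol = nd * (nd - 1) / 2)
  pair <- 0L
  for (i in seq_len(nd - 1)) {
    for (j in seq(i + 1, nd)) {
      pair <- pair + 1L
      ok <- stats::complete.cases(profiles_list[[i]][, 1],
                                  profiles_list[[j]][, 1])
      if (sum(ok) < 3) next
      a <- profiles_list[[i]][ok, , drop = FALSE]
      b <- profiles_list[[j]][ok, , drop = FALSE]
      ra <- apply(a, 2, rank)
      rb <- apply(b, 2, rank)
      sa <- apply(ra, 2, stats::sd)
      sb <- apply(rb, 2, stats::sd)
      ra <- scale(ra)
      rb <- scale(rb)
      rho <- colSums(ra * rb) / (sum(ok) - 1)
      rho[sa == 0 | sb == 0] <- NA_real_
      acc[, pair] <- rho
    }
  }
  out <- rowMeans(acc, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  names(out) <- colnames(profiles_list[[1]])
  out
}

#' Select one probe per gene by differential stability
#'
#' For each gene, the probe with the most consistent regional profile across
#' donors (maximal differential stability) is selected.  Ties, and genes
#' whose DS is undefined for every probe (e.g. a single-donor dataset), fall
#' back to the lexicographically smallest probe id.
#'
#' @param ds named numeric vector of per-probe differential stability.
#' @param probe_gene data.frame with columns `probe_id`, `gene` covering the
#'   probes in `ds`.
#' @return named character vector mapping gene -> selected probe id.
#' @export
select_probe_per_gene <- function(ds, probe_gene) {
  probe_gene <- probe_gene[probe_gene$probe_id %in% names(ds), , drop = FALSE]
  if (nrow(probe_gene) == 0L) {
    stop("no retained probes to select from", call. = FALSE)
  }
  sel <- vapply(split(probe_gene$probe_id, probe_gene$gene), function(ids) {
    ids <- sort(ids)
    d <- ds[ids]
    if (all(is.na(d))) return(ids[1])
    best <- max(d, na.rm = TRUE)
    ids[which(!is.na(d) & d == best)][1]
  }, character(1))
  sel
}

#' Mirror tissue samples across the midline
#'
#' Adds, for every sample, a duplicate with the x-coordinate negated (the
#' sagittal mirror image), copying expression values and background calls.
#' Doubles the sample count; midline samples acquire a coincident duplicate.
#'
#' @param table a [donor_sample_table()].
#' @return a `donor_sample_table` with 2N samples; mirrored sample ids carry
#'   the suffix `"_m"`.
#' @export
mirror_samples <- function(table) {
  stopifnot(inherits(table, "donor_sample_table"))
  m <- table$samples
  m$sample_id <- paste0(m$sample_id, "_m")
  m$x <- -m$x
  samples <- rbind(table$samples, m)
  expr <- cbind(table$expr, table$expr)
  pa <- cbind(table$pa, table$pa)
  colnames(expr) <- colnames(pa) <- samples$sample_id
  donor_sample_table(table$donor_id, samples, table$probes, expr, pa)
}

#' Assign tissue samples to parcels
#'
#' Each sample is assigned to the parcel with the nearest centroid in the
#' same hemisphere, provided that distance is at most `tol_mm`; otherwise it
#' is left unassigned.  Samples exactly equidistant from two centroids go to
#' the parcel with the smaller index.  Sample hemisphere is taken from the
#' sign of x (x < 0 = left).
#'
#' @param samples data.frame with columns `x`, `y`, `z` (one row per sample),
#'   or a [donor_sample_table()].
#' @param parc a [parcellation()].
#' @param tol_mm assignment tolerance in mm (> 0; default 2).
#' @return integer vector of parcel indices into `parc$parcel_id` (`NA` =
#'   unassigned).
#' @export
assign_samples <- function(samples, parc, tol_mm = 2) {
  stopifnot(inherits(parc, "parcellation"), tol_mm > 0)
  if (inherits(samples, "donor_sample_table")) samples <- samples$samples
  if (n_parcels(parc) == 0L) stop("empty parcellation", call. = FALSE)
  xyz <- as.matrix(samples[, c("x", "y", "z")])
  hemi_s <- ifelse(xyz[, 1] < 0, "L", "R")
  out <- rep(NA_integer_, nrow(xyz))
  for (h in c("L", "R")) {
    si <- which(hemi_s == h)
    pi <- which(parc$hemisphere == h)
    if (!length(si) || !length(pi)) next
    cen <- parc$centroid[pi, , drop = FALSE]
    for (s in si) {
      d2 <- colSums((t(cen) - xyz[s, ])^2)
      best <- which.min(d2)  # ties -> first (lowest parcel index)
      if (sqrt(d2[best]) <= tol_mm) out[s] <- pi[best]
    }
  }
  out
}

#' Interpolate expression for parcels without samples
#'
#' Empty parcels receive the inverse-distance-weighted mean of the `k`
#' nearest tissue samples to the parcel centroid (weights 1/d normalized to
#' sum one, distances floored at `d_floor` mm).  This evaluates the
#' nearest-sample interpolation rule at parcel level.
#'
#' @param mat numeric parcels x genes matrix with `NA` rows for empty
#'   parcels.
#' @param sample_expr numeric samples x genes matrix of (normalized) sample
#'   expression.
#' @param sample_xyz numeric samples x 3 matrix of sample coordinates (mm).
#' @param parc a [parcellation()] aligned with the rows of `mat`.
#' @param k number of nearest samples to use (default 10).
#' @param d_floor minimum distance in mm (default 0.1).
#' @return the completed matrix (no `NA` rows).
#' @export
fill_missing_parcels <- function(mat, sample_expr, sample_xyz, parc,
                                 k = 10, d_floor = 0.1) {
  stopifnot(inherits(parc, "parcellation"), nrow(mat) == n_parcels(parc))
  if (nrow(sample_expr) == 0L) {
    stop("donor has zero assigned samples", call. = FALSE)
  }
  empty <- which(!stats::complete.cases(mat))
  for (p in empty) {
    d <- sqrt(colSums((t(sample_xyz) - parc$centroid[p, ])^2))
    take <- order(d)[seq_len(min(k, length(d)))]
    w <- 1 / pmax(d[take], d_floor)
    w <- w / sum(w)
    mat[p, ] <- as.numeric(w %*% sample_expr[take, , drop = FALSE])
  }
  mat
}

#' Construct a region-by-gene expression matrix
#' @param parcels ordered parcel ids; `genes` ordered gene symbols.
#' @param genes gene symbols matching the columns of `values`.
#' @param values numeric P x G matrix.
#' @param ds per-gene differential stability (named, may be `NA`).
#' @param n_donors number of donors averaged.
#' @return object of class `region_expression`.
#' @export
region_expression <- function(parcels, genes, values, ds, n_donors) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(parcels), ncol(values) == length(genes),
            length(ds) == length(genes))
  dimnames(values) <- list(parcels, genes)
  names(ds) <- genes
  structure(list(parcels = parcels, genes = genes, values = values,
                 ds = ds, n_donors = n_donors),
            class = "region_expression")
}

#' @export
print.region_expression <- function(x, ...) {
  cat(sprintf("<region_expression> %d parcels x %d genes (%d donor%s)\n",
              length(x$parcels), length(x$genes), x$n_donors,
              if (x$n_donors == 1) "" else "s"))
  invisible(x)
}

#' Assemble a donor-averaged parcel-by-gene expression matrix
#'
#' Runs the full microarray processing chain: pool above-background calls
#' across donors and filter probes; mirror samples bilaterally; assign
#' samples to parcels within `tol_mm`; compute per-probe differential
#' stability from raw within-parcel average profiles and select one probe
#' per gene; normalize each donor's sample-level expression with the robust
#' sigmoid across genes within sample, then across samples within gene;
#' average samples within parcel; interpolate empty parcels from the nearest
#' samples; average parcel-by-gene matrices across donors; and drop genes
#' whose differential stability does not exceed `ds_threshold`.
#'
#' @param donors list of [donor_sample_table()]s sharing a probe set.
#' @param parc a [parcellation()].
#' @param ds_threshold retain genes with DS strictly greater than this
#'   (default 0.1).  With a single donor DS is undefined and the filter is
#'   skipped.
#' @param tol_mm sample-to-parcel assignment tolerance (default 2 mm).
#' @param max_below_fraction probe intensity filter threshold (default 0.5).
#' @param mirror mirror samples bilaterally before assignment (default TRUE).
#' @param k_fill neighbours used to interpolate empty parcels (default 10).
#' @return a [region_expression()] with no missing entries, parcel order
#'   matching `parc`.
#' @export
assemble_expression <- function(donors, parc, ds_threshold = 0.1, tol_mm = 2,
                                max_below_fraction = 0.5, mirror = TRUE,
                                k_fill = 10) {
  stopifnot(length(donors) >= 1,
            all(vapply(donors, inherits, logical(1), "donor_sample_table")),
            inherits(parc, "parcellation"))
  P <- n_parcels(parc)
  keep_probes <- filter_probes(donors, max_below_fraction)
  if (length(keep_probes) == 0L) stop("no probes survive the intensity filter",
                                      call. = FALSE)

  prepped <- lapply(donors, function(d) {
    if (mirror) d <- mirror_samples(d)
    assign <- assign_samples(d$samples, parc, tol_mm)
    ok <- !is.na(assign)
    if (!any(ok)) stop("donor ", d$donor_id, " has no assignable samples",
                       call. = FALSE)
    list(donor = d, assign = assign[ok], which = which(ok))
  })

  # per-probe raw within-parcel average profiles, for probe selection
  probe_ids <- keep_probes
  raw_profiles <- lapply(prepped, function(pp) {
    e <- t(pp$donor$expr[probe_ids, pp$which, drop = FALSE])
    prof <- rowsum(e, group = pp$assign) / as.vector(table(pp$assign))
    out <- matrix(NA_real_, P, length(probe_ids),
                  dimnames = list(parc$parcel_id, probe_ids))
    out[as.integer(rownames(prof)), ] <- prof
    out
  })
  if (length(donors) >= 2) {
    ds_probe <- ds_batch(raw_profiles)
  } else {
    ds_probe <- stats::setNames(rep(NA_real_, length(probe_ids)), probe_ids)
  }
  sel <- select_probe_per_gene(ds_probe, donors[[1]]$probes)
  genes <- names(sel)

  per_donor <- lapply(prepped, function(pp) {
    e <- pp$donor$expr[sel, pp$which, drop = FALSE]
    rownames(e) <- genes
    # pass 1: across genes within each sample; pass 2: across samples per gene
    if (length(genes) >= 2) {
      e <- apply(e, 2, robust_sigmoid)
      rownames(e) <- genes
    }
    if (ncol(e) >= 2) {
      e <- t(apply(e, 1, robust_sigmoid))
      if (length(genes) == 1) e <- matrix(e, nrow = 1)
      rownames(e) <- genes
      colnames(e) <- pp$donor$samples$sample_id[pp$which]
    }
    mat <- rowsum(t(e), group = pp$assign) / as.vector(table(pp$assign))
    full <- matrix(NA_real_, P, length(genes),
                   dimnames = list(parc$parcel_id, genes))
    full[as.integer(rownames(mat)), ] <- mat
    xyz <- as.matrix(pp$donor$samples[pp$which, c("x", "y", "z")])
    fill_missing_parcels(full, t(e), xyz, parc, k = k_fill)
  })

  avg <- Reduce(`+`, per_donor) / length(per_donor)
  if (any(!is.finite(avg))) {
    stop("assembled matrix has missing entries after interpolation",
         call. = FALSE)
  }
  ds_gene <- ds_probe[sel]
  names(ds_gene) <- genes
  if (length(donors) >= 2) {
    keep <- !is.na(ds_gene) & ds_gene > ds_threshold
    avg <- avg[, keep, drop = FALSE]
    ds_gene <- ds_gene[keep]
    genes <- genes[keep]
  }
  out <- region_expression(parc$parcel_id, genes, avg, ds_gene,
                           length(donors))
  attr(out, "selected_probes") <- sel[genes]
  attr(out, "retained_probes") <- keep_probes
  out
}
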