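#' Random 3D rotation matrix
#'
#' Draws a rotation uniformly from SO(3) (Haar measure) via QR decomposition
#' of a standard-normal matrix with sign correction; reflections are mapped
#' to rotations by flipping one axis.
#'
#' @return 3 x 3 orthonormal matrix with determinant +1.
#' @export
random_rotation <- function() {
  z <- matrix(stats::rnorm(9), 3, 3)
  qd <- qr(z)
  Q <- qr.Q(qd)
  Q <- Q %*% diag(sign(diag(qr.R(qd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Project points onto the unit sphere about their own centroid mean.
project_unit <- function(xyz) {
  v <- sweep(xyz, 2, colMeans(xyz))
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) stop("cannot project a centroid at the hemisphere mean",
                          call. = FALSE)
  v / nrm
}

# Greedy ascending-distance matching of original to rotated unit vectors.
# Returns perm with perm[i] = rotated point matched to original position i.
spin_match <- function(orig, rotated) {
  n <- nrow(orig)
  D <- -tcrossprod(orig, rotated)  # monotone in angular/Euclidean distance
  ord <- order(D)
  greedy_match(ord - 1L, n)
}

#' Spatial-autocorrelation-preserving spin ensemble
#'
#' Builds `n_rot` duplicate-free parcel permutations by rotating parcel
#' centroids on the sphere.  Per rotation, left-hemisphere centroids
#' (projected to the unit sphere about the hemisphere mean) are rotated by a
#' random rotation R and right-hemisphere centroids by its sagittal mirror
#' M R M (M = diag(-1, 1, 1)); each original parcel is then assigned a
#' distinct rotated parcel by greedy ascending-distance matching within its
#' hemisphere, so permutations are hemisphere-closed bijections.
#'
#' @param parc a [parcellation()] with at least 2 parcels per hemisphere.
#' @param n_rot number of rotations (default 10000).
#' @param seed integer seed governing the whole ensemble.
#' @return object of class `spin_ensemble` with fields `perms` (n_rot x P
#'   integer matrix; row k maps parcel i to source parcel `perms[k, i]`),
#'   `n_rot`, `seed`.
#' @export
spin_permutations <- function(parc, n_rot = 10000, seed = NULL) {
  stopifnot(inherits(parc, "parcellation"), n_rot >= 1)
  if (!is.null(seed)) set.seed(seed)
  idx_l <- which(parc$hemisphere == "L")
  idx_r <- which(parc$hemisphere == "R")
  if (length(idx_l) < 2 || length(idx_r) < 2) {
    stop("each hemisphere needs at least 2 parcels", call. = FALSE)
  }
  u_l <- project_unit(parc$centroid[idx_l, , drop = FALSE])
  u_r <- project_unit(parc$centroid[idx_r, , drop = FALSE])
  M <- diag(c(-1, 1, 1))
  P <- n_parcels(parc)
  perms <- matrix(0L, n_rot, P)
  for (k in seq_len(n_rot)) {
    R <- random_rotation()
    Rm <- M %*% R %*% M
    p_l <- spin_match(u_l, u_l %*% t(R))
    p_r <- spin_match(u_r, u_r %*% t(Rm))
    row <- integer(P)
    row[idx_l] <- idx_l[p_l]
    row[idx_r] <- idx_r[p_r]
    perms[k, ] <- row
  }
  structure(list(perms = perms, n_rot = n_rot, seed = seed,
                 parcel_id = parc$parcel_id, kind = "spin"),
            class = "spin_ensemble")
}

#' Naive i.i.d. permutation ensemble
#'
#' Unconstrained random parcel permutations (ignoring spatial structure and
#' hemispheres), for comparison against the spin ensemble.
#'
#' @param P number of parcels, or a [parcellation()].
#' @param n_rot number of permutations.
#' @param seed integer seed.
#' @return object of class `spin_ensemble` with `kind = "iid"`.
#' @export
iid_permutations <- function(P, n_rot, seed = NULL) {
  if (inherits(P, "parcellation")) P <- n_parcels(P)
  if (!is.null(seed)) set.seed(seed)
  perms <- t(vapply(seq_len(n_rot), function(k) sample.int(P),
                    integer(P)))
  structure(list(perms = perms, n_rot = n_rot, seed = seed,
                 parcel_id = as.character(seq_len(P)), kind = "iid"),
            class = "spin_ensemble")
}

#' @export
print.spin_ensemble <- function(x, ...) {
  cat(sprintf("<spin_ensemble> %s: %d permutations x %d parcels (seed %s)\n",
              x$kind, x$n_rot, ncol(x$perms),
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

# Ranks standardized to mean 0, SD 1 (denominator n - 1); average ranks for
# ties.  Pearson on these equals Spearman's rho.
scale_ranks <- function(x) {
  r <- rank(x)
  s <- stats::sd(r)
  if (s == 0) return(rep(NaN, length(x)))
  (r - mean(r)) / s
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in [-1, 1]; `NA` with a warning if either vector has zero rank
#'   variance.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  rx <- scale_ranks(x)
  ry <- scale_ranks(y)
  if (anyNA(rx) || anyNA(ry)) {
    warning("zero rank variance; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(rx * ry) / (length(x) - 1)
}

#' Spin test for the correlation of two brain maps
#'
#' Observed statistic is the Spearman correlation of the two maps; the null
#' distribution is obtained by permuting the first map with each ensemble
#' row and recorrelating with the second.  The two-sided p-value uses +1
#' smoothing: p = (1 + #\{|null| >= |rho|\}) / (n_rot + 1), so p is never
#' below 1 / (n_rot + 1).
#'
#' @param a,b [brain_map()]s or numeric vectors aligned with the ensemble's
#'   parcellation.
#' @param ens a [spin_permutations()] ensemble.
#' @return object of class `correlation_result` with fields `rho`, `p_spin`,
#'   `n_rot`, `tail`, and the null correlations in `null_rho`.
#' @export
spin_correlation_test <- function(a, b, ens) {
  stopifnot(inherits(ens, "spin_ensemble"))
  av <- map_values(a)
  bv <- map_values(b)
  if (length(av) != length(bv)) stop("map length mismatch", call. = FALSE)
  if (length(av) != ncol(ens$perms)) {
    stop("maps are not aligned with the ensemble parcellation", call. = FALSE)
  }
  P <- length(av)
  ra <- scale_ranks(av)
  rb <- scale_ranks(bv)
  if (anyNA(ra) || anyNA(rb)) {
    stop("zero rank variance; spin test undefined", call. = FALSE)
  }
  rho <- sum(ra * rb) / (P - 1)
  # ranks of a permuted map are the permuted ranks, so nulls reduce to a
  # matrix-vector product over the standardized ranks
  RA <- matrix(ra[ens$perms], nrow = ens$n_rot)
  nulls <- as.numeric(RA %*% rb) / (P - 1)
  p <- (1 + sum(abs(nulls) >= abs(rho))) / (ens$n_rot + 1)
  structure(list(rho = rho, p_spin = p, n_rot = ens$n_rot,
                 tail = "two_sided", null_rho = nulls),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("rho = %.3f, p_spin = %.4g (%s, %d rotations)\n",
              x$rho, x$p_spin, x$tail, x$n_rot))
  invisible(x)
}

#' Class enrichment against spin nulls
#'
#' For each parcel class, the observed mean of the (z-scored) map over the
#' fixed class mask is compared with the means of the spun maps over the
#' same mask.  The two-sided p-value measures deviation from the null
#' median: p = (1 + #\{|null - med| >= |obs - med|\}) / (n_rot + 1), with
#' direction reported as the sign of obs - med.
#'
#' @param m a z-scored [brain_map()] or numeric vector.
#' @param labels per-parcel class labels aligned with the map.
#' @param ens a [spin_permutations()] ensemble.
#' @param ignore labels to skip (default `"ignore"`); empty classes are
#'   skipped with a warning.
#' @return data.frame with one row per class: `class`, `n_parcels`,
#'   `observed_mean`, `null_median`, `p_spin`, `direction`.
#' @export
class_enrichment_test <- function(m, labels, ens, ignore = "ignore") {
  stopifnot(inherits(ens, "spin_ensemble"))
  v <- map_values(m)
  labels <- as.character(labels)
  stopifnot(length(labels) == length(v), length(v) == ncol(ens$perms))
  classes <- setdiff(unique(labels[!is.na(labels)]), ignore)
  classes <- sort(classes)
  rows <- lapply(classes, function(cl) {
    mask <- which(!is.na(labels) & labels == cl)
    if (length(mask) == 0L) {
      warning("skipping empty class ", cl, call. = FALSE)
      return(NULL)
    }
    obs <- mean(v[mask])
    nulls <- rowMeans(matrix(v[ens$perms[, mask, drop = FALSE]],
                             nrow = ens$n_rot))
    med <- stats::median(nulls)
    p <- (1 + sum(abs(nulls - med) >= abs(obs - med))) / (ens$n_rot + 1)
    data.frame(class = cl, n_parcels = length(mask), observed_mean = obs,
               null_median = med, p_spin = p,
               direction = if (obs >= med) "greater" else "lesser",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate control; adjusted values are monotone in the
#' input and clipped at 1.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(is.numeric(pvals))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Node degree and strength of a connectivity matrix
#'
#' Degree counts the nonzero off-diagonal connections of each node; strength
#' sums the incident connection weights.
#'
#' @param adj square symmetric matrix with zero diagonal.
#' @param tol symmetry tolerance (default 1e-9).
#' @return data.frame with columns `node`, `degree`, `strength`.
#' @export
degree_strength <- function(adj, tol = 1e-9) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("matrix must be square", call. = FALSE)
  if (max(abs(adj - t(adj))) > tol) {
    stop("matrix asymmetric beyond tolerance", call. = FALSE)
  }
  if (any(diag(adj) != 0)) stop("diagonal must be zero", call. = FALSE)
  nodes <- rownames(adj)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(adj)))
  data.frame(node = nodes,
             degree = as.integer(rowSums(adj != 0)),
             strength = rowSums(adj),
             row.names = NULL, stringsAsFactors = FALSE)
}
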