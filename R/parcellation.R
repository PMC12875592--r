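#' Construct a parcellation
#'
#' A parcellation is an ordered set of cortical parcels with hemisphere
#' labels, centroid coordinates in mm (right-handed space, x > 0 = right
#' hemisphere) and optional categorical annotations (e.g. cytoarchitectonic
#' class, intrinsic network).
#'
#' @param parcel_id character vector of unique parcel identifiers.
#' @param hemisphere per-parcel hemisphere, `"L"` or `"R"`.
#' @param centroid numeric P x 3 matrix of centroid coordinates (x, y, z) mm.
#' @param annotations named list of per-parcel categorical vectors, each of
#'   length P.
#' @return object of class `parcellation`.
#' @export
parcellation <- function(parcel_id, hemisphere, centroid, annotations = list()) {
  parcel_id <- as.character(parcel_id)
  if (anyDuplicated(parcel_id)) stop("parcel ids must be unique", call. = FALSE)
  hemisphere <- as.character(hemisphere)
  stopifnot(all(hemisphere %in% c("L", "R")))
  centroid <- as.matrix(centroid)
  stopifnot(ncol(centroid) == 3, nrow(centroid) == length(parcel_id),
            all(is.finite(centroid)))
  colnames(centroid) <- c("x", "y", "z")
  rownames(centroid) <- parcel_id
  for (a in annotations) {
    if (length(a) != length(parcel_id)) {
      stop("every annotation vector must have one entry per parcel",
           call. = FALSE)
    }
  }
  structure(list(parcel_id = parcel_id, hemisphere = hemisphere,
                 centroid = centroid, annotations = annotations),
            class = "parcellation")
}

#' Number of parcels in a parcellation
#' @param parc a [parcellation()].
#' @return integer count.
#' @export
n_parcels <- function(parc) length(parc$parcel_id)

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d parcels (%d L / %d R), annotations: %s\n",
              n_parcels(x), sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
              if (length(x$annotations)) {
                paste(names(x$annotations), collapse = ", ")
              } else "none"))
  invisible(x)
}

# Project both hemispheres onto one common unit sphere: each hemisphere's
# centroids are normalized about that hemisphere's own mean, and the right
# hemisphere is reflected sagittally so homotopic parcels align.
common_sphere <- function(parc) {
  out <- matrix(NA_real_, n_parcels(parc), 3)
  for (h in c("L", "R")) {
    idx <- which(parc$hemisphere == h)
    if (!length(idx)) next
    v <- sweep(parc$centroid[idx, , drop = FALSE], 2,
               colMeans(parc$centroid[idx, , drop = FALSE]))
    v <- v / sqrt(rowSums(v^2))
    if (h == "R") v[, 1] <- -v[, 1]
    out[idx, ] <- v
  }
  rownames(out) <- parc$parcel_id
  out
}
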