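#' Construct a brain map
#'
#' One scalar per parcel plus metadata on how it was summarized.
#'
#' @param parcels ordered parcel ids.
#' @param values numeric vector, one value per parcel.
#' @param name map label.
#' @param kind summary kind: `"mean"`, `"pc1"` or `"zscored"`.
#' @param variance_explained proportion of variance captured (PC1 maps only).
#' @return object of class `brain_map`.
#' @export
brain_map <- function(parcels, values, name = "map", kind = "mean",
                      variance_explained = NULL) {
  values <- as.numeric(values)
  stopifnot(length(values) == length(parcels), all(is.finite(values)))
  names(values) <- parcels
  structure(list(parcels = as.character(parcels), values = values,
                 meta = list(name = name, kind = kind,
                             variance_explained = variance_explained)),
            class = "brain_map")
}

#' @export
print.brain_map <- function(x, ...) {
  cat(sprintf("<brain_map> %s (%s): %d parcels, range [%.3g, %.3g]\n",
              x$meta$name, x$meta$kind, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

# Accept a brain_map or a bare numeric vector.
map_values <- function(m) {
  if (inherits(m, "brain_map")) m$values else as.numeric(m)
}

#' Mean expression map of a pathway gene set
#'
#' Per-parcel unweighted mean over the pathway's gene columns available in
#' the expression matrix.  Pathway genes absent from the matrix are logged
#' via the `missing_genes` attribute.
#'
#' @param expr a [region_expression()].
#' @param gs a [pathway_geneset()].
#' @return a [brain_map()] of kind `"mean"`.
#' @export
pathway_mean_map <- function(expr, gs) {
  stopifnot(inherits(expr, "region_expression"), inherits(gs, "pathway_geneset"))
  present <- intersect(gs$genes, expr$genes)
  if (length(present) == 0L) {
    stop("no genes of pathway '", gs$name, "' present in the matrix; absent: ",
         paste(gs$genes, collapse = ", "), call. = FALSE)
  }
  m <- brain_map(expr$parcels,
                 rowMeans(expr$values[, present, drop = FALSE]),
                 name = gs$name, kind = "mean")
  attr(m, "missing_genes") <- setdiff(gs$genes, present)
  attr(m, "n_genes") <- length(present)
  m
}

#' Z-score a brain map
#'
#' Centers and scales the map to mean 0 and population SD 1.
#'
#' @param m a [brain_map()] or numeric vector.
#' @return a [brain_map()] of kind `"zscored"`.
#' @export
zscore_map <- function(m) {
  v <- map_values(m)
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  if (sd_pop == 0) stop("cannot z-score a constant map", call. = FALSE)
  parcels <- if (inherits(m, "brain_map")) m$parcels else {
    as.character(seq_along(v))
  }
  nm <- if (inherits(m, "brain_map")) m$meta$name else "map"
  brain_map(parcels, (v - mu) / sd_pop, name = nm, kind = "zscored")
}

#' First principal component map of a pathway gene set
#'
#' PC1 scores over parcels of the parcel-by-pathway-gene submatrix, with
#' gene columns centered and scaled (correlation PCA).  The sign is fixed so
#' that the PC1 map correlates non-negatively with the pathway mean map.
#'
#' @param expr a [region_expression()].
#' @param gs a [pathway_geneset()] with at least two genes present.
#' @return a [brain_map()] of kind `"pc1"` with `variance_explained` set.
#' @export
pathway_pc1_map <- function(expr, gs) {
  stopifnot(inherits(expr, "region_expression"), inherits(gs, "pathway_geneset"))
  present <- intersect(gs$genes, expr$genes)
  if (length(present) < 2) {
    stop("PC1 map needs >= 2 pathway genes in the matrix", call. = FALSE)
  }
  X <- expr$values[, present, drop = FALSE]
  if (nrow(X) <= 2 || nrow(unique(X)) < 2) {
    stop("degenerate input: need > 2 parcels and >= 2 distinct rows",
         call. = FALSE)
  }
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("constant gene column; cannot scale for PC1", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1]
  mean_map <- rowMeans(X)
  if (stats::cor(scores, mean_map) < 0) scores <- -scores
  ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  brain_map(expr$parcels, scores, name = gs$name, kind = "pc1",
            variance_explained = ve)
}

#' Average a brain map over parcel classes
#'
#' @param m a [brain_map()] or numeric vector.
#' @param labels per-parcel categorical labels (same length as the map).
#' @param ignore labels to exclude (default `NA` and `"ignore"`).
#' @return data.frame with columns `class`, `n_parcels`, `mean`; classes with
#'   zero parcels are omitted with a warning.
#' @export
group_mean <- function(m, labels, ignore = "ignore") {
  v <- map_values(m)
  stopifnot(length(labels) == length(v))
  labels <- as.character(labels)
  keep <- !is.na(labels) & !(labels %in% ignore)
  lv <- unique(labels[!is.na(labels)])
  empty <- setdiff(setdiff(lv, ignore), labels[keep])
  if (length(empty)) {
    warning("omitting empty class(es): ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  sp <- split(v[keep], labels[keep])
  data.frame(class = names(sp),
             n_parcels = vapply(sp, length, integer(1)),
             mean = vapply(sp, mean, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
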