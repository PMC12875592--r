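# Small programmatic fixtures shared across test files.

# A tiny donor whose samples sit exactly on parcel centroids of `parc`,
# with expression taken from a supplied parcels x genes pattern.
tiny_donor <- function(donor_id, parc, pattern, sampled = seq_len(nrow(pattern)),
                       noise_sd = 0, baseline = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- colnames(pattern)
  xyz <- parc$centroid[sampled, , drop = FALSE]
  samples <- data.frame(sample_id = sprintf("%s_S%02d", donor_id,
                                            seq_along(sampled)),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        structure = parc$parcel_id[sampled],
                        stringsAsFactors = FALSE)
  expr <- baseline + t(pattern[sampled, , drop = FALSE])
  if (noise_sd > 0) {
    expr <- expr + matrix(rnorm(length(expr), sd = noise_sd),
                          nrow(expr), ncol(expr))
  }
  probes <- data.frame(probe_id = paste0(genes, "_1"), gene = genes,
                       stringsAsFactors = FALSE)
  rownames(expr) <- probes$probe_id
  pa <- matrix(TRUE, nrow(expr), ncol(expr))
  donor_sample_table(donor_id, samples, probes, expr, pa)
}

# Brute-force mean pairwise Spearman (independent oracle for DS).
ds_oracle <- function(profiles) {
  nd <- ncol(profiles)
  vals <- c()
  for (i in seq_len(nd - 1)) {
    for (j in seq(i + 1, nd)) {
      ok <- complete.cases(profiles[, i], profiles[, j])
      vals <- c(vals, cor(rank(profiles[ok, i]), rank(profiles[ok, j])))
    }
  }
  mean(vals)
}

# Step-up FDR definition (independent oracle for bh_fdr).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, m * p[o] / seq_len(m))
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# A small lifespan dataset with explicit per-stage sample design.
tiny_lifespan <- function(genes, regions, n_per_cell = 2, seed = 1,
                          stage_table = default_stage_table(),
                          value_fun = function(g, stage_idx) 2^runif(1, 1, 5)) {
  set.seed(seed)
  tab <- stage_table[order(stage_table$index), ]
  rows <- expand.grid(rep = seq_len(n_per_cell), stage = seq_len(nrow(tab)),
                      region = regions, stringsAsFactors = FALSE)
  rows$donor_id <- sprintf("d%02d_%d", rows$stage, rows$rep)
  ages <- (tab$min_pcd + tab$max_pcd) / 2
  rows$age_pcd <- ages[rows$stage]
  rows$sample_id <- sprintf("s%03d", seq_len(nrow(rows)))
  expr <- matrix(0, length(genes), nrow(rows), dimnames = list(genes, NULL))
  for (g in seq_along(genes)) {
    for (s in seq_len(nrow(rows))) {
      expr[g, s] <- value_fun(genes[g], rows$stage[s])
    }
  }
  lifespan_dataset(rows[, c("sample_id", "donor_id", "region", "age_pcd")],
                   expr, tab)
}
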