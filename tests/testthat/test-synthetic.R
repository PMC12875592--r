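test_that("synthetic parcellations are mirror-symmetric without duplicates", {
  parc <- make_parcellation(100, seed = 91)
  expect_equal(n_parcels(parc), 200)
  expect_equal(sum(parc$hemisphere == "L"), 100)
  left <- parc$centroid[parc$hemisphere == "L", ]
  right <- parc$centroid[parc$hemisphere == "R", ]
  expect_equal(unname(right[, 1]), -unname(left[, 1]))
  expect_equal(unname(right[, 2:3]), unname(left[, 2:3]))
  # the sign of x encodes hemisphere
  expect_true(all(left[, 1] < 0) && all(right[, 1] > 0))
  # no coincident centroids within a hemisphere
  expect_gt(min(dist(left)), 0)
  # annotations mirror across hemispheres and are complete
  expect_equal(parc$annotations$class[1:100], parc$annotations$class[101:200])
  expect_length(parc$annotations$network, 200)
})

test_that("generators are pure functions of spec and seed", {
  parc1 <- make_parcellation(20, seed = 92)
  parc2 <- make_parcellation(20, seed = 92)
  expect_identical(parc1, parc2)
  expect_false(isTRUE(all.equal(parc1$centroid,
                                make_parcellation(20, seed = 93)$centroid)))
  m1 <- gp_maps(parc1, 0.3, n = 2, seed = 94)
  m2 <- gp_maps(parc1, 0.3, n = 2, seed = 94)
  expect_identical(m1, m2)
  expect_false(isTRUE(all.equal(m1, gp_maps(parc1, 0.3, n = 2, seed = 95))))
  spec <- synthetic_spec(n_parcels_per_hemisphere = 15, n_donors = 2,
                         n_genes = 12, seed = 96)
  expect_identical(make_donor_tables(spec)$donors[[1]]$expr,
                   make_donor_tables(spec)$donors[[1]]$expr)
})

test_that("GP maps span the white-noise and smooth limits", {
  parc <- make_parcellation(60, seed = 97)
  u <- energymaps:::common_sphere(parc)
  ang <- acos(pmin(pmax(tcrossprod(u), -1), 1))
  # nearest-neighbour pairs within the left hemisphere
  lidx <- which(parc$hemisphere == "L")
  al <- ang[lidx, lidx]
  diag(al) <- Inf
  nn <- apply(al, 1, which.min)
  neigh_cor <- function(maps) {
    cor(as.numeric(maps[lidx, ]), as.numeric(maps[lidx[nn], ]))
  }
  # with 60 parcels/hemisphere neighbours sit ~0.45 rad apart, so the
  # lambda = 0.5 kernel implies a neighbour correlation near exp(-0.9) ~ 0.4
  smooth <- gp_maps(parc, 0.5, n = 100, seed = 98)
  rough <- gp_maps(parc, 0.005, n = 100, seed = 99)
  expect_gt(neigh_cor(smooth), 0.25)
  expect_lt(abs(neigh_cor(rough)), 0.1)
  # mirrored fields are near bilaterally symmetric; independent ones are not
  ridx <- match(sub("^L", "R", parc$parcel_id[lidx]), parc$parcel_id)
  mir <- gp_maps(parc, 0.5, n = 20, seed = 98, bilateral = "mirrored")
  expect_gt(cor(mir[lidx, 1], mir[ridx, 1]), 0.99)
  expect_lt(abs(cor(as.numeric(smooth[lidx, 1:50]),
                    as.numeric(smooth[ridx, 1:50]))), 0.2)
})

test_that("donor tables carry the documented cohort structure", {
  spec <- synthetic_spec(n_parcels_per_hemisphere = 20, n_donors = 6,
                         n_genes = 30, seed = 101, fraction_unsampled = 0.2,
                         right_hemisphere_donors = 2, decoy_fraction = 0.5)
  co <- make_donor_tables(spec)
  expect_length(co$donors, 6)
  # only the first two donors sample the right hemisphere
  rh <- vapply(co$donors, function(d) any(d$samples$x > 0), logical(1))
  expect_equal(rh, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # a fifth of candidate parcels is left unsampled
  expect_equal(nrow(co$donors[[3]]$samples), 20 - floor(0.2 * 20))
  # decoy probes exist and share gene symbols with faithful probes
  pr <- co$donors[[1]]$probes
  expect_equal(sum(grepl("_1$", pr$probe_id)), length(co$decoy_genes))
  expect_true(all(co$decoy_genes %in% pr$gene[grepl("_2$", pr$probe_id)]))
  # planted truth is bilaterally symmetric
  tl <- co$truth[co$parc$hemisphere == "L", ]
  tr <- co$truth[match(sub("^L", "R",
                           co$parc$parcel_id[co$parc$hemisphere == "L"]),
                       co$parc$parcel_id), ]
  expect_equal(unname(tl), unname(tr))
})

test_that("probe selection finds the faithful probe despite decoys", {
  hits <- vapply(1:5, function(s) {
    spec <- synthetic_spec(n_parcels_per_hemisphere = 25, n_donors = 4,
                           n_genes = 20, seed = 200 + s, decoy_fraction = 1)
    co <- make_donor_tables(spec)
    ex <- assemble_expression(co$donors, co$parc, ds_threshold = -1)
    mean(grepl("_2$", attr(ex, "selected_probes")[co$decoy_genes]))
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the lifespan generator plants its documented probes", {
  spec <- synthetic_spec(n_parcels_per_hemisphere = 10, n_regions = 3,
                         n_per_cell = 3, seed = 102)
  life <- make_lifespan_dataset(spec)
  ds <- life$dataset
  expect_true("ALWAYSLOW" %in% rownames(ds$expr))
  expect_equal(sum(rownames(ds$expr) == life$duplicated_gene), 2)
  clean <- lifespan_cleanup(ds)
  expect_false("ALWAYSLOW" %in% rownames(clean$expr))
  expect_equal(sum(rownames(clean$expr) == life$duplicated_gene), 1)
  # every stage x region cell is populated
  expect_true(all(table(ds$samples$region, ds$samples$stage) ==
                    spec$n_per_cell))
})

test_that("flat stage effects produce flat recovered trajectories", {
  flat <- lapply(default_stage_effects(), function(x) x * 0)
  slopes <- vapply(1:10, function(s) {
    spec <- synthetic_spec(n_parcels_per_hemisphere = 10, n_regions = 3,
                           n_per_cell = 4, stage_effects = flat,
                           seed = 300 + s)
    life <- make_lifespan_dataset(spec)
    ds <- lifespan_cleanup(life$dataset)
    ds$expr <- log2_transform(ds$expr)
    ds$expr <- upper_quartile_normalize(ds$expr, ds$samples$donor_id)
    tr <- stage_trajectory(ds, make_synthetic_genesets()$ppp)
    unname(coef(lm(tr$median ~ tr$index))[2])
  }, numeric(1))
  # no systematic stage trend
  expect_lt(abs(mean(slopes)), 0.05)
})

test_that("synthetic inputs round-trip losslessly through the writers", {
  spec <- synthetic_spec(n_parcels_per_hemisphere = 12, n_donors = 2,
                         n_genes = 15, seed = 103)
  dir <- withr::local_tempdir()
  gen <- write_synthetic_inputs(spec, dir)
  parc <- read_parcellation_tsv(file.path(dir, "parcellation.tsv"))
  expect_equal(parc$parcel_id, gen$cohort$parc$parcel_id)
  expect_equal(parc$centroid, gen$cohort$parc$centroid, tolerance = 1e-9)
  expect_equal(as.character(parc$annotations$class),
               as.character(gen$cohort$parc$annotations$class))
  d1 <- read_donor_dir(file.path(dir, "donors", "donor1"))
  expect_equal(d1$expr, gen$cohort$donors[[1]]$expr, tolerance = 1e-9)
  expect_identical(d1$pa, gen$cohort$donors[[1]]$pa)
  life <- read_lifespan_tsv(file.path(dir, "lifespan_samples.tsv"),
                            file.path(dir, "lifespan_expression.tsv"))
  expect_equal(dim(life$expr), dim(gen$lifespan$dataset$expr))
  expect_equal(unname(life$expr), unname(gen$lifespan$dataset$expr),
               tolerance = 1e-8)
})
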