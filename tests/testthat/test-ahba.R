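test_that("probe intensity filter pools donors and discards the boundary case", {
  pa <- rbind(p1 = c(rep(FALSE, 6), rep(TRUE, 4)),   # 60% below
              p2 = c(rep(FALSE, 4), rep(TRUE, 6)),   # 40% below
              p3 = c(rep(FALSE, 5), rep(TRUE, 5)))   # exactly 50% below
  kept <- filter_probes(pa, 0.5)
  expect_equal(as.character(kept), "p2")
  expect_equal(unname(attr(kept, "below_fraction")), c(0.6, 0.4, 0.5))
  expect_error(filter_probes(pa[, 0, drop = FALSE]), "zero samples")
})

test_that("differential stability hits the exact endpoints", {
  prof <- cbind(d1 = 1:10, d2 = 1:10)
  expect_equal(differential_stability(prof), 1)
  expect_equal(differential_stability(cbind(1:10, 10:1)), -1)
  expect_error(differential_stability(cbind(1:10)), "2 donors")
  # constant donor profile: pair undefined, excluded with warning
  expect_warning(ds <- differential_stability(cbind(1:10, rep(2, 10), 10:1)))
  expect_equal(ds, -1)
  expect_warning(ds2 <- differential_stability(cbind(rep(1, 5), rep(2, 5))))
  expect_true(is.na(ds2))
})

test_that("differential stability equals the brute-force pairwise Spearman mean", {
  set.seed(41)
  for (rep in 1:20) {
    prof <- matrix(rnorm(20 * 4), 20, 4)
    # knock out a few parcels per donor to exercise pairwise-complete handling
    prof[sample(80, 8)] <- NA
    expect_equal(differential_stability(prof), ds_oracle(prof),
                 tolerance = 1e-9)
  }
})

test_that("probe selection maximizes DS with a lexicographic tie-break", {
  pg <- data.frame(probe_id = c("pB", "pA", "pC", "pZ"),
                   gene = c("G1", "G1", "G2", "G3"))
  ds <- c(pB = 0.8, pA = 0.3, pC = 0.5, pZ = NA)
  sel <- select_probe_per_gene(ds, pg)
  expect_equal(sel[["G1"]], "pB")
  expect_equal(sel[["G2"]], "pC")
  expect_equal(sel[["G3"]], "pZ")   # undefined DS -> lexicographic fallback
  ds_tie <- c(pB = 0.5, pA = 0.5, pC = 0.1, pZ = 0)
  expect_equal(select_probe_per_gene(ds_tie, pg)[["G1"]], "pA")
})

test_that("mirroring doubles samples with the x sign flipped", {
  parc <- make_parcellation(10, seed = 5)
  pat <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(parc$parcel_id,
                                                      c("A", "B", "C")))
  d <- tiny_donor("d1", parc, pat, sampled = 1:5)
  d$samples$x[1] <- 0  # midline case
  m <- mirror_samples(d)
  expect_equal(nrow(m$samples), 10)
  expect_equal(m$samples$x[6:10], -d$samples$x)
  expect_equal(m$samples$x[6], 0)           # coincident duplicate kept
  expect_equal(unname(m$expr[, 6:10]), unname(d$expr))
})

test_that("sample assignment respects tolerance, hemisphere and tie-breaks", {
  parc <- parcellation(c("L1", "L2", "R1"), c("L", "L", "R"),
                       rbind(c(-10, 0, 0), c(-14, 0, 0), c(10, 0, 0)))
  s <- data.frame(sample_id = c("a", "b", "c", "d"),
                  x = c(-10, -12, -20, 10), y = c(0, 0, 0, 0.5),
                  z = c(0, 0, 0, 0))
  out <- assign_samples(s, parc, tol_mm = 2)
  expect_equal(out[1], 1L)        # exactly at a centroid
  expect_equal(out[2], 1L)        # equidistant within tol -> lower index
  expect_true(is.na(out[3]))      # 6 mm away from everything
  expect_equal(out[4], 3L)        # right hemisphere sample -> right parcel
  expect_error(assign_samples(s, parc, tol_mm = 0), "tol_mm > 0")
})

test_that("parcel interpolation matches the inverse-distance formula", {
  parc <- parcellation(c("L1", "L2"), c("L", "L"),
                       rbind(c(-10, 0, 0), c(-20, 0, 0)))
  mat <- rbind(c(5, 7), c(NA, NA))
  # one sample at distance d -> exactly that sample's value
  one <- fill_missing_parcels(mat, matrix(c(2, 4), 1), cbind(-23, 0, 0), parc,
                              k = 10)
  expect_equal(one[2, ], c(2, 4))
  # two equidistant samples -> plain average
  two <- fill_missing_parcels(mat, rbind(c(2, 0), c(4, 0)),
                              rbind(c(-18, 0, 0), c(-22, 0, 0)), parc)
  expect_equal(two[2, 1], 3)
  # k = 3 at distances (1, 2, 4), values (1, 1, 9): weights (4, 2, 1)/7
  three <- fill_missing_parcels(mat,
                                rbind(c(1, 0), c(1, 0), c(9, 0)),
                                rbind(c(-21, 0, 0), c(-22, 0, 0), c(-24, 0, 0)),
                                parc, k = 3)
  expect_equal(three[2, 1], (4 * 1 + 2 * 1 + 1 * 9) / 7, tolerance = 1e-9)
  expect_error(fill_missing_parcels(mat, matrix(numeric(), 0, 2),
                                    matrix(numeric(), 0, 3), parc),
               "zero")
})

test_that("robust sigmoid matches its formula and is affine-invariant", {
  x <- c(1, 2, 3, 4, 100)
  got <- robust_sigmoid(x, rescale = FALSE)
  iqr <- unname(quantile(x, 0.75) - quantile(x, 0.25))
  manual <- 1 / (1 + exp(-(x - median(x)) / (iqr / 1.35)))
  expect_equal(got, manual, tolerance = 1e-12)
  expect_equal(got[3], 0.5)  # value at the median
  # rescaled output spans [0, 1] and preserves order
  r <- robust_sigmoid(x)
  expect_equal(range(r), c(0, 1))
  expect_equal(order(r), order(x))
  # positive affine transform leaves the output unchanged
  expect_equal(robust_sigmoid(3.7 * x + 11), r, tolerance = 1e-12)
  # zero IQR -> flagged constant 0.5
  z0 <- robust_sigmoid(rep(5, 4))
  expect_equal(as.numeric(z0), rep(0.5, 4))
  expect_true(attr(z0, "degenerate"))
})

test_that("single-donor assembly reproduces that donor's normalized matrix", {
  set.seed(42)
  parc <- make_parcellation(12, seed = 6)
  genes <- sprintf("G%02d", 1:8)
  pat <- matrix(rnorm(24 * 8), 24, 8, dimnames = list(parc$parcel_id, genes))
  d <- tiny_donor("d1", parc, pat)  # all parcels sampled
  out <- assemble_expression(list(d), parc, mirror = FALSE)
  expect_equal(out$parcels, parc$parcel_id)
  expect_setequal(out$genes, genes)
  expect_true(all(is.finite(out$values)))
  expect_true(all(is.na(out$ds)))  # DS undefined for one donor
  # manual reference: two sigmoid passes on the sample matrix
  e <- d$expr
  rownames(e) <- genes
  e <- apply(e, 2, robust_sigmoid)
  rownames(e) <- genes
  e <- t(apply(e, 1, robust_sigmoid))
  expect_equal(unname(out$values[, genes]), unname(t(e)), tolerance = 1e-12)
})

test_that("two identical donors give DS 1 and the shared matrix", {
  set.seed(43)
  parc <- make_parcellation(12, seed = 6)
  genes <- sprintf("G%02d", 1:6)
  pat <- matrix(rnorm(24 * 6), 24, 6, dimnames = list(parc$parcel_id, genes))
  d1 <- tiny_donor("d1", parc, pat)
  d2 <- tiny_donor("d2", parc, pat)
  both <- assemble_expression(list(d1, d2), parc, mirror = FALSE)
  solo <- assemble_expression(list(d1), parc, mirror = FALSE)
  expect_equal(unname(both$ds), rep(1, 6))
  expect_equal(both$values, solo$values[, both$genes], tolerance = 1e-12)
})

test_that("raising the DS threshold never increases the retained gene count", {
  spec <- synthetic_spec(n_parcels_per_hemisphere = 15, n_donors = 3,
                         n_genes = 20, seed = 9, decoy_fraction = 0)
  co <- make_donor_tables(spec)
  counts <- vapply(c(-1, 0.1, 0.5, 0.9), function(th) {
    length(assemble_expression(co$donors, co$parc, ds_threshold = th)$genes)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a left-only donor yields mirror-symmetric expression patterns", {
  set.seed(44)
  parc <- make_parcellation(15, seed = 7)
  genes <- c("A", "B", "C")
  half <- matrix(rnorm(15 * 3), 15, 3)
  pat <- rbind(half, half)  # mirror-symmetric planted pattern
  dimnames(pat) <- list(parc$parcel_id, genes)
  d <- tiny_donor("d1", parc, pat, sampled = which(parc$hemisphere == "L"))
  out <- assemble_expression(list(d), parc, mirror = TRUE)
  left <- out$values[parc$hemisphere == "L", ]
  right <- out$values[parc$hemisphere == "R", ]
  expect_equal(unname(left), unname(right), tolerance = 1e-9)
})
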