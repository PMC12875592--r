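test_that("ages map to the documented developmental stages", {
  tab <- default_stage_table()
  expect_equal(nrow(tab), 8)
  expect_equal(stage_of_age(c(60, 100, 200, 300, 1000, 3000, 5000, 8000)),
               c("early_fetal", "mid_fetal", "late_fetal", "infancy",
                 "early_childhood", "late_childhood", "adolescence",
                 "adulthood"))
  expect_true(is.na(stage_of_age(20)))
  # boundaries: lower bound inclusive
  expect_equal(stage_of_age(91), "mid_fetal")
  expect_equal(stage_of_age(280), "infancy")
})

test_that("cleanup drops stage-incomplete regions and sub-threshold genes", {
  ds <- tiny_lifespan(genes = c("GOOD", "LOW"), regions = c("r1", "r2"),
                      n_per_cell = 5, seed = 81,
                      value_fun = function(g, s) {
                        if (g == "LOW") runif(1, 0, 0.5) else 2^runif(1, 1, 5)
                      })
  # region r2 loses all its adulthood samples -> r2 must be dropped
  drop <- ds$samples$region == "r2" & ds$samples$stage == "adulthood"
  ds$samples <- ds$samples[!drop, ]
  ds$expr <- ds$expr[, !drop]
  out <- lifespan_cleanup(ds)
  expect_equal(unique(out$samples$region), "r1")
  expect_false("LOW" %in% rownames(out$expr))
  expect_true("GOOD" %in% rownames(out$expr))
  # idempotent
  again <- lifespan_cleanup(out)
  expect_equal(again$expr, out$expr)
  expect_equal(again$samples, out$samples)
})

test_that("the expression filter boundary is inclusive at 80%", {
  # gene at RPKM >= 1 in exactly 4/5 samples of every cell -> retained
  counter <- new.env()
  counter$i <- 0
  ds <- tiny_lifespan(genes = c("EDGE", "REF"), regions = "r1", n_per_cell = 5,
                      seed = 82,
                      value_fun = function(g, s) {
                        if (g == "REF") return(4)
                        counter$i <- counter$i + 1
                        if (counter$i %% 5 == 0) 0.5 else 2
                      })
  out <- lifespan_cleanup(ds)
  expect_true("EDGE" %in% rownames(out$expr))
})

test_that("duplicate gene symbols collapse to the first occurrence", {
  ds <- tiny_lifespan(genes = c("A", "B"), regions = "r1", n_per_cell = 2,
                      seed = 83, value_fun = function(g, s) 4)
  dup <- ds$expr["A", , drop = FALSE] * 2
  rownames(dup) <- "A"
  ds$expr <- rbind(ds$expr, dup)
  out <- lifespan_cleanup(ds)
  expect_equal(sum(rownames(out$expr) == "A"), 1)
  expect_equal(out$expr["A", ], ds$expr[1, ])
})

test_that("log2 transform hits the documented anchors and rejects negatives", {
  expect_equal(log2_transform(0), 0)
  expect_equal(log2_transform(1), 1)
  expect_equal(log2_transform(7), 3)
  expect_error(log2_transform(-1), "negative")
})

test_that("upper-quartile normalization equalizes donor upper quartiles", {
  # single donor -> unchanged
  m <- matrix(runif(20, 1, 9), 4, 5)
  expect_equal(upper_quartile_normalize(m, rep("d1", 5)), m,
               tolerance = 1e-12)
  # two donors with q75 = 2 and 4 -> scaled by 3/2 and 3/4
  m2 <- cbind(matrix(2, 4, 2), matrix(4, 4, 2))
  don <- c("a", "a", "b", "b")
  out <- upper_quartile_normalize(m2, don)
  expect_equal(unname(out[, 1]), rep(3, 4))
  expect_equal(unname(out[, 3]), rep(3, 4))
  # post-condition on random multi-donor fixtures + rank preservation
  set.seed(84)
  for (rep in 1:20) {
    nd <- sample(2:5, 1)
    donor <- rep(paste0("d", seq_len(nd)), each = 4)
    mm <- matrix(rexp(8 * length(donor)), 8)
    pre_q75 <- vapply(split(seq_along(donor), donor),
                      function(cl) quantile(mm[, cl], 0.75, names = FALSE),
                      numeric(1))
    got <- upper_quartile_normalize(mm, donor)
    post <- vapply(split(seq_along(donor), donor),
                   function(cl) quantile(got[, cl], 0.75, names = FALSE),
                   numeric(1))
    expect_equal(unname(post), rep(mean(pre_q75), nd), tolerance = 1e-9)
    for (d in unique(donor)) {
      cl <- donor == d
      expect_equal(order(got[3, cl]), order(mm[3, cl]))
    }
  }
  expect_error(upper_quartile_normalize(matrix(0, 2, 2), c("a", "a")), "a")
})

test_that("stage trajectories are medians of sample-level pathway means", {
  ds <- tiny_lifespan(genes = c("G1", "G2"), regions = "r1", n_per_cell = 3,
                      seed = 85, value_fun = function(g, s) 2^runif(1, 1, 5))
  gs <- pathway_geneset("p", c("G1", "G2"))
  tr <- stage_trajectory(ds, gs)
  expect_equal(tr$stage, default_stage_table()$stage)
  sm <- colMeans(ds$expr)
  expect_equal(tr$median,
               as.numeric(tapply(sm, factor(ds$samples$stage,
                                            levels = tr$stage), median)),
               tolerance = 1e-12)
  # robustness to outliers: samples (1, 2, 100) -> median 2
  ds2 <- ds
  one_stage <- ds2$samples$stage == "infancy" & ds2$samples$region == "r1"
  ds2$expr["G1", one_stage] <- c(1, 2, 100)
  ds2$expr["G2", one_stage] <- c(1, 2, 100)
  tr2 <- stage_trajectory(ds2, gs)
  expect_equal(tr2$median[tr2$stage == "infancy"], 2)
  # invariance to sample order
  perm <- sample(ncol(ds$expr))
  ds3 <- ds
  ds3$samples <- ds$samples[perm, ]
  ds3$expr <- ds$expr[, perm]
  expect_equal(stage_trajectory(ds3, gs)$median, tr$median)
})

test_that("LOESS smoothing is exact on lines, constants, and a direct oracle", {
  set.seed(86)
  age <- sort(runif(40, 60, 10000))
  lx <- log10(age)
  lin <- 2 + 3 * lx
  sm <- loess_trajectory(age, lin, span = 0.75)
  expect_equal(sm$fitted, 2 + 3 * sm$log10_age, tolerance = 1e-6)
  cst <- loess_trajectory(age, rep(5, 40))
  expect_equal(cst$fitted, rep(5, 100), tolerance = 1e-9)
  # independent tricube-weighted local linear fit at 5 probe points
  y <- 1 + (lx - 3)^2 + rnorm(40, sd = 0.1)
  span <- 0.75
  got <- loess_trajectory(age, y, span = span)
  q <- floor(span * length(lx))
  for (x0 in got$log10_age[c(10, 30, 50, 70, 90)]) {
    d <- abs(lx - x0)
    h <- sort(d)[q]
    w <- pmax(1 - pmin(d / h, 1)^3, 0)^3
    fit <- lm(y ~ lx, weights = w)
    want <- unname(predict(fit, newdata = data.frame(lx = x0)))
    idx <- which.min(abs(got$log10_age - x0))
    expect_equal(got$fitted[idx], want, tolerance = 1e-6)
  }
  expect_error(loess_trajectory(age[1:5], y[1:5]), "10 points")
})

test_that("planted monotone trajectories are recovered across seeds", {
  planted <- default_stage_effects()$ppp
  rho <- vapply(1:10, function(s) {
    spec <- synthetic_spec(n_parcels_per_hemisphere = 10, n_regions = 3,
                           n_per_cell = 4, seed = 100 + s)
    life <- make_lifespan_dataset(spec)
    ds <- lifespan_cleanup(life$dataset)
    ds$expr <- log2_transform(ds$expr)
    ds$expr <- upper_quartile_normalize(ds$expr, ds$samples$donor_id)
    tr <- stage_trajectory(ds, make_synthetic_genesets()$ppp)
    cor(tr$median, planted, method = "spearman")
  }, numeric(1))
  expect_gte(mean(rho), 0.9)
})

test_that("the microarray filter variant thresholds on log2 signal", {
  ds <- tiny_lifespan(genes = c("HI", "MID"), regions = "r1", n_per_cell = 2,
                      seed = 87,
                      value_fun = function(g, s) if (g == "HI") 200 else 20)
  out <- lifespan_cleanup(ds, filter = "log2signal", log2_threshold = 6)
  expect_true("HI" %in% rownames(out$expr))     # log2(201) > 7.6
  expect_false("MID" %in% rownames(out$expr))   # log2(21) ~ 4.4
})
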