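test_that("regression-form DLID reproduces hand-evaluated values", {
  # descriptors of the study's top C9 pocket: 614.1 A^3, 0.996, 0.895
  expect_equal(dlid_regression(614.1, 0.996, 0.895), 2.0237789, tolerance = 1e-7)
  expect_equal(dlid_regression(300, 0.8, 0.6), 0.04987735, tolerance = 1e-6)
  # linearity: +0.1 buriedness shifts the score by exactly 0.394
  expect_equal(dlid_regression(300, 0.9, 0.6) - dlid_regression(300, 0.8, 0.6),
               0.394)
  # volume doubling adds exactly 1.71 * log10(2)
  expect_equal(dlid_regression(800, 0.5, 0.5) - dlid_regression(400, 0.5, 0.5),
               1.71 * log10(2))
  expect_error(dlid_regression(-5, 0.5, 0.5), "positive")
  expect_error(dlid_regression(300, 1.5, 0.5), "buriedness")
})

test_that("density-form DLID counts standardized-space neighbors", {
  # single all-DLLC neighbor: log10(1) + 1.71
  ref1 <- reference_pocket_set(500, 0.9, 0.8, TRUE, neighborhood_radius = 5)
  expect_equal(dlid_density(500, 0.9, 0.8, ref1), 1.71)

  # half the neighbors DLLC: log10(0.5) + 1.71
  ref2 <- reference_pocket_set(rep(500, 4), rep(0.9, 4), rep(0.8, 4),
                               c(TRUE, TRUE, FALSE, FALSE),
                               neighborhood_radius = 5)
  expect_equal(dlid_density(500, 0.9, 0.8, ref2), log10(0.5) + 1.71)

  # zero neighbors raises the classed fallback condition
  ref3 <- reference_pocket_set(c(100, 5000), c(0.1, 0.95), c(0.1, 0.9),
                               c(TRUE, FALSE), neighborhood_radius = 0.05)
  expect_error(dlid_density(1000, 0.5, 0.5, ref3),
               class = "pocketrank_no_neighbors")
  # ... which dlid_score() converts into the regression value
  expect_equal(dlid_score(1000, 0.5, 0.5, ref3),
               dlid_regression(1000, 0.5, 0.5))

  # neighbors but none DLLC: -Inf, flagged, with a warning
  ref4 <- reference_pocket_set(rep(500, 3), rep(0.9, 3), rep(0.8, 3),
                               c(FALSE, FALSE, FALSE), neighborhood_radius = 5)
  expect_warning(v <- dlid_density(500, 0.9, 0.8, ref4), "-Inf")
  expect_identical(as.numeric(v), -Inf)
  expect_true(attr(v, "flagged"))
})

test_that("density-form DLID agrees with an exhaustive-scan oracle", {
  set.seed(11)
  n <- 200
  vol <- 10^runif(n, 1.5, 3.5)
  bur <- runif(n)
  hyd <- runif(n)
  dllc <- runif(n) < 0.4
  ref <- reference_pocket_set(vol, bur, hyd, dllc, neighborhood_radius = 1)

  oracle <- function(qv, qb, qh) {
    feat <- cbind(log10(vol), bur, hyd)
    mu <- colMeans(feat)
    sdv <- apply(feat, 2, sd)
    z <- sweep(sweep(feat, 2, mu), 2, sdv, "/")
    q <- (c(log10(qv), qb, qh) - mu) / sdv
    nb <- which(sqrt(rowSums(sweep(z, 2, q)^2)) <= 1)
    log10(sum(dllc[nb]) / length(nb)) + 1.71
  }
  for (i in c(3, 57, 120)) {  # queries planted at reference points
    expect_equal(dlid_density(vol[i], bur[i], hyd[i], ref),
                 oracle(vol[i], bur[i], hyd[i]))
  }
})

test_that("SiteScore and Dscore reproduce hand values in both modes", {
  expect_equal(site_score(100, 0.76, 1.0), 0.733 + 0.6688 * 0.76 - 0.20)
  expect_equal(site_score(100, 0.76, 1.0, literal = TRUE),
               7.33 + 0.6688 * 0.76 - 0.20)
  expect_equal(site_score(0, 0, 0), 0)
  expect_equal(site_score(0, 0, 0, literal = TRUE), 0)
  expect_equal(dscore(100, 0.9, 0.5), 0.94 + 0.54 - 0.162)
  expect_equal(dscore(0, 0, 0), 0)
  expect_error(site_score(-1, 0.5, 0.5), "non-negative")
  expect_error(dscore(10, 1.2, 0.5), "enclosure")
})

test_that("caps: n at 100 in both scores, p only in SiteScore", {
  expect_equal(site_score(150, 0.5, 0.5), site_score(100, 0.5, 0.5))
  expect_equal(dscore(150, 0.5, 0.5), dscore(100, 0.5, 0.5))
  # SiteScore caps p at 1: no difference beyond the cap
  expect_equal(site_score(50, 0.5, 2.0), site_score(50, 0.5, 1.0))
  # Dscore leaves p uncapped: exactly -0.324 per unit
  expect_equal(dscore(50, 0.5, 2.0) - dscore(50, 0.5, 1.0), -0.324)
})

test_that("scores are monotone in their descriptors", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(0:120, 1); e <- runif(1); p <- runif(1, 0, 2)
    dn <- sample(1:20, 1); de <- runif(1, 0, 1 - e); dp <- runif(1, 0, 1)
    expect_gte(site_score(n + dn, e, p), site_score(n, e, p))
    expect_gte(site_score(n, e + de, p), site_score(n, e, p))
    expect_lte(site_score(n, e, p + dp), site_score(n, e, p))
    expect_gte(dscore(n + dn, e, p), dscore(n, e, p))
    expect_lte(dscore(n, e, p + dp), dscore(n, e, p))
    v <- runif(1, 50, 2000); b <- runif(1); h <- runif(1)
    expect_gt(dlid_regression(v * 1.5, b, h), dlid_regression(v, b, h))
    expect_gte(dlid_regression(v, min(1, b + 0.1), h), dlid_regression(v, b, h))
  }
})

test_that("druggability thresholds: DLID strictly above 0.5, SiteScore >= 0.80", {
  cls <- classify_druggability(dlid = c(0.5, 0.51, NA),
                               site_score = c(0.80, 0.799, NA))
  expect_equal(cls$dlid_druggable, c(FALSE, TRUE, FALSE))
  expect_equal(cls$site_druggable, c(TRUE, FALSE, FALSE))
})
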