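# Cavity detection and descriptors on engineered geometries.

test_that("a closed hollow sphere yields exactly one pocket of the right size", {
  cs <- cavity_case()
  expect_length(cs$pockets, 1)
  p <- cs$pockets[[1]]
  # volume bookkeeping is exact; accuracy vs the analytic ball is bounded
  expect_identical(p$volume, length(p$cells) * 0.8^3)
  analytic <- 4 / 3 * pi * 6^3
  expect_lt(abs(p$volume - analytic) / analytic, 0.25)
  expect_gt(nrow(p$surface_points), 0)
})

test_that("open and degenerate inputs are handled", {
  expect_length(find_pockets(make_helix_structure(20)), 0)
  few <- toy_structure(c("C", "C", "C"), matrix(rnorm(9), ncol = 3))
  expect_error(find_pockets(few), "degenerate")
})

test_that("two disjoint engineered cavities give two pockets by volume", {
  a <- make_cavity_structure(inner_radius = 6, shell_thickness = 2.5, seed = 1)
  b <- make_cavity_structure(inner_radius = 4.5, shell_thickness = 2.5, seed = 2)
  pk <- find_pockets(combine_structures(a, b, offset = c(40, 0, 0)))
  expect_length(pk, 2)
  vols <- vapply(pk, `[[`, numeric(1), "volume")
  expect_true(vols[1] > vols[2])
  # the larger pocket is near the first cavity (centered at the origin)
  expect_lt(sqrt(sum(colMeans(pk[[1]]$surface_points)^2)), 5)
})

test_that("shell membership follows the 3.5 A surface-point rule exactly", {
  pocket <- fake_pocket(matrix(0, nrow = 1, ncol = 3))
  near <- toy_structure("C", matrix(c(0, 0, 3.4), ncol = 3))
  far <- toy_structure("C", matrix(c(0, 0, 3.6), ncol = 3))
  expect_length(assign_shell(pocket, near), 1)
  expect_length(assign_shell(pocket, far), 0)

  # engineered cavity: shell equals the brute-force residue scan
  cs <- cavity_case()
  p <- cs$pockets[[1]]
  s <- cs$structure
  coords <- as.matrix(s$atoms[, c("x", "y", "z")])
  brute <- unique(unlist(lapply(seq_len(nrow(coords)), function(i) {
    d <- sqrt(colSums((t(p$surface_points) - coords[i, ])^2))
    if (any(d <= 3.5)) residue_keys(s)[i] else NULL
  })))
  expect_setequal(cs$shell, brute)

  expect_warning(sh <- assign_shell(fake_pocket(matrix(0, 0, 3)), near), "empty")
  expect_length(sh, 0)
})

test_that("SASA matches the closed form, additivity and a reference value", {
  one <- toy_structure("C", matrix(0, 1, 3))
  expect_equal(sasa(one), 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-6)

  # two atoms far apart: areas add
  two <- toy_structure(c("C", "O"), rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(sum(sasa(two)),
               4 * pi * (1.7 + 1.4)^2 + 4 * pi * (1.52 + 1.4)^2,
               tolerance = 1e-6)

  # frozen cross-check against an independent Shrake-Rupley implementation
  # (biotite 1.4.0, same radii/probe/point count) on a 12-atom fixture
  set.seed(42)
  n <- 12
  fix <- toy_structure(sample(c("C", "N", "O", "S"), n, TRUE),
                       matrix(runif(3 * n, 0, 8), ncol = 3))
  expect_equal(sum(sasa(fix, n_points = 960)), 701.1992, tolerance = 0.005)
})

test_that("buriedness behaves at its limits and rejects empty shells", {
  # a shell that IS the whole structure is equally exposed in context and in
  # isolation: buriedness 0
  cs <- cavity_case()
  s <- cs$structure
  p <- cs$pockets[[1]]
  all_res <- unique(residue_keys(s))
  expect_equal(compute_buriedness(p, s, shell = all_res), 0)
  # the true pocket shell is strongly buried in the closed sphere
  expect_gt(compute_buriedness(p, s, shell = cs$shell), 0.5)
  expect_error(compute_buriedness(p, s, shell = character(0)), "empty shell")
})

test_that("hydrophobicity reflects the lining composition", {
  cs <- cavity_case()  # all-carbon lining
  expect_equal(compute_hydrophobicity(cs$pockets[[1]], cs$structure,
                                      shell = cs$shell), 1.0)

  polar <- make_cavity_structure(inner_radius = 5, shell_thickness = 2.5,
                                 lining_composition = 0, seed = 2)
  pk <- find_pockets(polar)
  expect_equal(compute_hydrophobicity(pk[[1]], polar), 0.0)

  half <- make_cavity_structure(inner_radius = 6, shell_thickness = 2.5,
                                lining_composition = 0.5, seed = 3)
  pk <- find_pockets(half)
  h <- compute_hydrophobicity(pk[[1]], half)
  expect_gt(h, 0.35)
  expect_lt(h, 0.65)
})

test_that("sitemap descriptors hit their limit cases and are deterministic", {
  cs <- cavity_case()
  d <- compute_sitemap_descriptors(cs$pockets[[1]], cs$structure,
                                   shell = cs$shell)
  expect_gt(d$enclosure, 0.6)   # closed cavity: most rays blocked
  expect_lte(d$enclosure, 1)
  expect_gt(d$site_point_count, 0)
  expect_gte(d$hydrophilic_score, 0)
  # all-carbon lining: zero hydrophilic density, so the balance is undefined
  expect_identical(d$balance, NA_real_)
  half <- make_cavity_structure(inner_radius = 5, shell_thickness = 2.5,
                                lining_composition = 0.5, seed = 8)
  hp <- find_pockets(half)[[1]]
  dh <- compute_sitemap_descriptors(hp, half, buriedness = 0.5,
                                    hydrophobicity = 0.5)
  expect_equal(dh$balance, dh$hydrophobic_score / dh$hydrophilic_score)
  expect_true(d$buriedness >= 0 && d$buriedness <= 1)
  expect_true(d$hydrophobicity >= 0 && d$hydrophobicity <= 1)

  # a site point in free space, far from every atom: enclosure 0, p 0
  far_struct <- toy_structure(rep("O", 4),
                              matrix(c(100, 0, 0, 0, 100, 0, 0, 0, 100,
                                       100, 100, 100), ncol = 3, byrow = TRUE))
  lonely <- fake_pocket(matrix(0, 1, 3))
  lonely$grid <- list(origin = c(0, 0, 0), dim = c(1L, 1L, 1L), spacing = 0.8)
  lonely$cells <- 1L
  d0 <- compute_sitemap_descriptors(lonely, far_struct, shell = character(0),
                                    buriedness = 0, hydrophobicity = 0)
  expect_equal(d0$enclosure, 0)
  expect_equal(d0$hydrophilic_score, 0)

  # bit-identical rerun (fixed ray directions, no RNG)
  d2 <- compute_sitemap_descriptors(cs$pockets[[1]], cs$structure,
                                    shell = cs$shell)
  expect_identical(d, d2)
})

test_that("volume is stable under grid refinement for a smooth cavity", {
  s <- make_cavity_structure(inner_radius = 5, shell_thickness = 2.5, seed = 5)
  v_coarse <- find_pockets(s, grid_spacing = 0.8)[[1]]$volume
  v_fine <- find_pockets(s, grid_spacing = 0.4)[[1]]$volume
  expect_lt(abs(v_fine - v_coarse) / v_coarse, 0.15)
})

test_that("score_pockets assembles one scored row per pocket", {
  cs <- cavity_case()
  tab <- score_pockets(cs$structure)
  expect_equal(nrow(tab), 1)
  expect_true(all(c("volume", "buriedness", "hydrophobicity", "dlid",
                    "site_score", "dscore", "dlid_druggable",
                    "site_druggable") %in% names(tab)))
  expect_equal(tab$dlid,
               dlid_regression(tab$volume, tab$buriedness, tab$hydrophobicity))
})
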