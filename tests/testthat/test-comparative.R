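test_that("percent differences reproduce the printed validity pairs", {
  pairs <- list(c(2175, 2379, 9), c(540, 555, 3), c(295, 340, 15),
                c(3400, 3560, 5), c(654, 719, 10), c(1371, 1513, 10),
                c(98, 96, -2), c(63, 91, 44))
  for (p in pairs)
    expect_identical(percentDifference(p[1], p[2])$rounded, as.integer(p[3]))
  expect_equal(percentDifference(2175, 2379)$pct, 9.3793, tolerance = 1e-4)
  expect_identical(percentDifference(77, 77)$rounded, 0L)
  expect_error(percentDifference(0, 5), "undefined")
})

test_that("forward and reverse percent differences are reciprocal", {
  set.seed(17)
  for (i in 1:20) {
    a <- sample(50:5000, 1); b <- sample(50:5000, 1)
    p1 <- percentDifference(a, b)$pct
    p2 <- percentDifference(b, a)$pct
    expect_true(p1 * p2 <= 0)
    expect_equal((1 + p1 / 100) * (1 + p2 / 100), 1, tolerance = 1e-12)
  }
})

test_that("the validity table adds an ALL row over summed counts", {
  manual <- c(CTXg = 2175, HIP = 540, STR = 295)
  auto <- c(CTXg = 2379, HIP = 555, STR = 340)
  tab <- validityTable(manual, auto)
  expect_identical(tab$pct_diff_rounded[1:3], c(9L, 3L, 15L))
  expect_identical(tab$label[4], "ALL")
  expect_identical(tab$count_ref[4], 3010)
  expect_identical(tab$pct_diff_rounded[4],
                   percentDifference(3010, 3274)$rounded)

  same <- validityTable(c(A = 10), c(A = 10))
  expect_identical(same$pct_diff, c(0, 0))

  set.seed(17)
  m <- stats::setNames(sample(100:999, 5), letters[1:5])
  a <- stats::setNames(sample(100:999, 5), letters[1:5])
  tab <- validityTable(m, a)
  expect_equal(tab$pct_diff[1:5], unname(100 * (a - m) / m))
  expect_error(validityTable(c(A = 1), c(B = 1)), "different groups")
})

test_that("rater reliability summarizes absolute differences at all levels", {
  idn <- raterReliability(list(c(A = 10, B = 20), c(A = 10, B = 20)))
  expect_identical(unname(idn$range), c(0, 0))

  two <- raterReliability(list(c(A = 100, B = 50), c(A = 110, B = 40)))
  expect_setequal(two$perGroup$abs_pct_diff, c(10, 20))
  expect_identical(unname(two$range), c(10, 20))

  # five perturbed raters against a brute-force pairwise recomputation
  set.seed(8)
  groups <- paste0("G", 1:4)
  ref <- stats::setNames(sample(200:900, 4), groups)
  tables <- c(list(ref), lapply(1:4, function(i)
    stats::setNames(round(ref * runif(4, 0.75, 1.3)), groups)))
  got <- raterReliability(tables, reference = 1)
  alldiffs <- c()
  for (i in 2:5) for (g in groups)
    alldiffs <- c(alldiffs, abs(100 * (tables[[i]][[g]] - ref[[g]]) / ref[[g]]))
  expect_equal(unname(got$range), c(min(alldiffs), max(alldiffs)))
  expect_identical(nrow(got$perRater), 4L)
  expect_identical(nrow(got$perGroupRange), 4L)
  expect_error(raterReliability(list(c(A = 1))), "at least two")
})

test_that("cell-type fractions behave and complement to one", {
  expect_identical(cellTypeFraction(500, 500), 0.5)
  expect_identical(cellTypeFraction(0, 7), 0)
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 0, 1e4); b <- runif(1, 0, 1e4)
    expect_equal(cellTypeFraction(a, b), a / (a + b), tolerance = 1e-10)
    expect_equal(cellTypeFraction(a, b) + cellTypeFraction(b, a), 1,
                 tolerance = 1e-12)
  }
  expect_error(cellTypeFraction(0, 0), "undefined")
})

mkEstimates <- function(ids, densities, volumes = rep(1, length(ids))) {
  data.frame(region = as.character(ids),
             total_estimate = densities * volumes,
             volume_mm3 = volumes, stringsAsFactors = FALSE)
}

test_that("cross-species rows reproduce the printed density comparisons", {
  mapping <- data.frame(target_acronym = c("DG", "PaS"))
  mapping$ids_a <- list(10L, 11L)   # rat atlas ids
  mapping$ids_b <- list(20L, 21L)   # mouse atlas ids
  rat <- mkEstimates(c(10, 11), c(231, 1185))
  mouse <- mkEstimates(c(20, 21), c(178, 2614))
  tab <- crossSpeciesTable(rat, mouse, mapping)

  dg <- tab[tab$target_acronym == "DG", ]
  expect_identical(roundHalfUp(-dg$pct_lower_a_vs_b), 30)  # rat 30% higher
  pas <- tab[tab$target_acronym == "PaS", ]
  expect_equal(pas$pct_lower_a_vs_b, 54.667, tolerance = 1e-3)
  expect_true(pas$pct_lower_a_vs_b >= 46 && pas$pct_lower_a_vs_b <= 55)

  same <- crossSpeciesTable(mkEstimates(1, 100), mkEstimates(2, 100),
                            data.frame(target_acronym = "X",
                                       ids_a = I(list(1L)),
                                       ids_b = I(list(2L))))
  expect_identical(same$pct_lower_a_vs_b, 0)
  expect_identical(same$ratio, 1)
})

test_that("cross-species densities pool volume-correctly and scale-invariantly", {
  mapping <- data.frame(target_acronym = "HIPm")
  mapping$ids_a <- list(c(1L, 2L)); mapping$ids_b <- list(c(3L, 4L))
  a <- mkEstimates(c(1, 2), c(100, 300), volumes = c(3, 1))
  b <- mkEstimates(c(3, 4), c(200, 200), volumes = c(2, 2))
  tab <- crossSpeciesTable(a, b, mapping)
  expect_equal(tab$density_a, (100 * 3 + 300 * 1) / 4)  # not mean(100, 300)
  expect_equal(tab$density_b, 200)

  # uniform rescaling of both atlas volumes leaves pct_lower unchanged
  a2 <- a; a2$volume_mm3 <- a2$volume_mm3 * 5
  b2 <- b; b2$volume_mm3 <- b2$volume_mm3 * 5
  tab2 <- crossSpeciesTable(a2, b2, mapping)
  expect_equal(tab2$pct_lower_a_vs_b, tab$pct_lower_a_vs_b)

  miss <- crossSpeciesTable(a, b, data.frame(target_acronym = "Z",
                                             ids_a = I(list(9L)),
                                             ids_b = I(list(3L))))
  expect_identical(miss$status, "missing source region")
  expect_true(is.na(miss$pct_lower_a_vs_b))
})

test_that("gradient classification follows the rank correlation", {
  mk <- function(n) data.frame(axis_coord_mm = seq(0, by = -0.2,
                                                   length.out = length(n)),
                               n_profiles = n,
                               region_area_px = 1000)
  dec <- gradientProfile(mk(c(10, 8, 6, 4)), 10, 40)
  expect_identical(dec@rho, -1)
  expect_identical(dec@classification, "decreasing")

  flat <- gradientProfile(mk(c(5, 5, 5, 5, 5)), 10, 40)
  expect_identical(flat@rho, 0)
  expect_identical(flat@classification, "none")

  inc <- gradientProfile(mk(c(2, 4, 9, 11, 30)), 10, 40)
  expect_identical(inc@classification, "increasing")

  few <- gradientProfile(mk(c(3, 2, 1)), 10, 40)
  expect_identical(few@classification, "insufficient data")
  expect_true(is.na(few@rho))

  # zero-area sections are ignored, not counted as sections
  d <- mk(c(9, 7, 5, 3, 1)); d$region_area_px[3] <- 0
  g <- gradientProfile(d, 10, 40)
  expect_identical(nrow(g@table), 4L)
  expect_identical(g@classification, "decreasing")
})

test_that("gradient calls are invariant to monotone density transforms", {
  set.seed(19)
  for (i in 1:5) {
    n <- sample(5:40, 8)
    base <- data.frame(axis_coord_mm = seq(-1, by = -0.1, length.out = 8),
                       n_profiles = n, region_area_px = 800)
    cubed <- base; cubed$n_profiles <- n^3 / 1e3
    g1 <- gradientProfile(base, 10, 40)
    g2 <- gradientProfile(cubed, 10, 40)
    expect_equal(g1@rho, g2@rho, tolerance = 1e-12)
    expect_identical(g1@classification, g2@classification)
    expect_equal(g1@rho, bruteSpearman(seq_len(8), n), tolerance = 1e-12)
  }
})

test_that("a planted dorsoventral ramp is recovered through the full chain", {
  nSec <- 8
  g <- generateAtlasSeries(nSec, c(60, 80), 1, "bands",
                           axisStart = -1, axisStep = 0.2, seed = 19)
  counts <- round(seq(36, 4, length.out = nSec))
  masks <- vector("list", nSec)
  truths <- list()
  for (i in seq_len(nSec)) {
    pc <- plantCells(g$sections[i], countSpec = c("2" = counts[i]),
                     radiusRange = c(2, 3), seed = 19 + i)
    masks[[i]] <- pc$masks[[1]]
  }
  objs <- extractSeries(masks, g$sections)
  cnt <- countProfiles(objs, g$sections)
  cnt$axis_coord_mm <- vapply(g$sections,
                              function(s) s@axisCoord,
                              numeric(1))[cnt$section_index]
  prof <- gradientProfile(cnt[cnt$region == "2", ], 10, 40, label = "R1")
  expect_identical(prof@classification, "decreasing")
  expect_lte(prof@rho, -0.5)
  expect_equal(prof@rho,
               bruteSpearman(seq_len(nSec),
                             prof@table$density_per_mm3),
               tolerance = 1e-12)
})
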