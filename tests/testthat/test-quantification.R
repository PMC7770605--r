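test_that("Abercrombie's correction has the right limits and monotonicity", {
  expect_identical(abercrombie(1000, 40, 0), 1000)
  expect_identical(abercrombie(0, 40, 15), 0)
  expect_equal(abercrombie(3400, 40, 15), 3400 * 40 / 55)
  expect_error(abercrombie(10, 0, 15), "T must be > 0")
  expect_error(abercrombie(-1, 40, 15), "n must be >= 0")
  # monotone in n and T, antitone in D
  expect_gt(abercrombie(200, 40, 15), abercrombie(100, 40, 15))
  expect_gt(abercrombie(100, 50, 15), abercrombie(100, 40, 15))
  expect_lt(abercrombie(100, 40, 20), abercrombie(100, 40, 15))
})

test_that("corrected interval-extrapolated totals reproduce the worked pair", {
  p <- quantParams(thickness = 40, diameter = 15, interval = 6)
  manual <- estimateRegions(
    data.frame(section_index = 1, region = "MEC", n_profiles = 3400), p)
  expect_equal(manual$n_corrected, 2472.7273, tolerance = 1e-4)
  expect_identical(manual$total_estimate, 14836L)
  auto <- estimateRegions(
    data.frame(section_index = 1, region = "MEC", n_profiles = 3560), p)
  expect_identical(auto$total_estimate, 15535L)
})

test_that("profile counting is conservative and honours the grouping", {
  empty <- countProfiles(list(extractObjects(matrix(0L, 16, 16))),
                         list(new("AtlasSection", labels = matrix(2L, 16, 16),
                                  sectionIndex = 1L, pixelSize = 10,
                                  thickness = 40, axisCoord = 0,
                                  hemisphere = NULL)))
  expect_true(all(empty$n_profiles == 0))

  set.seed(21)
  series <- makePlantedSeries(4, 4, shape = c(70, 100),
                              countSpec = c("2" = 5L, "3" = 4L,
                                            "4" = 3L, "5" = 2L), seed = 21)
  objs <- extractSeries(series$masks, series$sections)

  # identity grouping equals per-leaf counts
  perLeaf <- countProfiles(objs, series$sections)
  want <- truthCounts(series$truth)
  for (i in seq_len(nrow(want))) {
    got <- perLeaf$n_profiles[perLeaf$section_index == want$section_index[i] &
                              perLeaf$region == want$region_id[i]]
    expect_identical(got, want$n[i])
  }

  # custom grouping: counts pool to summed leaf counts
  grouping <- resolveGrouping(series$ontology,
                              data.frame(leaf_id = c(2L, 3L, 4L),
                                         group_acronym = c("AB", "AB", "C")))
  pooled <- countProfiles(objs, series$sections, grouping)
  for (s in 1:4) {
    expect_identical(
      pooled$n_profiles[pooled$section_index == s & pooled$region == "AB"],
      sum(want$n[want$section_index == s & want$region_id %in% c(2, 3)]))
    expect_identical(
      sum(pooled$n_profiles[pooled$section_index == s]),
      sum(want$n[want$section_index == s]))
  }
})

test_that("density is total over atlas volume, halved for one hemisphere", {
  nd <- data.frame(id = c(1L, 2L), acronym = c("ROOT", "A"),
                   name = c("root", "a"), parent_id = c(NA, 1L),
                   r = 0:1, g = c(0L, 0L), b = c(0L, 0L),
                   volume_mm3 = c(4, 4), oversaturated = FALSE)
  ont <- new("RegionOntology", nodes = nd)
  p <- quantParams(40, 0, 1)
  cnt <- data.frame(section_index = 1, region = "2", n_profiles = 1000)
  uni <- estimateRegions(cnt, p, ont, scope = "unilateral")
  expect_identical(uni$volume_mm3, 2)
  expect_identical(uni$density_per_mm3, 500)
  bi <- estimateRegions(cnt, p, ont, scope = "bilateral")
  expect_identical(bi$density_per_mm3, 250)
  # density x volume = total, exactly, before display rounding
  expect_identical(uni$density_per_mm3 * uni$volume_mm3,
                   as.numeric(uni$total_estimate))
})

test_that("totals are linear in the raw counts up to rounding", {
  p <- quantParams(40, 15, 6)
  for (n in c(7, 123, 3400)) {
    one <- estimateRegions(data.frame(section_index = 1, region = "X",
                                      n_profiles = n), p)$total_estimate
    two <- estimateRegions(data.frame(section_index = 1:2, region = "X",
                                      n_profiles = n), p)$total_estimate
    expect_lte(abs(two - 2 * one), 1)
  }
})

test_that("group totals equal summed leaf totals within rounding", {
  p <- quantParams(40, 15, 6)
  set.seed(2)
  leaves <- data.frame(section_index = 1,
                       region = as.character(2:6),
                       n_profiles = sample(50:400, 5))
  perLeaf <- estimateRegions(leaves, p)
  pooled <- estimateRegions(
    data.frame(section_index = 1, region = "G",
               n_profiles = sum(leaves$n_profiles)), p)
  expect_lte(abs(pooled$total_estimate - sum(perLeaf$total_estimate)),
             nrow(leaves))
  expect_identical(pooled$n_raw, sum(perLeaf$n_raw))
})

test_that("hemisphere estimates merge into bilateral totals", {
  p <- quantParams(40, 0, 1)
  nd <- data.frame(id = c(1L, 2L), acronym = c("ROOT", "A"),
                   name = c("root", "a"), parent_id = c(NA, 1L),
                   r = 0:1, g = c(0L, 0L), b = c(0L, 0L),
                   volume_mm3 = c(2, 2), oversaturated = FALSE)
  ont <- new("RegionOntology", nodes = nd)
  mk <- function(n) estimateRegions(
    data.frame(section_index = 1, region = "2", n_profiles = n), p, ont)

  eq <- bilateralMerge(mk(500), mk(500))
  expect_identical(eq$total_estimate, 1000L)
  expect_identical(eq$scope, "bilateral")
  expect_identical(eq$volume_mm3, 2)
  expect_identical(eq$density_per_mm3, 500)

  idn <- bilateralMerge(mk(0), mk(321))
  expect_identical(idn$total_estimate, 321L)
  expect_error(bilateralMerge(mk(1), eq), "unilateral")
})

test_that("hemisphere-split counting conserves whole-image totals", {
  series <- makePlantedSeries(2, 2, shape = c(60, 80),
                              countSpec = c("2" = 6L, "3" = 5L), seed = 4)
  secs <- lapply(series$sections, function(s) {
    s@hemisphere <- cbind(matrix(1L, 60, 40), matrix(2L, 60, 40))
    s
  })
  totals <- c(left = 0L, right = 0L, whole = 0L)
  for (i in seq_along(secs)) {
    tab <- objectTable(assignRegions(extractObjects(series$masks[[i]]),
                                     secs[[i]]))
    totals["left"] <- totals["left"] + sum(tab$hemisphere == "left")
    totals["right"] <- totals["right"] + sum(tab$hemisphere == "right")
    totals["whole"] <- totals["whole"] + nrow(tab)
  }
  expect_identical(totals[["left"]] + totals[["right"]], totals[["whole"]])
  expect_identical(totals[["whole"]], sum(truthCounts(series$truth)$n))
})

test_that("oversaturated regions are suppressed, including via ancestors", {
  ont <- loadOntology(demoOntologyPath())  # leaf 12 (RT) is flagged
  p <- quantParams(40, 15, 6)
  cnt <- data.frame(section_index = 1, region = as.character(c(5, 11, 12)),
                    n_profiles = c(100, 80, 60))
  est <- estimateRegions(cnt, p, ont)
  rt <- est[est$region == "12", ]
  expect_identical(rt$status, "not reported (oversaturated)")
  expect_true(is.na(rt$total_estimate) && is.na(rt$density_per_mm3))
  expect_identical(est$status[est$region %in% c("5", "11")], rep("ok", 2))

  # no flags -> untouched
  est2 <- excludeFlagged(est[est$region != "12", ],
                         new("RegionOntology",
                             nodes = transform(regionNodes(ont),
                                               oversaturated = FALSE)))
  expect_identical(est2$status, rep("ok", 2))

  # flag on a parent suppresses all member leaves in a leaf-level report
  nd <- regionNodes(ont)
  nd$oversaturated[nd$id == 4] <- TRUE  # thalamus: leaves 11 and 12
  flagged <- excludeFlagged(est, new("RegionOntology", nodes = nd))
  expect_identical(flagged$status[flagged$region %in% c("11", "12")],
                   rep("not reported (oversaturated)", 2))
  expect_identical(flagged$status[flagged$region == "5"], "ok")

  # and a group containing a flagged leaf is suppressed as a whole
  grouping <- resolveGrouping(ont, data.frame(
    leaf_id = c(11L, 12L), group_acronym = c("THg", "THg")))
  gest <- estimateRegions(
    data.frame(section_index = 1, region = "THg", n_profiles = 140),
    p, ont, grouping)
  expect_identical(gest$status, "not reported (oversaturated)")
})
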