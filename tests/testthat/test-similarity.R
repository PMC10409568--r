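test_that("DSA selection is the intersection of the two top-N rank sets", {
  # identically ranked measures: DSA = top-N of either
  rt <- c(8, 7, 6, 5, 4, 3, 2, 1)
  sel <- select_dsa(rt, rt / 10, lesion = 8, fraction = 0.25)
  expect_identical(as.integer(sel$dsa), c(1L, 2L))
  expect_length(sel$dsa, round(0.25 * 8))
  # exactly reversed rankings with fraction < 0.5: empty intersection
  sel2 <- select_dsa(rt, rev(rt) / 10, lesion = 8, fraction = 0.25)
  expect_length(sel2$dsa, 0)
  # toy case against exhaustive set arithmetic
  rt3 <- c(0.3, 0.9, 0.1, 0.8, 0.2, 0.5, 0.4, 0.7)
  dj3 <- c(0.2, -0.6, 0.1, 0.05, -0.9, 0.5, 0.3, 0.01)
  sel3 <- select_dsa(rt3, dj3, lesion = 3, fraction = 0.25)
  top_rt <- setdiff(order(-rt3), 3)[1:2]
  top_dj <- setdiff(order(-abs(dj3)), 3)[1:2]
  expect_setequal(as.integer(sel3$dsa), intersect(top_rt, top_dj))
  expect_true(all(as.integer(sel3$dsa) %in% as.integer(sel3$top_rt)))
  expect_true(all(as.integer(sel3$dsa) %in% as.integer(sel3$top_djj)))
  # all-zero RT warns
  expect_warning(select_dsa(rep(0, 8), dj3, lesion = 1), "zero")
})

test_that("overlap report follows the |common|/|DSA| convention", {
  mk <- function(idx, n = 20, src = "SSA")
    structure(as.integer(idx), n_regions = n, fraction = 0.25,
              source = src, class = "area_set")
  expect_equal(overlap(mk(1:5), mk(1:5, src = "DSA"))$overlap_fraction, 1)
  expect_equal(overlap(mk(1:5), mk(6:10, src = "DSA"))$overlap_fraction, 0)
  # |SSA∩DSA| = 8, |DSA| = 13 -> 8/13
  ov <- overlap(mk(1:10), mk(c(3:10, 12:16), src = "DSA"))
  expect_equal(ov$overlap_fraction, 8 / 13)
  expect_identical(ov$denominator_convention, "dsa")
  # empty DSA: flagged, fraction 0
  ov0 <- overlap(mk(1:4), mk(integer(0), src = "DSA"))
  expect_true(ov0$empty_dsa)
  expect_equal(ov0$overlap_fraction, 0)
  # alternative denominators
  expect_equal(overlap(mk(1:10), mk(c(3:10, 12:16), src = "DSA"),
                       denominator = "ssa")$overlap_fraction, 8 / 10)
})

test_that("measure correlations match closed-form Pearson/OLS", {
  x <- c(0.1, 0.4, 0.2, 0.9, 0.7, 0.5, 0.3)
  tab <- measure_correlations(jc = x, rt = x, djj = -2 * x + 3, lesion = 7)
  expect_equal(tab$r[tab$pair == "JC-RT"], 1)
  expect_equal(tab$slope[tab$pair == "JC-RT"], 1, ignore_attr = TRUE)
  expect_equal(tab$intercept[tab$pair == "JC-RT"], 0, ignore_attr = TRUE,
               tolerance = 1e-12)
  # |dJJ| = |−2x + 3| = 3 − 2x on this range: r = −1 against x
  expect_equal(tab$r[tab$pair == "JC-absdJJ"], -1)
  # 6-point toy against lm() and cor()
  set.seed(10)
  jc <- runif(7); rt <- runif(7); dj <- rnorm(7)
  tab2 <- measure_correlations(jc, rt, dj, lesion = 2)
  keep <- -2
  fit <- lm(abs(dj)[keep] ~ jc[keep])
  row <- tab2[tab2$pair == "JC-absdJJ", ]
  expect_equal(row$r, cor(jc[keep], abs(dj)[keep]), tolerance = 1e-12)
  expect_equal(row$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(row$intercept, unname(coef(fit)[1]), tolerance = 1e-12)
  # constant vector: degenerate flag, r = 0
  tab3 <- measure_correlations(rep(1, 7), rt, dj, lesion = 1)
  expect_true(all(tab3$degenerate[tab3$pair != "RT-absdJJ"]))
  expect_equal(tab3$r[1], 0)
})

test_that("common top areas use the same rank machinery as DSA", {
  x <- c(9, 8, 7, 6, 5, 4, 3, 2)
  y <- c(9, 1, 7, 2, 5, 3, 8, 4)
  cta <- common_top_areas(x, y, fraction = 0.5)
  expect_setequal(as.integer(cta),
                  intersect(order(-x)[1:4], order(-y)[1:4]))
  expect_identical(as.integer(common_top_areas(x, rev(x), fraction = 0.25)),
                   integer(0))
})

test_that("probability of appearance counts subjects correctly", {
  mk <- function(idx) structure(as.integer(idx), n_regions = 6,
                                fraction = 0.5, source = "SSA",
                                class = "area_set")
  pa <- probability_of_appearance(list(mk(c(1, 2)), mk(c(2, 3)), mk(2)))
  expect_equal(as.numeric(pa), c(1 / 3, 1, 1 / 3, 0, 0, 0))
  expect_equal(attr(pa, "n_subjects"), 3)
  # permutation invariance over subject order
  pa2 <- probability_of_appearance(list(mk(2), mk(c(1, 2)), mk(c(2, 3))))
  expect_equal(as.numeric(pa), as.numeric(pa2))
  # single subject: PA is 0/1 valued
  pa1 <- probability_of_appearance(list(mk(c(4, 5))))
  expect_true(all(pa1 %in% c(0, 1)))
})
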