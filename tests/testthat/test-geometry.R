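test_that("resampling preserves constant and linear profiles exactly", {
  tube <- centerline_profile(seq(0, 100, 5), rep(1.5, 21))
  rs <- resample_profile(tube, 1)
  expect_length(rs$s_mm, 101)
  expect_equal(rs$r_mm, rep(1.5, 101))

  taper <- centerline_profile(seq(0, 100, 10), 2 - 0.01 * seq(0, 100, 10))
  rs <- resample_profile(taper, 0.5)
  expect_equal(rs$r_mm[rs$s_mm == 50], 1.5)
  # endpoints preserved bit-exactly
  expect_identical(rs$r_mm[1], 2)
  expect_identical(rs$r_mm[length(rs$r_mm)], 1)
})

test_that("monotone interpolation tracks an analytic cosine bump without overshoot", {
  bump <- function(s) {
    r <- rep(1.5, length(s))
    inside <- s >= 40 & s <= 60
    r[inside] <- 1.5 - 0.4 * (1 - cos(2 * pi * (s[inside] - 40) / 20)) / 2
    r
  }
  coarse <- centerline_profile(seq(0, 100, 2), bump(seq(0, 100, 2)))
  fine <- resample_profile(coarse, 0.25)
  expect_lt(max(abs(fine$r_mm - bump(fine$s_mm))), 0.05)
  # shape preservation: no overshoot above the healthy lumen or below the
  # sampled minimum
  expect_lte(max(fine$r_mm), 1.5 + 1e-12)
  expect_gte(min(fine$r_mm), min(coarse$r_mm) - 1e-12)
})

test_that("invalid profiles are rejected with geometry errors", {
  expect_error(centerline_profile(c(0, 10, 5), c(1, 1, 1)), "increasing")
  expect_error(centerline_profile(c(0, 10), c(1, -1)), "positive")
  expect_error(centerline_profile(0, 1), "2 samples")
  tube <- centerline_profile(c(0, 50), c(1.5, 1.5))
  expect_error(resample_profile(tube, 0), class = "ffrct_geometry_error")
  expect_error(resample_profile(tube, 60), class = "ffrct_geometry_error")
})

test_that("reference diameters come from shoulder medians with linear interpolation", {
  s <- seq(0, 100, 0.5)
  tube <- centerline_profile(s, cosine_narrowed_d(s, 3, 40, 60, 0.5) / 2)
  ref <- reference_diameter_profile(tube, c(40, 60))
  expect_equal(ref$d_ref_prox, 3)
  expect_equal(ref$d_ref_dist, 3)
  expect_equal(ref$reference, rep(3, length(s)))

  # linear taper 3.0 -> 2.0 over 100 mm: interpolated reference at mid-lesion
  # equals the taper's own value up to the shoulder-median offset
  tap <- centerline_profile(s, (3 - 0.01 * s) / 2)
  ref <- reference_diameter_profile(tap, c(40, 60))
  # shoulder samples at s = 35 .. 39.5: median diameter is d(37.25)
  expect_equal(ref$d_ref_prox, 3 - 0.01 * 37.25, tolerance = 1e-6)
  expect_equal(ref$reference[s == 50], 3 - 0.01 * 50, tolerance = 1e-3)

  # median shoulder is insensitive to a single outlier sample
  r_out <- cosine_narrowed_d(s, 3, 40, 60, 0.5) / 2
  clean <- reference_diameter_profile(centerline_profile(s, r_out), c(40, 60))
  r_out[s == 37] <- 2.6   # one corrupted shoulder sample
  dirty <- reference_diameter_profile(centerline_profile(s, r_out), c(40, 60))
  expect_equal(dirty$d_ref_prox, clean$d_ref_prox)

  expect_error(reference_diameter_profile(tube, c(2, 60)),
               class = "ffrct_geometry_error")
  expect_error(reference_diameter_profile(tube, c(40, 98)),
               class = "ffrct_geometry_error")
})

test_that("lesion detection finds, grades, and merges narrowings", {
  expect_equal(nrow(detect_lesions(tube_tree())), 0L)

  les <- detect_lesions(lesion_tree(depth = 0.5))
  expect_equal(nrow(les), 1L)
  expect_equal(les$pct_ds, 50, tolerance = 1 / 50)   # 50 +/- 1
  expect_gt(les$s_start, 35)
  expect_lt(les$s_end, 65)

  # two 60% flat-bottomed narrowings 3 mm apart merge into one serial lesion
  trap <- function(s, a, b, depth, ramp = 1) {
    m <- rep(1, length(s))
    m[s >= a + ramp & s <= b - ramp] <- 1 - depth
    up <- s >= a & s < a + ramp
    m[up] <- 1 - depth * (s[up] - a) / ramp
    dn <- s > b - ramp & s <= b
    m[dn] <- 1 - depth * (b - s[dn]) / ramp
    m
  }
  s <- seq(0, 100, 0.5)
  d <- 3 * trap(s, 35, 48, 0.6) * trap(s, 51, 64, 0.6)
  two <- coronary_tree(list(main = list(
    profile = centerline_profile(s, d / 2), parent = NULL)), "main", 120)
  les2 <- detect_lesions(two, merge_gap = 5)
  expect_equal(nrow(les2), 1L)
  expect_lt(les2$s_start, 37)
  expect_gt(les2$s_end, 62)

  expect_error(detect_lesions(list()), class = "ffrct_geometry_error")
})

test_that("no lesion is reported when no sample breaches the threshold", {
  # 20% narrowing stays invisible at a 30% threshold
  shallow <- lesion_tree(depth = 0.2)
  expect_equal(nrow(detect_lesions(shallow, min_pct_ds = 30)), 0L)
})

test_that("percent stenosis is invariant under uniform radius rescaling", {
  t1 <- lesion_tree(depth = 0.45)
  segs <- t1$segments
  segs$main$profile <- centerline_profile(segs$main$profile$s_mm,
                                          1.7 * segs$main$profile$r_mm)
  t2 <- coronary_tree(segs, "main", 120)
  expect_equal(detect_lesions(t2)$pct_ds, detect_lesions(t1)$pct_ds,
               tolerance = 1e-9)
})

test_that("resampling moves detected lesion boundaries by less than one spacing", {
  tr <- lesion_tree(depth = 0.5, ds = 0.5)
  a <- detect_lesions(tr, ds = 0.5)
  b <- detect_lesions(tr, ds = 0.25)
  expect_lt(abs(a$s_start - b$s_start), 0.5 + 1e-9)
  expect_lt(abs(a$s_end - b$s_end), 0.5 + 1e-9)
})

test_that("tree JSON serialization round-trips every numeric field exactly", {
  trees <- list(lesion_tree(), bifurcation_tree())
  for (tr in trees) {
    f <- withr::local_tempfile(fileext = ".json")
    write_tree(tr, f)
    back <- read_tree(f)
    expect_equal(back$myocardial_volume_ml, tr$myocardial_volume_ml,
                 tolerance = 0)
    for (id in names(tr$segments)) {
      expect_equal(back$segments[[id]]$profile$s_mm,
                   tr$segments[[id]]$profile$s_mm, tolerance = 0)
      expect_equal(back$segments[[id]]$profile$r_mm,
                   tr$segments[[id]]$profile$r_mm, tolerance = 0)
    }
    # write(read(f)) is stable
    f2 <- withr::local_tempfile(fileext = ".json")
    write_tree(back, f2)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("malformed tree files raise structured schema errors", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"inlet": "a", "segments": {"a": {"s_mm": [0, 10], "r_mm": [1, 1], "parent": null}}}', f)
  expect_error(read_tree(f), "myocardial_volume")

  writeLines(paste0('{"myocardial_volume_ml": 120, "inlet": "a", "segments": ',
                    '{"a": {"s_mm": [0,10], "r_mm": [1,1], "parent": "b"}, ',
                    '"b": {"s_mm": [0,10], "r_mm": [1,1], "parent": "a"}}}'), f)
  expect_error(read_tree(f), class = "ffrct_topology_error")

  # two roots
  writeLines(paste0('{"myocardial_volume_ml": 120, "inlet": "a", "segments": ',
                    '{"a": {"s_mm": [0,10], "r_mm": [1,1], "parent": null}, ',
                    '"b": {"s_mm": [0,10], "r_mm": [1,1], "parent": null}}}'), f)
  expect_error(read_tree(f), "exactly one root")
})
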