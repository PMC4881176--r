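test_that("CNP counts per normal sample follow the 5-epsilon rule", {
  set.seed(51)
  eps <- 0.2
  clean <- fake_decomposed(rnorm(1e4, 0, eps), eps, id = "n1",
                           tissue = "normal")
  cs <- count_cnp_per_normal_sample(list(clean), k = 5)
  expect_lte(cs$n_cnp, 3L)   # 2 * pnorm(-5) * 1e4 is ~0.006 expected sites

  fcnv <- rnorm(1e4, 0, eps)
  fcnv[1001:1020] <- 8 * eps
  germ <- fake_decomposed(fcnv, eps, id = "n2", tissue = "normal")
  cs2 <- count_cnp_per_normal_sample(list(germ), k = 5)
  expect_gte(cs2$n_cnp, 20L)

  tum <- fake_decomposed(rnorm(100, 0, eps), eps, tissue = "tumor")
  expect_error(count_cnp_per_normal_sample(list(tum)), "normal-tissue")
})

test_that("CNP outlier fencing flags only extreme normals", {
  mk <- function(counts) {
    s <- data.frame(sample_id = paste0("n", seq_along(counts)),
                    n_cnp = as.integer(counts))
    structure(s, class = c("cnp_summary", "data.frame"))
  }
  expect_false(any(flag_cnp_outliers(mk(rep(5, 20)))$outlier))
  set.seed(52)
  counts <- c(rpois(99, 5), 5000)
  flagged <- suppressMessages(flag_cnp_outliers(mk(counts)))
  expect_equal(sum(flagged$outlier), 1L)
  expect_true(flagged$outlier[100])
  expect_false(any(flag_cnp_outliers(mk(counts), rule = Inf)$outlier))
  expect_error(flag_cnp_outliers(mk(c(1, 2))), ">= 5")
})

test_that("normal-sample event counts inside an interval count samples once", {
  quiet <- lapply(1:5, function(i)
    fake_calls(rep("neutral", 50), id = paste0("n", i)))
  expect_equal(normal_event_count_in_interval(quiet, "chr1", 1, 50000), 0L)

  # a multi-site germline event in one normal counts once
  s <- rep("neutral", 50); s[20:24] <- "gain"
  three <- c(lapply(1:3, function(i) fake_calls(s, id = paste0("g", i))),
             quiet[1:2])
  expect_equal(normal_event_count_in_interval(three, "chr1", 19000, 25000), 3L)
  expect_warning(normal_event_count_in_interval(three, "chr1", 9e6, 9.5e6),
                 "outside")
})

test_that("asymmetry test reduces to the exact binomial", {
  expect_equal(gain_loss_asymmetry_test(5, 5), 1)
  expect_equal(gain_loss_asymmetry_test(10, 0), 2 * 0.5^10)
  expect_equal(gain_loss_asymmetry_test(10, 0, sided = "one"), 0.5^10)
  expect_warning(p0 <- gain_loss_asymmetry_test(0, 0), "undefined")
  expect_equal(p0, 1)
  # label swap leaves the two-sided p unchanged
  expect_equal(gain_loss_asymmetry_test(3, 12), gain_loss_asymmetry_test(12, 3))
})

test_that("each of the four selection criteria gates regions independently", {
  mk_peak <- function(height, ci_lo, ci_hi, pos = 50000L) {
    structure(data.frame(chrom = "chr1", site = 50L, pos = pos,
                         direction = "gain", height = height,
                         ci_lo = as.integer(ci_lo), ci_hi = as.integer(ci_hi),
                         n_boot = 100L, ci_defined = TRUE,
                         stringsAsFactors = FALSE),
              class = c("peak_set", "data.frame"))
  }
  track <- fake_track(n_gain = c(rep(0L, 49), 20L, rep(0L, 50)),
                      n_loss = rep(0L, 100), n_samples = 30L)
  no_events <- lapply(1:5, function(i)
    fake_calls(rep("neutral", 100), id = paste0("n", i)))

  # all four criteria pass
  r <- select_focal_regions(mk_peak(20, 40000, 540000), track, no_events)
  expect_true(r$selected)
  expect_true(all(r$flag_height, r$flag_ci_width, r$flag_normal,
                  r$flag_asymmetry))
  expect_equal(r$n_gain, 20L)

  # CI of 1.2 Mb fails the width criterion
  r2 <- select_focal_regions(mk_peak(20, 40000, 1240000), track, no_events)
  expect_false(r2$selected)
  expect_false(r2$flag_ci_width)

  # height 7 fails the floor
  track7 <- fake_track(n_gain = c(rep(0L, 49), 7L, rep(0L, 50)),
                       n_loss = rep(0L, 100), n_samples = 30L)
  r3 <- select_focal_regions(mk_peak(7, 40000, 540000), track7, no_events)
  expect_false(r3$selected)
  expect_false(r3$flag_height)

  # 3 normal events pass (< 4), 4 fail
  s <- rep("neutral", 100); s[50] <- "loss"
  ev <- function(n) c(lapply(seq_len(n), function(i)
    fake_calls(s, id = paste0("e", i))), no_events)
  r4 <- select_focal_regions(mk_peak(20, 40000, 540000), track, ev(3))
  expect_true(r4$selected)
  expect_equal(r4$n_normal_events, 3L)
  r5 <- select_focal_regions(mk_peak(20, 40000, 540000), track, ev(4))
  expect_false(r5$selected)
  expect_false(r5$flag_normal)

  # symmetric gains/losses fail the asymmetry criterion
  track_sym <- fake_track(n_gain = c(rep(0L, 49), 10L, rep(0L, 50)),
                          n_loss = c(rep(0L, 49), 10L, rep(0L, 50)),
                          n_samples = 30L)
  r6 <- select_focal_regions(mk_peak(10, 40000, 540000), track_sym, no_events)
  expect_false(r6$selected)
  expect_false(r6$flag_asymmetry)

  # no normals supplied: criterion reported as not evaluated, passes vacuously
  r7 <- select_focal_regions(mk_peak(20, 40000, 540000), track, NULL)
  expect_true(r7$selected)
  expect_false(r7$normal_evaluated)
  expect_true(is.na(r7$n_normal_events))

  # tightening a threshold never adds a region
  r8 <- select_focal_regions(mk_peak(20, 40000, 540000), track, no_events,
                             max_ci_width = 1e5)
  expect_false(r8$selected)
})
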