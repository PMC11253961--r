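# Screen-level filtering, merging, thresholding, and hit calling.

test_that("cell-record filter retains bright nuclei of plausible volume", {
  rec <- tibble::tibble(
    plate = 1L, well = "w1",
    nuclear_mean_gfp = c(800, 500, 800, 800, 751),
    nuclear_gfp_volume = c(50, 50, 500, 10, 200),
    rdna_volume_ratio = 0.1, rdna_intensity_ratio = 1)
  out <- suppressMessages(filter_cell_records(rec))
  # intensity 800/vol 50 kept; intensity 500 removed; vol 500 removed;
  # boundaries 10 and 200 are inclusive
  expect_equal(out$nuclear_mean_gfp, c(800, 800, 751))
  expect_equal(out$nuclear_gfp_volume, c(50, 10, 200))
  # drop direction inverts the rule
  out_drop <- suppressMessages(filter_cell_records(rec, direction = "drop"))
  expect_equal(out_drop$nuclear_mean_gfp, c(500, 800))
})

test_that("well summaries use medians and drop sparse wells", {
  rec <- tibble::tibble(
    plate = rep(1L, 59),
    well = c(rep("a", 29), rep("b", 30)),
    rdna_volume_ratio = c(rep(0.5, 29), rep(0.1, 15), rep(0.3, 15)),
    rdna_intensity_ratio = 1)
  out <- suppressMessages(summarize_wells(rec))
  # the 29-cell well is dropped
  expect_equal(out$well, "b")
  expect_equal(attr(out, "dropped_wells")$well, "a")
  # median of 15 x 0.1 and 15 x 0.3 (order statistic, even n)
  expect_equal(out$median_volume_ratio, median(c(rep(0.1, 15), rep(0.3, 15))))
  # constant well: median equals the value
  rec_c <- tibble::tibble(plate = 1L, well = "c",
                          rdna_volume_ratio = rep(0.42, 30),
                          rdna_intensity_ratio = rep(1.5, 30))
  expect_equal(suppressMessages(summarize_wells(rec_c))$median_volume_ratio, 0.42)
})

test_that("mated duplicates are merged by the mean of replicate medians", {
  wells <- tibble::tibble(
    plate = c(1L, 1L, 1L), well = c("w1", "w2", "w3"),
    n_cells = c(40L, 35L, 40L),
    median_volume_ratio = c(0.50, 0.70, 0.20),
    median_intensity_ratio = c(1.0, 1.2, 2.0))
  pm <- tibble::tibble(plate = 1L, well = c("w1", "w2", "w3"),
                       strain = c("sA", "sA", "sB"),
                       replicate = c(1L, 2L, 1L))
  out <- merge_mated_duplicates(wells, pm)
  expect_equal(out$strain, "sA")
  expect_equal(out$median_volume_ratio, 0.60)
  expect_equal(out$median_intensity_ratio, 1.1)
  # sB lost a replicate -> excluded with a reason
  exc <- attr(out, "excluded")
  expect_equal(exc$strain, "sB")
  expect_equal(exc$reason, "missing_replicate")
  # identical replicates: merged summary equals either one
  wells2 <- wells[1:2, ]
  wells2$median_volume_ratio <- 0.5
  out2 <- merge_mated_duplicates(wells2, pm[1:2, ])
  expect_equal(out2$median_volume_ratio, 0.5)
  # unmapped wells error
  expect_error(merge_mated_duplicates(wells, pm[1:2, ]), "no strain mapping")
})

test_that("wild-type thresholds match a direct quantile oracle", {
  wt <- tibble::tibble(
    volume_ratio = c(0.40, 0.45, 0.50, 0.50, 0.55, 0.55, 0.60, 0.65),
    intensity_ratio = c(0.40, 0.45, 0.50, 0.50, 0.55, 0.55, 0.60, 0.65))
  thr <- compute_wt_thresholds(wt)
  expect_equal(thr$volume[["centre"]], 0.525)
  expect_equal(thr$volume[["spread"]], 0.075)   # type-7 IQR
  expect_equal(thr$volume[["high"]], 0.550)
  expect_equal(thr$volume[["low"]], 0.50625)
  # oracle cross-check
  iqr_o <- quantile7(wt$volume_ratio, 0.75) - quantile7(wt$volume_ratio, 0.25)
  expect_equal(thr$volume[["spread"]], iqr_o)

  # degenerate: all medians equal -> high = low = centre
  wt_eq <- tibble::tibble(volume_ratio = rep(0.5, 8),
                          intensity_ratio = rep(1, 8))
  thr_eq <- compute_wt_thresholds(wt_eq)
  expect_equal(unname(thr_eq$volume[c("high", "low")]), c(0.5, 0.5))

  # translation equivariance
  thr_sh <- compute_wt_thresholds(dplyr::mutate(
    wt, volume_ratio = volume_ratio + 0.2,
    intensity_ratio = intensity_ratio + 0.2))
  expect_equal(thr_sh$volume[["centre"]], thr$volume[["centre"]] + 0.2)
  expect_equal(thr_sh$volume[["high"]], thr$volume[["high"]] + 0.2)
  expect_equal(thr_sh$volume[["low"]], thr$volume[["low"]] + 0.2)

  # permutation invariance
  set.seed(2)
  thr_perm <- compute_wt_thresholds(wt[sample(8), ])
  expect_equal(tidy(thr_perm), tidy(thr))

  expect_error(compute_wt_thresholds(wt[1, ]), "at least 2")
})

test_that("hit calls require both metrics past the threshold", {
  wt <- tibble::tibble(volume_ratio = seq(0.4, 0.6, length.out = 8),
                       intensity_ratio = seq(1.8, 2.2, length.out = 8))
  thr <- compute_wt_thresholds(wt)
  s <- tibble::tibble(
    strain = c("both_hi", "vol_hi_only", "both_lo", "mid"),
    median_volume_ratio = c(0.9, 0.9, 0.1, 0.5),
    median_intensity_ratio = c(3.0, 2.0, 0.5, 2.0))
  out <- suppressMessages(call_hits(s, thr))
  expect_equal(out$call, c("high", "normal", "low", "normal"))

  # monotonicity: raising both metrics never demotes a call
  rank_call <- function(x) match(x, c("low", "normal", "high"))
  up <- dplyr::mutate(s, median_volume_ratio = median_volume_ratio + 0.05,
                      median_intensity_ratio = median_intensity_ratio + 0.2)
  out_up <- suppressMessages(call_hits(up, thr))
  expect_true(all(rank_call(out_up$call) >= rank_call(out$call)))
})

test_that("copy-number equivalence uses an inclusive 10 percent bound", {
  expect_true(copy_number_equivalent(110, 100))
  expect_false(copy_number_equivalent(111, 100))
  expect_true(copy_number_equivalent(90, 100))
  expect_error(copy_number_equivalent(0, 100), "positive")
})

test_that("screen pipeline conserves strains and recovers planted truth", {
  st <- sim_screen_tables(seed = 7)
  res <- suppressMessages(screen_call(st$cells, st$platemap, wt_plates = 1:8))
  hits <- tidy(res)

  # conservation: every mutant strain appears exactly once in hits or exclusions
  all_strains <- sort(unique(st$platemap$strain[st$platemap$strain != "WT"]))
  accounted <- sort(c(hits$strain, res$exclusions$strain))
  expect_equal(accounted, all_strains)

  # planted truth recovered without miscalls
  cmp <- dplyr::inner_join(hits, st$truth, by = "strain")
  expect_equal(sum(cmp$call == "high" & cmp$truth == "high"), 10)
  expect_equal(sum(cmp$call == "low" & cmp$truth == "low"), 10)
  expect_equal(sum(cmp$call != "normal" & cmp$truth == "null"), 0)

  # the planted sparse well excludes its strain with a logged reason
  short_strain <- st$truth$strain[st$truth$short_well]
  expect_true(short_strain %in% res$exclusions$strain)
  expect_true(nrow(res$dropped_wells) >= 1)

  # glance reports the class counts
  g <- glance(res)
  expect_equal(g$n_high, 10)
  expect_equal(g$n_low, 10)
  expect_equal(g$n_quantified, 95)
})

test_that("a null screen calls few hits", {
  # no planted effects: false calls are bounded by the threshold design
  n_bad <- 0; n_tot <- 0
  for (s in 1:3) {
    st <- sim_screen_tables(n_strains = 48, n_high = 0, n_low = 0,
                            cells_per_well = 35, seed = 100 + s)
    res <- suppressMessages(screen_call(st$cells, st$platemap, wt_plates = 1:8))
    n_bad <- n_bad + sum(res$hits$call != "normal")
    n_tot <- n_tot + nrow(res$hits)
  }
  expect_lt(n_bad / n_tot, 0.10)
})
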