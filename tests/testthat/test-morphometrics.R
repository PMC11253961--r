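# Compartment masks, per-cell readouts, staging, and outlier filtering.

mk_masks <- function(nuc_idx, nol_idx, shape = c(3, 6, 6)) {
  g <- array(FALSE, shape); g[nuc_idx] <- TRUE
  m <- array(FALSE, shape); m[nol_idx] <- TRUE
  derive_compartments(g, m)
}

test_that("compartment set identities hold voxelwise", {
  set.seed(5)
  shape <- c(4, 8, 8)
  g <- array(runif(prod(shape)) < 0.4, shape)
  m <- array(runif(prod(shape)) < 0.3, shape)
  cm <- derive_compartments(g, m)
  expect_identical(cm$rdna, cm$nucleus & cm$nucleolus)
  expect_identical(cm$bulk_chromatin, cm$nucleus & !cm$nucleolus)
  expect_true(!any(cm$rdna & cm$bulk_chromatin))
  # disjoint masks give an empty rDNA object
  cm2 <- derive_compartments(g & FALSE | array(c(TRUE, rep(FALSE, 255)), shape),
                             array(c(FALSE, TRUE, rep(FALSE, 254)), shape))
  expect_equal(sum(cm2$rdna), 0)
  expect_error(derive_compartments(g, m[1:2, , ]), "shape")
})

test_that("measure_cell computes volumes, means, and ratio readouts", {
  # nucleus 100 voxels at GFP 50; rDNA 20 voxels at GFP 150
  shape <- c(4, 10, 10)
  g <- array(FALSE, shape); g[1:100] <- TRUE
  m <- array(FALSE, shape); m[1:20] <- TRUE
  gfp <- array(0, shape)
  gfp[1:20] <- 150; gfp[21:100] <- 25   # nuclear mean = (20*150 + 80*25)/100 = 50
  cm <- derive_compartments(g, m)
  r <- measure_cell(cm, gfp)
  expect_equal(r$nuclear_volume, 100)
  expect_equal(r$nuclear_mean_gfp, 50)
  expect_equal(r$rdna_volume_ratio, 0.20)
  expect_equal(r$rdna_intensity_ratio, 3.0)
  expect_equal(r$mcherry_volume_ratio, 0.20)

  # nucleolus == nucleus with uniform GFP: all three ratios are 1
  cm2 <- derive_compartments(g, g)
  r2 <- measure_cell(cm2, array(80, shape))
  expect_equal(r2$rdna_volume_ratio, 1)
  expect_equal(r2$rdna_intensity_ratio, 1)
  expect_equal(r2$mcherry_volume_ratio, 1)

  # empty rDNA object: zero ratios plus a flag, not an error
  m3 <- array(FALSE, shape); m3[101:120] <- TRUE
  r3 <- measure_cell(derive_compartments(g, m3), gfp)
  expect_equal(r3$rdna_volume_ratio, 0)
  expect_equal(r3$rdna_intensity_ratio, 0)
  expect_match(r3$flags, "no_rdna_object")

  # empty nucleus errors
  g0 <- array(FALSE, shape)
  expect_error(measure_cell(derive_compartments(g0, m), gfp), "empty")
})

test_that("rDNA extension is the physical distance between midpoints", {
  shape <- c(10, 20, 30)
  g <- array(FALSE, shape); m <- array(FALSE, shape)
  # rdna voxel at (5, 10, 20); bulk voxel at (5, 10, 10)
  g[5, 10, 20] <- TRUE; g[5, 10, 10] <- TRUE
  m[5, 10, 20] <- TRUE
  cm <- derive_compartments(g, m)
  gfp <- array(1, shape)
  expect_equal(compute_extension(cm, gfp, pixel_size_xy = 0.11, z_step = 0.3),
               10 * 0.11)
  # offset of 2 slices in z only
  g2 <- array(FALSE, shape); m2 <- array(FALSE, shape)
  g2[5, 10, 10] <- TRUE; g2[7, 10, 10] <- FALSE  # bulk at z=5
  g2[7, 12, 12] <- TRUE; m2[7, 12, 12] <- TRUE   # rdna at z=7
  g2[5, 12, 12] <- TRUE                          # second bulk voxel
  cm2 <- derive_compartments(g2, m2)
  ext <- compute_extension(cm2, array(1, shape), 0.11, 0.3)
  # bulk centroid (5, 11, 11), rdna (7, 12, 12)
  expect_equal(ext, sqrt((2 * 0.3)^2 + (0.11)^2 + (0.11)^2))
  # coincident centroids give zero
  g3 <- array(FALSE, shape); m3 <- array(FALSE, shape)
  g3[5, 10, 10:12] <- TRUE; m3[5, 10, 11] <- TRUE
  ext3 <- compute_extension(derive_compartments(g3, m3), array(1, shape),
                            0.11, 0.3)
  expect_equal(ext3, 0)
  # empty region errors with the region name
  expect_error(compute_extension(derive_compartments(m3, m3),
                                 array(1, shape)), "bulk_chromatin")
})

test_that("intensity weighting moves the extension midpoint", {
  shape <- c(3, 5, 9)
  g <- array(FALSE, shape); m <- array(FALSE, shape)
  g[2, 3, 1:2] <- TRUE      # bulk: two voxels
  g[2, 3, 6:8] <- TRUE; m[2, 3, 6:8] <- TRUE  # rdna: three voxels
  cm <- derive_compartments(g, m)
  gfp <- array(1, shape); gfp[2, 3, 8] <- 10   # bright rdna tail
  w <- compute_extension(cm, gfp, 1, 1, weighted = TRUE)
  b <- compute_extension(cm, gfp, 1, 1, weighted = FALSE)
  expect_gt(w, b)  # weighted centroid pulled toward the bright voxel
})

test_that("multinucleate filtering removes cells without exactly one nucleus", {
  cells <- tibble::tibble(cell_id = c("a", "b", "c", "d"),
                          nucleus_count = c(1L, 2L, 0L, 1L))
  expect_message(out <- filter_multinucleate(cells), "removed 2")
  expect_equal(out$cell_id, c("a", "d"))
  expect_equal(attr(out, "n_removed"), 2)
})

test_that("staging splits the population into length tertiles", {
  # n = 9 distinct lengths: exact tertiles
  cells <- tibble::tibble(cell_id = letters[1:9], cell_length = 5:13)
  st <- stage_population(cells)
  expect_equal(st$stage[st$cell_length %in% 5:7], rep("early_G2", 3))
  expect_equal(st$stage[st$cell_length %in% 8:10], rep("mid_G2", 3))
  expect_equal(st$stage[st$cell_length %in% 11:13], rep("late_G2", 3))

  # all lengths equal: ties across the boundary all go to mid G2
  eq <- tibble::tibble(cell_id = letters[1:6], cell_length = rep(9, 6))
  expect_true(all(stage_population(eq)$stage == "mid_G2"))

  # n = 10: boundary size from a sort-and-slice oracle (round(0.33 * 10) = 3)
  set.seed(3)
  len <- sample(seq(5, 14, length.out = 10))
  cells10 <- tibble::tibble(cell_id = sprintf("c%02d", 1:10),
                            cell_length = len)
  st10 <- stage_population(cells10)
  srt <- sort(len)
  expect_setequal(st10$cell_id[st10$stage == "early_G2"],
                  cells10$cell_id[len %in% srt[1:3]])
  expect_setequal(st10$cell_id[st10$stage == "late_G2"],
                  cells10$cell_id[len %in% srt[8:10]])

  # deterministic under permutation
  perm <- sample(10)
  st_perm <- stage_population(cells10[perm, ])
  expect_equal(dplyr::arrange(st_perm, cell_id), dplyr::arrange(st10, cell_id))

  expect_error(stage_population(cells10[0, ]), "empty")
})

test_that("IQR outlier filter matches a direct quantile oracle", {
  out <- iqr_outlier_filter(c(1, 2, 3, 4, 100))
  expect_equal(out$removed, 100)
  expect_equal(out$kept, c(1, 2, 3, 4))
  # oracle fences
  q1 <- quantile7(c(1, 2, 3, 4, 100), 0.25)
  q3 <- quantile7(c(1, 2, 3, 4, 100), 0.75)
  expect_equal(out$fences, c(q1 - 1.5 * (q3 - q1), q3 + 1.5 * (q3 - q1)))

  # identical values: IQR zero, nothing removed
  expect_length(iqr_outlier_filter(rep(3.3, 10))$removed, 0)

  # order of kept values preserved
  set.seed(8)
  x <- rnorm(50)
  kept <- iqr_outlier_filter(x)$kept
  expect_true(all(diff(match(kept, x)) > 0))

  # standard normal removal fraction ~ 0.7%
  set.seed(123)
  z <- rnorm(10000)
  frac <- length(iqr_outlier_filter(z)$removed) / 10000
  expect_gt(frac, 0.004)
  expect_lt(frac, 0.010)

  expect_warning(out_small <- iqr_outlier_filter(c(1, 2, 3)), "fewer than 4")
  expect_equal(out_small$kept, c(1, 2, 3))
})

test_that("ratio metrics are invariant to a global GFP gain", {
  sc <- sim_scene(seed = 6)
  q1 <- quantify_scene(sc$stack)
  vox <- sc$stack$voxels
  vox[1, , , ] <- vox[1, , , ] * 3.7
  stk2 <- image_stack(vox, sc$stack$channels,
                      sc$stack$pixel_size_xy, sc$stack$z_step)
  q2 <- quantify_scene(stk2)
  expect_equal(q2$rdna_volume_ratio, q1$rdna_volume_ratio, tolerance = 1e-8)
  expect_equal(q2$rdna_intensity_ratio, q1$rdna_intensity_ratio,
               tolerance = 1e-8)
  expect_equal(q2$mcherry_volume_ratio, q1$mcherry_volume_ratio,
               tolerance = 1e-8)
})

test_that("rDNA volume ratio never exceeds the mCherry volume ratio", {
  for (s in 1:3) {
    q <- quantify_scene(sim_scene(seed = s)$stack)
    expect_lte(q$rdna_volume_ratio, q$mcherry_volume_ratio + 1e-12)
  }
})
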