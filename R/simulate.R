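# Synthetic-data generators.  Every input class the pipeline consumes
# can be generated with known ground truth: 3D two-channel scenes,
# staged cell populations, screen cell-record tables, SGA colony-density
# grids, and FRAP traces.  All generators are pure functions of their
# parameters and a seed.

ellipsoid_mask <- function(shape, center, semi, dz = 0, dy = 0, dx = 0) {
  z <- ((seq_len(shape[1]) + dz - center[1]) / semi[1])^2
  y <- ((seq_len(shape[2]) + dy - center[2]) / semi[2])^2
  x <- ((seq_len(shape[3]) + dx - center[3]) / semi[3])^2
  outer(outer(z, y, `+`), x, `+`) <= 1
}

# sub-voxel coverage fractions of the chromatin and nucleolar
# compartments (anti-aliased rendering of the analytic surfaces)
compartment_coverage <- function(shape, nuc_c, nuc_s, nol_c, nol_s,
                                 shell_s, ss = 3) {
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  acc_chrom <- array(0, shape)
  acc_nol <- array(0, shape)
  for (dz in off) for (dy in off) for (dx in off) {
    e_nuc <- ellipsoid_mask(shape, nuc_c, nuc_s, dz, dy, dx)
    e_nol <- ellipsoid_mask(shape, nol_c, nol_s, dz, dy, dx)
    e_shell <- ellipsoid_mask(shape, nol_c, shell_s, dz, dy, dx)
    acc_chrom <- acc_chrom + (e_nuc & !e_shell)
    acc_nol <- acc_nol + (e_nol & e_nuc)
  }
  list(chrom = acc_chrom / ss^3, nol = acc_nol / ss^3)
}

#' Generate a two-channel 3D scene with ground-truth masks
#'
#' Renders one fission-yeast nucleus: an ellipsoidal chromatin body
#' (GapR-GFP, a DNA-bound marker) with a nucleolus embedded at its
#' periphery.  Because the marker binds DNA, the nucleolar interior is
#' GFP-poor (background level) except for the rDNA itself, which is
#' rendered as foci grown from the nucleolar--chromatin contact point
#' where the rDNA arrays anchor to the rest of chromosome 3.  A thin
#' chromatin-depleted shell separates bulk chromatin from the nucleolar
#' compartment, as around real nucleoli.  The mCherry channel carries
#' the nucleolar compartment.  Optional linear background shading and
#' Gaussian (plus optional Poisson) noise model acquisition artifacts.
#'
#' The target `rdna_fraction` is the rDNA volume divided by the total
#' GFP-mask (DNA-occupied nuclear) volume, matching the measured rDNA
#' volume ratio.  If the default nucleolus cannot accommodate the
#' requested fraction, it is progressively shifted inward and enlarged
#' (rDNA-rich nucleoli extend further into the nucleus).
#'
#' @param shape volume dimensions `(z, y, x)` in voxels.
#' @param nucleus_center,nucleus_semi ellipsoid center and semi-axes
#'   `(z, y, x)`; defaults place a nucleus of ~2.6 um diameter at the
#'   volume center.
#' @param nucleolus_semi nucleolus semi-axes before feasibility
#'   adaptation.
#' @param rdna_fraction target rDNA / nuclear volume fraction, in (0, 1).
#' @param foci_count number of rDNA foci (the first grows from the
#'   chromatin contact point, others from random nucleolar seeds).
#' @param gfp_levels named vector `(background, nucleoplasm, rdna_foci)`
#'   in AU; must satisfy foci > nucleoplasm > background.
#' @param mcherry_levels named vector `(background, nucleolus)` in AU.
#' @param noise_sd additive Gaussian noise, AU.  The default gives a
#'   signal-to-noise ratio of 5 for the chromatin signal.
#' @param poisson add Poisson shot noise before the Gaussian term.
#' @param background_plane `(gx, gy)` AU/pixel gradient added to every
#'   slice of both channels.
#' @param shell_width width in xy pixels of the chromatin-depleted
#'   perinucleolar shell.
#' @param supersample linear sub-voxel sampling factor for rendering the
#'   analytic surfaces (1 = binary voxelization).
#' @param pixel_size_xy,z_step voxel geometry, micrometres.
#' @param seed RNG seed; identical parameters and seed give
#'   bit-identical output.
#' @return list with `stack` (an [image_stack()]), `truth` (a
#'   `segmentation_masks` ground truth), and `params` (including the
#'   achieved rDNA fraction).
#' @export
sim_scene <- function(shape = c(25, 64, 64),
                      nucleus_center = NULL,
                      nucleus_semi = c(8, 12, 12),
                      nucleolus_semi = c(6.2, 9.3, 9.3),
                      rdna_fraction = 0.15,
                      foci_count = 1,
                      gfp_levels = c(background = 10, nucleoplasm = 100,
                                     rdna_foci = 115),
                      mcherry_levels = c(background = 10, nucleolus = 150),
                      noise_sd = 18,
                      poisson = FALSE,
                      background_plane = c(0, 0),
                      shell_width = 2.5,
                      supersample = 1,
                      pixel_size_xy = 0.11,
                      z_step = 0.3,
                      seed = 1) {
  if (rdna_fraction <= 0 || rdna_fraction >= 1) {
    abort("`rdna_fraction` must lie in (0, 1).")
  }
  if (!(gfp_levels[["rdna_foci"]] > gfp_levels[["nucleoplasm"]] &&
        gfp_levels[["nucleoplasm"]] > gfp_levels[["background"]])) {
    abort("gfp levels must satisfy rdna_foci > nucleoplasm > background.")
  }
  if (mcherry_levels[["nucleolus"]] <= mcherry_levels[["background"]]) {
    abort("mcherry nucleolus level must exceed background.")
  }
  nucleus_center <- nucleus_center %||% ceiling(shape / 2)
  zw <- z_step / pixel_size_xy

  withr::with_seed(seed, {
    # nucleolus sits at the nuclear periphery, centred on the nuclear
    # surface along +x; adapt inward/larger until the rDNA target fits
    off <- nucleus_semi[3]
    semi <- nucleolus_semi
    for (it in 1:12) {
      nol_center <- nucleus_center + c(0, 0, off)
      cov <- compartment_coverage(
        shape, nucleus_center, nucleus_semi, nol_center, semi,
        semi + c(shell_width / zw, shell_width, shell_width),
        ss = supersample)
      nol <- cov$nol >= 0.5
      chrom <- cov$chrom >= 0.5
      n_chrom <- sum(chrom)
      r_target <- round(rdna_fraction * n_chrom / (1 - rdna_fraction))
      if (r_target <= 0.9 * sum(nol)) break
      off <- off - 1
      semi <- semi * c(1.03, 1.04, 1.04)
    }
    if (r_target > sum(nol) || r_target < 1 ||
        sum(nol) > n_chrom + r_target) {
      abort("scene geometry cannot accommodate the requested rdna_fraction: the nucleolar compartment would exceed the DNA-occupied nuclear volume.")
    }

    # grow rDNA foci inside the nucleolus, first focus anchored at the
    # chromatin contact point (closest nucleolar voxel to nuclear centre)
    idx <- which(nol, arr.ind = TRUE)
    d_ctr <- sqrt(((idx[, 1] - nucleus_center[1]) * zw)^2 +
                  (idx[, 2] - nucleus_center[2])^2 +
                  (idx[, 3] - nucleus_center[3])^2)
    seeds <- idx[which.min(d_ctr), , drop = FALSE]
    if (foci_count > 1) {
      extra <- idx[sample.int(nrow(idx), foci_count - 1), , drop = FALSE]
      seeds <- rbind(seeds, extra)
    }
    d_min <- rep(Inf, nrow(idx))
    for (s in seq_len(nrow(seeds))) {
      ds <- sqrt(((idx[, 1] - seeds[s, 1]) * zw)^2 +
                 (idx[, 2] - seeds[s, 2])^2 +
                 (idx[, 3] - seeds[s, 3])^2)
      d_min <- pmin(d_min, ds)
    }
    rdna <- array(FALSE, shape)
    rdna[idx[order(d_min)[seq_len(r_target)], , drop = FALSE]] <- TRUE

    plane <- outer(rep(1, shape[2]), seq_len(shape[3])) * background_plane[1] +
      outer(seq_len(shape[2]), rep(1, shape[3])) * background_plane[2]

    render <- function(levels_arr) {
      vol <- levels_arr
      for (i in seq_len(shape[1])) vol[i, , ] <- vol[i, , ] + plane
      if (poisson) vol <- array(rpois(length(vol), pmax(vol, 0)), shape)
      if (noise_sd > 0) vol <- vol + rnorm(length(vol), 0, noise_sd)
      pmax(vol, 0)
    }
    gfp <- gfp_levels[["background"]] +
      (gfp_levels[["nucleoplasm"]] - gfp_levels[["background"]]) * cov$chrom
    gfp[rdna] <- gfp_levels[["rdna_foci"]]
    mch <- mcherry_levels[["background"]] +
      (mcherry_levels[["nucleolus"]] - mcherry_levels[["background"]]) * cov$nol
    gfp <- render(gfp)
    mch <- render(mch)

    voxels <- array(0, c(2, shape))
    voxels[1, , , ] <- gfp
    voxels[2, , , ] <- mch
    stack <- image_stack(voxels,
                         c(nuclear_gfp = 1, nucleolar_mcherry = 2),
                         pixel_size_xy = pixel_size_xy, z_step = z_step)
    truth <- structure(
      list(nucleus = chrom | rdna,
           nucleolus = nol,
           rdna = rdna,
           bulk_chromatin = chrom),
      class = "segmentation_masks")
    achieved <- sum(rdna) / (sum(chrom) + sum(rdna))
    list(stack = stack, truth = truth,
         params = list(shape = shape, nucleus_center = nucleus_center,
                       nucleus_semi = nucleus_semi, nucleolus_semi = semi,
                       nucleolus_center = nol_center,
                       rdna_fraction = rdna_fraction,
                       achieved_fraction = achieved,
                       gfp_levels = gfp_levels,
                       mcherry_levels = mcherry_levels,
                       noise_sd = noise_sd, seed = seed))
  })
}

#' Generate a staged cell population with rendered scenes
#'
#' Draws a population of cells across the G2 interval: each cell gets a
#' stage (early/mid/late G2 with probabilities `stage_mix`), a cell
#' length from that stage's distribution, and a rendered two-channel
#' scene.  A configurable fraction of cells is binucleate (post-mitotic,
#' two nuclei rendered side by side) to exercise the multinucleate
#' filter.  Phenotype classes rescale the rDNA geometry and brightness:
#' `"condensed"` shrinks the rDNA volume fraction and brightens the foci
#' (the starvation direction); `"expanded"` inflates both (the TOR
#' activation direction).
#'
#' @param n number of cells.
#' @param phenotype `"wt"`, `"condensed"`, or `"expanded"`.
#' @param binucleate_fraction expected fraction of binucleate cells.
#' @param stage_mix probabilities for (early, mid, late) G2.
#' @param shape,nucleus_semi,nucleolus_semi scene geometry per cell
#'   (smaller defaults than [sim_scene()] keep populations light).
#' @param rdna_fraction wild-type rDNA volume fraction before phenotype
#'   scaling.
#' @param noise_sd additive Gaussian noise, AU.
#' @param volume_multiplier,intensity_multiplier override the phenotype
#'   class multipliers.
#' @param seed RNG seed.
#' @return list with `cells` (tibble: cell_id, cell_length,
#'   nucleus_count, phenotype, stage_true) and `scenes` / `truths`
#'   (lists keyed by cell_id).
#' @export
sim_population <- function(n, phenotype = c("wt", "condensed", "expanded"),
                           binucleate_fraction = 0,
                           stage_mix = c(1, 1, 1) / 3,
                           shape = c(17, 48, 48),
                           nucleus_semi = c(5, 8, 8),
                           nucleolus_semi = c(4, 5.5, 5.5),
                           rdna_fraction = 0.15,
                           noise_sd = 18,
                           volume_multiplier = NULL,
                           intensity_multiplier = NULL,
                           seed = 1) {
  stopifnot(n >= 1)
  phenotype <- match.arg(phenotype)
  mult <- switch(phenotype,
                 wt = c(vol = 1, int = 1),
                 condensed = c(vol = 0.6, int = 1.8),
                 expanded = c(vol = 1.5, int = 1.4))
  mult["vol"] <- volume_multiplier %||% mult[["vol"]]
  mult["int"] <- intensity_multiplier %||% mult[["int"]]
  gfp_levels <- c(background = 10, nucleoplasm = 100,
                  rdna_foci = 10 + mult[["int"]] * (115 - 10))
  frac <- rdna_fraction * mult[["vol"]]

  length_params <- list(early_G2 = c(8, 0.4), mid_G2 = c(10, 0.4),
                        late_G2 = c(12.5, 0.5))
  withr::with_seed(seed, {
    stages <- sample(names(length_params), n, replace = TRUE, prob = stage_mix)
    lengths <- vapply(stages, function(s) {
      p <- length_params[[s]]
      max(rnorm(1, p[1], p[2]), 4)
    }, numeric(1))
    binuc <- runif(n) < binucleate_fraction
    cell_seeds <- sample.int(1e6, n)
  })

  ids <- sprintf("cell_%03d", seq_len(n))
  scenes <- list(); truths <- list()
  for (i in seq_len(n)) {
    if (binuc[i]) {
      sc <- sim_binucleate_scene(shape, nucleus_semi, nucleolus_semi, frac,
                                 gfp_levels, noise_sd, cell_seeds[i])
    } else {
      sc <- sim_scene(shape = shape,
                      nucleus_semi = nucleus_semi,
                      nucleolus_semi = nucleolus_semi,
                      rdna_fraction = frac,
                      gfp_levels = gfp_levels,
                      noise_sd = noise_sd,
                      seed = cell_seeds[i])
    }
    scenes[[ids[i]]] <- sc$stack
    truths[[ids[i]]] <- sc$truth
  }
  cells <- tibble(cell_id = ids,
                  cell_length = unname(lengths),
                  nucleus_count = ifelse(binuc, 2L, 1L),
                  phenotype = phenotype,
                  stage_true = unname(stages))
  list(cells = cells, scenes = scenes, truths = truths)
}

# two post-mitotic nuclei rendered side by side along y
sim_binucleate_scene <- function(shape, nucleus_semi, nucleolus_semi, frac,
                                 gfp_levels, noise_sd, seed) {
  semi <- nucleus_semi * c(1, 0.75, 0.75)
  off <- ceiling(shape[2] / 4)
  a <- sim_scene(shape = shape,
                 nucleus_center = c(ceiling(shape[1] / 2),
                                    ceiling(shape[2] / 2) - off,
                                    ceiling(shape[3] / 2)),
                 nucleus_semi = semi,
                 nucleolus_semi = nucleolus_semi * 0.75,
                 rdna_fraction = frac, gfp_levels = gfp_levels,
                 noise_sd = 0, seed = seed)
  b <- sim_scene(shape = shape,
                 nucleus_center = c(ceiling(shape[1] / 2),
                                    ceiling(shape[2] / 2) + off,
                                    ceiling(shape[3] / 2)),
                 nucleus_semi = semi,
                 nucleolus_semi = nucleolus_semi * 0.75,
                 rdna_fraction = frac, gfp_levels = gfp_levels,
                 noise_sd = 0, seed = seed + 1)
  vox <- pmax(a$stack$voxels, b$stack$voxels)
  vox <- withr::with_seed(seed, pmax(vox + rnorm(length(vox), 0, noise_sd), 0))
  stack <- image_stack(vox, a$stack$channels,
                       a$stack$pixel_size_xy, a$stack$z_step)
  truth <- structure(
    list(nucleus = a$truth$nucleus | b$truth$nucleus,
         nucleolus = a$truth$nucleolus | b$truth$nucleolus,
         rdna = a$truth$rdna | b$truth$rdna,
         bulk_chromatin = a$truth$bulk_chromatin | b$truth$bulk_chromatin),
    class = "segmentation_masks")
  list(stack = stack, truth = truth)
}

#' Generate a screen cell-record table with planted hits
#'
#' Emulates the strain-level structure of an arrayed imaging screen:
#' strains in mated duplicate across plates, wild-type control wells on
#' every plate, per-cell ratio readouts, and the artifacts the screen
#' filters are designed to catch (low-intensity/extreme-volume records
#' from empty wells, and a well with too few cells).  Wild-type control
#' wells carry a per-plate batch offset, emulating the between-batch
#' variation that the repeated controls sample across the screening
#' campaign; the planted high/low strains are shifted on both metrics by
#' `effect_iqr_multiple` times the interquartile range of the wild-type
#' plate medians realized in the table.
#'
#' @param n_strains number of mutant strains.
#' @param n_high,n_low number of planted high / low strains.
#' @param effect_iqr_multiple planted shift in units of the wild-type
#'   plate-median IQR.
#' @param cells_per_well valid cell records per well.
#' @param n_plates number of plates (wild-type controls on each).
#' @param wt_wells_per_plate wild-type control wells per plate.
#' @param artifacts_per_well filter-violating records added per well.
#' @param short_well plant one well with 29 cells (below the 30-cell
#'   minimum) for the last null strain.
#' @param base_volume,sd_volume,base_intensity,sd_intensity per-cell
#'   ratio distributions.
#' @param wt_plate_jitter named vector: SD of the per-plate batch offset
#'   applied to wild-type control wells, per metric.
#' @param seed RNG seed.
#' @return list with `cells`, `platemap`, `truth` (strain, truth in
#'   high/low/null, short_well flag), and `wt_iqr` (realized IQR of the
#'   wild-type plate medians per metric).
#' @export
sim_screen_tables <- function(n_strains = 96, n_high = 10, n_low = 10,
                              effect_iqr_multiple = 3,
                              cells_per_well = 40, n_plates = 8,
                              wt_wells_per_plate = 4,
                              artifacts_per_well = 3,
                              short_well = TRUE,
                              base_volume = 0.15, sd_volume = 0.03,
                              base_intensity = 2.0, sd_intensity = 0.3,
                              wt_plate_jitter = c(volume = 0.03,
                                                  intensity = 0.25),
                              seed = 1) {
  stopifnot(n_high + n_low <= n_strains)
  strains <- sprintf("S%03d", seq_len(n_strains))
  truth_lab <- c(rep("high", n_high), rep("low", n_low),
                 rep("null", n_strains - n_high - n_low))
  short_strain <- if (short_well) strains[n_strains] else NA_character_

  withr::with_seed(seed, {
    draw_valid <- function(k, dv, di) {
      tibble(
        nuclear_mean_gfp = pmax(rnorm(k, 1500, 200), 800),
        nuclear_gfp_volume = pmin(pmax(round(rnorm(k, 100, 25)), 15), 195),
        rdna_volume_ratio = pmax(rnorm(k, base_volume + dv, sd_volume), 0.001),
        rdna_intensity_ratio = pmax(rnorm(k, base_intensity + di, sd_intensity), 0.01),
        mcherry_volume_ratio = pmax(rnorm(k, 0.30, 0.05), 0.01)
      )
    }
    draw_artifacts <- function(k) {
      tibble(
        nuclear_mean_gfp = pmin(pmax(rnorm(k, 400, 80), 50), 740),
        nuclear_gfp_volume = ifelse(runif(k) < 0.5,
                                    round(runif(k, 220, 400)),
                                    round(runif(k, 1, 8))),
        rdna_volume_ratio = runif(k, 0, 1),
        rdna_intensity_ratio = runif(k, 0, 4),
        mcherry_volume_ratio = runif(k, 0, 1)
      )
    }

    # wild-type control wells with per-plate batch offsets, centred so
    # the campaign-wide control mean stays on the population reference
    d_vol <- rnorm(n_plates, 0, wt_plate_jitter[["volume"]])
    d_int <- rnorm(n_plates, 0, wt_plate_jitter[["intensity"]])
    d_vol <- d_vol - mean(d_vol)
    d_int <- d_int - mean(d_int)
    wt_rows <- list()
    for (p in seq_len(n_plates)) {
      for (w in seq_len(wt_wells_per_plate)) {
        well <- sprintf("wt_p%d_%d", p, w)
        vals <- dplyr::bind_rows(draw_valid(cells_per_well, d_vol[p], d_int[p]),
                                 draw_artifacts(artifacts_per_well))
        vals$plate <- p; vals$well <- well
        vals$strain <- "WT"; vals$replicate <- ((w - 1L) %% 2L) + 1L
        wt_rows[[well]] <- vals
      }
    }
    wt_cells <- dplyr::bind_rows(wt_rows)

    # realized wild-type plate medians and their IQR (valid records only)
    wt_valid <- dplyr::filter(wt_cells,
                              .data$nuclear_mean_gfp > 750,
                              .data$nuclear_gfp_volume >= 10,
                              .data$nuclear_gfp_volume <= 200)
    wt_med <- wt_valid |>
      dplyr::group_by(.data$plate) |>
      dplyr::summarise(v = median(.data$rdna_volume_ratio),
                       i = median(.data$rdna_intensity_ratio),
                       .groups = "drop")
    iqr7 <- function(x) diff(quantile(x, c(0.25, 0.75), names = FALSE, type = 7))
    wt_iqr <- c(volume = iqr7(wt_med$v), intensity = iqr7(wt_med$i))

    shift <- function(lab) switch(lab,
      high = c(effect_iqr_multiple * wt_iqr[["volume"]],
               effect_iqr_multiple * wt_iqr[["intensity"]]),
      low = c(-effect_iqr_multiple * wt_iqr[["volume"]],
              -effect_iqr_multiple * wt_iqr[["intensity"]]),
      null = c(0, 0))

    mut_rows <- list(); mut_map <- list()
    for (s in seq_len(n_strains)) {
      p <- ((s - 1L) %% n_plates) + 1L
      sh <- shift(truth_lab[s])
      for (rep_i in 1:2) {
        well <- sprintf("m%03d_r%d", s, rep_i)
        k <- cells_per_well
        if (identical(strains[s], short_strain) && rep_i == 1L) k <- 29L
        vals <- dplyr::bind_rows(draw_valid(k, sh[1], sh[2]),
                                 draw_artifacts(artifacts_per_well))
        vals$plate <- p; vals$well <- well
        vals$strain <- strains[s]; vals$replicate <- rep_i
        mut_rows[[well]] <- vals
        mut_map[[well]] <- tibble(plate = p, well = well,
                                  strain = strains[s], replicate = rep_i)
      }
    }
    wt_map_tbl <- wt_cells |>
      dplyr::distinct(.data$plate, .data$well, .data$strain, .data$replicate)
    cells <- dplyr::bind_rows(wt_cells, dplyr::bind_rows(mut_rows)) |>
      dplyr::select("plate", "well", "strain", "replicate",
                    dplyr::everything())
    platemap <- dplyr::bind_rows(wt_map_tbl, dplyr::bind_rows(mut_map))
    truth <- tibble(strain = strains, truth = truth_lab,
                    short_well = strains == short_strain &
                      !is.na(short_strain))
    list(cells = as_tibble(cells), platemap = platemap, truth = truth,
         wt_iqr = wt_iqr)
  })
}

#' Generate an SGA truth map over a query panel
#'
#' Builds a (query, gene) truth table for [sim_sga_plates()]: baseline
#' genes leave the panel phenotypes unchanged (RPL queries resistant,
#' control queries sensitive); genes essential for resistance sensitize
#' all five RPL queries; repressor genes confer resistance on all three
#' control queries.  A fraction of baseline pairs can be left unmeasured
#' to emulate failed matings.
#'
#' @param n_genes total candidate genes.
#' @param n_essential,n_repressor planted gene classes.
#' @param resistant_queries,control_queries query panel ids.
#' @param unmeasured_rate fraction of baseline-gene pairs left
#'   unmeasured.
#' @param seed RNG seed.
#' @return list with `truth` (query_strain, candidate_gene, truth) and
#'   `genes` (candidate_gene, class).
#' @export
sim_sga_truth <- function(n_genes = 40, n_essential = 5, n_repressor = 4,
                          resistant_queries = paste0("RPL", 1:5),
                          control_queries = paste0("CTL", 1:3),
                          unmeasured_rate = 0.02, seed = 1) {
  stopifnot(n_essential + n_repressor <= n_genes)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  cls <- c(rep("essential", n_essential), rep("repressor", n_repressor),
           rep("baseline", n_genes - n_essential - n_repressor))
  withr::with_seed(seed, {
    rows <- purrr::map2(genes, cls, function(g, cl) {
      rpl <- if (cl == "essential") "sensitive" else "resistant"
      ctl <- if (cl == "repressor") "resistant" else "sensitive"
      tb <- tibble(
        query_strain = c(resistant_queries, control_queries),
        candidate_gene = g,
        truth = c(rep(rpl, length(resistant_queries)),
                  rep(ctl, length(control_queries))))
      if (cl == "baseline") {
        drop <- runif(nrow(tb)) < unmeasured_rate
        tb$truth[drop] <- "unmeasured"
      }
      tb
    })
    list(truth = dplyr::bind_rows(rows),
         genes = tibble(candidate_gene = genes, class = cls))
  })
}

#' Generate SGA colony-density plates realizing a truth map
#'
#' Renders a DMSO and a Torin1 plate consistent with a (query, gene)
#' truth map.  Sensitive pairs grow normally on DMSO but get a Torin1
#' density of 1 (no growth); resistant pairs retain at least half their
#' DMSO density on Torin1; unmeasured pairs are `NA` in both conditions.
#' DMSO densities for sensitive pairs are drawn from the upper part of
#' the colony-size distribution so that the rank-based no-growth floor
#' (which exists to clean empty positions) lands only on colonies whose
#' fold change it cannot misrepresent.  A warning is issued if the
#' planted no-growth set is smaller than the rank floor would require.
#'
#' @param truth tibble (query_strain, candidate_gene, truth) with truth
#'   in sensitive/resistant/unmeasured.
#' @param dmso_mean centre of the DMSO colony-density distribution.
#' @param day imaging day recorded in the table.
#' @param seed RNG seed.
#' @return long tibble (plate, condition, query_strain, candidate_gene,
#'   density, day) ready for [sga_score()].
#' @export
sim_sga_plates <- function(truth, dmso_mean = 2000, day = 5, seed = 1) {
  stopifnot(all(c("query_strain", "candidate_gene", "truth") %in% names(truth)))
  sc <- dmso_mean / 2000
  withr::with_seed(seed, {
    n <- nrow(truth)
    dmso <- dplyr::case_when(
      truth$truth == "sensitive" ~ runif(n, 2000, 2300) * sc,
      truth$truth == "resistant" ~ runif(n, 1600, 2000) * sc,
      TRUE ~ NA_real_)
    torin <- dplyr::case_when(
      truth$truth == "sensitive" ~ 1,
      truth$truth == "resistant" ~ runif(n, 0.55, 0.95) * dmso,
      TRUE ~ NA_real_)
    n_pos <- sum(!is.na(torin) & torin > 0)
    n_floor <- floor(0.05 * n_pos)
    if (sum(truth$truth == "sensitive") < n_floor) {
      warn("fewer planted no-growth pairs than the rank floor will convert; some resistant pairs may be floored.")
    }
    dplyr::bind_rows(
      dplyr::mutate(truth[c("query_strain", "candidate_gene")],
                    plate = "P1", condition = "DMSO", density = dmso,
                    day = day),
      dplyr::mutate(truth[c("query_strain", "candidate_gene")],
                    plate = "P1", condition = "Torin1", density = torin,
                    day = day))
  })
}

#' Generate FRAP traces with known recovery parameters
#'
#' Pre-bleach plateau, instantaneous bleach at `bleach_frame` to
#' `bleach_level`, then exponential recovery with time constant `tau_s`
#' toward `mobile_fraction` of the bleached depth.  Measured series are
#' scaled by a per-cell detector gain, attenuated by slow acquisition
#' photobleaching shared with the reference compartment, offset by a
#' camera background, and corrupted by Gaussian noise, so that the
#' normalization in [normalize_trace()] must undo all three.
#'
#' @param n number of cells (traces).
#' @param mobile_fraction recovering fraction of the bleached depth, in
#'   `[0, 1]`.
#' @param tau_s recovery time constant, seconds.
#' @param bleach_level ROI level immediately after the bleach, as a
#'   fraction of pre-bleach (0 = complete bleach).
#' @param noise_sd Gaussian noise as a fraction of the pre-bleach signal.
#' @param n_frames,dt frames and frame interval (seconds).
#' @param bleach_frame index of the first post-bleach frame.
#' @param gain,background detector gain (AU) and camera offset (AU).
#' @param acq_tau time constant of acquisition photobleaching, seconds.
#' @param seed RNG seed.
#' @return list of trace tibbles (time_s, roi, reference, background),
#'   with attributes `bleach_frame` and `true_plateau`.
#' @export
sim_frap_traces <- function(n = 7, mobile_fraction = 0.5, tau_s = 20,
                            bleach_level = 0, noise_sd = 0.02,
                            n_frames = 100, dt = 3, bleach_frame = 11,
                            gain = 800, background = 100, acq_tau = 2000,
                            seed = 1) {
  stopifnot(mobile_fraction >= 0, mobile_fraction <= 1, tau_s > 0,
            bleach_frame >= 2, bleach_frame <= n_frames)
  times <- (seq_len(n_frames) - 1) * dt
  t_bleach <- times[bleach_frame]
  ideal <- ifelse(
    seq_len(n_frames) < bleach_frame, 1,
    bleach_level + mobile_fraction * (1 - bleach_level) *
      (1 - exp(-(times - t_bleach) / tau_s)))
  withr::with_seed(seed, {
    traces <- purrr::map(seq_len(n), function(i) {
      g <- gain * runif(1, 0.8, 1.2)
      acq <- exp(-times / acq_tau)
      tibble(
        time_s = times,
        roi = ideal * acq * g + background + rnorm(n_frames, 0, noise_sd * g),
        reference = acq * g + background +
          rnorm(n_frames, 0, noise_sd * g / 3),
        background = background + rnorm(n_frames, 0, noise_sd * g / 10)
      )
    })
    attr(traces, "bleach_frame") <- bleach_frame
    attr(traces, "true_plateau") <-
      bleach_level + mobile_fraction * (1 - bleach_level)
    traces
  })
}
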