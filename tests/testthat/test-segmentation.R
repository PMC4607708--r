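test_that("estimate_rpe_row finds the hyper-reflective row with smaller-row ties", {
  img <- matrix(0.1, 60, 20)
  img[35, ] <- 1
  expect_equal(estimate_rpe_row(img), 35L)

  img2 <- matrix(0.1, 60, 20)
  img2[20, ] <- 1; img2[45, ] <- 1
  expect_equal(estimate_rpe_row(img2), 20L)

  ph <- generate_phantom(small_spec(speckle = FALSE), seed = 1)
  r <- estimate_rpe_row(normalize_intensity(ph$scan))
  expect_gt(r, min(ph$truth$isos))
  expect_lt(r, max(ph$truth$rpe_outer) + 1)
})

test_that("RPE centerline locks onto the bright band", {
  ph <- generate_phantom(small_spec(speckle = FALSE), seed = 2)
  norm <- normalize_intensity(ph$scan)
  r0 <- estimate_rpe_row(norm)
  p <- segment_rpe_center(norm, r0)
  expect_lte(max(abs(p$rows - ph$truth$rpe_center)), 1.01)

  # degenerate band: halfwidth 0 pins the path to the initial row
  p0 <- segment_rpe_center(norm, r0, band_halfwidth = 0L)
  expect_true(all(p0$rows == r0))

  phs <- generate_phantom(small_spec(), seed = 3)
  norms <- normalize_intensity(phs$scan)
  ps <- segment_rpe_center(norms, estimate_rpe_row(norms))
  expect_lte(mean(abs(ps$rows - phs$truth$rpe_center)), 2)
})

test_that("IS/OS segmentation hits the band top and flags missing bands", {
  ph <- generate_phantom(small_spec(speckle = FALSE), seed = 4)
  norm <- normalize_intensity(ph$scan)
  rpe <- segment_rpe_center(norm, estimate_rpe_row(norm))
  isos <- segment_isos(norm, rpe)
  expect_lte(mean(abs(isos$rows - ph$truth$isos)), 1)
  expect_false(isos$low_confidence)

  # anchors on the true boundary are honoured exactly
  cols <- c(40L, 100L, 160L)
  a <- data.frame(column = cols, row = round(ph$truth$isos[cols]))
  isos_a <- segment_isos(norm, rpe, anchors = a)
  expect_equal(isos_a$rows[cols], a$row)

  # phantom whose outer nuclear layer runs straight into the gap (no IS/OS
  # band, no reflectance step at its position): path returned but flagged
  lv <- c(vitreous = 0.05, inner = 0.35, onl = 0.15, isos = 0.15,
          gap = 0.15, rpe = 0.85, rpe_core = 0.95, choroid = 0.25)
  ph2 <- generate_phantom(small_spec(speckle = FALSE, levels = lv), seed = 4)
  norm2 <- normalize_intensity(ph2$scan)
  rpe2 <- segment_rpe_center(norm2, estimate_rpe_row(norm2))
  expect_warning(isos2 <- segment_isos(norm2, rpe2, offset_min_um = 25),
                 "low confidence")
  expect_true(isos2$low_confidence)
  expect_length(isos2$rows, 200L)
})

test_that("RPE outer border recovery and band clipping guard", {
  ph <- generate_phantom(small_spec(speckle = FALSE), seed = 5)
  norm <- normalize_intensity(ph$scan)
  rpe <- segment_rpe_center(norm, estimate_rpe_row(norm))
  outer <- segment_rpe_outer(norm, rpe)
  expect_lte(mean(abs(outer$rows - ph$truth$rpe_outer)), 1)

  # band pushed entirely below the image
  fake <- rpe; fake$rows <- rep(199L, 200L)
  expect_error(segment_rpe_outer(norm, fake, offset_min_um = 50,
                                 offset_max_um = 120),
               "outside")
})

test_that("frame averaging does not degrade outer-border recovery", {
  err1 <- errN <- numeric(8)
  for (i in 1:8) {
    ph1 <- generate_phantom(small_spec(n_frames = 1L), seed = 100 + i)
    phN <- generate_phantom(small_spec(n_frames = 10L), seed = 100 + i)
    e <- function(ph) {
      norm <- normalize_intensity(ph$scan)
      rpe <- segment_rpe_center(norm, estimate_rpe_row(norm))
      mean(abs(segment_rpe_outer(norm, rpe)$rows - ph$truth$rpe_outer))
    }
    err1[i] <- e(ph1); errN[i] <- e(phN)
  }
  expect_lte(mean(errN), mean(err1) + 1e-9)
})

test_that("ILM recovery survives the pit and a detached hyaloid", {
  ph <- generate_phantom(small_spec(speckle = FALSE), seed = 6)
  norm <- normalize_intensity(ph$scan)
  rpe <- segment_rpe_center(norm, estimate_rpe_row(norm))
  isos <- segment_isos(norm, rpe)
  ilm <- segment_ilm(norm, isos)
  expect_lte(mean(abs(ilm$rows - ph$truth$ilm)), 1)
  # pit columns specifically
  pit <- (ph$truth$fovea_col - 10):(ph$truth$fovea_col + 10)
  expect_lte(mean(abs(ilm$rows[pit] - ph$truth$ilm[pit])), 1)

  ph_h <- generate_phantom(small_spec(speckle = FALSE, hyaloid = TRUE,
                                      hyaloid_contrast = 0.25), seed = 6)
  norm_h <- normalize_intensity(ph_h$scan)
  rpe_h <- segment_rpe_center(norm_h, estimate_rpe_row(norm_h))
  isos_h <- segment_isos(norm_h, rpe_h)
  ilm_h <- segment_ilm(norm_h, isos_h)
  expect_lte(mean(abs(ilm_h$rows - ph_h$truth$ilm)), 2)

  # anchors on the true ILM are exact at those columns
  cols <- c(30L, 170L)
  a <- data.frame(column = cols, row = round(ph$truth$ilm[cols]))
  ilm_a <- segment_ilm(norm, isos, anchors = a)
  expect_equal(ilm_a$rows[cols], a$row)
})

test_that("segment_all recovers all four boundaries and is deterministic", {
  ph <- generate_phantom(small_spec(), seed = 7)
  seg1 <- segment_all(ph$scan)
  seg2 <- segment_all(ph$scan)
  expect_identical(as.data.frame(seg1), as.data.frame(seg2))

  tr <- ph$truth
  expect_lte(mae_path(seg1$ilm, tr$ilm), 2)
  expect_lte(mae_path(seg1$isos, tr$isos), 2)
  expect_lte(mae_path(seg1$rpe_center, tr$rpe_center), 2)
  expect_lte(mae_path(seg1$rpe_outer, tr$rpe_outer), 2)
})

test_that("ordering and continuity invariants hold on random phantoms", {
  set.seed(8)
  for (i in 1:12) {
    ph <- generate_phantom(
      small_spec(pit_depth_um = runif(1, 60, 110),
                 isos_depth_um = runif(1, 280, 330),
                 speckle = i %% 2 == 0),
      seed = 200 + i)
    seg <- suppressWarnings(segment_all(ph$scan))
    df <- as.data.frame(seg)
    inner <- 2:(nrow(df) - 1)
    expect_true(all(df$ilm[inner] < df$isos[inner]))
    expect_true(all(df$isos[inner] < df$rpe_center[inner]))
    expect_true(all(df$rpe_center[inner] < df$rpe_outer[inner]))
    for (p in list(seg$ilm, seg$isos, seg$rpe_center, seg$rpe_outer)) {
      expect_true(all(abs(diff(p$rows - seg$shifts$shifts)) <= 2))
    }
  }
})

test_that("segmentation is reported in original coordinates under jitter", {
  ph <- generate_phantom(small_spec(speckle = FALSE, jitter_max_px = 6),
                         seed = 9)
  seg <- segment_all(ph$scan, oct_seg_config(max_shift = 12))
  expect_lte(mae_path(seg$ilm, ph$truth$ilm), 1)
  expect_lte(mae_path(seg$rpe_outer, ph$truth$rpe_outer), 1)
})

test_that("a bright vitreous floater either fails loudly or is fixed by anchors", {
  ph <- generate_phantom(small_spec(speckle = FALSE, floater = TRUE),
                         seed = 10)
  res <- tryCatch(suppressWarnings(segment_all(ph$scan)),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_s3_class(res, "octseg_ordering_error")
  } else {
    # unaided ILM may be dragged to the floater; anchors must repair it
    cols <- as.integer(seq(10, 190, by = 30))
    a <- list(ilm = data.frame(column = cols,
                               row = round(ph$truth$ilm[cols])))
    seg_a <- suppressWarnings(segment_all(ph$scan, anchors = a))
    expect_lte(mae_path(seg_a$ilm, ph$truth$ilm), 2)
  }
})

test_that("segmentation JSON round trip preserves the result", {
  ph <- generate_phantom(small_spec(speckle = FALSE), seed = 11)
  seg <- segment_all(ph$scan)
  f <- tempfile(fileext = ".json")
  write_segmentation_json(seg, f)
  back <- read_segmentation_json(f)
  expect_equal(back$ilm$rows, seg$ilm$rows)
  expect_equal(back$rpe_outer$rows, seg$rpe_outer$rows)
  expect_equal(back$calibration$axial_scale_um,
               seg$calibration$axial_scale_um)
  expect_equal(back$config$max_jump, seg$config$max_jump)
  unlink(f)
})
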