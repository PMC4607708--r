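#' Phantom B-scan specification
#'
#' Parameters of the synthetic B-scan generator. The phantom emulates the
#' layered reflectivity of a macular line scan (dark vitreous, brighter
#' inner retina, dark outer nuclear layer, bright IS/OS band, dimmer gap,
#' bright RPE band with a brighter core, dimmer choroid), a Gaussian foveal
#' pit, an optionally detached posterior hyaloid, multiplicative speckle,
#' per-column axial jitter and frame averaging.
#'
#' Geometry follows common spectral-domain line-scan protocols; the default
#' is a 6-mm / 512 A-scan scan. Anatomy defaults put the central point
#' thickness near 226 um and the foveal outer-segment/RPE complex near
#' 76 um thinning to 62 um peripherally, i.e. healthy adult magnitudes.
#'
#' Axial depths are measured in micrometres from the image top. The inner
#' limiting membrane is `ilm_base_um + pit_depth_um * G(x)` where `G` is a
#' Gaussian bump of full width at half maximum `pit_width_mm` centred at
#' `pit_center_mm`; the IS/OS top is flat at `isos_depth_um`; the RPE outer
#' border is the IS/OS top plus the outer complex thickness, which
#' interpolates between `rpeos_fovea_um` and `rpeos_periph_um` with the
#' same Gaussian profile.
#'
#' @param rows,n_ascans Image size in pixels.
#' @param axial_scale_um Axial sampling (um per pixel row).
#' @param scan_length_mm Nominal lateral extent (mm).
#' @param ilm_base_um Peripheral ILM depth.
#' @param pit_depth_um,pit_width_mm,pit_center_mm Foveal pit shape
#'   (`pit_center_mm = NULL` centres the pit on the scan).
#' @param isos_depth_um Depth of the (flat) IS/OS top.
#' @param isos_band_um Thickness of the bright IS/OS band.
#' @param rpeos_fovea_um,rpeos_periph_um IS/OS-to-RPE-outer thickness at the
#'   fovea and periphery (the foveal complex is the thicker one).
#' @param rpe_band_um Thickness of the bright RPE band (its lower edge is
#'   the RPE outer border); a 6-um brighter core marks the band centre.
#' @param onl_um Thickness of the dark outer nuclear layer above the IS/OS.
#' @param levels Named intensities in `[0, 1]` for `vitreous`, `inner`,
#'   `onl`, `isos`, `gap`, `rpe`, `rpe_core`, `choroid`.
#' @param hyaloid Add a detached posterior hyaloid line in the vitreous?
#' @param hyaloid_contrast Hyaloid edge contrast relative to the ILM edge.
#' @param floater Add a bright vitreous floater (adversarial variant)?
#' @param speckle Multiplicative unit-mean exponential speckle?
#' @param n_frames Number of averaged speckle realizations (1 = single
#'   look; high-end line protocols average up to 100 raw B-scans).
#' @param jitter_max_px Per-column axial jitter bound (integer pixels).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(rows = 256L, n_ascans = 512L,
                         axial_scale_um = 3.87, scan_length_mm = 6,
                         ilm_base_um = 60, pit_depth_um = 94,
                         pit_width_mm = 1.8, pit_center_mm = NULL,
                         isos_depth_um = 304, isos_band_um = 15,
                         rpeos_fovea_um = 76, rpeos_periph_um = 62,
                         rpe_band_um = 20, onl_um = 70,
                         levels = c(vitreous = 0.05, inner = 0.35,
                                    onl = 0.15, isos = 0.8, gap = 0.3,
                                    rpe = 0.85, rpe_core = 0.95,
                                    choroid = 0.25),
                         hyaloid = FALSE, hyaloid_contrast = 0.2,
                         floater = FALSE,
                         speckle = TRUE, n_frames = 1L,
                         jitter_max_px = 0L) {
  if (is.null(pit_center_mm)) pit_center_mm <- scan_length_mm / 2
  spec <- list(rows = as.integer(rows), n_ascans = as.integer(n_ascans),
               axial_scale_um = axial_scale_um,
               scan_length_mm = scan_length_mm,
               ilm_base_um = ilm_base_um, pit_depth_um = pit_depth_um,
               pit_width_mm = pit_width_mm, pit_center_mm = pit_center_mm,
               isos_depth_um = isos_depth_um, isos_band_um = isos_band_um,
               rpeos_fovea_um = rpeos_fovea_um,
               rpeos_periph_um = rpeos_periph_um,
               rpe_band_um = rpe_band_um, onl_um = onl_um,
               levels = levels, hyaloid = isTRUE(hyaloid),
               hyaloid_contrast = hyaloid_contrast,
               floater = isTRUE(floater),
               speckle = isTRUE(speckle), n_frames = as.integer(n_frames),
               jitter_max_px = as.integer(jitter_max_px))
  required <- c("vitreous", "inner", "onl", "isos", "gap", "rpe",
                "rpe_core", "choroid")
  if (!all(required %in% names(levels)) ||
      any(levels < 0) || any(levels > 1)) {
    stop("`levels` must name all compartments with values in [0, 1]",
         call. = FALSE)
  }
  if (rpeos_fovea_um < rpeos_periph_um) {
    stop("the foveal outer complex must be at least as thick as the periphery",
         call. = FALSE)
  }
  if (ilm_base_um + pit_depth_um >= isos_depth_um - onl_um) {
    stop("phantom boundaries out of order: pit floor reaches the outer nuclear layer",
         call. = FALSE)
  }
  if (isos_band_um + rpe_band_um >= rpeos_periph_um) {
    stop("IS/OS and RPE bands thicker than the outer complex", call. = FALSE)
  }
  structure(spec, class = "phantom_spec")
}

phantom_boundaries_um <- function(spec) {
  lat_um <- spec$scan_length_mm * 1000 / spec$n_ascans
  x_mm <- ((seq_len(spec$n_ascans)) - 0.5) * lat_um / 1000
  sigma <- spec$pit_width_mm / 2.355  # FWHM -> sd
  g <- exp(-((x_mm - spec$pit_center_mm)^2) / (2 * sigma^2))
  ilm <- spec$ilm_base_um + spec$pit_depth_um * g
  isos <- rep(spec$isos_depth_um, spec$n_ascans)
  rpeos <- spec$rpeos_periph_um +
    (spec$rpeos_fovea_um - spec$rpeos_periph_um) * g
  rpe_outer <- isos + rpeos
  list(x_mm = x_mm, ilm = ilm, onl_top = isos - spec$onl_um,
       isos = isos, isos_bot = isos + spec$isos_band_um,
       rpe_top = rpe_outer - spec$rpe_band_um,
       rpe_outer = rpe_outer,
       rpe_center = rpe_outer - spec$rpe_band_um / 2)
}

# partial-volume rasterization of piecewise-constant columns
composite_phantom <- function(spec, b) {
  R <- spec$rows; C <- spec$n_ascans; h <- spec$axial_scale_um
  core_half <- 3  # um, bright RPE core half-thickness
  tops <- rbind(0, b$ilm, b$onl_top, b$isos, b$isos_bot, b$rpe_top,
                b$rpe_center - core_half, b$rpe_center + core_half,
                b$rpe_outer)
  bots <- rbind(tops[-1L, , drop = FALSE], R * h)
  lv <- spec$levels
  lev <- c(lv[["vitreous"]], lv[["inner"]], lv[["onl"]], lv[["isos"]],
           lv[["gap"]], lv[["rpe"]], lv[["rpe_core"]], lv[["rpe"]],
           lv[["choroid"]])
  z_lo <- matrix((seq_len(R) - 1) * h, R, C)
  z_hi <- z_lo + h
  img <- matrix(0, R, C)
  for (i in seq_along(lev)) {
    topM <- matrix(tops[i, ], R, C, byrow = TRUE)
    botM <- matrix(bots[i, ], R, C, byrow = TRUE)
    ov <- pmax(0, pmin(z_hi, botM) - pmax(z_lo, topM))
    img <- img + lev[i] * ov / h
  }
  if (spec$hyaloid) {
    # thin faint line floating in the vitreous above the ILM
    hy_top <- pmax(b$ilm - 30, 8)
    hy_bot <- hy_top + 8
    dlev <- spec$hyaloid_contrast * (lv[["inner"]] - lv[["vitreous"]])
    topM <- matrix(hy_top, R, C, byrow = TRUE)
    botM <- matrix(hy_bot, R, C, byrow = TRUE)
    img <- img + dlev * pmax(0, pmin(z_hi, botM) - pmax(z_lo, topM)) / h
  }
  if (spec$floater) {
    # bright elliptical blob in the vitreous near the scan centre
    cc <- C / 2; cr_um <- max(b$ilm[1L] - 35, 15)
    rr <- (z_lo + h / 2 - cr_um) / 15      # ~15 um axial semi-axis
    colM <- matrix(seq_len(C), R, C, byrow = TRUE)
    el <- rr^2 + ((colM - cc) / (0.05 * C))^2
    img[el <= 1] <- 0.9
  }
  img
}

jitter_image <- function(img, jitter) {
  R <- nrow(img)
  for (c in which(jitter != 0L)) {
    src <- pmin(pmax(seq_len(R) - jitter[c], 1L), R)  # edge replication
    img[, c] <- img[src, c]
  }
  img
}

#' Generate a synthetic B-scan with known ground truth
#'
#' Deterministic given `(spec, seed)`. Boundaries are rasterized with
#' partial-volume mixing; speckle is multiplicative unit-mean exponential
#' noise, averaged over `n_frames` independent realizations with the
#' boundaries fixed (emulating frame averaging); integer per-column jitter
#' is applied after compositing and is reflected in the returned truth.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for speckle and jitter.
#' @return An object of class `oct_phantom`: `scan` (an [oct_scan()]),
#'   `truth` (floating-point boundary rows in the jittered image, the fovea
#'   column and true thickness profiles in um) and the injected `jitter`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  b <- phantom_boundaries_um(spec)
  img <- composite_phantom(spec, b)
  R <- spec$rows; C <- spec$n_ascans; h <- spec$axial_scale_um

  if (spec$speckle) {
    acc <- matrix(0, R, C)
    for (f in seq_len(spec$n_frames)) {
      acc <- acc + img * matrix(stats::rexp(R * C), R, C)
    }
    img <- acc / spec$n_frames
  }
  jitter <- if (spec$jitter_max_px > 0) {
    sample(-spec$jitter_max_px:spec$jitter_max_px, C, replace = TRUE)
  } else integer(C)
  img <- jitter_image(img, jitter)

  cal <- oct_calibration(h, spec$scan_length_mm, C)
  scan <- oct_scan(img, cal, id = sprintf("phantom-seed%d", seed))

  retina_um <- b$rpe_outer - b$ilm
  truth <- list(
    ilm = b$ilm / h + jitter,
    isos = b$isos / h + jitter,
    rpe_center = b$rpe_center / h + 0.5 + jitter,
    rpe_outer = b$rpe_outer / h + jitter,
    fovea_col = which.min(retina_um),
    retina_um = retina_um,
    rpeos_um = b$rpe_outer - b$isos)
  structure(list(scan = scan, truth = truth, jitter = jitter, spec = spec,
                 seed = seed),
            class = "oct_phantom")
}

#' @export
print.oct_phantom <- function(x, ...) {
  cat(sprintf("OCT phantom (seed %d): %d x %d, speckle %s, %d frame(s), jitter <= %d px\n",
              x$seed, x$spec$rows, x$spec$n_ascans,
              if (x$spec$speckle) "on" else "off", x$spec$n_frames,
              x$spec$jitter_max_px))
  cat(sprintf("  true CPT %.1f um, foveal outer complex %.1f um\n",
              min(x$truth$retina_um), max(x$truth$rpeos_um)))
  invisible(x)
}

#' Device geometry templates
#'
#' Two common line-scan geometries: `"A"` is 512 A-scans over 6 mm without
#' frame averaging; `"B"` is 768 A-scans over 8.7 mm with 100-frame
#' averaging.
#'
#' @param device `"A"` or `"B"`.
#' @param ... Overrides passed on to [phantom_spec()].
#' @return A [phantom_spec()].
#' @export
device_template <- function(device = c("A", "B"), ...) {
  device <- match.arg(device)
  args <- list(...)
  base <- if (device == "A") {
    list(n_ascans = 512L, scan_length_mm = 6, n_frames = 1L)
  } else {
    list(n_ascans = 768L, scan_length_mm = 8.7, n_frames = 100L)
  }
  do.call(phantom_spec, utils::modifyList(base, args))
}

#' Generate a paired synthetic cohort
#'
#' For each eye one latent anatomy is drawn (between-eye variation on the
#' overall retinal depth, pit depth and outer complex thickness) and
#' rendered under both device templates. In `"two_device"` mode, device B's
#' RPE outer border is pushed deeper by `bias_um`: the injected bias stands
#' in for the apparent thickening that frame averaging can produce at a
#' weak posterior edge, so both the retinal and the outer-complex thickness
#' carry it. Because `bias_um` already represents the averaging effect, the
#' default templates apply the same single-look speckle treatment to both
#' devices (geometries still differ); rendering device B with its full
#' 100-frame averaging on top of an injected bias would count the same
#' effect twice. Pass `device_template("B")` unchanged to simulate the
#' physical averaging difference itself. In `"repeat_visit"` mode the same
#' template is rendered twice with independent speckle and a small
#' within-eye anatomical perturbation.
#'
#' @param n_eyes Number of eyes (>= 2).
#' @param spec_a,spec_b Device templates (see [device_template()]).
#' @param bias_um Outer-boundary bias added to device B (um).
#' @param between_eye_sd_um SD of the between-eye retinal depth variation.
#' @param pit_sd_um,rpeos_sd_um Between-eye SDs of pit depth and outer
#'   complex thickness.
#' @param within_eye_sd_um Repeat-visit anatomical perturbation SD.
#' @param mode `"two_device"` or `"repeat_visit"`.
#' @param seed Integer seed.
#' @return List of class `oct_cohort`: per-eye phantom pairs and a tidy
#'   truth table (`eye_id, device, layer_pair, offset_mm = NA, value`
#'   columns hold per-eye true foveal/peripheral parameters).
#' @export
generate_cohort <- function(n_eyes = 37L,
                            spec_a = device_template("A"),
                            spec_b = device_template("B", n_frames = 1L),
                            bias_um = 0, between_eye_sd_um = 17,
                            pit_sd_um = 8, rpeos_sd_um = 4,
                            within_eye_sd_um = 2.3,
                            mode = c("two_device", "repeat_visit"),
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_eyes >= 2L)
  set.seed(seed)
  eyes <- vector("list", n_eyes)
  for (i in seq_len(n_eyes)) {
    d_depth <- stats::rnorm(1L, 0, between_eye_sd_um)
    d_pit <- stats::rnorm(1L, 0, pit_sd_um)
    d_rpeos <- stats::rnorm(1L, 0, rpeos_sd_um)
    latent <- list(isos_depth_um = spec_a$isos_depth_um + d_depth,
                   pit_depth_um = max(spec_a$pit_depth_um + d_pit, 20),
                   rpeos_fovea_um = spec_a$rpeos_fovea_um + d_rpeos,
                   rpeos_periph_um = spec_a$rpeos_periph_um + d_rpeos)
    sa <- do.call(phantom_spec,
                  utils::modifyList(unclass(spec_a), latent))
    lb <- latent
    if (mode == "two_device") {
      lb$rpeos_fovea_um <- lb$rpeos_fovea_um + bias_um
      lb$rpeos_periph_um <- lb$rpeos_periph_um + bias_um
      sb <- do.call(phantom_spec,
                    utils::modifyList(unclass(spec_b), lb))
    } else {
      w <- stats::rnorm(1L, 0, within_eye_sd_um)
      lb$isos_depth_um <- lb$isos_depth_um + w
      sb <- do.call(phantom_spec,
                    utils::modifyList(unclass(spec_a), lb))
    }
    seed_a <- sample.int(.Machine$integer.max, 1L)
    seed_b <- sample.int(.Machine$integer.max, 1L)
    eyes[[i]] <- list(eye_id = sprintf("eye%02d", i),
                      a = generate_phantom(sa, seed_a),
                      b = generate_phantom(sb, seed_b))
  }
  truth <- do.call(rbind, lapply(eyes, function(e) {
    data.frame(eye_id = e$eye_id,
               device = c("A", "B"),
               true_cpt_um = c(min(e$a$truth$retina_um),
                               min(e$b$truth$retina_um)),
               true_rpeos_fovea_um = c(max(e$a$truth$rpeos_um),
                                       max(e$b$truth$rpeos_um)))
  }))
  structure(list(eyes = eyes, truth = truth, mode = mode,
                 bias_um = bias_um, seed = seed),
            class = "oct_cohort")
}

#' Segment and measure every scan of a cohort
#'
#' Runs [segment_all()] and [quantify_thickness()] on each phantom of a
#' cohort and returns the tidy thickness table the agreement module reads:
#' one row per eye, device, layer pair and grid offset.
#'
#' @param cohort An `oct_cohort`.
#' @param config An [oct_seg_config()].
#' @param offsets_mm Lateral sampling grid (mm).
#' @return Data frame with `eye_id, device, visit, layer_pair, offset_mm,
#'   thickness_um, missing`.
#' @export
measure_cohort <- function(cohort, config = oct_seg_config(),
                           offsets_mm = seq(-3, 3, by = 0.5)) {
  stopifnot(inherits(cohort, "oct_cohort"))
  one <- function(ph, eye_id, device, visit) {
    seg <- segment_all(ph$scan, config)
    q <- quantify_thickness(seg, offsets_mm)
    do.call(rbind, lapply(c("retina", "rpeos"), function(lp) {
      pts <- q[[lp]]$points
      data.frame(eye_id = eye_id, device = device, visit = visit,
                 layer_pair = if (lp == "retina") "RETINA" else "RPEOS",
                 offset_mm = pts$offset_mm,
                 thickness_um = pts$thickness_um,
                 missing = pts$missing)
    }))
  }
  visit_b <- if (cohort$mode == "repeat_visit") 2L else 1L
  dev_b <- if (cohort$mode == "repeat_visit") "A" else "B"
  do.call(rbind, lapply(cohort$eyes, function(e) {
    rbind(one(e$a, e$eye_id, "A", 1L),
          one(e$b, e$eye_id, dev_b, visit_b))
  }))
}
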