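#' Specify a periosteal callus compartment
#'
#' A compartment of mineralizing callus accreted on the periosteal surface of
#' the shaft, on either the plate-facing (cis) or far (trans) side, centred
#' axially on the osteotomy gap. Callus mineral densities live in the
#' 250--1000 mgHA/ccm band that separates forming callus from native cortex.
#'
#' @param side `"cis"` or `"trans"`.
#' @param target_volume Target compartment volume in ccm (cm^3).
#' @param density Compartment mineral density, mgHA/ccm, in \[250, 1000\].
#' @param axial_extent Axial length (mm) of the compartment, centred on the
#'   gap centre.
#' @return A `callus_compartment` list.
#' @export
callus_compartment <- function(side, target_volume, density,
                               axial_extent = 24) {
  side <- match.arg(side, c("cis", "trans"))
  if (!is.numeric(target_volume) || target_volume <= 0)
    stopf("callus target_volume must be > 0 ccm")
  if (density < 250 || density > 1000)
    stopf("callus density must lie in [250, 1000] mgHA/ccm, got %g", density)
  if (axial_extent <= 0) stopf("axial_extent must be > 0 mm")
  structure(list(side = side, target_volume = target_volume,
                 density = density, axial_extent = axial_extent),
            class = "callus_compartment")
}

#' Specify a synthetic osteotomy phantom
#'
#' Describes an osteotomized cortical shaft: a hollow cylinder of cortical
#' bone along the third image axis, interrupted by a transverse gap (3 mm by
#' default, matching the standardized parallel osteotomy gap), with optional
#' periosteal callus compartments, transverse screws and additive Gaussian
#' reconstruction noise. All geometry is in mm, densities in mgHA/ccm.
#'
#' @param shaft_outer_diameter,shaft_inner_diameter Outer/inner cortex
#'   diameter, mm.
#' @param shaft_length Scanned shaft length, mm (the axial field of view).
#' @param gap_width Osteotomy gap width, mm (default 3).
#' @param voxel_pitch Isotropic voxel pitch, mm. The scanner's nominal pitch
#'   is 0.0607 mm; the default 0.2 mm keeps desk-scale runs fast while the
#'   pitch remains a free parameter.
#' @param cortical_density,marrow_density Densities of native cortex and
#'   medullary canal content, mgHA/ccm.
#' @param callus_compartments List of [callus_compartment()] specs.
#' @param screw_axial_positions Axial positions (mm) of the screws; the two
#'   innermost must straddle the gap.
#' @param include_metal If `TRUE`, screws are rendered as metal cylinders.
#' @param metal_density Metal density, mgHA/ccm.
#' @param endosteal_callus If `TRUE`, a thin endosteal callus lining is added
#'   inside the medullary canal over the gap region. Off by default: the
#'   endosteal extent is only qualitatively known, so no fidelity is claimed.
#' @param noise_sd SD of additive Gaussian noise, mgHA/ccm (applied after
#'   labelling).
#' @param fov_margin Transverse clearance (mm) between the outer shaft
#'   surface and the edge of the field of view, reserved for callus.
#' @param seed Integer seed making the phantom reproducible.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shaft_outer_diameter = 20,
                         shaft_inner_diameter = 14,
                         shaft_length = 40,
                         gap_width = 3,
                         voxel_pitch = 0.2,
                         cortical_density = 1200,
                         marrow_density = 100,
                         callus_compartments = list(),
                         screw_axial_positions = c(6, 11, 16, 24, 29, 34),
                         include_metal = FALSE,
                         metal_density = 3000,
                         endosteal_callus = FALSE,
                         noise_sd = 0,
                         fov_margin = 6,
                         seed = 1L) {
  if (shaft_inner_diameter >= shaft_outer_diameter)
    stopf("shaft_inner_diameter must be < shaft_outer_diameter")
  if (gap_width <= 0 || gap_width >= shaft_length)
    stopf("gap_width must satisfy 0 < gap_width < shaft_length")
  if (voxel_pitch <= 0) stopf("voxel_pitch must be > 0 mm")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  callus_compartments <- lapply(callus_compartments, function(cc) {
    if (!inherits(cc, "callus_compartment")) do.call(callus_compartment, cc)
    else cc
  })
  structure(list(shaft_outer_diameter = shaft_outer_diameter,
                 shaft_inner_diameter = shaft_inner_diameter,
                 shaft_length = shaft_length,
                 gap_width = gap_width,
                 voxel_pitch = voxel_pitch,
                 cortical_density = cortical_density,
                 marrow_density = marrow_density,
                 callus_compartments = callus_compartments,
                 screw_axial_positions = screw_axial_positions,
                 include_metal = include_metal,
                 metal_density = metal_density,
                 endosteal_callus = endosteal_callus,
                 noise_sd = noise_sd,
                 fov_margin = fov_margin,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Truth label codes for phantom voxels.
PHANTOM_LABELS <- c(background = 0L, marrow = 1L, cortical = 2L,
                    callus_cis = 3L, callus_trans = 4L, metal = 5L)

#' Generate a calibrated phantom volume with known ground truth
#'
#' Rasterizes a [phantom_spec()] onto a voxel grid. Callus voxels are accreted
#' shell-wise outward from the periosteal surface, on the requested side and
#' within the compartment's axial extent, until the voxelized volume is the
#' closest achievable to the target. The returned truth records the exact
#' achieved voxel volumes, so every downstream stage has an oracle.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{volume}{[calibrated_volume()] of densities (noise included).}
#'     \item{truth}{`phantom_truth`: `labels` (integer array coded as in
#'       `callusmorph:::PHANTOM_LABELS`), `true_volumes` (ccm, exactly voxel
#'       count x voxel volume), `true_densities` (mgHA/ccm),
#'       `cis_halfspace_normal`, `gap_bounds` (mm), `screw_axial_positions`,
#'       `plate_extent` and `pitch`.}
#'   }
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  p <- spec$voxel_pitch
  fov_xy <- spec$shaft_outer_diameter + 2 * spec$fov_margin
  nx <- ny <- as.integer(round(fov_xy / p))
  nz <- as.integer(round(spec$shaft_length / p))
  cx <- nx * p / 2
  cy <- ny * p / 2

  xs <- voxel_centers(nx, p) - cx
  ys <- voxel_centers(ny, p) - cy
  zs <- voxel_centers(nz, p)
  r2 <- outer(xs^2, ys^2, `+`)            # in-plane squared radius, nx x ny
  r_out <- spec$shaft_outer_diameter / 2
  r_in <- spec$shaft_inner_diameter / 2
  gap_center <- spec$shaft_length / 2
  gap <- c(gap_center - spec$gap_width / 2, gap_center + spec$gap_width / 2)
  in_gap_slice <- zs >= gap[1] & zs < gap[2]

  labels <- array(PHANTOM_LABELS[["background"]], c(nx, ny, nz))
  cortex_plane <- r2 <= r_out^2 & r2 > r_in^2
  marrow_plane <- r2 <= r_in^2
  for (k in seq_len(nz)) {
    if (!in_gap_slice[k]) {
      sl <- labels[, , k]
      sl[cortex_plane] <- PHANTOM_LABELS[["cortical"]]
      sl[marrow_plane] <- PHANTOM_LABELS[["marrow"]]
      labels[, , k] <- sl
    }
  }

  # Shell-wise periosteal callus accretion: candidate voxels outside the
  # cortical surface, on the requested half (cis = +x), within the axial
  # extent, taken in order of increasing radius.
  x3 <- array(rep(xs, times = ny * nz), c(nx, ny, nz))
  r2_3 <- array(rep(r2, times = nz), c(nx, ny, nz))
  z3 <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
  voxvol_ccm <- p^3 / 1000
  for (cc in spec$callus_compartments) {
    half <- if (cc$side == "cis") x3 > 0 else x3 <= 0
    axial <- abs(z3 - gap_center) <= cc$axial_extent / 2
    cand <- which(labels == PHANTOM_LABELS[["background"]] &
                    r2_3 > r_in^2 & half & axial &
                    (r2_3 > r_out^2 | abs(z3 - gap_center) <= spec$gap_width / 2))
    k_want <- as.integer(round(cc$target_volume / voxvol_ccm))
    if (k_want > length(cand)) {
      max_r <- sqrt(max(r2_3[cand]))
      limiting <- if (fov_xy / 2 - max_r < 2 * p)
        sprintf("transverse field of view (fov_margin = %g mm)", spec$fov_margin)
      else
        sprintf("axial extent (%g mm)", cc$axial_extent)
      stopf(paste0("callus compartment (%s, %.3g ccm) not achievable: only ",
                   "%.3g ccm available; limiting dimension: %s"),
            cc$side, cc$target_volume, length(cand) * voxvol_ccm, limiting)
    }
    ord <- cand[order(r2_3[cand], cand)]
    lab <- PHANTOM_LABELS[[paste0("callus_", cc$side)]]
    labels[ord[seq_len(k_want)]] <- lab
  }

  if (spec$endosteal_callus && length(spec$callus_compartments)) {
    # thin lining inside the canal over the gap region; density of the first
    # compartment; volume folded into its side's truth bookkeeping
    lining <- which(labels == PHANTOM_LABELS[["background"]] &
                      r2_3 <= r_in^2 & r2_3 > (r_in - 1)^2 &
                      abs(z3 - gap_center) <= spec$gap_width / 2 + 2)
    side <- spec$callus_compartments[[1]]$side
    labels[lining] <- PHANTOM_LABELS[[paste0("callus_", side)]]
  }

  if (spec$include_metal) {
    # screws as cylinders along x (plate side = +x) through the bone
    screw_r <- 2.5
    for (zpos in spec$screw_axial_positions) {
      hit <- outer(ys^2, (zs - zpos)^2, `+`) <= screw_r^2  # ny x nz
      for (k in which(colSums(hit) > 0)) {
        sl <- labels[, , k]
        sl[, hit[, k]] <- PHANTOM_LABELS[["metal"]]
        labels[, , k] <- sl
      }
    }
  }

  dens_map <- c(0, spec$marrow_density, spec$cortical_density,
                rep(NA_real_, 2), spec$metal_density)
  cis_d <- trans_d <- NA_real_
  for (cc in spec$callus_compartments) {
    if (cc$side == "cis") cis_d <- cc$density else trans_d <- cc$density
  }
  dens_map[4] <- cis_d %||% NA_real_
  dens_map[5] <- trans_d %||% NA_real_
  values <- array(dens_map[labels + 1L], dim(labels))
  values[is.na(values)] <- 0

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    values <- values + stats::rnorm(length(values), sd = spec$noise_sd)
  }

  counts <- tabulate(labels + 1L, nbins = 6L)
  names(counts) <- names(PHANTOM_LABELS)
  true_volumes <- counts * voxvol_ccm
  true_densities <- c(marrow = spec$marrow_density,
                      cortical = spec$cortical_density,
                      callus_cis = cis_d, callus_trans = trans_d,
                      metal = spec$metal_density)

  truth <- structure(list(labels = labels,
                          true_volumes = true_volumes,
                          true_densities = true_densities,
                          cis_halfspace_normal = c(1, 0, 0),
                          gap_bounds = gap,
                          screw_axial_positions = spec$screw_axial_positions,
                          plate_extent = range(spec$screw_axial_positions) +
                            c(-2, 2),
                          pitch = rep(p, 3)),
                     class = "phantom_truth")
  list(volume = calibrated_volume(values, p), truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth: compartment volumes (ccm)\n")
  print(round(x$true_volumes[x$true_volumes > 0], 4))
  cat(sprintf("  gap [%.2f, %.2f] mm; screws at %s mm\n", x$gap_bounds[1],
              x$gap_bounds[2], paste(x$screw_axial_positions, collapse = ", ")))
  invisible(x)
}

#' Draw per-sample callus volumes for a treatment-group design
#'
#' Samples compartment target volumes with lognormal between-animal variation
#' around group means `base * multiplier`. Factored out of
#' [generate_group_dataset()] so that statistical power can be checked by
#' Monte-Carlo without rasterizing phantoms.
#'
#' @param base_volume Mean compartment volume (ccm) of the reference group.
#' @param multipliers Named numeric vector of group effect multipliers, e.g.
#'   `c(LS = 1, VFLS3 = 1.4, VFLS6 = 1.93)`.
#' @param n_per_group Animals per group (>= 2).
#' @param cv Coefficient of variation of the lognormal between-animal
#'   variation (0 gives exact group means).
#' @param seed Integer seed.
#' @return data.frame with columns `group`, `sample`, `volume` (ccm).
#' @export
draw_group_volumes <- function(base_volume, multipliers, n_per_group,
                               cv = 0.25, seed = 1L) {
  if (any(multipliers <= 0)) stopf("effect multipliers must be > 0")
  if (n_per_group < 2) stopf("n_per_group must be >= 2")
  set.seed(as.integer(seed))
  out <- lapply(names(multipliers), function(g) {
    m <- base_volume * multipliers[[g]]
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      v <- stats::rlnorm(n_per_group, meanlog = log(m) - sdlog^2 / 2,
                         sdlog = sdlog)
    } else v <- rep(m, n_per_group)
    data.frame(group = g, sample = paste0(g, "_", seq_len(n_per_group)),
               volume = v)
  })
  do.call(rbind, out)
}

#' Generate a full treatment-group phantom dataset
#'
#' Emulates a three-groups-of-six design: per-sample cis/trans compartment
#' volumes are drawn with [draw_group_volumes()]-style lognormal variation
#' around group means obtained from a template spec scaled by the group
#' effect multipliers, and one phantom is rasterized per sample. Truth is
#' retained for recovery tests.
#'
#' @param template A [phantom_spec()] with at least one callus compartment;
#'   its compartment volumes define the reference-group means.
#' @param multipliers Named numeric vector of per-group callus-volume
#'   multipliers.
#' @param n_per_group Samples per group (>= 2).
#' @param cv Between-animal coefficient of variation (lognormal).
#' @param seed Integer seed.
#' @return List of samples; each has `volume`, `truth`, `group`, `sample`.
#' @export
generate_group_dataset <- function(template, multipliers, n_per_group = 6,
                                   cv = 0.25, seed = 1L) {
  stopifnot(inherits(template, "phantom_spec"))
  if (!length(template$callus_compartments))
    stopf("template spec needs at least one callus compartment")
  if (any(multipliers <= 0)) stopf("effect multipliers must be > 0")
  if (n_per_group < 2) stopf("n_per_group must be >= 2")
  set.seed(as.integer(seed))
  samples <- list()
  for (g in names(multipliers)) {
    for (i in seq_len(n_per_group)) {
      spec_i <- template
      spec_i$seed <- as.integer(sample.int(2^31 - 1, 1))
      spec_i$callus_compartments <-
        lapply(template$callus_compartments, function(cc) {
          m <- cc$target_volume * multipliers[[g]]
          if (cv > 0) {
            sdlog <- sqrt(log(1 + cv^2))
            cc$target_volume <- stats::rlnorm(1, log(m) - sdlog^2 / 2, sdlog)
          } else cc$target_volume <- m
          cc
        })
      ph <- generate_phantom(spec_i)
      samples[[length(samples) + 1L]] <-
        list(volume = ph$volume, truth = ph$truth, group = g,
             sample = paste0(g, "_", i))
    }
  }
  samples
}
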