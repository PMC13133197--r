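# End-to-end pipeline: two-vertebra phantom scene -> segmentation ->
# porosity -> fabric -> micromechanics -> meshed model with cage and
# posterior fixation -> linear FE -> damage report.

#' Build the interbody fusion model from a phantom scene
#'
#' Runs the full patient-specific property pipeline on a synthetic
#' two-vertebra scene: isotropic resampling, threshold segmentation of the
#' cortical shell and trabecular core, HU-distribution fit and porosity
#' calibration, per-tissue gradient structure tensor, micromechanical
#' stiffness mapping, and a conforming voxel-derived tetrahedral mesh of
#' bone, interbody cage and posterior fixation (pedicle screws + rods,
#' tied by shared nodes). The cage is either a homogenized porous
#' hydroxyapatite lattice (effective stiffness from periodic voxel
#' homogenization) or a solid Ti6Al4V ring.
#'
#' @param spec a [phantom_spec].
#' @param gap_mm disc-space gap (default 9).
#' @param scaffold `"fcc"`, `"kelvin"` (homogenized porous HAp) or
#'   `"ti_ring"`.
#' @param mesh_edge_mm target element edge (default 2).
#' @param cage_porosity lattice porosity (default 0.75).
#' @param cage_stiffness optional precomputed 6x6 cage stiffness (MPa);
#'   when `NULL` it is homogenized at `homogenize_n` voxels per cell.
#' @param homogenize_n homogenization grid (default 32; coarser than the
#'   reference 64 to keep the end-to-end run light, see vignette).
#' @param E0_hap,nu_hap dense hydroxyapatite constants (100 GPa, 0.3).
#' @param E_ti,nu_ti Ti6Al4V constants.
#' @param E0_trab trabecular strut tissue modulus (MPa).
#' @return object of class `interbody_model`.
#' @export
build_interbody_model <- function(spec = phantom_spec(), gap_mm = 9,
                                  scaffold = c("fcc", "kelvin", "ti_ring"),
                                  mesh_edge_mm = 2, cage_porosity = 0.75,
                                  cage_stiffness = NULL, homogenize_n = 32,
                                  E0_hap = 1e5, nu_hap = 0.3,
                                  E_ti = 113800, nu_ti = 0.342,
                                  E0_trab = 13000) {
  scaffold <- match.arg(scaffold)
  scene <- make_two_vertebra_scene(spec, gap_mm)
  iso <- resample_isotropic(scene$volume, min(spec$spacing))

  # threshold segmentation with shell closing
  lo_cort <- spec$hu_cortical_range[1] - 150
  lo_body <- spec$hu_trabecular_mode - 3 * spec$hu_trabecular_spread
  cort <- segment_by_threshold(iso, lo_cort, Inf,
                               morphology_ops = list(c("close", 1)))
  body <- segment_by_threshold(iso, lo_body, Inf,
                               morphology_ops = list(c("close", 1),
                                                     c("open", 1)))
  trab <- body & !cort
  # drop stray soft-tissue voxels: keep trabecular only inside an eroded body
  trab <- trab & erode3(body, 1)

  hu <- iso$values
  fit <- fit_hu_threshold(sample(hu[body], min(50000, sum(body))),
                          family = "auto")
  cal <- calibration_params(
    hu_mode_trab = hu_mode_estimate(hu[trab]),
    hu_min_trab = min(hu[trab]),
    hu_threshold = fit$threshold,
    hu_min_cort = min(hu[cort]),
    distribution_family = fit$family)
  pf <- porosity_field(iso, cort, trab, cal)
  fab_c <- gradient_structure_tensor(iso, cort)
  fab_t <- gradient_structure_tensor(iso, trab)
  ef <- map_bone_properties(pf, fab_c, fab_t, E0_trab = E0_trab)

  # scene labels for meshing: 1 cortical, 2 trabecular, 3 cage, 4 screws,
  # 5 rods
  lab <- array(0L, dim(iso$values))
  lab[trab] <- 2L
  lab[cort] <- 1L
  xs <- voxel_coords(iso)
  d <- dim(lab)
  X <- array(xs[[1]], d)
  Y <- array(rep(xs[[2]], each = d[1]), d)
  Z <- array(rep(xs[[3]], each = d[1] * d[2]), d)
  fp <- scene$gap$footprint_half_axes
  cage_mask <- (X / fp[1])^2 + (Y / fp[2])^2 <= 1 &
    Z > scene$gap$z_lower & Z < scene$gap$z_upper & lab == 0L
  if (scaffold == "ti_ring") {
    wall <- 3.8
    ring <- (X / fp[1])^2 + (Y / fp[2])^2 <= 1 &
      ((X / (fp[1] - wall))^2 + (Y / (fp[2] - wall))^2 >= 1)
    lab[cage_mask & ring] <- 3L
  } else {
    lab[cage_mask] <- 3L
  }
  # posterior fixation: screws along y into each body, rods along z
  r_screw <- 2.5
  x_rod <- c(-8, 8)
  y_rod <- -(spec$body_half_axes[2] + 2)
  z_centres <- scene$gap$centres
  screw <- array(FALSE, d)
  for (x0 in x_rod) for (z0 in z_centres) {
    cyl <- (X - x0)^2 + (Z - z0)^2 <= r_screw^2 & Y >= y_rod & Y <= 0
    screw <- screw | cyl
  }
  rod <- array(FALSE, d)
  for (x0 in x_rod) {
    cyl <- (X - x0)^2 + (Y - y_rod)^2 <= r_screw^2 &
      Z >= min(z_centres) & Z <= max(z_centres)
    rod <- rod | cyl
  }
  lab[screw & lab == 0L] <- 4L
  lab[screw & lab > 0L & lab < 3L] <- 4L   # screw displaces bone along its path
  lab[rod & lab == 0L] <- 5L

  # priority sampling keeps the sub-cell cortical shell and the fixation
  # cylinders connected in the coarse mesh
  mesh <- make_tet_mesh(image_volume(lab, iso$spacing, iso$origin),
                        mesh_edge_mm,
                        priority = rbind(c(1, 0.25)),
                        connectivity = "largest")

  # materials
  if (scaffold != "ti_ring" && is.null(cage_stiffness)) {
    hom <- homogenize_unit_cell(scaffold, cell_size = 3, E0 = E0_hap,
                                nu0 = nu_hap, n = homogenize_n,
                                target_porosity = cage_porosity)
    cage_stiffness <- hom$C
  }
  if (scaffold == "ti_ring") cage_stiffness <- iso_stiffness(E_ti, nu_ti)
  mats <- matrix(0, 21, nrow(mesh$elems))
  bone_el <- which(mesh$elem_label %in% c(1L, 2L))
  # assign bone by nearest voxel; non-bone labels get their own materials
  sub <- nearest_voxel_assign(
    tet_mesh(mesh$nodes, mesh$elems[bone_el, , drop = FALSE],
             mesh$elem_label[bone_el]),
    ef, default_stiffness = isotropic_fallback_stiffness(0.6))
  mats[, bone_el] <- sub
  mats[, mesh$elem_label == 3L] <- pack_voigt(check_voigt(cage_stiffness))
  mats[, mesh$elem_label %in% c(4L, 5L)] <- pack_voigt(iso_stiffness(E_ti, nu_ti))

  # supports and coupling
  zr <- range(mesh$nodes[, 3])
  cell <- attr(mesh, "cell_mm")[3]
  fixed <- select_nodes(mesh, function(x, y, z) z < zr[1] + 0.6 * cell)
  top <- select_nodes(mesh, function(x, y, z) z > zr[2] - 0.6 * cell)
  rp <- c(0, 0, zr[2] + 5)

  structure(list(mesh = mesh, materials = mats, fixed_nodes = fixed,
                 coupling = list(ref_point = rp, nodes = top),
                 sets = list(cortical = which(mesh$elem_label == 1L),
                             trabecular = which(mesh$elem_label == 2L),
                             cage = which(mesh$elem_label == 3L),
                             screws = which(mesh$elem_label == 4L),
                             rods = which(mesh$elem_label == 5L)),
                 scaffold = scaffold, cage_porosity = cage_porosity,
                 cage_stiffness = cage_stiffness,
                 calibration = cal, elasticity = ef,
                 fabric = list(cortical = fab_c, trabecular = fab_t),
                 porosity = pf, scene = scene, labels = lab,
                 E0_hap = E0_hap), class = "interbody_model")
}

# histogram mode estimate (robust to the long tail)
hu_mode_estimate <- function(x) {
  dd <- density(x, n = 512)
  dd$x[which.max(dd$y)]
}

#' @export
print.interbody_model <- function(x, ...) {
  cat(sprintf("interbody_model (%s cage): %d elements (%d bone, %d cage, %d fixation)\n",
              x$scaffold, nrow(x$mesh$elems),
              length(x$sets$cortical) + length(x$sets$trabecular),
              length(x$sets$cage),
              length(x$sets$screws) + length(x$sets$rods)))
  invisible(x)
}

#' Run a load case on the interbody model
#'
#' Solves the linear-static problem and assembles the damage report:
#' failed cage volume (total / tension / compression, thresholds from the
#' porosity-strength law for homogenized porous cages, yield-less solid Ti
#' reported against the dense thresholds), damaged trabecular volume,
#' fixation metrics, macroscopic stiffness and rotation, and the
#' anterior/posterior split of the failed cage volume.
#'
#' @param model an `interbody_model`.
#' @param case a [load_case].
#' @param thresholds a [damage_thresholds].
#' @return object of class `damage_report`.
#' @export
run_interbody_case <- function(model, case = load_case("standing"),
                               thresholds = damage_thresholds()) {
  stopifnot(inherits(model, "interbody_model"), inherits(case, "load_case"))
  res <- solve_linear_static(model$mesh, model$materials, model$fixed_nodes,
                             coupling = model$coupling, load = case)
  if (model$scaffold == "ti_ring") {
    tlim <- thresholds$sigma_yield
    clim <- thresholds$sigma_yield
  } else {
    tlim <- macroscopic_strength(thresholds$hap_tension, model$cage_porosity)
    clim <- macroscopic_strength(thresholds$hap_compression,
                                 model$cage_porosity)
  }
  cage <- model$sets$cage
  fv <- c(total = failed_volume(res, cage, tlim, clim, "either"),
          tension = failed_volume(res, cage, tlim, clim, "tension"),
          compression = failed_volume(res, cage, tlim, clim, "compression"))
  # anterior (+y) vs posterior (-y) halves of the cage
  cen <- element_centroids(model$mesh)
  ant <- cage[cen[cage, 2] > 0]
  post <- cage[cen[cage, 2] <= 0]
  fv_ant <- if (length(ant)) failed_volume(res, ant, tlim, clim, "either") else 0
  fv_post <- if (length(post)) failed_volume(res, post, tlim, clim, "either") else 0
  dtv <- damaged_trabecular_volume(res, model$sets$trabecular,
                                   thresholds$trabecular_strain_limit)
  rods <- model$sets$rods
  rod_split <- split(rods, cen[rods, 1] > 0)
  fx <- fixation_metrics(res, model$mesh, rod_split, case$force[3],
                         thresholds$sigma_yield)
  mr <- macroscopic_response(res, case)
  structure(list(case = case$name,
                 failed_volume_pct = fv,
                 failed_anterior_pct = fv_ant,
                 failed_posterior_pct = fv_post,
                 damaged_trabecular_pct = dtv,
                 fixation = fx,
                 stiffness_kN_mm = mr$stiffness_kN_mm,
                 rotation_deg = mr$rotation_deg,
                 equilibrium_residual = res$equilibrium_residual,
                 result = res), class = "damage_report")
}

#' @export
print.damage_report <- function(x, ...) {
  cat(sprintf("damage_report (%s):\n", x$case))
  cat(sprintf("  failed cage volume: %.3f%% (tension %.3f%%, compression %.3f%%)\n",
              x$failed_volume_pct["total"], x$failed_volume_pct["tension"],
              x$failed_volume_pct["compression"]))
  cat(sprintf("  anterior/posterior failed: %.3f%% / %.3f%%\n",
              x$failed_anterior_pct, x$failed_posterior_pct))
  cat(sprintf("  damaged trabecular volume: %.3f%%\n", x$damaged_trabecular_pct))
  cat(sprintf("  fixation: yield ratio %.1f, load share %.2f%%\n",
              x$fixation$yield_ratio, x$fixation$load_share_pct))
  cat(sprintf("  stiffness %.2f kN/mm, rotation %.2e deg\n",
              x$stiffness_kN_mm, x$rotation_deg))
  invisible(x)
}

#' Export a damage report as JSON and CSV
#'
#' @param report a `damage_report`.
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @return invisible list of written paths.
#' @export
write_damage_report <- function(report, json_path = NULL, csv_path = NULL) {
  lst <- list(case = report$case,
              failed_volume_pct = as.list(report$failed_volume_pct),
              failed_anterior_pct = report$failed_anterior_pct,
              failed_posterior_pct = report$failed_posterior_pct,
              damaged_trabecular_pct = report$damaged_trabecular_pct,
              fixation = report$fixation,
              stiffness_kN_mm = report$stiffness_kN_mm,
              rotation_deg = report$rotation_deg)
  if (!is.null(json_path)) {
    con <- file(json_path, "w")
    writeLines(simple_json(lst), con)
    close(con)
  }
  if (!is.null(csv_path)) {
    flat <- unlist(lst)
    utils::write.csv(data.frame(metric = names(flat), value = as.character(flat)),
                     csv_path, row.names = FALSE)
  }
  invisible(list(json = json_path, csv = csv_path))
}

simple_json <- function(x, indent = "") {
  if (is.list(x)) {
    nm <- names(x)
    items <- vapply(seq_along(x), function(i) {
      sprintf("%s  \"%s\": %s", indent, nm[i],
              simple_json(x[[i]], paste0(indent, "  ")))
    }, character(1))
    paste0("{\n", paste(items, collapse = ",\n"), "\n", indent, "}")
  } else if (is.character(x)) {
    sprintf("\"%s\"", x)
  } else if (length(x) > 1) {
    paste0("[", paste(format(unname(x), digits = 10), collapse = ", "), "]")
  } else {
    format(unname(x), digits = 10)
  }
}
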