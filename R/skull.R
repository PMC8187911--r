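# Parametric synthetic calvaria: a closed ellipsoidal shell (bone + optional
# CSF layer) around an ellipsoidal intracranial volume, with grid-aligned
# suture bands, a foramen magnum opening, Renier-"H" craniotomies, brain-lobe
# partitions, craniometric landmarks and constraint node sets. The polar
# axis of the surface grid is anteroposterior, which makes every suture a
# coordinate band: coronal/lambdoid are latitude rings, the midline and
# squamosal lines are meridian strips.

#' Craniotomy specification (Renier's "H" technique)
#'
#' The fused sagittal strip is removed as a rectangular cut across the
#' parietal region (posterior of the coronal, anterior of the lambdoid
#' suture), divided into two squares and reinserted, leaving open kerf gaps
#' around the reinserted bone; one wedge per side extends from the cut to
#' the squamosal suture.
#'
#' @param parietal_cut_width width of the rectangular midline cut, mm
#'   (30-40).
#' @param kerf_gap residual open gap left around the reinserted pieces, mm.
#' @param n_reinserted_squares number of reinserted squares (2).
#' @param wedge_count_per_side lateral wedges per side (1 or 2).
#' @return an object of class `craniotomy_spec`.
#' @export
craniotomy_spec <- function(parietal_cut_width = 35, kerf_gap = 10,
                            n_reinserted_squares = 2L,
                            wedge_count_per_side = 1L) {
  if (parietal_cut_width < 30 || parietal_cut_width > 40)
    stop("parietal_cut_width must lie in [30, 40] mm")
  if (kerf_gap <= 0) stop("kerf_gap must be positive")
  if (n_reinserted_squares != 2L)
    stop("only the two-square reinsertion pattern is supported")
  if (!wedge_count_per_side %in% c(1L, 2L))
    stop("wedge_count_per_side must be 1 or 2")
  structure(list(parietal_cut_width = parietal_cut_width,
                 kerf_gap = kerf_gap,
                 n_reinserted_squares = as.integer(n_reinserted_squares),
                 wedge_count_per_side = as.integer(wedge_count_per_side)),
            class = "craniotomy_spec")
}

#' Synthetic skull parameters
#'
#' Geometry of the parametric calvaria standing in for a patient CT
#' segmentation: a 4-month-old sagittal-synostosis skull with a fused
#' sagittal suture, patent metopic/coronal/lambdoid/squamosal sutures and
#' anterior fontanelle, an intracranial volume of 659 ml, and optionally a
#' uniform 2-3 mm CSF layer between brain and bone.
#'
#' @param icv_target_volume intracranial volume to enclose, ml.
#' @param shell_thickness calvarial bone thickness, mm.
#' @param csf_thickness CSF layer thickness, mm in [0, 3]; 0 disables the
#'   layer (the "CSF absent" model).
#' @param suture_width named list of suture widths, mm; the
#'   `anterior_fontanelle` entry is the fontanelle diameter.
#' @param fused_sutures character vector of fused sutures (default the
#'   sagittal, the synostotic suture).
#' @param craniotomy_spec a [craniotomy_spec()], or `NULL` for an
#'   unoperated skull.
#' @param ellipsoid_semi_axes inner-calvaria semi-axes, mm
#'   (anteroposterior, mediolateral, vertical); rescaled uniformly so the
#'   enclosed ICV matches `icv_target_volume`.
#' @param mesh_size target element edge length, mm.
#' @param n_brain_layers radial element layers in the brain.
#' @param seed integer seed for the (optional) meshing jitter.
#' @param jitter relative amplitude of random angular jitter of the
#'   non-structural grid lines (0 = deterministic grid).
#' @return an object of class `skull_params`.
#' @export
skull_params <- function(icv_target_volume = 659,
                         shell_thickness = 3,
                         csf_thickness = 0,
                         suture_width = list(),
                         fused_sutures = "sagittal",
                         craniotomy_spec = "default",
                         ellipsoid_semi_axes = c(70, 47, 48),
                         mesh_size = 10,
                         n_brain_layers = 3L,
                         seed = 0L,
                         jitter = 0) {
  sw <- list(metopic = 3, coronal = 5, lambdoid = 5, squamosal = 3,
             sagittal = 2, anterior_fontanelle = 25)
  sw[names(suture_width)] <- suture_width
  if (identical(craniotomy_spec, "default"))
    craniotomy_spec <- get("craniotomy_spec", mode = "function")()
  if (icv_target_volume <= 0) stop("icv_target_volume must be positive")
  if (shell_thickness <= 0) stop("shell_thickness must be positive")
  if (csf_thickness < 0 || csf_thickness > 3)
    stop("csf_thickness must lie in [0, 3] mm")
  if (any(ellipsoid_semi_axes <= 0)) stop("ellipsoid_semi_axes must be positive")
  if (mesh_size <= 0) stop("mesh_size must be positive")
  if (any(unlist(sw) <= 0)) stop("suture widths must be positive")
  structure(list(icv_target_volume = icv_target_volume,
                 shell_thickness = shell_thickness,
                 csf_thickness = csf_thickness,
                 suture_width = sw,
                 fused_sutures = fused_sutures,
                 craniotomy_spec = craniotomy_spec,
                 ellipsoid_semi_axes = ellipsoid_semi_axes,
                 mesh_size = mesh_size,
                 n_brain_layers = as.integer(n_brain_layers),
                 seed = as.integer(seed), jitter = jitter),
            class = "skull_params")
}

# Fixed anatomical layout angles (radians) plus the mm->angle conversions
# for the current characteristic radius.
.skull_layout <- function(params, semi_inner) {
  R <- mean(semi_inner + params$shell_thickness / 2)
  ang <- function(w) w / R
  sw <- params$suture_width
  lay <- list(
    R = R,
    theta_coronal = 55 * pi / 180,
    theta_lambdoid = 125 * pi / 180,
    phi_squamosal = 70 * pi / 180,
    phi_base = 115 * pi / 180,
    fm_dir = .dir_tp(105 * pi / 180, pi),     # foramen magnum centre
    fm_radius = ang(14),
    nas_dir = .dir_tp(30 * pi / 180, pi),     # nasion patch centre
    nas_radius = ang(9),
    af_radius = ang(sw$anterior_fontanelle / 2),
    d_metopic = ang(sw$metopic) / 2,
    d_sagittal = ang(sw$sagittal) / 2,
    d_coronal = ang(sw$coronal) / 2,
    d_lambdoid = ang(sw$lambdoid) / 2,
    d_squamosal = ang(sw$squamosal) / 2
  )
  cs <- params$craniotomy_spec
  if (!is.null(cs)) {
    lay$phi_strip <- ang(cs$parietal_cut_width) / 2
    lay$d_kerf <- ang(cs$kerf_gap)
    lay$phi_inner <- lay$phi_strip - lay$d_kerf
    # the cut sits within the parietal plate: a bone bridge separates it
    # from the lambdoid suture, and its anterior edge stays clear of the
    # anterior fontanelle (the surgeon does not cut through the fontanelle)
    bridge <- ang(5)
    t0 <- lay$theta_coronal +
      max(lay$d_coronal + bridge, lay$af_radius + ang(2))
    t5 <- lay$theta_lambdoid - lay$d_lambdoid - bridge
    span <- t5 - t0
    lsq <- (span - 3 * lay$d_kerf) / 2
    if (lsq <= 0 || lay$phi_inner <= 0) {
      max_kerf <- floor(min(span / 3, lay$phi_strip) * R * 10) / 10
      stop(sprintf(paste0("craniotomy kerf gap %.1f mm does not fit the ",
                          "parietal span; achievable maximum is about %.1f mm"),
                   cs$kerf_gap, max_kerf))
    }
    lay$theta_cuts <- t0 + cumsum(c(0, lay$d_kerf, lsq, lay$d_kerf, lsq,
                                    lay$d_kerf))
    lay$theta_wedge <- c(mean(lay$theta_cuts[3:4]),
                         if (cs$wedge_count_per_side == 2L)
                           mean(lay$theta_cuts[1:2]))
    lay$wedge_halfwidth <- lay$d_kerf / 2
  }
  lay
}

# theta and phi grids: structural break angles plus jittered fill
.skull_grids <- function(params, lay) {
  target <- params$mesh_size / lay$R
  tb <- c(0, pi,
          lay$theta_coronal + c(-1, 1) * lay$d_coronal,
          lay$theta_lambdoid + c(-1, 1) * lay$d_lambdoid,
          pi / 2,
          if (!is.null(params$craniotomy_spec)) lay$theta_cuts)
  pb_half <- c(0, lay$d_metopic, pi / 2, pi,
               lay$phi_squamosal + c(-1, 1) * lay$d_squamosal,
               lay$phi_base,
               if (!is.null(params$craniotomy_spec))
                 c(lay$phi_strip, lay$phi_inner))
  thetas <- .fill_grid(tb, 0, pi, target)
  ph <- .fill_grid(sort(unique(pb_half)), 0, pi, target)
  if (params$jitter > 0) {
    set.seed(params$seed)
    jit <- function(g, protect) {
      fill <- !(g %in% protect)
      if (any(fill)) {
        h <- diff(range(g)) / length(g)
        g[fill] <- g[fill] + stats::runif(sum(fill), -1, 1) *
          params$jitter * h
      }
      sort(g)
    }
    thetas <- jit(thetas, tb)
    ph <- jit(ph, pb_half)
  }
  phis <- sort(unique(c(-ph[ph > 1e-12 & ph < pi - 1e-12], ph)))
  list(thetas = thetas, phis = phis)
}

# centroid angles (theta in [0,pi], phi in (-pi,pi]) of unit directions
.centroid_angles <- function(cen) {
  d <- cen / sqrt(rowSums(cen^2))
  list(theta = acos(pmin(1, pmax(-1, d[, 1]))),
       phi = atan2(d[, 2], d[, 3]), d = d)
}

# angular distance between unit directions and a single direction
.angle_to <- function(d, dir0) {
  acos(pmin(1, pmax(-1, d %*% as.vector(dir0))))
}

# Region labels for bone-layer shell elements from centroid angles.
.label_bone <- function(th, ph, d, lay, fused) {
  n <- length(th)
  lab <- rep("craniofacial", n)
  aph <- abs(ph)
  in_vault <- aph < lay$phi_base
  lab[in_vault & th < lay$theta_coronal - lay$d_coronal] <- "frontal"
  mid <- th >= lay$theta_coronal + lay$d_coronal &
    th <= lay$theta_lambdoid - lay$d_lambdoid
  lab[mid & aph < lay$phi_squamosal - lay$d_squamosal & ph >= 0] <- "parietal_L"
  lab[mid & aph < lay$phi_squamosal - lay$d_squamosal & ph < 0] <- "parietal_R"
  lab[mid & aph >= lay$phi_squamosal + lay$d_squamosal & in_vault & ph >= 0] <-
    "temporal_L"
  lab[mid & aph >= lay$phi_squamosal + lay$d_squamosal & in_vault & ph < 0] <-
    "temporal_R"
  lab[in_vault & th > lay$theta_lambdoid + lay$d_lambdoid] <- "occipital"
  # suture bands override plates
  lab[mid & abs(aph - lay$phi_squamosal) < lay$d_squamosal] <- "squamosal"
  lab[abs(th - lay$theta_coronal) <= lay$d_coronal &
        aph < lay$phi_squamosal + lay$d_squamosal] <- "coronal"
  lab[abs(th - lay$theta_lambdoid) <= lay$d_lambdoid &
        aph < lay$phi_squamosal + lay$d_squamosal] <- "lambdoid"
  lab[aph <= lay$d_metopic & th < lay$theta_coronal - lay$d_coronal] <- "metopic"
  sag <- aph <= lay$d_sagittal & th >= lay$theta_coronal - lay$d_coronal &
    th <= lay$theta_lambdoid + lay$d_lambdoid
  lab[sag] <- if ("sagittal" %in% fused) "sagittal_fused" else "sagittal"
  af <- .angle_to(d, .dir_tp(lay$theta_coronal, 0)) < lay$af_radius
  lab[af] <- "anterior_fontanelle"
  lab
}

# Brain lobes by anatomical sectors of the normalised coordinates.
.label_lobes <- function(cen, semi) {
  xn <- cen[, 1] / semi[1]; yn <- cen[, 2] / semi[2]; zn <- cen[, 3] / semi[3]
  lab <- rep("brain_parietal", nrow(cen))
  lab[abs(yn) > 0.45 & zn < 0.1] <- "brain_temporal"
  lab[xn > 0.25] <- "brain_frontal"
  lab[xn < -0.45] <- "brain_occipital"
  lab[xn < -0.1 & zn < -0.45] <- "cerebellum"
  lab
}

#' Generate the synthetic labelled calvaria
#'
#' Builds the parametric skull: an ellipsoidal calvarial shell with
#' grid-aligned suture bands (sagittal fused by default), an optional bonded
#' CSF layer, a separately meshed brain (five lobes) registered as a contact
#' pair against the inner calvaria, a foramen magnum opening with its
#' constraint ring, a nasion constraint patch, craniometric landmarks, and
#' (unless disabled) the Renier-"H" craniotomies. The inner geometry is
#' rescaled so the enclosed ICV matches the target volume to well within 1%.
#'
#' @param params a [skull_params()].
#' @return a `labeled_mesh`.
#' @export
generate_calvaria <- function(params = skull_params()) {
  stopifnot(inherits(params, "skull_params"))
  semi <- params$ellipsoid_semi_axes
  target_mm3 <- params$icv_target_volume * 1000
  mesh <- NULL
  for (pass in 1:6) {
    mesh <- .build_skull(params, semi)
    v <- sum(tet_volumes(mesh)[startsWith(mesh$region, "brain") |
                                 mesh$region %in% c("cerebellum", "csf")])
    ratio <- target_mm3 / v
    if (abs(ratio - 1) < 2e-3) break
    semi <- semi * ratio^(1 / 3)
  }
  if (abs(ratio - 1) >= 0.01)
    stop("ICV volume calibration failed to converge")
  mesh <- place_landmarks(mesh)
  if (!is.null(params$craniotomy_spec))
    mesh <- apply_craniotomies(mesh, params$craniotomy_spec)
  mesh
}

# One construction pass at fixed inner semi-axes.
.build_skull <- function(params, semi_inner) {
  lay <- .skull_layout(params, semi_inner)
  gr <- .skull_grids(params, lay)
  surf <- .surface_grid(gr$thetas, gr$phis)
  tb <- params$shell_thickness
  tc <- params$csf_thickness
  semis <- if (tc > 0)
    list(semi_inner - tc, semi_inner, semi_inner + tb)
  else list(semi_inner, semi_inner + tb)
  shell <- .shell_mesh(surf, semis)
  brain_semi <- semis[[1]]
  brain <- .ball_mesh(surf, brain_semi, params$n_brain_layers)

  # foramen magnum: remove whole shell columns (all layers) near the
  # foramen direction
  cen_sh <- (shell$nodes[shell$tets[, 1], ] + shell$nodes[shell$tets[, 2], ] +
             shell$nodes[shell$tets[, 3], ] + shell$nodes[shell$tets[, 4], ]) / 4
  ang_sh <- .centroid_angles(cen_sh)
  fm <- as.vector(.angle_to(ang_sh$d, lay$fm_dir)) < lay$fm_radius
  removed_tris <- unique(shell$tri[fm])
  keep <- !(shell$tri %in% removed_tris)
  ring_nodes <- intersect(unique(as.vector(shell$tets[!keep, ])),
                          unique(as.vector(shell$tets[keep, ])))

  # labels
  n_layers <- length(semis) - 1L
  bone_layer <- n_layers            # outermost layer is bone
  lab_shell <- rep("csf", nrow(shell$tets))
  bsel <- shell$layer == bone_layer
  angb <- .centroid_angles(cen_sh[bsel, , drop = FALSE])
  lab_shell[bsel] <- .label_bone(angb$theta, angb$phi, angb$d, lay,
                                 params$fused_sutures)
  cen_br <- (brain$nodes[brain$tets[, 1], ] + brain$nodes[brain$tets[, 2], ] +
             brain$nodes[brain$tets[, 3], ] + brain$nodes[brain$tets[, 4], ]) / 4
  lab_brain <- .label_lobes(cen_br, brain_semi)

  # assemble: shell nodes first, then brain nodes
  n_shell_nodes <- nrow(shell$nodes)
  nodes <- rbind(shell$nodes, brain$nodes)
  elems <- rbind(shell$tets[keep, , drop = FALSE],
                 brain$tets + n_shell_nodes)
  region <- c(lab_shell[keep], lab_brain)

  # contact pair: brain outer surface against inner calvaria (or CSF) surface
  kept_tris <- setdiff(seq_len(nrow(surf$tris)), removed_tris)
  master_tris <- surf$tris[kept_tris, , drop = FALSE]  # boundary 1 node ids
  slave_off <- n_shell_nodes + brain$outer_offset
  contact <- list(
    slave_nodes = slave_off + seq_len(surf$n_surf),
    slave_tris = surf$tris + slave_off,
    master_tris = master_tris
  )

  # constraint node sets on the shell
  nd_ang <- .centroid_angles(shell$nodes)
  nas <- which(as.vector(.angle_to(nd_ang$d, lay$nas_dir)) < lay$nas_radius)
  node_sets <- list(foramen_magnum_ring = sort(ring_nodes),
                    nasion = sort(nas))

  labeled_mesh(nodes, elems, region, node_sets = node_sets,
               contact = contact,
               params = list(skull = params, layout = lay,
                             semi_inner = semi_inner,
                             semi_outer = semi_inner + tb,
                             n_shell_nodes = n_shell_nodes))
}

#' Replicate the surgical craniotomies on a generated skull
#'
#' Relabels the fused sagittal strip region as the Renier-"H" pattern: the
#' rectangular midline cut across the parietal region carrying two
#' reinserted bone squares surrounded by open kerf gaps, plus lateral wedges
#' extending to the squamosal suture. Only labels change; the geometry is
#' untouched.
#'
#' @param mesh a `labeled_mesh` from [generate_calvaria()] (patent parietal
#'   plates, fused sagittal suture).
#' @param spec a [craniotomy_spec()].
#' @return the relabelled `labeled_mesh`.
#' @export
apply_craniotomies <- function(mesh, spec) {
  stopifnot(inherits(spec, "craniotomy_spec"))
  if (!any(startsWith(mesh$region, "parietal")))
    stop("mesh has no patent parietal plates")
  if (!any(mesh$region == "sagittal_fused"))
    stop("mesh has no fused sagittal region to resect")
  # recompute the cut layout for this spec (errors if it does not fit)
  params2 <- mesh$params$skull
  params2$craniotomy_spec <- spec
  lay <- .skull_layout(params2, mesh$params$semi_inner)
  cen <- element_centroids(mesh)
  ang <- .centroid_angles(cen)
  th <- ang$theta; aph <- abs(ang$phi)
  shell_like <- region_class(mesh$region) %in% c("bone", "suture")
  tcut <- lay$theta_cuts
  in_strip <- shell_like & th >= tcut[1] & th <= tcut[6] &
    aph <= lay$phi_strip
  lab <- mesh$region
  side <- ifelse(ang$phi >= 0, "L", "R")
  lateral <- in_strip & aph > lay$phi_inner
  lab[lateral] <- paste0("craniotomy_strip_", side[lateral])
  inner <- in_strip & aph <= lay$phi_inner
  band <- findInterval(th[inner], tcut, rightmost.closed = TRUE)
  kerf_names <- c("craniotomy_kerf_anterior", "reinserted_bone",
                  "craniotomy_kerf_middle", "reinserted_bone",
                  "craniotomy_kerf_posterior")
  lab[inner] <- kerf_names[pmin(pmax(band, 1), 5)]
  for (tw in lay$theta_wedge) {
    wed <- shell_like & abs(th - tw) <= lay$wedge_halfwidth &
      aph > lay$phi_strip & aph < lay$phi_squamosal - lay$d_squamosal
    lab[wed] <- paste0("craniotomy_wedge_", side[wed])
  }
  if (!any(startsWith(lab, "craniotomy")))
    stop("craniotomy relabelling selected no elements")
  mesh$region <- lab
  mesh
}

#' Place craniometric landmarks
#'
#' Sets the six landmarks used for the skull dimensions: glabella and
#' opisthocranion (extreme anterior/posterior midline surface nodes), left
#' and right euryons (extreme lateral surface nodes), bregma (superior
#' midline node at the coronal-sagittal junction) and basion (anterior node
#' of the foramen magnum ring).
#'
#' @param mesh a `labeled_mesh` with a non-empty boundary surface.
#' @return the mesh with its `landmarks` set.
#' @export
place_landmarks <- function(mesh) {
  bf <- boundary_faces(mesh)
  if (!nrow(bf)) stop("mesh has an empty boundary surface")
  bn <- sort(unique(as.vector(bf)))
  nd <- mesh$nodes
  width_y <- diff(range(nd[bn, 2]))
  tol <- max(1e-9, 0.02 * width_y)
  mid <- bn[abs(nd[bn, 2]) < tol]
  if (!length(mid)) mid <- bn[abs(nd[bn, 2]) < 0.1 * width_y]
  lm <- c(glabella = mid[which.max(nd[mid, 1])],
          opisthocranion = mid[which.min(nd[mid, 1])],
          euryon_L = bn[which.max(nd[bn, 2])],
          euryon_R = bn[which.min(nd[bn, 2])])
  # bregma: coronal-sagittal junction when the layout is known, otherwise
  # the superior midline node
  lay <- mesh$params$layout
  if (!is.null(lay)) {
    dir_b <- .dir_tp(lay$theta_coronal, 0)
    sup <- mid[nd[mid, 3] > 0]
    dang <- as.vector(.angle_to(nd[sup, , drop = FALSE] /
                        sqrt(rowSums(nd[sup, , drop = FALSE]^2)), dir_b))
    # several surfaces share the junction ray; take the outermost node
    cand <- sup[dang < min(dang) + 1e-6]
    lm["bregma"] <- cand[which.max(rowSums(nd[cand, , drop = FALSE]^2))]
  } else {
    lm["bregma"] <- mid[which.max(nd[mid, 3])]
  }
  ring <- mesh$node_sets$foramen_magnum_ring
  lm["basion"] <- if (length(ring)) ring[which.max(nd[ring, 1])]
    else mid[which.min(nd[mid, 3])]
  mesh$landmarks <- lm
  mesh
}
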