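# Structured latitude/longitude meshing of ellipsoidal balls and shells.
#
# The polar axis is the anteroposterior (x) axis, so that the calvarial
# sutures of the synthetic skull are grid-aligned bands: coronal and lambdoid
# sutures are latitude rings, the metopic/sagittal midline and the squamosal
# lines are meridian strips. theta in [0, pi] is the angle from the anterior
# pole, phi in (-pi, pi] rolls around the x axis with phi = 0 at the vertex
# (top of the skull) and |phi| = pi at the base.

# unit direction for (theta, phi)
.dir_tp <- function(theta, phi) {
  cbind(cos(theta), sin(theta) * sin(phi), sin(theta) * cos(phi))
}

# radius of the ellipsoid with the given semi-axes along unit directions d
.ellipsoid_radius <- function(d, semi) {
  1 / sqrt((d[, 1] / semi[1])^2 + (d[, 2] / semi[2])^2 + (d[, 3] / semi[3])^2)
}

# Closed triangulated surface grid on the unit sphere.
# Returns node directions, their (theta, phi), and triangles.
.surface_grid <- function(thetas, phis) {
  nt <- length(thetas); np <- length(phis)
  stopifnot(nt >= 3, np >= 4,
            abs(thetas[1]) < 1e-12, abs(thetas[nt] - pi) < 1e-12)
  inner <- thetas[2:(nt - 1)]
  n_surf <- 2L + (nt - 2L) * np
  theta_n <- c(0, rep(inner, each = np), pi)
  phi_n <- c(NA_real_, rep(phis, nt - 2L), NA_real_)
  dirs <- matrix(0, n_surf, 3)
  dirs[1, ] <- c(1, 0, 0)
  dirs[n_surf, ] <- c(-1, 0, 0)
  if (nt > 2L)
    dirs[2:(n_surf - 1L), ] <- .dir_tp(rep(inner, each = np), rep(phis, nt - 2L))
  row_id <- function(i, j) 1L + (i - 2L) * np + j  # i in 2..nt-1, j in 1..np
  jn <- function(j) ifelse(j == np, 1L, j + 1L)    # periodic wrap
  js <- seq_len(np)
  tris <- rbind(
    cbind(1L, row_id(2L, js), row_id(2L, jn(js))),                    # north fan
    if (nt > 3L) .split_quads(do.call(rbind, lapply(2:(nt - 2L), function(i)
      cbind(row_id(i, js), row_id(i + 1L, js),
            row_id(i + 1L, jn(js)), row_id(i, jn(js)))))),
    cbind(n_surf, row_id(nt - 1L, jn(js)), row_id(nt - 1L, js))       # south fan
  )
  list(dirs = dirs, tris = tris, theta = theta_n, phi = phi_n,
       n_surf = n_surf, thetas = thetas, phis = phis)
}

# Extrude a surface grid into a multi-layer shell. `semis` is a list of
# semi-axes, one per layer boundary (innermost first). Layer k of the shell
# lies between boundaries k and k+1. Node ids: boundary k occupies
# (k-1)*n_surf + surf_id. Returns nodes, tets, and per-element layer and
# parent surface-triangle indices.
.shell_mesh <- function(surf, semis) {
  nb <- length(semis)
  stopifnot(nb >= 2)
  n_surf <- surf$n_surf
  nodes <- do.call(rbind, lapply(semis, function(s)
    surf$dirs * .ellipsoid_radius(surf$dirs, s)))
  nt <- nrow(surf$tris)
  tets <- NULL; layer <- NULL; tri <- NULL
  for (k in seq_len(nb - 1L)) {
    off0 <- (k - 1L) * n_surf; off1 <- k * n_surf
    prisms <- cbind(surf$tris + off0, surf$tris + off1)
    tk <- .split_prisms(prisms)
    tets <- rbind(tets, tk)
    layer <- c(layer, rep(k, nrow(tk)))
    tri <- c(tri, rep(seq_len(nt), each = 3L))
  }
  tets <- .orient_tets(nodes, tets)
  list(nodes = nodes, tets = tets, layer = layer, tri = tri, n_surf = n_surf)
}

# Solid ellipsoidal ball: a central vertex fan plus radial prism layers up to
# the surface defined by `semi`. Node ids: centre = 1, radial level l
# (l = 1..n_radial, outermost = n_radial) occupies 1 + (l-1)*n_surf + surf_id.
.ball_mesh <- function(surf, semi, n_radial = 3L) {
  n_surf <- surf$n_surf
  p_out <- surf$dirs * .ellipsoid_radius(surf$dirs, semi)
  fr <- seq_len(n_radial) / n_radial
  nodes <- rbind(c(0, 0, 0),
                 do.call(rbind, lapply(fr, function(f) p_out * f)))
  ntri <- nrow(surf$tris)
  fan <- cbind(1L, surf$tris + 1L)
  tets <- fan; layer <- rep(1L, nrow(fan)); tri <- seq_len(ntri)
  if (n_radial > 1L) for (l in seq_len(n_radial - 1L)) {
    off0 <- 1L + (l - 1L) * n_surf; off1 <- 1L + l * n_surf
    prisms <- cbind(surf$tris + off0, surf$tris + off1)
    tk <- .split_prisms(prisms)
    tets <- rbind(tets, tk)
    layer <- c(layer, rep(l + 1L, nrow(tk)))
    tri <- c(tri, rep(seq_len(ntri), each = 3L))
  }
  tets <- .orient_tets(nodes, tets)
  list(nodes = nodes, tets = tets, layer = layer, tri = tri, n_surf = n_surf,
       outer_offset = 1L + (n_radial - 1L) * n_surf)
}

# theta/phi grids with mandatory break angles inserted and the remaining gaps
# filled to approximately `target` radians
.fill_grid <- function(breaks, lo, hi, target) {
  b <- sort(unique(pmin(pmax(breaks, lo), hi)))
  b <- b[!duplicated(round(b / 1e-9))]
  if (b[1] > lo + 1e-9) b <- c(lo, b)
  if (b[length(b)] < hi - 1e-9) b <- c(b, hi)
  out <- b[1]
  for (k in 2:length(b)) {
    gap <- b[k] - b[k - 1]
    nseg <- max(1L, round(gap / target))
    out <- c(out, b[k - 1] + gap * seq_len(nseg) / nseg)
  }
  out
}

#' Concentric ball-in-shell benchmark mesh
#'
#' A solid sphere (or ellipsoid) of radius `r_inner` inside a shell extending
#' to `r_outer`, meshed with matching structured surface grids and registered
#' as a contact pair (ball surface nodes against inner-shell triangles). This
#' is the classic thick-walled-sphere benchmark geometry used to verify the
#' thermal-expansion contact solver against the Lame closed-form solution.
#'
#' @param r_inner ball radius (mm).
#' @param r_outer shell outer radius (mm), greater than `r_inner`.
#' @param n_theta,n_phi angular resolution of the surface grid.
#' @param n_radial radial layers in the ball.
#' @param n_shell_layers radial layers across the shell thickness.
#' @return a `labeled_mesh` with regions `core` and `shell` and a contact pair.
#' @export
ball_shell_mesh <- function(r_inner = 50, r_outer = 55,
                            n_theta = 17, n_phi = 24,
                            n_radial = 4L, n_shell_layers = 1L) {
  stopifnot(r_outer > r_inner)
  thetas <- seq(0, pi, length.out = n_theta)
  phis <- seq(-pi, pi, length.out = n_phi + 1)[-1]
  surf <- .surface_grid(thetas, phis)
  ball <- .ball_mesh(surf, rep(r_inner, 3), n_radial)
  rb <- r_inner + (r_outer - r_inner) * (0:n_shell_layers) / n_shell_layers
  shell <- .shell_mesh(surf, lapply(rb, rep, 3))
  n_ball <- nrow(ball$nodes)
  nodes <- rbind(ball$nodes, shell$nodes)
  tets <- rbind(ball$tets, shell$tets + n_ball)
  region <- c(rep("core", nrow(ball$tets)), rep("shell", nrow(shell$tets)))
  contact <- list(slave_nodes = ball$outer_offset + seq_len(surf$n_surf),
                  slave_tris = surf$tris + ball$outer_offset,
                  master_tris = surf$tris + n_ball)
  labeled_mesh(nodes, tets, region, contact = contact,
               params = list(r_inner = r_inner, r_outer = r_outer))
}
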