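# Craniometric outputs: skull dimensions and cephalic index, ICV volume,
# suture/craniotomy patency timelines, cross-section outlines, and regional
# contact-pressure statistics.

# round half away from zero (printed clinical indices use this convention,
# unlike R's round-half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cephalic index
#'
#' Skull width divided by length, times 100, reported to two decimals
#' (higher = rounder skull). This is the formula consistent with every
#' printed clinical value; it is computed from the euryon-to-euryon width
#' and the glabella-to-opisthocranion length.
#'
#' @param width biparietal width, mm.
#' @param length_ glabella-opisthocranion length, mm.
#' @return cephalic index, rounded half away from zero to 2 decimals.
#' @export
cephalic_index <- function(width, length_) {
  stopifnot(width > 0, length_ > 0)
  round_half_up(width / length_ * 100, 2)
}

#' Measure skull dimensions
#'
#' Euclidean distances between the placed landmarks: length (glabella to
#' opisthocranion), width (between the euryons), height (basion to bregma),
#' plus the cephalic index and the enclosed ICV volume.
#'
#' @param mesh a `labeled_mesh` with landmarks placed.
#' @param age optional age (months) recorded in the report.
#' @return a one-row data frame of class `morphometrics_report`.
#' @export
measure <- function(mesh, age = NA_real_) {
  lm <- mesh$landmarks
  need <- c("glabella", "opisthocranion", "euryon_L", "euryon_R",
            "bregma", "basion")
  missing <- setdiff(need, names(lm))
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "))
  nd <- mesh$nodes
  d <- function(a, b) sqrt(sum((nd[lm[[a]], ] - nd[lm[[b]], ])^2))
  len <- d("glabella", "opisthocranion")
  wid <- d("euryon_L", "euryon_R")
  hei <- d("basion", "bregma")
  icv <- tryCatch(icv_volume(mesh), error = function(e) NA_real_)
  out <- data.frame(length = round_half_up(len, 2),
                    width = round_half_up(wid, 2),
                    height = round_half_up(hei, 2),
                    cephalic_index = cephalic_index(wid, len),
                    icv_ml = icv, age = age)
  class(out) <- c("morphometrics_report", class(out))
  out
}

#' Intracranial volume of a labelled mesh
#'
#' Sum of the volumes of all ICV-labelled tetrahedra (brain lobes,
#' cerebellum, CSF), converted to millilitres.
#'
#' @param mesh a `labeled_mesh`.
#' @return volume in ml.
#' @export
icv_volume <- function(mesh) {
  sel <- startsWith(mesh$region, "brain") |
    mesh$region %in% c("cerebellum", "csf")
  if (!any(sel)) stop("mesh has no ICV-labelled (brain/CSF) elements")
  sum(tet_volumes(mesh)[sel]) / 1000
}

#' Suture and craniotomy patency timeline
#'
#' Fraction of each suture/craniotomy region still unossified at each
#' recorded age of a growth run; the closure age of a region is the first
#' age at which its fraction reaches zero.
#'
#' @param run a `calvaria_growth` object (or a list of per-age `ossified`
#'   logical vectors with an accompanying region vector and ages).
#' @return a data frame of class `patency_timeline` with columns `region`,
#'   `age`, `fraction_open`.
#' @export
patency <- function(run) {
  if (inherits(run, "calvaria_growth")) {
    region <- run$region0
    snaps <- run$snapshots
  } else {
    region <- run$region
    snaps <- run$snapshots
  }
  nel <- length(region)
  sel <- region_class(region) %in% c("suture", "craniotomy")
  regs <- sort(unique(region[sel]))
  rows <- list()
  for (s in snaps) {
    if (length(s$ossified) != nel)
      stop("inconsistent element counts across the snapshot series")
    for (r in regs) {
      m <- region == r
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, age = s$age, fraction_open = mean(!s$ossified[m]))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("patency_timeline", class(out))
  out
}

#' Closure ages from a patency timeline
#'
#' @param pat a `patency_timeline`.
#' @return named vector: first recorded age at which each region's open
#'   fraction is zero (`NA` if it never closes).
#' @export
closure_ages <- function(pat) {
  vapply(split(pat, pat$region), function(d) {
    d <- d[order(d$age), ]
    i <- which(d$fraction_open <= 0)
    if (length(i)) d$age[min(i)] else NA_real_
  }, numeric(1))
}

#' @export
plot.patency_timeline <- function(x, ...) {
  regs <- unique(x$region)
  cols <- grDevices::hcl.colors(max(3, length(regs)), "Dark 3")
  plot(NA, xlim = range(x$age), ylim = c(0, 1),
       xlab = "age (months)", ylab = "fraction patent",
       main = "Suture / craniotomy patency", ...)
  for (i in seq_along(regs)) {
    d <- x[x$region == regs[i], ]
    graphics::lines(d$age, d$fraction_open, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomleft", legend = regs, col = cols[seq_along(regs)],
                   lwd = 2, cex = 0.7, bty = "n")
  invisible(x)
}

#' Regional contact-pressure report
#'
#' Minimum, maximum and mean contact pressure over the intracranial surface
#' faces, grouped by the brain lobe each face belongs to. All faces of a
#' lobe enter the statistics; faces out of contact contribute zero, so the
#' minima are typically 0 and the mean is a whole-surface average.
#'
#' @param state a solved `sim_state` with contact results.
#' @param mesh the `labeled_mesh` the state belongs to.
#' @return a data frame of class `pressure_report` with one row per lobe.
#' @export
pressure_report <- function(state, mesh) {
  fp <- extract_contact_pressure(state, mesh)
  # assign each intracranial surface face to the lobe of the brain element
  # that owns it
  st <- mesh$contact$slave_tris
  lo <- pmin(st[, 1], st[, 2], st[, 3])
  hi <- pmax(st[, 1], st[, 2], st[, 3])
  key_face <- paste(lo, st[, 1] + st[, 2] + st[, 3] - lo - hi, hi, sep = "_")
  brain_sel <- which(startsWith(mesh$region, "brain") |
                       mesh$region == "cerebellum")
  bf <- .tet_faces(.corners(mesh)[brain_sel, , drop = FALSE])
  owner <- brain_sel[bf$owner[match(key_face, bf$key)]]
  lobe <- mesh$region[owner]
  if (anyNA(lobe)) stop("unlabelled intracranial surface faces")
  agg <- function(f) as.numeric(tapply(fp$pressure, lobe, f))
  out <- data.frame(lobe = sort(unique(lobe)),
                    min = agg(min), max = agg(max), mean = agg(mean))
  class(out) <- c("pressure_report", class(out))
  out
}

#' Planar cross-section outline
#'
#' Intersects the outer boundary surface of the mesh with a plane and
#' returns the resulting outline polyline(s).
#'
#' @param mesh a `labeled_mesh`.
#' @param plane `"midsagittal"` (y = 0), `"coronal"` (x = x0), `"axial"`
#'   (z = z0), or a list with `point` and `normal`.
#' @param offset plane offset along its normal for the named planes.
#' @return a matrix of 2-D outline coordinates (in-plane axes), with an
#'   attribute `segments` giving the 3-D segment endpoints; rows of `NA`
#'   separate disconnected loops. An empty matrix is returned (with a
#'   message) when the plane misses the mesh.
#' @export
cross_section <- function(mesh, plane = "midsagittal", offset = 0) {
  if (is.character(plane)) {
    plane <- switch(match.arg(plane, c("midsagittal", "coronal", "axial")),
      midsagittal = list(point = c(0, offset, 0), normal = c(0, 1, 0),
                         axes = rbind(c(1, 0, 0), c(0, 0, 1))),
      coronal = list(point = c(offset, 0, 0), normal = c(1, 0, 0),
                     axes = rbind(c(0, 1, 0), c(0, 0, 1))),
      axial = list(point = c(0, 0, offset), normal = c(0, 0, 1),
                   axes = rbind(c(1, 0, 0), c(0, 1, 0))))
  }
  if (is.null(plane$axes)) {
    n <- plane$normal / sqrt(sum(plane$normal^2))
    a1 <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a1 <- a1 - sum(a1 * n) * n; a1 <- a1 / sqrt(sum(a1^2))
    plane$axes <- rbind(a1, .cross3(n, a1))
  }
  # outer skull surface: when the mesh carries both a skull and an
  # intracranial block, take the boundary of the bone-class elements and
  # keep the faces pointing away from the assembly centre (excludes the
  # inner cavity surface); otherwise use the whole boundary
  cls <- region_class(mesh$region)
  nd <- mesh$nodes
  if (any(cls == "brain") && any(cls != "brain")) {
    shell_ids <- which(cls %in% c("bone", "suture", "craniotomy", "csf"))
    tf <- .tet_faces(.corners(mesh)[shell_ids, , drop = FALSE])
    cnt <- table(tf$key)
    keep <- tf$key %in% names(cnt)[cnt == 1L]
    bf <- tf$faces[keep, , drop = FALSE]
    own <- shell_ids[tf$owner[keep]]
    ctr <- colMeans(nd)
    fc <- (nd[bf[, 1], ] + nd[bf[, 2], ] + nd[bf[, 3], ]) / 3
    ec <- element_centroids(mesh)[own, , drop = FALSE]
    outward <- rowSums(sweep(fc, 2, ctr)^2) > rowSums(sweep(ec, 2, ctr)^2)
    bf <- bf[outward, , drop = FALSE]
  } else {
    bf <- boundary_faces(mesh)
  }
  sd_ <- as.vector((nd %*% plane$normal) - sum(plane$point * plane$normal))
  f1 <- sd_[bf[, 1]]; f2 <- sd_[bf[, 2]]; f3 <- sd_[bf[, 3]]
  cut <- pmax(f1, f2, f3) >= 0 & pmin(f1, f2, f3) <= 0
  if (!any(cut)) {
    message("plane does not intersect the mesh")
    return(matrix(numeric(0), 0, 2))
  }
  segs <- list()
  for (i in which(cut)) {
    vs <- bf[i, ]
    dv <- sd_[vs]
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      d1 <- dv[e[1]]; d2 <- dv[e[2]]
      if ((d1 <= 0 && d2 > 0) || (d1 > 0 && d2 <= 0)) {
        t <- d1 / (d1 - d2)
        pts[[length(pts) + 1L]] <- nd[vs[e[1]], ] +
          t * (nd[vs[e[2]], ] - nd[vs[e[1]], ])
      }
    }
    if (length(pts) == 2)
      segs[[length(segs) + 1L]] <- rbind(pts[[1]], pts[[2]])
  }
  if (!length(segs)) {
    message("plane does not intersect the mesh")
    return(matrix(numeric(0), 0, 2))
  }
  seg3 <- do.call(rbind, segs)
  p2 <- sweep(seg3, 2, plane$point) %*% t(plane$axes)
  # keep only the outermost outline points: project and return as ordered
  # loops via nearest-neighbour chaining of segments
  out <- .chain_segments(p2)
  attr(out, "segments") <- seg3
  out
}

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

# order intersection segments (rows 2k-1, 2k of p2) into polylines
.chain_segments <- function(p2) {
  ns <- nrow(p2) / 2
  used <- rep(FALSE, ns)
  loops <- list()
  tol <- 1e-6 * max(1, diff(range(p2)))
  ends <- function(k) list(a = p2[2 * k - 1, ], b = p2[2 * k, ])
  while (any(!used)) {
    k <- which(!used)[1]; used[k] <- TRUE
    e <- ends(k)
    path <- rbind(e$a, e$b)
    repeat {
      tail_ <- path[nrow(path), ]
      cand <- which(!used)
      if (!length(cand)) break
      da <- vapply(cand, function(j) sum((p2[2 * j - 1, ] - tail_)^2), 0)
      db <- vapply(cand, function(j) sum((p2[2 * j, ] - tail_)^2), 0)
      jbest <- which.min(pmin(da, db))
      if (min(da[jbest], db[jbest]) > tol^2 * 1e6) break
      j <- cand[jbest]; used[j] <- TRUE
      nxt <- if (da[jbest] <= db[jbest]) p2[2 * j, ] else p2[2 * j - 1, ]
      path <- rbind(path, nxt)
    }
    loops[[length(loops) + 1L]] <- path
  }
  out <- NULL
  for (l in loops) out <- rbind(out, l, c(NA, NA))
  out[-nrow(out), , drop = FALSE]
}

.draw_outline <- function(out, ...) {
  graphics::lines(out[, 1], out[, 2], ...)
}

#' Total length of a cross-section outline
#' @param out output of [cross_section()].
#' @return summed polyline length (mm).
#' @export
outline_length <- function(out) {
  if (!nrow(out)) return(0)
  d <- diff(out)
  sum(sqrt(rowSums(d^2)), na.rm = TRUE)
}
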