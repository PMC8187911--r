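#' Labelled tetrahedral mesh
#'
#' The central mesh container of the package: node coordinates in millimetres,
#' linear (4-node) or quadratic (10-node) tetrahedral connectivity, one region
#' label per element (bone plates, sutures, craniotomies, CSF, brain lobes),
#' named node sets (constraint rings, landmarks) and an optional contact-pair
#' registry (slave node set on the intracranial surface, master triangles on
#' the inner calvaria).
#'
#' @param nodes numeric matrix, one row per node, columns x, y, z (mm).
#' @param elems integer matrix, one row per tetrahedron (4 or 10 columns).
#' @param region character vector, one region label per element.
#' @param node_sets named list of integer node-index vectors.
#' @param landmarks named integer vector of landmark node indices.
#' @param contact `NULL` or a list with `slave_nodes` (integer vector) and
#'   `master_tris` (integer matrix, 3 columns).
#' @param order element order, 1 (linear) or 2 (quadratic).
#' @param ossified logical vector per element; converted (bone-formed)
#'   elements keep their original region label but are flagged here.
#' @param params optional list of generation parameters, kept for provenance.
#'
#' @return An object of class `labeled_mesh`.
#' @export
labeled_mesh <- function(nodes, elems, region,
                         node_sets = list(), landmarks = integer(),
                         contact = NULL, order = 1L,
                         ossified = rep(FALSE, nrow(elems)),
                         params = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  stopifnot(ncol(nodes) == 3,
            ncol(elems) == if (order == 1L) 4L else 10L,
            length(region) == nrow(elems),
            length(ossified) == nrow(elems))
  if (nrow(elems) > 0 && (min(elems) < 1L || max(elems) > nrow(nodes)))
    stop("element connectivity refers to nodes outside the coordinate table")
  structure(list(nodes = nodes, elems = elems, region = as.character(region),
                 node_sets = node_sets, landmarks = landmarks,
                 contact = contact, order = as.integer(order),
                 ossified = ossified, params = params),
            class = "labeled_mesh")
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("Labelled tetrahedral mesh (order %d): %d nodes, %d elements\n",
              x$order, nrow(x$nodes), nrow(x$elems)))
  tab <- sort(table(x$region), decreasing = TRUE)
  cat("Regions:\n")
  for (nm in names(tab)) cat(sprintf("  %-22s %6d elements\n", nm, tab[[nm]]))
  if (any(x$ossified))
    cat(sprintf("Ossified elements: %d\n", sum(x$ossified)))
  if (length(x$node_sets))
    cat("Node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  if (length(x$landmarks))
    cat("Landmarks:", paste(names(x$landmarks), collapse = ", "), "\n")
  if (!is.null(x$contact))
    cat(sprintf("Contact pair: %d slave nodes / %d master triangles\n",
                length(x$contact$slave_nodes), nrow(x$contact$master_tris)))
  invisible(x)
}

#' @export
summary.labeled_mesh <- function(object, ...) {
  vols <- tet_volumes(object)
  data.frame(region = names(tapply(vols, object$region, sum)),
             elements = as.integer(table(object$region)[
               names(tapply(vols, object$region, sum))]),
             volume_mm3 = as.numeric(tapply(vols, object$region, sum)),
             row.names = NULL)
}

# corner connectivity regardless of order
.corners <- function(mesh) mesh$elems[, 1:4, drop = FALSE]

#' Signed tetrahedron volumes
#'
#' @param mesh a `labeled_mesh` (or a list with `nodes` and `elems`).
#' @return numeric vector of element volumes in mm^3 (absolute value).
#' @export
tet_volumes <- function(mesh) {
  el <- .corners(mesh); nd <- mesh$nodes
  a <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  b <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  c_ <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  abs(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Element centroids
#' @param mesh a `labeled_mesh`.
#' @return numeric matrix of centroid coordinates (mm), one row per element.
#' @export
element_centroids <- function(mesh) {
  el <- .corners(mesh); nd <- mesh$nodes
  (nd[el[, 1], , drop = FALSE] + nd[el[, 2], , drop = FALSE] +
   nd[el[, 3], , drop = FALSE] + nd[el[, 4], , drop = FALSE]) / 4
}

# All 4 faces of each tet, as a data frame of sorted node triples with the
# owning element index. Used for conformity checks and surface extraction.
.tet_faces <- function(elems) {
  f <- rbind(elems[, c(1, 2, 3)], elems[, c(1, 2, 4)],
             elems[, c(1, 3, 4)], elems[, c(2, 3, 4)])
  owner <- rep(seq_len(nrow(elems)), 4)
  fs <- t(apply(f, 1, sort))
  list(faces = fs, owner = owner,
       key = paste(fs[, 1], fs[, 2], fs[, 3], sep = "_"))
}

#' Check mesh conformity
#'
#' Every interior triangular face must be shared by exactly two tetrahedra and
#' every boundary face by exactly one; element volumes must be positive.
#'
#' @param mesh a `labeled_mesh`.
#' @return `TRUE` invisibly, or an error describing the defect.
#' @export
check_conforming <- function(mesh) {
  if (any(tet_volumes(mesh) <= 0)) stop("degenerate (zero-volume) elements present")
  tf <- .tet_faces(.corners(mesh))
  cnt <- table(tf$key)
  if (any(cnt > 2))
    stop("non-conforming mesh: ", sum(cnt > 2), " faces shared by >2 elements")
  invisible(TRUE)
}

#' Extract the boundary surface of a set of elements
#'
#' Faces belonging to exactly one tetrahedron of the given element subset.
#'
#' @param mesh a `labeled_mesh`.
#' @param elem_ids integer element indices (default: all elements).
#' @return integer matrix of triangles (3 columns of node indices).
#' @export
boundary_faces <- function(mesh, elem_ids = seq_len(nrow(mesh$elems))) {
  el <- .corners(mesh)[elem_ids, , drop = FALSE]
  tf <- .tet_faces(el)
  cnt <- table(tf$key)
  keep <- tf$key %in% names(cnt)[cnt == 1L]
  tf$faces[keep, , drop = FALSE]
}

# Interface faces between two element subsets (shared triangles).
.interface_faces <- function(mesh, ids_a, ids_b) {
  fa <- boundary_faces(mesh, ids_a)
  fb <- boundary_faces(mesh, ids_b)
  ka <- paste(fa[, 1], fa[, 2], fa[, 3], sep = "_")
  kb <- paste(fb[, 1], fb[, 2], fb[, 3], sep = "_")
  fa[ka %in% kb, , drop = FALSE]
}

#' Mirror-symmetry error about the midsagittal plane
#'
#' Reflects all node coordinates about y = 0 and reports the largest distance
#' from a reflected node to its nearest original node.
#'
#' @param mesh a `labeled_mesh`.
#' @return maximum nearest-neighbour distance (mm) of the reflected node set.
#' @export
mirror_symmetry_error <- function(mesh) {
  nd <- mesh$nodes
  refl <- nd; refl[, 2] <- -refl[, 2]
  # block nearest-neighbour search to keep memory bounded
  n <- nrow(nd); err <- numeric(n)
  bs <- 2000L
  for (s in seq(1L, n, by = bs)) {
    idx <- s:min(s + bs - 1L, n)
    d2 <- outer(rowSums(refl[idx, , drop = FALSE]^2), rowSums(nd^2), "+") -
      2 * refl[idx, , drop = FALSE] %*% t(nd)
    err[idx] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  max(err)
}

# ---- element subdivision primitives ----------------------------------------

# Split triangular prisms (rows: bottom a,b,c then top above-a, above-b,
# above-c) into 3 tetrahedra each, with face diagonals chosen through the
# smallest global node index so that adjacent prisms tessellate conformingly.
.split_prisms <- function(P) {
  stopifnot(ncol(P) == 6)
  perms <- rbind(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4), c(3, 1, 2, 6, 4, 5),
                 c(4, 6, 5, 1, 3, 2), c(5, 4, 6, 2, 1, 3), c(6, 5, 4, 3, 2, 1))
  m <- nrow(P)
  imin <- max.col(-P, ties.method = "first")
  Q <- matrix(0L, m, 6)
  for (k in 1:6) Q[, k] <- P[cbind(seq_len(m), perms[imin, k])]
  condA <- pmin(Q[, 2], Q[, 6]) < pmin(Q[, 3], Q[, 5])
  tets <- matrix(0L, 3L * m, 4L)
  ia <- which(condA); ib <- which(!condA)
  if (length(ia)) {
    tets[3 * (ia - 1) + 1, ] <- Q[ia, c(1, 2, 3, 6), drop = FALSE]
    tets[3 * (ia - 1) + 2, ] <- Q[ia, c(1, 2, 6, 5), drop = FALSE]
    tets[3 * (ia - 1) + 3, ] <- Q[ia, c(1, 5, 6, 4), drop = FALSE]
  }
  if (length(ib)) {
    tets[3 * (ib - 1) + 1, ] <- Q[ib, c(1, 2, 3, 5), drop = FALSE]
    tets[3 * (ib - 1) + 2, ] <- Q[ib, c(1, 5, 3, 6), drop = FALSE]
    tets[3 * (ib - 1) + 3, ] <- Q[ib, c(1, 5, 6, 4), drop = FALSE]
  }
  tets
}

# Split quads (rows: cyclic n1,n2,n3,n4) into 2 triangles, diagonal through
# the smallest node index (conforming across shared edges).
.split_quads <- function(Q) {
  m <- nrow(Q)
  imin <- max.col(-Q, ties.method = "first")
  d13 <- imin == 1L | imin == 3L
  tris <- matrix(0L, 2L * m, 3L)
  i1 <- which(d13); i2 <- which(!d13)
  if (length(i1)) {
    tris[2 * (i1 - 1) + 1, ] <- Q[i1, c(1, 2, 3), drop = FALSE]
    tris[2 * (i1 - 1) + 2, ] <- Q[i1, c(1, 3, 4), drop = FALSE]
  }
  if (length(i2)) {
    tris[2 * (i2 - 1) + 1, ] <- Q[i2, c(2, 3, 4), drop = FALSE]
    tris[2 * (i2 - 1) + 2, ] <- Q[i2, c(2, 4, 1), drop = FALSE]
  }
  tris
}

# Orient all tets to positive signed volume (swap last two corners).
.orient_tets <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  c_ <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  neg <- det < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  tets
}

#' Structured box mesh
#'
#' Axis-aligned box meshed with a regular grid of hexahedra, each split into
#' conforming tetrahedra. Used for solver benchmarks and 1-D front fixtures.
#'
#' @param lengths box edge lengths (mm), length-3 vector.
#' @param n number of cells per direction, length-3 integer vector.
#' @param origin coordinates of the box corner (default the origin).
#' @param region label given to every element.
#' @return a `labeled_mesh`.
#' @export
box_mesh <- function(lengths = c(1, 1, 1), n = c(2, 2, 2),
                     origin = c(0, 0, 0), region = "solid") {
  n <- as.integer(n)
  xs <- seq(origin[1], origin[1] + lengths[1], length.out = n[1] + 1)
  ys <- seq(origin[2], origin[2] + lengths[2], length.out = n[2] + 1)
  zs <- seq(origin[3], origin[3] + lengths[3], length.out = n[3] + 1)
  nid <- function(i, j, k) ((k - 1) * (n[2] + 1) + (j - 1)) * (n[1] + 1) + i
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  colnames(nodes) <- NULL
  # split each hex into two prisms sharing the (i,j)->(i+1,j+1) vertical wall,
  # then use the conforming prism splitter
  ij <- expand.grid(i = seq_len(n[1]), j = seq_len(n[2]), k = seq_len(n[3]))
  i <- ij$i; j <- ij$j; k <- ij$k
  v000 <- nid(i, j, k);     v100 <- nid(i + 1, j, k)
  v010 <- nid(i, j + 1, k); v110 <- nid(i + 1, j + 1, k)
  v001 <- nid(i, j, k + 1);     v101 <- nid(i + 1, j, k + 1)
  v011 <- nid(i, j + 1, k + 1); v111 <- nid(i + 1, j + 1, k + 1)
  prisms <- rbind(cbind(v000, v100, v110, v001, v101, v111),
                  cbind(v000, v110, v010, v001, v111, v011))
  tets <- .orient_tets(nodes, .split_prisms(prisms))
  labeled_mesh(nodes, tets, rep(region, nrow(tets)))
}
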