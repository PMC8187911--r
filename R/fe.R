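# Small-strain isotropic linear elasticity on tetrahedra, with growth loading
# through the thermal-expansion analogy: a prescribed isotropic stress-free
# strain alpha*I on growing regions, assembled as an initial-strain load.

# Constant shape-function gradients of linear tets.
# Returns list of four M x 3 matrices (gradient of N_i per element) and V.
.tet4_grads <- function(nodes, elems) {
  x1 <- nodes[elems[, 1], , drop = FALSE]
  a <- nodes[elems[, 2], , drop = FALSE] - x1
  b <- nodes[elems[, 3], , drop = FALSE] - x1
  c_ <- nodes[elems[, 4], , drop = FALSE] - x1
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  if (any(abs(det) < 1e-14))
    stop("degenerate tetrahedron in mesh (zero volume)")
  # rows of inv(A) where A has columns (a, b, c): cross products / det
  r1 <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1]) / det
  r2 <- cbind(c_[, 2] * a[, 3] - c_[, 3] * a[, 2],
              c_[, 3] * a[, 1] - c_[, 1] * a[, 3],
              c_[, 1] * a[, 2] - c_[, 2] * a[, 1]) / det
  r3 <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1]) / det
  list(g = list(-(r1 + r2 + r3), r1, r2, r3), V = abs(det) / 6)
}

#' Assemble the linear-elastic system
#'
#' Builds the global stiffness matrix and the growth (thermal-analogy) load
#' vector for a labelled tetrahedral mesh. All materials are linear isotropic;
#' the load vector is the assembly of the isotropic stress-free strain
#' `alpha * I` over the elements flagged as growing.
#'
#' @param mesh a `labeled_mesh` (order 1 or 2).
#' @param materials a `material_card`; every region label present in the mesh
#'   must resolve to a material.
#' @param alpha either a single number (applied to the growing material
#'   classes of `materials`) or a per-element numeric vector of stress-free
#'   strains.
#' @return list with `K` (sparse symmetric stiffness, 3N x 3N), `f` (growth
#'   load vector), and the per-element `E`, `nu`, `alpha` actually used.
#' @export
fe_assemble <- function(mesh, materials, alpha = 0) {
  mat <- .resolve_materials(mesh, materials)
  m <- nrow(mesh$elems)
  if (length(alpha) == 1L) alpha <- ifelse(mat$grows, alpha, 0)
  stopifnot(length(alpha) == m)
  lam <- mat$E * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu))
  mu <- mat$E / (2 * (1 + mat$nu))
  ndof <- 3L * nrow(mesh$nodes)
  if (mesh$order == 1L) {
    gr <- .tet4_grads(mesh$nodes, mesh$elems)
    g <- gr$g; V <- gr$V
    ntrip <- 144L * m
    I <- integer(ntrip); J <- integer(ntrip); X <- numeric(ntrip)
    pos <- 0L
    kap <- (3 * lam + 2 * mu) * alpha * V
    fI <- integer(12L * m); fX <- numeric(12L * m); fpos <- 0L
    for (i in 1:4) {
      di <- 3L * (mesh$elems[, i] - 1L)
      for (r in 1:3) {
        fI[fpos + seq_len(m)] <- di + r
        fX[fpos + seq_len(m)] <- kap * g[[i]][, r]
        fpos <- fpos + m
      }
    }
    f <- .scatter(fI, fX, ndof)
    for (i in 1:4) for (j in 1:4) {
      gi <- g[[i]]; gj <- g[[j]]
      dij <- gi[, 1] * gj[, 1] + gi[, 2] * gj[, 2] + gi[, 3] * gj[, 3]
      di <- 3L * (mesh$elems[, i] - 1L); dj <- 3L * (mesh$elems[, j] - 1L)
      for (r in 1:3) for (s in 1:3) {
        val <- V * (lam * gi[, r] * gj[, s] + mu * gi[, s] * gj[, r] +
                      if (r == s) mu * dij else 0)
        idx <- pos + seq_len(m)
        I[idx] <- di + r; J[idx] <- dj + s; X[idx] <- val
        pos <- pos + m
      }
    }
    K <- Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(ndof, ndof))
  } else {
    K <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(ndof, ndof))
    f <- numeric(ndof)
    qp <- .tet10_quadrature()
    trip_i <- vector("list", m); trip_j <- vector("list", m)
    trip_x <- vector("list", m)
    for (e in seq_len(m)) {
      ke <- .tet10_element(mesh$nodes[mesh$elems[e, ], ], lam[e], mu[e],
                           alpha[e], qp)
      dofs <- as.vector(t(cbind(3L * (mesh$elems[e, ] - 1L) + 1L,
                                3L * (mesh$elems[e, ] - 1L) + 2L,
                                3L * (mesh$elems[e, ] - 1L) + 3L)))
      trip_i[[e]] <- rep(dofs, each = 30L)
      trip_j[[e]] <- rep(dofs, times = 30L)
      trip_x[[e]] <- as.vector(t(ke$K))
      f[dofs] <- f[dofs] + ke$f
    }
    K <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                              x = unlist(trip_x), dims = c(ndof, ndof))
  }
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  list(K = K, f = f, E = mat$E, nu = mat$nu, alpha = alpha)
}

# 4-point quadrature for quadratic tets (degree-2 exact)
.tet10_quadrature <- function() {
  a <- 0.5854101966249685; b <- 0.1381966011250105
  pts <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  list(L = pts, w = rep(0.25, 4))
}

# Quadratic tet element stiffness/force; edge-node order (12)(23)(31)(14)(24)(34)
.tet10_element <- function(X, lam, mu, alpha, qp) {
  g4 <- .tet4_grads(matrix(X[1:4, ], 4, 3), matrix(1:4, 1))
  gL <- rbind(g4$g[[1]][1, ], g4$g[[2]][1, ], g4$g[[3]][1, ], g4$g[[4]][1, ])
  V <- g4$V[1]
  edges <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam; diag(D)[1:3] <- lam + 2 * mu; diag(D)[4:6] <- mu
  K <- matrix(0, 30, 30); f <- numeric(30)
  e0 <- alpha * c(1, 1, 1, 0, 0, 0)
  for (q in seq_along(qp$w)) {
    L <- qp$L[q, ]
    gN <- matrix(0, 10, 3)
    for (i in 1:4) gN[i, ] <- (4 * L[i] - 1) * gL[i, ]
    for (k in 1:6) {
      i <- edges[k, 1]; j <- edges[k, 2]
      gN[4 + k, ] <- 4 * (L[i] * gL[j, ] + L[j] * gL[i, ])
    }
    B <- matrix(0, 6, 30)
    for (i in 1:10) {
      c0 <- 3 * (i - 1)
      B[1, c0 + 1] <- gN[i, 1]; B[2, c0 + 2] <- gN[i, 2]; B[3, c0 + 3] <- gN[i, 3]
      B[4, c0 + 1] <- gN[i, 2]; B[4, c0 + 2] <- gN[i, 1]
      B[5, c0 + 2] <- gN[i, 3]; B[5, c0 + 3] <- gN[i, 2]
      B[6, c0 + 1] <- gN[i, 3]; B[6, c0 + 3] <- gN[i, 1]
    }
    wV <- qp$w[q] * V
    K <- K + wV * t(B) %*% D %*% B
    f <- f + wV * t(B) %*% (D %*% e0)
  }
  list(K = K, f = as.vector(f))
}

#' Convert a linear mesh to quadratic tetrahedra
#'
#' Inserts midside nodes on every unique edge.
#'
#' @param mesh a `labeled_mesh` of order 1.
#' @return a `labeled_mesh` of order 2 (node sets and landmarks preserved).
#' @export
as_tet10 <- function(mesh) {
  stopifnot(mesh$order == 1L)
  el <- mesh$elems
  edges <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 1)],
                 el[, c(1, 4)], el[, c(2, 4)], el[, c(3, 4)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  uk <- !duplicated(key)
  mid_id <- match(key, key[uk]) + nrow(mesh$nodes)
  mids <- (mesh$nodes[edges[uk, 1], , drop = FALSE] +
           mesh$nodes[edges[uk, 2], , drop = FALSE]) / 2
  m <- nrow(el)
  el10 <- cbind(el, matrix(mid_id, m, 6))
  labeled_mesh(rbind(mesh$nodes, mids), el10, mesh$region,
               node_sets = mesh$node_sets, landmarks = mesh$landmarks,
               contact = mesh$contact, order = 2L, ossified = mesh$ossified,
               params = mesh$params)
}

#' Element strains from a displacement field
#'
#' Computes the small-strain tensor per element (evaluated at the centroid;
#' averaged over quadrature points for quadratic elements) and the hydrostatic
#' strain, the mean of the principal strains `tr(eps)/3`.
#'
#' @param mesh a `labeled_mesh`.
#' @param u displacement vector (3 entries per node) or N x 3 matrix.
#' @return list with `eps` (M x 6 matrix: xx, yy, zz, xy, yz, xz tensor
#'   components) and `eh` (hydrostatic strain per element).
#' @export
compute_strains <- function(mesh, u) {
  if (is.matrix(u)) u <- as.vector(t(u))
  stopifnot(length(u) == 3 * nrow(mesh$nodes))
  U <- matrix(u, ncol = 3, byrow = TRUE)
  if (mesh$order == 1L) {
    gr <- .tet4_grads(mesh$nodes, mesh$elems)
    m <- nrow(mesh$elems)
    H <- array(0, c(m, 3, 3))  # H[, r, s] = du_r/dx_s
    for (i in 1:4) {
      ui <- U[mesh$elems[, i], , drop = FALSE]
      for (r in 1:3) for (s in 1:3)
        H[, r, s] <- H[, r, s] + ui[, r] * gr$g[[i]][, s]
    }
    eps <- cbind(H[, 1, 1], H[, 2, 2], H[, 3, 3],
                 (H[, 1, 2] + H[, 2, 1]) / 2,
                 (H[, 2, 3] + H[, 3, 2]) / 2,
                 (H[, 1, 3] + H[, 3, 1]) / 2)
  } else {
    m <- nrow(mesh$elems)
    qp <- .tet10_quadrature()
    eps <- matrix(0, m, 6)
    edges <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
    for (e in seq_len(m)) {
      X <- mesh$nodes[mesh$elems[e, ], ]
      g4 <- .tet4_grads(matrix(X[1:4, ], 4, 3), matrix(1:4, 1))
      gL <- rbind(g4$g[[1]][1, ], g4$g[[2]][1, ], g4$g[[3]][1, ], g4$g[[4]][1, ])
      acc <- numeric(6)
      for (q in seq_along(qp$w)) {
        L <- qp$L[q, ]
        gN <- matrix(0, 10, 3)
        for (i in 1:4) gN[i, ] <- (4 * L[i] - 1) * gL[i, ]
        for (k in 1:6) {
          i <- edges[k, 1]; j <- edges[k, 2]
          gN[4 + k, ] <- 4 * (L[i] * gL[j, ] + L[j] * gL[i, ])
        }
        Hq <- t(U[mesh$elems[e, ], , drop = FALSE]) %*% gN
        acc <- acc + qp$w[q] * c(Hq[1, 1], Hq[2, 2], Hq[3, 3],
                                 (Hq[1, 2] + Hq[2, 1]) / 2,
                                 (Hq[2, 3] + Hq[3, 2]) / 2,
                                 (Hq[1, 3] + Hq[3, 1]) / 2)
      }
      eps[e, ] <- acc
    }
  }
  colnames(eps) <- c("xx", "yy", "zz", "xy", "yz", "xz")
  list(eps = eps, eh = rowSums(eps[, 1:3, drop = FALSE]) / 3)
}

# Solve K u = f with prescribed dofs (reduction / back-substitution).
.solve_dirichlet <- function(K, f, fixed_dofs, fixed_vals = NULL) {
  ndof <- length(f)
  fixed_dofs <- as.integer(fixed_dofs)
  if (is.null(fixed_vals)) fixed_vals <- numeric(length(fixed_dofs))
  free <- setdiff(seq_len(ndof), fixed_dofs)
  u <- numeric(ndof)
  u[fixed_dofs] <- fixed_vals
  rhs <- f[free]
  if (any(fixed_vals != 0))
    rhs <- rhs - as.vector(K[free, fixed_dofs, drop = FALSE] %*% fixed_vals)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  u[free] <- as.vector(Matrix::solve(Kff, rhs, sparse = TRUE))
  u
}

# All-dof constraint indices for a set of nodes.
.node_dofs <- function(nodes) as.vector(t(cbind(3L * (nodes - 1L) + 1L,
                                                3L * (nodes - 1L) + 2L,
                                                3L * (nodes - 1L) + 3L)))
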