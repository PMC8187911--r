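# Node-to-surface penalty contact with penalty-regularised Coulomb friction.
# Slave nodes (intracranial surface) are projected onto master triangles
# (inner calvaria); interpenetration is resisted by springs of per-area
# stiffness k_n, tangential relative motion by springs of per-area stiffness
# k_t whose secant stiffness is scaled down until the Coulomb cap
# |t| <= mu * p is met.

#' Contact specification
#'
#' Parameters of the penalty frictional contact between the intracranial
#' volume and the inner calvaria.
#'
#' @param friction Coulomb friction coefficient (dimensionless).
#' @param normal_stiffness normal penalty stiffness. In the default
#'   `"absolute"` mode this is an absolute per-unit-area penalty in
#'   N/mm per mm^2, i.e. contact pressure (MPa) = stiffness x penetration
#'   (mm); in `"factor"` mode it multiplies a characteristic elastic
#'   stiffness of the softer contacting material.
#' @param penetration_tol admissible penetration (mm in `"absolute"` mode).
#' @param tangential_stiffness tangential penalty (stick) stiffness of the
#'   regularised Coulomb model. Defaults to 5\% of the normal stiffness: the
#'   Coulomb cap `mu * p` is what limits the transmitted shear, so the stick
#'   stiffness only sets the slip-regularisation scale and a softer spring
#'   keeps the frictional return mapping well contracted.
#' @param stiffness_mode `"absolute"` or `"factor"`.
#' @return an object of class `contact_spec`.
#' @export
contact_spec <- function(friction = 0.1, normal_stiffness = 600,
                         penetration_tol = 0.5,
                         tangential_stiffness = 0.05 * normal_stiffness,
                         stiffness_mode = c("absolute", "factor")) {
  stiffness_mode <- match.arg(stiffness_mode)
  stopifnot(friction >= 0, normal_stiffness > 0, penetration_tol > 0,
            tangential_stiffness >= 0)
  structure(list(friction = friction, normal_stiffness = normal_stiffness,
                 penetration_tol = penetration_tol,
                 tangential_stiffness = tangential_stiffness,
                 stiffness_mode = stiffness_mode),
            class = "contact_spec")
}

#' @export
print.contact_spec <- function(x, ...) {
  cat(sprintf(paste0("Penalty contact: mu = %.3g, k_n = %.4g (%s), ",
                     "k_t = %.4g, penetration tol = %.3g mm\n"),
              x$friction, x$normal_stiffness, x$stiffness_mode,
              x$tangential_stiffness, x$penetration_tol))
  invisible(x)
}

# Vectorised closest point on triangle (Ericson, Real-Time Collision
# Detection). P, A, B, C: n x 3. Returns closest points Q and barycentric
# weights W (n x 3).
.closest_point_tri <- function(P, A, B, C) {
  n <- nrow(P)
  dot <- function(u, v) rowSums(u * v)
  ab <- B - A; ac <- C - A; ap <- P - A
  d1 <- dot(ab, ap); d2 <- dot(ac, ap)
  bp <- P - B; d3 <- dot(ab, bp); d4 <- dot(ac, bp)
  cp <- P - C; d5 <- dot(ab, cp); d6 <- dot(ac, cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  W <- matrix(0, n, 3)
  done <- rep(FALSE, n)
  assign_w <- function(mask, w1, w2, w3) {
    m <- mask & !done
    if (any(m)) {
      W[m, 1] <<- w1[m]; W[m, 2] <<- w2[m]; W[m, 3] <<- w3[m]
      done[m] <<- TRUE
    }
  }
  one <- rep(1, n); zero <- rep(0, n)
  assign_w(d1 <= 0 & d2 <= 0, one, zero, zero)                       # vertex A
  assign_w(d3 >= 0 & d4 <= d3, zero, one, zero)                      # vertex B
  v_ab <- d1 / (d1 - d3)
  assign_w(vc <= 0 & d1 >= 0 & d3 <= 0, 1 - v_ab, v_ab, zero)        # edge AB
  assign_w(d6 >= 0 & d5 <= d6, zero, zero, one)                      # vertex C
  w_ac <- d2 / (d2 - d6)
  assign_w(vb <= 0 & d2 >= 0 & d6 <= 0, 1 - w_ac, zero, w_ac)        # edge AC
  w_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  assign_w(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
           zero, 1 - w_bc, w_bc)                                     # edge BC
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  assign_w(rep(TRUE, n), 1 - v - w, v, w)                            # interior
  Q <- A * W[, 1] + B * W[, 2] + C * W[, 3]
  list(Q = Q, W = W)
}

# Master-surface topology used by the node-to-node pairing: the unique
# master vertices and, per vertex, its incident master triangles (for
# area-averaged vertex normals).
.contact_candidates <- function(coords, contact) {
  mt <- contact$master_tris
  mverts <- sort(unique(as.vector(mt)))
  inc <- split(rep(seq_len(nrow(mt)), 3), match(as.vector(mt), mverts))
  # vertices on the open boundary of the master surface (e.g. the foramen
  # magnum rim): their averaged normals are skewed, so pairs against them
  # are not penalised
  ed <- rbind(mt[, c(1, 2)], mt[, c(2, 3)], mt[, c(3, 1)])
  ek <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(ek)
  rim <- unique(as.vector(ed[ek %in% names(cnt)[cnt == 1L], ]))
  list(mverts = mverts, inc = inc, rim = rim)
}

# Tributary area per slave node from the slave surface triangles.
.slave_areas <- function(coords, contact) {
  st <- contact$slave_tris
  a <- coords[st[, 2], , drop = FALSE] - coords[st[, 1], , drop = FALSE]
  b <- coords[st[, 3], , drop = FALSE] - coords[st[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  tri_area <- sqrt(rowSums(cr^2)) / 2
  A <- numeric(length(contact$slave_nodes))
  pos <- match(as.vector(st), contact$slave_nodes)
  ok <- !is.na(pos)
  acc <- tapply(rep(tri_area / 3, 3)[ok], pos[ok], sum)
  A[as.integer(names(acc))] <- acc
  A
}

# Pair every slave node with its nearest master vertex at the given
# coordinates (the surfaces are generated coincident with matching grids, so
# node-to-node pairing is the natural discretisation). The contact normal is
# the area-weighted average of the normals of the master triangles incident
# to the paired vertex, oriented away from the cavity `centre`; penetration
# is the normal component of the slave-master offset (positive = slave
# beyond the master surface, i.e. interpenetrating the shell).
.contact_project <- function(coords, contact, cand, centre) {
  sl <- contact$slave_nodes
  ns <- length(sl)
  mverts <- cand$mverts
  S <- coords[sl, , drop = FALSE]
  MV <- coords[mverts, , drop = FALSE]
  nearest <- integer(ns)
  bs <- 2000L
  for (s0 in seq(1L, ns, by = bs)) {
    idx <- s0:min(s0 + bs - 1L, ns)
    d2 <- outer(rowSums(S[idx, , drop = FALSE]^2), rowSums(MV^2), "+") -
      2 * S[idx, , drop = FALSE] %*% t(MV)
    nearest[idx] <- max.col(-d2, ties.method = "first")
  }
  # area-weighted vertex normals of the master surface
  mt <- contact$master_tris
  a <- coords[mt[, 2], , drop = FALSE] - coords[mt[, 1], , drop = FALSE]
  b <- coords[mt[, 3], , drop = FALSE] - coords[mt[, 1], , drop = FALSE]
  tn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])   # |tn| = 2 x area
  vn <- matrix(0, length(mverts), 3)
  vi <- match(as.vector(mt), mverts)           # stacked tri vertices
  for (c_ in 1:3) {
    acc <- tapply(rep(tn[, c_], 3), vi, sum)
    vn[as.integer(names(acc)), c_] <- acc
  }
  nrm <- vn[nearest, , drop = FALSE]
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-300)
  m_id <- mverts[nearest]
  Q <- coords[m_id, , drop = FALSE]
  out <- Q - matrix(centre, ns, 3, byrow = TRUE)
  flip <- rowSums(nrm * out) < 0
  nrm[flip, ] <- -nrm[flip, ]
  pen <- rowSums(nrm * (S - Q))
  # reuse the triangle-based layout: all three "master" slots point at the
  # paired vertex with full weight on the first
  list(masters = cbind(m_id, m_id, m_id),
       W = cbind(rep(1, ns), rep(0, ns), rep(0, ns)),
       n = nrm, pen = pen, on_rim = m_id %in% cand$rim)
}

# Smooth unilateral penalty law: contact pressure (MPa) as a function of
# penetration (mm), a softplus with width `w` so the force is C-infinity,
# strictly repulsive, ~kn*pen for pen >> w and exponentially small for open
# gaps. `.contact_law` returns the pressure and its derivative (stiffness).
.contact_law <- function(pen, kn, w) {
  x <- pen / w
  p <- ifelse(x > 30, kn * pen, kn * w * log1p(exp(pmin(x, 30))))
  k <- kn / (1 + exp(-pmax(pmin(x, 40), -40)))
  list(p = p, k = k)
}

# Assemble penalty stiffness triplets and force for the current pairing:
# the consistent Newton linearisation of the smooth unilateral normal law
# about the anchor displacement u, plus tangential springs with the
# per-slave secant stiffness ktv (the regularised Coulomb model of the
# caller). kn_pair is the per-slave normal penalty (already capped by the
# local master stiffness; 0 excludes the pair).
.assemble_contact <- function(contact, proj, A, kn_pair, ktv, u, w) {
  sl <- contact$slave_nodes
  idx <- which(kn_pair > 0 & A > 0)
  if (!length(idx)) return(list(K = NULL, f = NULL))
  U <- matrix(u, ncol = 3, byrow = TRUE)
  nI <- length(idx)
  nodes4 <- cbind(sl[idx], proj$masters[idx, , drop = FALSE])  # nI x 4
  cw <- cbind(1, -proj$W[idx, , drop = FALSE])                 # nI x 4
  n_ <- proj$n[idx, , drop = FALSE]
  law <- .contact_law(proj$pen[idx], kn_pair[idx],
                      if (length(w) > 1) w[idx] else w)
  kA_n <- law$k * A[idx]
  kA_t <- ktv[idx] * A[idx]
  rel <- U[nodes4[, 1], , drop = FALSE]
  for (k in 2:4) rel <- rel + cw[, k] * U[nodes4[, k], , drop = FALSE]
  eua <- rowSums(n_ * rel)
  # force at anchor minus the stiffness part already carried by K * u
  Foff <- law$p * A[idx] - kA_n * eua
  I <- integer(144L * nI); J <- integer(144L * nI); X <- numeric(144L * nI)
  fI <- integer(12L * nI); fX <- numeric(12L * nI)
  pos <- 0L; fpos <- 0L
  for (a_ in 1:4) for (r in 1:3) {
    da <- 3L * (nodes4[, a_] - 1L) + r
    fX[fpos + seq_len(nI)] <- -Foff * cw[, a_] * n_[, r]
    fI[fpos + seq_len(nI)] <- da
    fpos <- fpos + nI
    for (b_ in 1:4) for (s in 1:3) {
      db <- 3L * (nodes4[, b_] - 1L) + s
      Prs <- (r == s) - n_[, r] * n_[, s]
      val <- cw[, a_] * cw[, b_] *
        (kA_n * n_[, r] * n_[, s] + kA_t * Prs)
      rng <- pos + seq_len(nI)
      I[rng] <- da; J[rng] <- db; X[rng] <- val
      pos <- pos + nI
    }
  }
  list(K = list(i = I, j = J, x = X), f = list(i = fI, x = fX))
}
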