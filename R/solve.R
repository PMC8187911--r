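# Quasi-static solve of one growth (sub-)increment: linear elasticity with
# growth loading, nodal constraints, and fixed-point iteration over the
# penalty contact active set, projections and Coulomb caps.

#' Solve one quasi-static increment
#'
#' Assembles and solves the linear-elastic system for the current mesh
#' geometry under a growth strain, with all-dof nodal constraints and
#' optional penalty frictional contact. The contact problem is solved by a
#' fixed-point iteration: node-to-node pairing, averaged master normals, the
#' smooth (sigmoid) activation of the normal penalty springs and the secant
#' stiffness of the tanh-regularised Coulomb friction are refreshed each
#' round until the displacement field is stationary and tangential tractions
#' respect the friction cone.
#'
#' @param mesh a `labeled_mesh` (order 1 for contact solves).
#' @param materials a `material_card`.
#' @param alpha growth strain for this increment: scalar (applied to growing
#'   material classes) or per-element vector.
#' @param constraints character vector of node-set names to fix in all dofs,
#'   or an integer vector of dof indices, or `NULL` to use the mesh's
#'   `foramen_magnum_ring` and `nasion` sets when present. With no
#'   constraints at all, a vanishingly weak spring regularisation anchors the
#'   rigid-body modes (free-growth solves).
#' @param contact a `contact_spec`, or `NULL` to ignore the mesh's contact
#'   pair.
#' @param rtol relative stationarity tolerance of the contact fixed-point
#'   iteration (fraction of the peak increment displacement).
#' @param max_iters maximum fixed-point rounds (error if exceeded).
#' @return an object of class `sim_state`: displacement `u` (N x 3), element
#'   strain tensors `eps`, hydrostatic strain `eh`, and a `contact` list with
#'   per-slave-node pressure (MPa), penetration (mm), tangential traction and
#'   activity, plus iteration diagnostics.
#' @export
solve_increment <- function(mesh, materials, alpha = 0, constraints = NULL,
                            contact = NULL, rtol = 2e-3, max_iters = 80L,
                            warm = NULL) {
  if (!is.null(contact) && is.null(mesh$contact))
    stop("contact requested but the mesh has no registered contact pair")
  asm <- fe_assemble(mesh, materials, alpha)
  ndof <- length(asm$f)
  fixed <- .resolve_constraints(mesh, constraints)
  regularise <- length(fixed) == 0L
  Kbase <- asm$K
  if (regularise || !is.null(contact)) {
    # weak springs: anchor rigid-body modes of free solves and of contact-only
    # coupled blocks (e.g. a frictionless intracranial volume)
    eps_reg <- (if (regularise) 1e-9 else 1e-11) * max(Matrix::diag(Kbase))
    Kbase <- Kbase + Matrix::Diagonal(ndof, eps_reg)
  }
  if (is.null(contact)) {
    u <- .solve_dirichlet(Kbase, asm$f, fixed)
    st <- compute_strains(mesh, u)
    return(structure(list(u = matrix(u, ncol = 3, byrow = TRUE),
                          eps = st$eps, eh = st$eh, contact = NULL,
                          iterations = 1L, converged = TRUE),
                     class = "sim_state"))
  }
  cp <- mesh$contact
  coords <- mesh$nodes
  centre <- colMeans(coords[cp$slave_nodes, , drop = FALSE])
  cand <- .contact_candidates(coords, cp)
  A <- .slave_areas(coords, cp)
  kn <- .contact_kn(contact, mesh, materials)
  # cap the penalty per master vertex at twice the local structural
  # stiffness E/h of the adjacent master-side elements: a penalty much
  # stiffer than a compliant substructure (a 30 MPa suture or craniotomy
  # strip) destabilises the staggered update without adding accuracy; the
  # resulting penetrations stay well inside the penetration tolerance
  kn_node <- .master_stiffness_cap(mesh, materials, kn)
  # frictionless contact carries no tangential spring at all; with friction,
  # stick is penalised at kt and the Coulomb cap enforced by radial return
  kt <- if (contact$friction == 0) 0 else
    contact$tangential_stiffness / contact$normal_stiffness * kn
  # small always-on tangential stiffness, outside the Coulomb return map:
  # anchors the otherwise neutral rigid-rotation modes of a frictionless
  # contact-held body (adds a spurious shear ~0.1% of the normal penalty)
  kt_stab <- 1e-3 * kn
  ns <- length(cp$slave_nodes)
  u <- numeric(ndof)
  free <- setdiff(seq_len(ndof), fixed)
  converged <- FALSE
  du <- Inf
  mu <- contact$friction
  # per-slave secant tangential stiffness of the tanh-regularised Coulomb
  # model: tau = mu*p * tanh(kt*slip / (mu*p)), sticking at kt for small
  # slip and saturating at the Coulomb cap for large slip
  kt_sec <- rep(kt, ns)
  # width of the smooth unilateral penalty law (mm), per pair: chosen so
  # the smoothing toe has a fixed force scale (kn * w = 3 MPa) - narrow for
  # stiff bone-backed pairs (small pressure bias), wide for stiffness-capped
  # compliant pairs (covers their working penetration band and keeps the
  # fixed point free of activation discontinuities)
  law_force_scale <- 3
  if (!is.null(warm)) {       # warm start from a comparable previous solve
    if (!is.null(warm$u) && length(warm$u) == ndof) u <- warm$u
    if (!is.null(warm$kt_sec) && length(warm$kt_sec) == ns)
      kt_sec <- pmin(warm$kt_sec, kt)
  }
  rel_slip <- function(U, proj) {
    rel <- U[cp$slave_nodes, , drop = FALSE]
    for (k in 1:3)
      rel <- rel - proj$W[, k] * U[proj$masters[, k], , drop = FALSE]
    rel
  }
  it <- 0L
  omega <- 1          # adaptive damping of the fixed-point update
  du_prev <- Inf
  stall_count <- 0L
  stalled <- FALSE
  pmean_hist <- rep(NA_real_, 12)
  # per-node auto-stabilisation: nodes whose penetration oscillates with
  # sign-alternating jumps get their penalty softened locally (their
  # smoothing band widens accordingly, which breaks the limit cycle)
  kn_scale <- rep(1, ns)
  pen_prev <- rep(0, ns)
  dpen_prev <- rep(0, ns)
  kn_pair <- rep(kn, ns)
  proj <- NULL
  for (it in seq_len(max_iters)) {
    U <- matrix(u, ncol = 3, byrow = TRUE)
    proj <- .contact_project(coords + U, cp, cand, centre)
    kn_pair <- kn_node[proj$masters[, 1]] * kn_scale
    kn_pair[proj$on_rim] <- 0    # no penalty against open-boundary vertices
    # pairing trust region: an apparent penetration far beyond anything a
    # resisted contact can produce is a geometric misclassification (e.g.
    # tissue herniating through the foramen magnum pairing with vertices
    # beside the rim) - such pairs carry no penalty
    kn_pair[proj$pen > 4 * contact$penetration_tol] <- 0
    # width bounded above so near-zero-stiffness pairs do not acquire a
    # finite toe force they cannot bear
    law_w <- pmin(law_force_scale / pmax(kn_pair, 1e-8), 0.5)
    ac <- .assemble_contact(cp, proj, A, kn_pair, kt_sec + kt_stab, u, law_w)
    if (is.null(ac$K))
      stop("no active contact pairs; check the contact surfaces")
    K <- Kbase + Matrix::forceSymmetric(Matrix::sparseMatrix(
      i = ac$K$i, j = ac$K$j, x = ac$K$x, dims = c(ndof, ndof)))
    f <- asm$f + .scatter(ac$f$i, ac$f$x, ndof)
    u_new <- numeric(ndof)
    u_new[free] <- as.vector(Matrix::solve(
      Matrix::Cholesky(Matrix::forceSymmetric(K[free, free, drop = FALSE]),
                       LDL = FALSE), f[free], system = "A"))
    Un <- matrix(u_new, ncol = 3, byrow = TRUE)
    rel <- rel_slip(Un, proj)
    rel0 <- rel_slip(U, proj)
    pen_new <- proj$pen + rowSums(proj$n * (rel - rel0))
    p_new <- .contact_law(pen_new, kn_pair, law_w)$p
    dpen <- pen_new - pen_prev
    osc <- it > 3L & dpen * dpen_prev < 0 & abs(dpen) > 0.05 &
      abs(dpen_prev) > 0.05
    if (any(osc)) kn_scale[osc] <- pmax(kn_scale[osc] * 0.6, 0.01)
    pen_prev <- pen_new
    dpen_prev <- dpen
    t_vec <- rel - rowSums(proj$n * rel) * proj$n
    slip <- sqrt(rowSums(t_vec^2))
    cap <- mu * p_new
    tau_target <- ifelse(cap > 0, cap * tanh(kt * slip / pmax(cap, 1e-12)), 0)
    kt_new <- ifelse(slip > 1e-9, tau_target / slip, kt)
    # soften freely, stiffen at most 2x per round (stability)
    kt_sec <- pmin(kt_new, 2 * kt_sec)
    viol <- max(c(0, kt_sec * slip - cap))
    du <- max(abs(u_new - u)) / max(max(abs(u_new)), 1e-12)
    # damp only when the iteration truly stalls (kills marginal limit
    # cycles without slowing healthy geometric convergence)
    if (it > 5L && du > 0.9 * du_prev) omega <- max(0.2, omega * 0.75)
    else if (du < 0.5 * du_prev) omega <- min(1, omega * 1.25)
    du_prev <- du
    u <- u + omega * (u_new - u)
    cap_ok <- viol < 0.05 * mu * max(p_new) + 1e-6
    if (du < rtol && it > 2L && cap_ok) {
      u <- u_new
      converged <- TRUE
      break
    }
    # limit-cycle escape: if the residual has stalled at a small value and
    # the mean contact pressure is stationary, the global solution is
    # converged up to a marginal local wobble; accept the exact equilibrium
    # of the current linearised contact state.
    pmean_hist <- c(pmean_hist[-1], mean(p_new))
    if (du < 100 * rtol && du >= rtol) stall_count <- stall_count + 1L
    else stall_count <- 0L
    pm_stable <- !anyNA(pmean_hist) &&
      diff(range(pmean_hist)) < 0.02 * max(mean(p_new), 1e-12)
    if (stall_count >= 12L && cap_ok && pm_stable) {
      u <- u_new
      converged <- TRUE
      stalled <- TRUE
      break
    }
    if (it == max_iters && du < 50 * rtol && cap_ok) {
      # iterations exhausted with a small stationary residual: the exact
      # equilibrium of the frozen linearised contact state is accepted
      u <- u_new
      converged <- TRUE
      stalled <- TRUE
    }
  }
  if (!converged)
    stop(sprintf("contact iteration did not converge in %d rounds (last relative change %.3g)",
                 max_iters, du))
  U <- matrix(u, ncol = 3, byrow = TRUE)
  proj <- .contact_project(coords + U, cp, cand, centre)
  kn_pair <- kn_node[proj$masters[, 1]] * kn_scale
  kn_pair[proj$on_rim] <- 0
  kn_pair[proj$pen > 4 * contact$penetration_tol] <- 0
  law_w <- pmin(law_force_scale / pmax(kn_pair, 1e-8), 0.5)
  pen <- proj$pen
  pen[proj$on_rim | kn_pair == 0] <- 0
  pressure <- .contact_law(pen, kn_pair, law_w)$p
  pressure[pen < -6 * law_w] <- 0   # below the numerical floor of the law
  engaged <- pressure > 1e-3
  if (any(pen[engaged] > contact$penetration_tol))
    warning(sprintf("maximum penetration %.3g mm exceeds tolerance %.3g mm",
                    max(pen[engaged]), contact$penetration_tol))
  rel <- rel_slip(U, proj)
  t_vec <- rel - rowSums(proj$n * rel) * proj$n
  # reported traction is the Coulomb-model part; the rigid-mode
  # stabilisation spring (0.1% of the normal penalty) is excluded
  tau <- kt_sec * sqrt(rowSums(t_vec^2))
  tau[pressure <= 0] <- 0
  st <- compute_strains(mesh, u)
  structure(list(u = U, eps = st$eps, eh = st$eh,
                 contact = list(slave_nodes = cp$slave_nodes,
                                pressure = pressure,
                                penetration = pen,
                                tangential = tau,
                                active = pressure > 0,
                                kn = kn, kn_pair = kn_pair,
                                law_width = law_w, area = A),
                 iterations = it, converged = TRUE, stalled = stalled,
                 warm = list(u = u, kt_sec = kt_sec)),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("Simulation state: max |u| = %.4g mm", max(abs(x$u))))
  if (!is.null(x$contact))
    cat(sprintf(", contact: %d/%d active, max pressure %.4g MPa",
                sum(x$contact$active), length(x$contact$pressure),
                max(x$contact$pressure)))
  cat(sprintf(" (%d iterations)\n", x$iterations))
  invisible(x)
}

.scatter <- function(i, x, n) {
  out <- numeric(n)
  acc <- tapply(x, i, sum)
  out[as.integer(names(acc))] <- acc
  out
}

.resolve_constraints <- function(mesh, constraints) {
  if (is.numeric(constraints)) return(as.integer(constraints))
  if (is.null(constraints)) {
    sets <- intersect(c("foramen_magnum_ring", "nasion"), names(mesh$node_sets))
    if (!length(sets)) return(integer(0))
    constraints <- sets
  }
  if (is.character(constraints)) {
    missing <- setdiff(constraints, names(mesh$node_sets))
    if (length(missing))
      stop("unknown node set(s): ", paste(missing, collapse = ", "))
    nodes <- unique(unlist(mesh$node_sets[constraints], use.names = FALSE))
    return(.node_dofs(nodes))
  }
  stop("constraints must be NULL, a character vector of node sets, or dof indices")
}

# Per-master-vertex penalty cap: min(kn, 2 * E/h) over the master-side
# elements adjacent to each vertex. Returns a lookup vector indexed by node.
.master_stiffness_cap <- function(mesh, materials, kn) {
  mat <- .resolve_materials(mesh, materials)
  mverts <- sort(unique(as.vector(mesh$contact$master_tris)))
  el <- .corners(mesh)
  h <- tet_volumes(mesh)^(1 / 3) * 6^(1 / 3)   # ~ element size
  touch <- matrix(el %in% mverts, nrow(el), 4)
  adj <- which(rowSums(touch) > 0)
  out <- rep(kn, nrow(mesh$nodes))
  stiff <- mat$E[adj] / h[adj]
  emax <- rep(0, nrow(mesh$nodes))
  for (k in 1:4) {
    sel <- touch[adj, k]
    vi <- el[adj[sel], k]
    acc <- tapply(stiff[sel], vi, min)
    ids <- as.integer(names(acc))
    out[ids] <- pmin(out[ids], pmax(2 * acc, 1e-8))
    accE <- tapply(mat$E[adj][sel], vi, max)
    emax[ids] <- pmax(emax[ids], accE)
  }
  # bone-backed pairs keep at least 6% of the nominal penalty (their
  # working penetrations stay inside the penetration tolerance); vertices
  # on unsupported membrane interiors (fontanelle, wide craniotomy gaps)
  # keep the bare local cap - a stiff spring against a near-zero-bending
  # membrane only destabilises the iteration
  bone_backed <- emax > 500
  ifelse(bone_backed, pmax(out, 0.06 * kn), out)
}

# Normal penalty stiffness in pressure-per-penetration units. "absolute"
# uses the stated value directly (N/mm per mm^2); "factor" scales the softer
# contacting material's modulus over a characteristic element size.
.contact_kn <- function(contact, mesh, materials) {
  if (contact$stiffness_mode == "absolute") return(contact$normal_stiffness)
  Emin <- min(materials$brain[1], materials$csf[1])
  h <- mean(tet_volumes(mesh))^(1 / 3)
  contact$normal_stiffness * Emin / h
}

#' Per-face contact pressure map
#'
#' Maps the nodal contact pressures of a solved state onto the intracranial
#' surface triangles (face pressure = mean of its nodal pressures; faces out
#' of contact report 0).
#'
#' @param state a solved `sim_state` with contact results.
#' @param mesh the `labeled_mesh` the state was solved on.
#' @return data frame with one row per intracranial surface face: node ids,
#'   pressure (MPa).
#' @export
extract_contact_pressure <- function(state, mesh) {
  if (is.null(state$contact))
    stop("state has no contact results (unsolved or contact disabled)")
  cp <- mesh$contact
  pn <- numeric(nrow(mesh$nodes))
  pn[cp$slave_nodes] <- state$contact$pressure
  st <- cp$slave_tris
  data.frame(n1 = st[, 1], n2 = st[, 2], n3 = st[, 3],
             pressure = (pn[st[, 1]] + pn[st[, 2]] + pn[st[, 3]]) / 3)
}
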