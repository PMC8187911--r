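# Six-interval intracranial expansion via the thermal-expansion analogy,
# volume-to-age mapping, and the two bone-formation algorithms (gradual
# front-based formation with hydrostatic-strain gating, and bulk modulus
# ramping).

#' Default intracranial-volume-to-age curve
#'
#' Monotone lookup table mapping ICV (ml) to age (months). The endpoints pin
#' the pre-operative state (659 ml at 4 months) and the follow-up
#' (1,245 ml at 76 months); the interior knots place the six equal-ratio
#' expansion volumes at the clinical milestone ages (7, 12, 24, 36 and 50
#' months), giving the strongly concave volume growth of infancy: most of
#' the volume gain happens in the first two years.
#'
#' @param v_pre,v_follow endpoint volumes, ml.
#' @param ages ages (months) assigned to the geometrically spaced volumes
#'   from `v_pre` to `v_follow` (length = number of intervals + 1).
#' @return data frame with columns `volume_ml`, `age_months`.
#' @export
icv_age_curve <- function(v_pre = 659, v_follow = 1245,
                          ages = c(4, 7, 12, 24, 36, 50, 76)) {
  n <- length(ages) - 1L
  vols <- v_pre * (v_follow / v_pre)^((0:n) / n)
  data.frame(volume_ml = vols, age_months = ages)
}

#' Build the growth schedule
#'
#' Splits the pre-operative to follow-up volume expansion into equal-ratio
#' intervals: each interval multiplies the volume by
#' `(v_follow/v_pre)^(1/n)`, i.e. applies the identical linear strain
#' `ratio^(1/3) - 1` per interval; interval end ages are read off the
#' volume-to-age curve.
#'
#' @param v_pre pre-operative ICV, ml.
#' @param v_follow follow-up ICV, ml (must exceed `v_pre`).
#' @param n_intervals number of expansion intervals.
#' @param curve monotone volume-to-age table (see [icv_age_curve()]).
#' @return an object of class `growth_schedule`: per-interval linear strain
#'   `alpha`, interval end ages, start age.
#' @export
build_schedule <- function(v_pre = 659, v_follow = 1245, n_intervals = 6L,
                           curve = icv_age_curve(v_pre, v_follow)) {
  if (v_pre <= 0 || v_follow <= v_pre)
    stop("need 0 < v_pre < v_follow")
  if (n_intervals < 1) stop("n_intervals must be >= 1")
  if (any(diff(curve$volume_ml) <= 0) || any(diff(curve$age_months) <= 0))
    stop("volume-to-age curve must be strictly increasing")
  n <- as.integer(n_intervals)
  ratio <- (v_follow / v_pre)^(1 / n)
  alpha <- rep(ratio^(1 / 3) - 1, n)
  vols <- v_pre * ratio^(0:n)
  ages <- stats::approx(curve$volume_ml, curve$age_months, xout = vols,
                        rule = 2)$y
  ages <- round(ages, 9)   # interpolation at the knots must hit them exactly
  structure(list(v_pre = v_pre, v_follow = v_follow, n_intervals = n,
                 alpha = alpha, volumes = vols, ages = ages,
                 start_age = ages[1], end_age = ages[n + 1], curve = curve),
            class = "growth_schedule")
}

#' @export
print.growth_schedule <- function(x, ...) {
  cat(sprintf("Growth schedule: %g -> %g ml in %d intervals (%.3g%% linear strain each)\n",
              x$v_pre, x$v_follow, x$n_intervals, 100 * x$alpha[1]))
  cat("interval end volumes (ml):", paste(round(x$volumes[-1], 1), collapse = ", "), "\n")
  cat("interval end ages (months):", paste(round(x$ages[-1], 2), collapse = ", "), "\n")
  invisible(x)
}

#' Bone-formation rule
#'
#' Scenario `"gradual"` converts suture/craniotomy elements lying within a
#' radius of the adjacent bone front each interval (radius = rate x months
#' of growth in the interval, applied bilaterally from both bone margins),
#' gated by the element hydrostatic strain lying inside `strain_window`;
#' converted elements receive the full bone stiffness immediately and extend
#' the front for subsequent intervals. Scenario `"bulk"` instead ramps the
#' elastic modulus of the whole suture/craniotomy regions up to bone
#' stiffness over the growth intervals.
#'
#' @param scenario `"gradual"` or `"bulk"`.
#' @param rates named formation rates in mm per month of volume growth. The
#'   names `suture` and `craniotomy` set the class defaults (0.1 and 0.8);
#'   any region label (e.g. `metopic`) may be given an override.
#' @param strain_window admissible hydrostatic-strain interval for
#'   conversion (default 0 to 0.5, i.e. 0-50\% tensile volumetric strain).
#' @param bulk_ramp optional named list (`suture`, `craniotomy`) of modulus
#'   schedules (MPa, one value per interval) for the bulk scenario; by
#'   default a geometric ramp from the baseline modulus to bone modulus.
#' @param force_close named vector of ages (months): any listed region still
#'   unossified when the simulation reaches that age is closed outright
#'   (used for the accelerated metopic/fontanelle closure test).
#' @return an object of class `formation_rule`.
#' @export
formation_rule <- function(scenario = c("gradual", "bulk"),
                           rates = c(suture = 0.1, craniotomy = 0.8),
                           strain_window = c(0, 0.5),
                           bulk_ramp = NULL,
                           force_close = NULL) {
  scenario <- match.arg(scenario)
  if (!all(c("suture", "craniotomy") %in% names(rates)))
    rates <- c(c(suture = 0.1, craniotomy = 0.8)[
      setdiff(c("suture", "craniotomy"), names(rates))], rates)
  if (any(rates < 0)) stop("formation rates must be >= 0")
  if (length(strain_window) != 2 || strain_window[1] > strain_window[2])
    stop("strain_window must be c(low, high) with low <= high")
  structure(list(scenario = scenario, rates = rates,
                 strain_window = strain_window, bulk_ramp = bulk_ramp,
                 force_close = force_close),
            class = "formation_rule")
}

#' @export
print.formation_rule <- function(x, ...) {
  cat(sprintf("Bone formation rule: scenario %s\n", x$scenario))
  cat("  rates (mm/month):",
      paste(names(x$rates), x$rates, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  hydrostatic strain window: [%g, %g]\n",
              x$strain_window[1], x$strain_window[2]))
  if (!is.null(x$force_close))
    cat("  forced closure:", paste(names(x$force_close), "by",
                                   x$force_close, "months", collapse = "; "), "\n")
  invisible(x)
}

# per-element formation rate (mm/month); 0 for non-candidate classes
.formation_rates <- function(region, rule) {
  cls <- region_class(region)
  rate <- numeric(length(region))
  rate[cls == "suture"] <- rule$rates[["suture"]]
  rate[cls == "craniotomy"] <- rule$rates[["craniotomy"]]
  extra <- setdiff(names(rule$rates), c("suture", "craniotomy"))
  for (nm in extra) rate[region == nm] <- rule$rates[[nm]]
  rate
}

# minimum distance from points P to a set of triangles (prefiltered by
# triangle-centroid distance)
.dist_to_faces <- function(P, nodes, faces, cutoff) {
  nf <- nrow(faces)
  np_ <- nrow(P)
  fc <- (nodes[faces[, 1], , drop = FALSE] + nodes[faces[, 2], , drop = FALSE] +
         nodes[faces[, 3], , drop = FALSE]) / 3
  ed <- sqrt(pmax(rowSums((nodes[faces[, 1], , drop = FALSE] - fc)^2),
                  rowSums((nodes[faces[, 2], , drop = FALSE] - fc)^2),
                  rowSums((nodes[faces[, 3], , drop = FALSE] - fc)^2)))
  out <- rep(Inf, np_)
  bs <- 500L
  for (s0 in seq(1L, np_, by = bs)) {
    idx <- s0:min(s0 + bs - 1L, np_)
    d2 <- outer(rowSums(P[idx, , drop = FALSE]^2), rowSums(fc^2), "+") -
      2 * P[idx, , drop = FALSE] %*% t(fc)
    d2 <- sqrt(pmax(d2, 0))
    near <- d2 <= matrix(cutoff + ed, length(idx), nf, byrow = TRUE)
    pr <- which(near, arr.ind = TRUE)
    if (!nrow(pr)) next
    fi <- pr[, 2]
    cp <- .closest_point_tri(P[idx[pr[, 1]], , drop = FALSE],
                             nodes[faces[fi, 1], , drop = FALSE],
                             nodes[faces[fi, 2], , drop = FALSE],
                             nodes[faces[fi, 3], , drop = FALSE])
    dd <- sqrt(rowSums((P[idx[pr[, 1]], , drop = FALSE] - cp$Q)^2))
    acc <- tapply(dd, pr[, 1], min)
    out[idx[as.integer(names(acc))]] <-
      pmin(out[idx[as.integer(names(acc))]], acc)
  }
  out
}

#' Gradual (front-based) bone-formation step
#'
#' Converts every unossified suture/craniotomy element whose centroid lies
#' within `rate x months` of the nearest bone front face and whose
#' hydrostatic strain lies inside the rule's strain window. Converted
#' elements keep their anatomical label but are flagged ossified (bone
#' stiffness), so the front advances across subsequent intervals.
#'
#' @param mesh a `labeled_mesh`.
#' @param eh per-element hydrostatic strain driving the strain gating.
#' @param rule a [formation_rule()].
#' @param months months of volume growth represented by this step.
#' @param front_faces optional triangle matrix (node indices) to measure
#'   formation distances from. By default the current interface between
#'   bone (including previously ossified elements) and the unossified
#'   suture/craniotomy regions is used. [grow_calvaria()] passes the
#'   original bone margin here together with the cumulative radius, which
#'   makes the propagating front's arrival time mesh-size independent.
#' @param radius optional per-element formation radius (mm) overriding
#'   `rate x months`.
#' @param coords node coordinates to measure distances in (defaults to the
#'   mesh's current coordinates; [grow_calvaria()] passes the pre-operative
#'   reference coordinates so the literature healing rates are applied in
#'   the frame they were calibrated in).
#' @return the mesh with an updated `ossified` flag (a superset of the
#'   previous one).
#' @export
gradual_formation_step <- function(mesh, eh, rule, months,
                                   front_faces = NULL, radius = NULL,
                                   coords = mesh$nodes) {
  if (is.null(eh) || length(eh) != nrow(mesh$elems))
    stop("per-element hydrostatic strain field is required for gradual formation")
  rate <- .formation_rates(mesh$region, rule)
  if (is.null(radius)) {
    stopifnot(months > 0)
    radius <- rate * months
  }
  cand <- which(rate > 0 & !mesh$ossified)
  if (!length(cand)) return(mesh)
  if (is.null(front_faces)) {
    bone_like <- which(region_class(mesh$region) == "bone" | mesh$ossified)
    if (!length(bone_like)) return(mesh)
    soft <- which(region_class(mesh$region) %in% c("suture", "craniotomy") &
                    !mesh$ossified)
    front_faces <- .interface_faces(mesh, bone_like, soft)
  }
  if (!nrow(front_faces)) return(mesh)
  el <- .corners(mesh)[cand, , drop = FALSE]
  cen <- (coords[el[, 1], , drop = FALSE] + coords[el[, 2], , drop = FALSE] +
          coords[el[, 3], , drop = FALSE] + coords[el[, 4], , drop = FALSE]) / 4
  d <- .dist_to_faces(cen, coords, front_faces, max(radius[cand]))
  # the 0-50% window is applied to the hydrostatic strain magnitude
  gate <- abs(eh[cand]) >= rule$strain_window[1] &
    abs(eh[cand]) <= rule$strain_window[2]
  mesh$ossified[cand[d <= radius[cand] & gate]] <- TRUE
  mesh
}

# original bone margin: interface between bone-class elements and the
# (patent) suture/craniotomy regions, as material faces
.formation_front <- function(mesh) {
  bone_like <- which(region_class(mesh$region) == "bone")
  soft <- which(region_class(mesh$region) %in% c("suture", "craniotomy"))
  if (!length(bone_like) || !length(soft))
    return(matrix(integer(0), 0, 3))
  .interface_faces(mesh, bone_like, soft)
}

#' Bulk bone-formation step
#'
#' Sets the suture/craniotomy class moduli for the given interval: the first
#' interval runs at the baseline modulus and the final interval at full bone
#' stiffness, with a geometric ramp in between (unless an explicit ramp is
#' supplied). Moduli never decrease.
#'
#' @param materials a `material_card`.
#' @param rule a [formation_rule()] with scenario `"bulk"`.
#' @param interval_index 1-based interval about to be solved.
#' @param n_intervals total number of intervals.
#' @param baseline the material card at the start of the run (ramp origin).
#' @return the updated `material_card` (moduli non-decreasing across
#'   intervals).
#' @export
bulk_formation_step <- function(materials, rule, interval_index, n_intervals,
                                baseline = materials) {
  k <- interval_index
  if (k > n_intervals) stop("interval_index exceeds n_intervals")
  for (clsn in c("suture", "craniotomy")) {
    ramp <- rule$bulk_ramp[[clsn]]
    if (is.null(ramp)) {
      e0 <- baseline[[clsn]][1]
      eb <- baseline$bone[1]
      expo <- if (n_intervals > 1) (seq_len(n_intervals) - 1) / (n_intervals - 1)
        else 1
      ramp <- e0 * (eb / e0)^expo
    }
    if (length(ramp) < n_intervals)
      stop("bulk ramp for class '", clsn, "' is shorter than n_intervals")
    materials[[clsn]][1] <- max(materials[[clsn]][1], ramp[k])
  }
  materials
}
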