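# The main driver: quasi-static incremental growth of the calvaria with
# updated-coordinate stepping. Each growth interval applies its linear
# expansion strain to the intracranial regions in sub-increments (each a
# fresh static solve on the updated, unstressed geometry), then applies the
# bone-formation rule with the months elapsed in that interval.

#' Grow the calvaria
#'
#' Runs the full post-operative growth simulation: for each interval of the
#' schedule, the brain (and CSF, if present) expands by the interval's
#' linear strain via the thermal-expansion analogy, the contact between the
#' intracranial volume and the inner calvaria is resolved, the geometry is
#' updated, and the bone-formation rule (gradual front-based or bulk
#' modulus ramp) is applied over the months spanned by the interval.
#'
#' @param mesh a `labeled_mesh`, normally from [generate_calvaria()].
#' @param materials a [material_card()].
#' @param schedule a [build_schedule()].
#' @param rule a [formation_rule()].
#' @param contact a [contact_spec()], or `NULL` for meshes without a contact
#'   pair (e.g. free-expansion checks).
#' @param constraints passed to [solve_increment()] (default: the mesh's
#'   foramen magnum ring and nasion sets).
#' @param n_sub sub-increments per interval (contact stability).
#' @param rtol,max_iters solver controls, see [solve_increment()].
#' @param verbose print per-interval progress.
#' @return an object of class `calvaria_growth`: the final mesh (deformed,
#'   with ossification flags), per-interval snapshots (age, ICV volume,
#'   skull dimensions, patency fractions, contact-pressure summaries), and
#'   the configuration used.
#' @export
grow_calvaria <- function(mesh, materials = material_card(),
                          schedule = build_schedule(),
                          rule = formation_rule(),
                          contact = contact_spec(),
                          constraints = NULL,
                          n_sub = 3L, rtol = 2e-3, max_iters = 80L,
                          verbose = interactive()) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  mesh0_region <- mesh$region
  mats <- materials
  mats0 <- materials
  n <- schedule$n_intervals
  snapshots <- vector("list", n + 1L)
  snapshots[[1]] <- .growth_snapshot(mesh, NULL, schedule$ages[1])
  last_state <- NULL
  front0 <- if (rule$scenario == "gradual") .formation_front(mesh) else NULL
  rate_el <- .formation_rates(mesh$region, rule)
  nodes0 <- mesh$nodes      # pre-operative reference frame for formation
  icv_sel <- startsWith(mesh$region, "brain") |
    mesh$region %in% c("cerebellum", "csf")
  track_icv <- any(icv_sel)
  for (i in seq_len(n)) {
    # volume feedback: the expansion is volume-driven, so each interval's
    # strain is set from the currently achieved ICV towards the scheduled
    # interval volume (compensates the elastic compression of the previous
    # interval's solve)
    a_i <- schedule$alpha[i]
    if (track_icv && !is.null(mesh$contact)) {
      v_now <- sum(tet_volumes(mesh)[icv_sel]) / 1000
      a_i <- max((schedule$volumes[i + 1] / v_now)^(1 / 3) - 1, 0)
    }
    a_sub <- (1 + a_i)^(1 / n_sub) - 1
    if (rule$scenario == "bulk")   # this interval's ramped stiffness
      mats <- bulk_formation_step(mats, rule, i, n, baseline = mats0)
    eh_acc <- numeric(nrow(mesh$elems))
    for (s in seq_len(n_sub)) {
      res <- .solve_adaptive(mesh, mats, a_sub, constraints, contact,
                             rtol, max_iters, depth = 0L,
                             context = sprintf("interval %d, sub-increment %d",
                                               i, s))
      mesh <- res$mesh
      eh_acc <- eh_acc + res$eh
      last_state <- res$state
    }
    months <- schedule$ages[i + 1] - schedule$ages[i]
    if (rule$scenario == "gradual") {
      # propagating-front arrival time: cumulative radius measured from the
      # original bone margin (mesh-size independent closure ages)
      mesh <- gradual_formation_step(
        mesh, eh_acc, rule, months, front_faces = front0,
        radius = rate_el * (schedule$ages[i + 1] - schedule$ages[1]),
        coords = nodes0)
    } else if (i == n) {
      # final ramp interval runs at bone stiffness: regions closed
      mesh$ossified[region_class(mesh$region) %in%
                      c("suture", "craniotomy")] <- TRUE
    }
    if (!is.null(rule$force_close)) {
      for (nm in names(rule$force_close))
        if (schedule$ages[i + 1] >= rule$force_close[[nm]])
          mesh$ossified[mesh$region == nm] <- TRUE
    }
    snapshots[[i + 1]] <- .growth_snapshot(mesh, last_state,
                                           schedule$ages[i + 1])
    if (verbose)
      message(sprintf(
        "interval %d/%d: age %.1f mo, ICV %.0f ml, ossified %d/%d, mean p %.3g MPa",
        i, n, schedule$ages[i + 1], snapshots[[i + 1]]$icv_ml,
        sum(mesh$ossified), length(mesh$ossified),
        snapshots[[i + 1]]$mean_pressure))
  }
  out <- structure(list(mesh = mesh, snapshots = snapshots,
                        schedule = schedule, rule = rule,
                        materials = materials, materials_final = mats,
                        contact = contact, n_sub = n_sub,
                        final_state = last_state,
                        region0 = mesh0_region),
                   class = "calvaria_growth")
  if (!is.null(mesh$contact)) {
    vf <- out$snapshots[[n + 1]]$icv_ml
    if (is.finite(vf) && abs(vf / schedule$v_follow - 1) > 0.03)
      warning(sprintf("final ICV %.0f ml deviates more than 3%% from the target %.0f ml",
                      vf, schedule$v_follow))
  }
  out
}

#' @rdname grow_calvaria
#' @param ... arguments passed to [grow_calvaria()].
#' @export
run_growth <- function(...) grow_calvaria(...)

# Adaptive substepping: if a growth step's contact iteration fails to
# converge, bisect the step (up to 3 times, i.e. 1/8 steps) and retry.
# Returns the updated mesh, the accumulated hydrostatic strain and the last
# solved state.
.solve_adaptive <- function(mesh, mats, alpha, constraints, contact,
                            rtol, max_iters, depth, context) {
  st <- tryCatch(
    solve_increment(mesh, mats, alpha, constraints = constraints,
                    contact = contact, rtol = rtol, max_iters = max_iters),
    error = function(e) e)
  if (!inherits(st, "error")) {
    mesh$nodes <- mesh$nodes + st$u
    return(list(mesh = mesh, eh = st$eh, state = st))
  }
  if (depth >= 3L)
    stop(context, ": ", conditionMessage(st), call. = FALSE)
  a_half <- sqrt(1 + alpha) - 1
  r1 <- .solve_adaptive(mesh, mats, a_half, constraints, contact, rtol,
                        max_iters, depth + 1L, context)
  r2 <- .solve_adaptive(r1$mesh, mats, a_half, constraints, contact, rtol,
                        max_iters, depth + 1L, context)
  list(mesh = r2$mesh, eh = r1$eh + r2$eh, state = r2$state)
}

.growth_snapshot <- function(mesh, state, age) {
  vols <- tet_volumes(mesh)
  icv_sel <- startsWith(mesh$region, "brain") |
    mesh$region %in% c("cerebellum", "csf")
  morpho <- if (length(mesh$landmarks) >= 6)
    measure(mesh, age = age) else NULL
  form_sel <- region_class(mesh$region) %in% c("suture", "craniotomy")
  pat <- if (any(form_sel)) {
    regs <- sort(unique(mesh$region[form_sel]))
    vapply(regs, function(r)
      mean(!mesh$ossified[mesh$region == r]), numeric(1))
  } else NULL
  pr <- if (!is.null(state) && !is.null(state$contact))
    pressure_report(state, mesh) else NULL
  list(age = age,
       icv_ml = sum(vols[icv_sel]) / 1000,
       morphometrics = morpho,
       patency = pat,
       pressure = pr,
       ossified = mesh$ossified,
       mean_pressure = if (!is.null(state) && !is.null(state$contact))
         mean(state$contact$pressure) else NA_real_,
       max_penetration = if (!is.null(state) && !is.null(state$contact))
         max(state$contact$penetration) else NA_real_)
}

#' @export
print.calvaria_growth <- function(x, ...) {
  n <- x$schedule$n_intervals
  cat(sprintf("Calvarial growth simulation: %d intervals, scenario %s\n",
              n, x$rule$scenario))
  cat(sprintf("  age %.1f -> %.1f months, ICV %.0f -> %.0f ml\n",
              x$schedule$start_age, x$schedule$end_age,
              x$snapshots[[1]]$icv_ml, x$snapshots[[n + 1]]$icv_ml))
  if (!is.null(x$snapshots[[n + 1]]$morphometrics)) {
    m <- x$snapshots[[n + 1]]$morphometrics
    cat(sprintf("  final dimensions: length %.2f, width %.2f, height %.2f mm, CI %.2f\n",
                m$length, m$width, m$height, m$cephalic_index))
  }
  cat(sprintf("  ossified elements: %d/%d\n", sum(x$mesh$ossified),
              length(x$mesh$ossified)))
  invisible(x)
}

#' @export
summary.calvaria_growth <- function(object, ...) {
  rows <- lapply(object$snapshots, function(s) {
    d <- data.frame(age = s$age, icv_ml = s$icv_ml,
                    mean_pressure = s$mean_pressure)
    if (!is.null(s$morphometrics)) {
      d$length <- s$morphometrics$length
      d$width <- s$morphometrics$width
      d$height <- s$morphometrics$height
      d$cephalic_index <- s$morphometrics$cephalic_index
    }
    d
  })
  do.call(rbind, rows)
}

#' @export
plot.calvaria_growth <- function(x, which = c("patency", "outline"), ...) {
  which <- match.arg(which)
  if (which == "patency") {
    plot(patency(x), ...)
  } else {
    out <- cross_section(x$mesh, "midsagittal")
    plot(NA, xlim = range(out[, 1]), ylim = range(out[, 2]), asp = 1,
         xlab = "x (mm)", ylab = "z (mm)",
         main = "Midsagittal outline at final age")
    .draw_outline(out, ...)
    invisible(x)
  }
}
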