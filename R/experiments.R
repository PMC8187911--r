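# The sensitivity-experiment grid: baseline, material-property tests,
# formation-rate tests, and the 2x2 comparison of intracranial content
# (CSF present/absent) against bone-formation method (gradual/bulk).

#' Experiment configuration
#'
#' Bundles everything one simulation needs: geometry, materials, growth
#' schedule, formation rule, contact parameters, intracranial-content model
#' and solver controls.
#'
#' @param name experiment name (unique within a run set).
#' @param geometry a [skull_params()].
#' @param materials a [material_card()].
#' @param growth a [build_schedule()].
#' @param formation a [formation_rule()].
#' @param contact a [contact_spec()].
#' @param csf_present logical: include the CSF layer (the "CSF present"
#'   model). When `TRUE` and the geometry has `csf_thickness = 0`, a
#'   2.5 mm layer is used.
#' @param n_sub sub-increments per growth interval.
#' @param seed integer seed (meshing jitter; simulations are otherwise
#'   deterministic).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(name, geometry = skull_params(),
                              materials = material_card(),
                              growth = build_schedule(),
                              formation = formation_rule(),
                              contact = contact_spec(),
                              csf_present = FALSE,
                              n_sub = 3L, seed = 0L) {
  stopifnot(is.character(name), nchar(name) > 0,
            inherits(geometry, "skull_params"),
            inherits(materials, "material_card"),
            inherits(growth, "growth_schedule"),
            inherits(formation, "formation_rule"),
            inherits(contact, "contact_spec"))
  if (csf_present && geometry$csf_thickness == 0)
    geometry$csf_thickness <- 2.5
  if (!csf_present) geometry$csf_thickness <- 0
  structure(list(name = name, geometry = geometry, materials = materials,
                 growth = growth, formation = formation, contact = contact,
                 csf_present = csf_present, n_sub = as.integer(n_sub),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment '%s': model %s, scenario %s, seed %d\n",
              x$name, if (x$csf_present) "I (CSF present)" else "II (CSF absent)",
              x$formation$scenario, x$seed))
  invisible(x)
}

#' Built-in sensitivity experiment grid
#'
#' The standard experiment set: the baseline model (bone 3000 MPa / 0.3,
#' sutures and craniotomies 30 MPa / 0.3, brain 100 MPa / 0.48, suture
#' formation 0.1 mm/month, craniotomy 0.8 mm/month, CSF absent, gradual
#' formation), the material-property sensitivities (Test 1: bone 421 MPa,
#' Poisson 0.22; Test 2: craniotomy 0.003 MPa; Test 3: brain 0.003 MPa),
#' the formation-rate sensitivities (Test 4: suture rate 0.2; Test 5:
#' suture 0.2 with metopic/anterior-fontanelle 0.6 closing by 24 months),
#' and the 2x2 grid of intracranial content (CSF present/absent) against
#' formation method (gradual/bulk). Tests 2 and 3 run with three times the
#' sub-increments because their extreme stiffness ratios degrade contact
#' conditioning.
#'
#' @param mesh_size target element edge length, mm.
#' @param n_brain_layers radial brain layers.
#' @param n_sub sub-increments per interval for the well-conditioned runs.
#' @param seed meshing seed.
#' @return named list of `experiment_config` objects. The baseline is the
#'   CSF-absent / gradual-formation member of the 2x2 grid.
#' @export
builtin_configs <- function(mesh_size = 10, n_brain_layers = 3L,
                            n_sub = 3L, seed = 0L) {
  geo <- function(csf = 0) skull_params(mesh_size = mesh_size,
                                        csf_thickness = csf,
                                        n_brain_layers = n_brain_layers,
                                        seed = seed)
  base_mats <- material_card()
  cfg <- function(name, materials = base_mats,
                  formation = formation_rule(), csf_present = FALSE,
                  nsub = n_sub)
    experiment_config(name, geometry = geo(if (csf_present) 2.5 else 0),
                      materials = materials, formation = formation,
                      csf_present = csf_present, n_sub = nsub, seed = seed)
  list(
    baseline = cfg("baseline"),
    test1 = cfg("test1", materials = material_card(bone = c(421, 0.22))),
    test2 = cfg("test2", materials = material_card(craniotomy = c(0.003, 0.3)),
                nsub = 3L * n_sub),
    test3 = cfg("test3", materials = material_card(brain = c(0.003, 0.48)),
                nsub = 3L * n_sub),
    test4 = cfg("test4", formation = formation_rule(
      rates = c(suture = 0.2, craniotomy = 0.8))),
    test5 = cfg("test5", formation = formation_rule(
      rates = c(suture = 0.2, craniotomy = 0.8,
                metopic = 0.6, anterior_fontanelle = 0.6),
      force_close = c(metopic = 24, anterior_fontanelle = 24))),
    modelI_gradual = cfg("modelI_gradual", csf_present = TRUE),
    modelI_bulk = cfg("modelI_bulk", csf_present = TRUE,
                      formation = formation_rule(scenario = "bulk")),
    modelII_bulk = cfg("modelII_bulk",
                       formation = formation_rule(scenario = "bulk"))
  )
}

#' Run one experiment
#'
#' Generates the synthetic skull for the configuration, runs the growth
#' simulation, and collects the outputs: the final morphometrics, the
#' regional pressure report, the patency timeline and a manifest of every
#' parameter used. Deterministic for a given configuration and seed.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, the reports are written
#'   as CSV and the manifest as JSON.
#' @param verbose print progress.
#' @return an object of class `experiment_bundle`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  mesh <- generate_calvaria(config$geometry)
  run <- grow_calvaria(mesh, materials = config$materials,
                       schedule = config$growth, rule = config$formation,
                       contact = config$contact, n_sub = config$n_sub,
                       verbose = verbose)
  n <- config$growth$n_intervals
  morpho <- do.call(rbind, lapply(run$snapshots, function(s) s$morphometrics))
  pat <- patency(run)
  pres <- run$snapshots[[n + 1]]$pressure
  bundle <- structure(list(name = config$name, config = config, run = run,
                           morphometrics = morpho, pressure = pres,
                           patency = pat,
                           manifest = .experiment_manifest(config)),
                      class = "experiment_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pfx <- file.path(out_dir, config$name)
    utils::write.csv(morpho, paste0(pfx, "_morphometrics.csv"),
                     row.names = FALSE)
    utils::write.csv(pat, paste0(pfx, "_patency.csv"), row.names = FALSE)
    if (!is.null(pres))
      utils::write.csv(pres, paste0(pfx, "_pressure.csv"), row.names = FALSE)
    jsonlite::write_json(bundle$manifest, paste0(pfx, "_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  bundle
}

.experiment_manifest <- function(config) {
  list(
    name = config$name,
    csf_present = config$csf_present,
    seed = config$seed,
    n_sub = config$n_sub,
    geometry = config$geometry[c("icv_target_volume", "shell_thickness",
                                 "csf_thickness", "ellipsoid_semi_axes",
                                 "mesh_size", "n_brain_layers",
                                 "fused_sutures")],
    suture_width = config$geometry$suture_width,
    craniotomy = unclass(config$geometry$craniotomy_spec),
    materials = unclass(config$materials)[c("bone", "suture", "craniotomy",
                                            "brain", "csf")],
    contact = unclass(config$contact),
    growth = config$growth[c("v_pre", "v_follow", "n_intervals", "ages")],
    formation = list(scenario = config$formation$scenario,
                     rates = as.list(config$formation$rates),
                     strain_window = config$formation$strain_window,
                     force_close = as.list(config$formation$force_close))
  )
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("Experiment bundle '%s'\n", x$name))
  print(x$run)
  invisible(x)
}

#' Tabulate experiment bundles
#'
#' Comparison tables across experiments: final-age skull dimensions and
#' cephalic index (one row per experiment), and per-lobe contact-pressure
#' statistics. Rows are sorted by experiment name for reproducible diffs.
#'
#' @param bundles list of `experiment_bundle` objects.
#' @return list with data frames `dimensions` and `pressure`.
#' @export
tabulate_experiments <- function(bundles) {
  if (!length(bundles)) stop("need at least one experiment bundle")
  dims <- do.call(rbind, lapply(bundles, function(b) {
    m <- b$morphometrics
    m <- m[nrow(m), , drop = FALSE]
    data.frame(experiment = b$name, age = m$age, length = m$length,
               width = m$width, height = m$height,
               cephalic_index = m$cephalic_index, icv_ml = m$icv_ml)
  }))
  dims <- dims[order(dims$experiment), , drop = FALSE]
  rownames(dims) <- NULL
  pres <- do.call(rbind, lapply(bundles, function(b) {
    if (is.null(b$pressure)) return(NULL)
    cbind(experiment = b$name, b$pressure)
  }))
  if (!is.null(pres)) {
    pres <- pres[order(pres$experiment, pres$lobe), , drop = FALSE]
    rownames(pres) <- NULL
  }
  list(dimensions = dims, pressure = pres)
}
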