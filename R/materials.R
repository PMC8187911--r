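# Region classification helpers. Elements keep their anatomical label for
# bookkeeping; the ossified flag switches their mechanical behaviour to bone.

.BONE_CLASS <- c("frontal", "parietal_L", "parietal_R", "occipital",
                 "temporal_L", "temporal_R", "craniofacial",
                 "sagittal_fused", "reinserted_bone", "core", "shell", "solid")
.SUTURE_CLASS <- c("metopic", "coronal", "lambdoid", "squamosal",
                   "anterior_fontanelle", "sagittal")

#' Classify region labels
#'
#' Maps a region label to its material class: `bone`, `suture`, `craniotomy`,
#' `csf` or `brain`.
#'
#' @param label character vector of region labels.
#' @return character vector of classes.
#' @export
region_class <- function(label) {
  out <- rep("bone", length(label))
  out[label %in% .SUTURE_CLASS] <- "suture"
  out[startsWith(label, "craniotomy")] <- "craniotomy"
  out[label == "csf"] <- "csf"
  out[startsWith(label, "brain") | label == "cerebellum"] <- "brain"
  out
}

#' Material card
#'
#' Elastic modulus (MPa) and Poisson's ratio per material class, with optional
#' per-label overrides. Defaults are the baseline calvarial growth properties:
#' bone 3000 MPa / 0.3, sutures 30 MPa / 0.3, craniotomies 30 MPa / 0.3,
#' brain 100 MPa / 0.48, CSF 40 MPa / 0.48. Growth (thermal-analogy) strain is
#' applied to the brain, and to the CSF when a CSF layer is present.
#'
#' @param bone,suture,craniotomy,brain,csf numeric length-2 vectors
#'   `c(E, nu)` per material class.
#' @param overrides named list of `c(E, nu)` for specific region labels,
#'   taking precedence over the class values.
#' @param grows character vector of material classes that receive the
#'   growth strain.
#' @return an object of class `material_card`.
#' @export
material_card <- function(bone = c(3000, 0.3), suture = c(30, 0.3),
                          craniotomy = c(30, 0.3), brain = c(100, 0.48),
                          csf = c(40, 0.48), overrides = list(),
                          grows = c("brain", "csf")) {
  card <- list(bone = bone, suture = suture, craniotomy = craniotomy,
               brain = brain, csf = csf, overrides = overrides, grows = grows)
  for (cl in c("bone", "suture", "craniotomy", "brain", "csf")) {
    v <- card[[cl]]
    if (length(v) != 2 || v[1] <= 0 || v[2] <= -1 || v[2] >= 0.5)
      stop("invalid material for class '", cl,
           "': need E > 0 and nu in (-1, 0.5)")
  }
  structure(card, class = "material_card")
}

#' @export
print.material_card <- function(x, ...) {
  cat("Material card (E in MPa, nu dimensionless):\n")
  for (cl in c("bone", "suture", "craniotomy", "brain", "csf"))
    cat(sprintf("  %-11s E = %8.4g  nu = %.3f%s\n", cl, x[[cl]][1], x[[cl]][2],
                if (cl %in% x$grows) "  [grows]" else ""))
  if (length(x$overrides))
    for (nm in names(x$overrides))
      cat(sprintf("  override %-12s E = %8.4g  nu = %.3f\n", nm,
                  x$overrides[[nm]][1], x$overrides[[nm]][2]))
  invisible(x)
}

# Resolve per-element E, nu and growth flag for a mesh. Ossified elements
# behave as bone (full bone modulus immediately on conversion).
.resolve_materials <- function(mesh, materials) {
  lab <- mesh$region
  cls <- region_class(lab)
  E <- numeric(length(lab)); nu <- numeric(length(lab))
  for (cl in unique(cls)) {
    sel <- cls == cl
    if (is.null(materials[[cl]]))
      stop("no material for class '", cl, "' (labels: ",
           paste(unique(lab[sel]), collapse = ", "), ")")
    E[sel] <- materials[[cl]][1]; nu[sel] <- materials[[cl]][2]
  }
  if (length(materials$overrides))
    for (nm in names(materials$overrides)) {
      sel <- lab == nm
      if (any(sel)) {
        E[sel] <- materials$overrides[[nm]][1]
        nu[sel] <- materials$overrides[[nm]][2]
      }
    }
  if (any(mesh$ossified)) {
    E[mesh$ossified] <- materials$bone[1]
    nu[mesh$ossified] <- materials$bone[2]
  }
  missing <- unique(lab[!(cls %in% names(materials))])
  if (length(missing))
    stop("no material for region label(s): ", paste(missing, collapse = ", "))
  list(E = E, nu = nu, grows = cls %in% materials$grows & !mesh$ossified)
}
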