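# Minimal ASCII mesh I/O: VTK XML unstructured grids (write-only, for
# inspection in ParaView) and Gmsh MSH 2.2 (write + read, the package's
# round-trip format; region labels travel as physical names, node sets and
# landmarks as $NodeData views).

#' Write a mesh as a VTK XML unstructured grid (.vtu)
#'
#' Region labels and the ossification flag are written as cell data; any
#' node sets and landmarks as point data indicator arrays. ASCII format.
#'
#' @param mesh a `labeled_mesh`.
#' @param path output file path.
#' @param point_data optional named list of per-node numeric vectors.
#' @param cell_data optional named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  el <- .corners(mesh)
  regions <- sort(unique(mesh$region))
  rid <- match(mesh$region, regions)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(x) paste(format(x, digits = 10, trim = TRUE,
                                  scientific = FALSE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(as.vector(t(mesh$nodes))))
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int64" Name="connectivity" format="ascii">')
  w(paste(as.vector(t(el)) - 1L, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="Int64" Name="offsets" format="ascii">')
  w(paste(4L * seq_len(m), collapse = " "))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(10L, m), collapse = " "))
  w('</DataArray>')
  w('</Cells>')
  w('<CellData>')
  w('<DataArray type="Int32" Name="region_id" format="ascii">')
  w(paste(rid, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="ossified" format="ascii">')
  w(paste(as.integer(mesh$ossified), collapse = " "))
  w('</DataArray>')
  for (nm in names(cell_data)) {
    w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
    w(num(cell_data[[nm]]))
    w('</DataArray>')
  }
  w('</CellData>')
  pd <- point_data
  for (nm in names(mesh$node_sets)) {
    v <- numeric(n); v[mesh$node_sets[[nm]]] <- 1
    pd[[paste0("set_", nm)]] <- v
  }
  if (length(mesh$landmarks)) {
    v <- numeric(n); v[mesh$landmarks] <- seq_along(mesh$landmarks)
    pd[["landmarks"]] <- v
  }
  w('<PointData>')
  for (nm in names(pd)) {
    w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
    w(num(pd[[nm]]))
    w('</DataArray>')
  }
  w('</PointData>')
  w('</Piece>')
  w(sprintf('<!-- regions: %s -->',
            paste(seq_along(regions), regions, sep = "=", collapse = " ")))
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Region labels become physical names; node sets and landmarks are stored
#' as named `$NodeData` views so that [read_msh()] round-trips the full
#' `labeled_mesh`.
#'
#' @param mesh a `labeled_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  el <- .corners(mesh)
  n <- nrow(mesh$nodes); m <- nrow(el)
  regions <- sort(unique(mesh$region))
  rid <- match(mesh$region, regions)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("$MeshFormat"); w("2.2 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames"); w(length(regions))
  for (i in seq_along(regions)) w(sprintf('3 %d "%s"', i, regions[i]))
  w("$EndPhysicalNames")
  w("$Nodes"); w(n)
  writeLines(paste(seq_len(n),
                   format(mesh$nodes[, 1], digits = 12, trim = TRUE),
                   format(mesh$nodes[, 2], digits = 12, trim = TRUE),
                   format(mesh$nodes[, 3], digits = 12, trim = TRUE)), con)
  w("$EndNodes")
  w("$Elements"); w(m)
  writeLines(paste(seq_len(m), 4L, 2L, rid, rid,
                   el[, 1], el[, 2], el[, 3], el[, 4]), con)
  w("$EndElements")
  write_view <- function(name, values) {
    w("$NodeData")
    w(1); w(sprintf('"%s"', name))
    w(1); w(0)
    w(3); w(0); w(1); w(length(values))
    nz <- which(values != 0)
    # gmsh requires all listed nodes; keep it dense for simplicity
    writeLines(paste(seq_along(values),
                     format(values, digits = 12, trim = TRUE)), con)
    w("$EndNodeData")
  }
  for (nm in names(mesh$node_sets)) {
    v <- numeric(n); v[mesh$node_sets[[nm]]] <- 1
    write_view(paste0("set:", nm), v)
  }
  if (length(mesh$landmarks)) {
    v <- numeric(n); v[mesh$landmarks] <- seq_along(mesh$landmarks)
    write_view(paste0("landmarks:", paste(names(mesh$landmarks),
                                          collapse = ",")), v)
  }
  if (any(mesh$ossified)) {
    # element data view for the ossification flag
    w("$ElementData")
    w(1); w('"ossified"')
    w(1); w(0)
    w(3); w(0); w(1); w(m)
    writeLines(paste(seq_len(m), as.integer(mesh$ossified)), con)
    w("$EndElementData")
  }
  invisible(path)
}

#' Read a Gmsh MSH 2.2 mesh written by [write_msh()]
#'
#' @param path file path.
#' @return a `labeled_mesh` (region labels from physical names; node sets,
#'   landmarks and the ossification flag restored from the data views).
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) return(NULL)
    lines[(i0 + 1):(i1 - 1)]
  }
  ph <- sec("PhysicalNames")
  regions <- character(0)
  if (!is.null(ph)) {
    for (l in ph[-1]) {
      p <- strsplit(l, " ")[[1]]
      if (length(p) >= 3)
        regions[as.integer(p[2])] <- gsub('"', "", paste(p[-(1:2)],
                                                         collapse = " "))
    }
  }
  nl <- sec("Nodes")
  nn <- as.integer(nl[1])
  nod <- matrix(as.numeric(unlist(strsplit(nl[-1], " +"))), ncol = 4,
                byrow = TRUE)
  nodes <- nod[order(nod[, 1]), 2:4, drop = FALSE]
  elns <- sec("Elements")
  rows <- strsplit(elns[-1], " +")
  tets <- do.call(rbind, lapply(rows, function(p) {
    p <- as.integer(p)
    if (p[2] != 4L) return(NULL)
    ntag <- p[3]
    c(p[4], p[(4 + ntag):(7 + ntag)])
  }))
  region <- regions[tets[, 1]]
  elems <- tets[, 2:5, drop = FALSE]
  node_sets <- list(); landmarks <- integer()
  # data views
  i <- 1
  while (!is.na(i0 <- match("$NodeData", lines[i:length(lines)]))) {
    i0 <- i0 + i - 1L
    i1 <- match("$EndNodeData", lines[i0:length(lines)]) + i0 - 1L
    blk <- lines[(i0 + 1):(i1 - 1)]
    name <- gsub('"', "", blk[2])
    nv <- as.integer(blk[8])
    vals <- matrix(as.numeric(unlist(strsplit(blk[8 + seq_len(nv)], " +"))),
                   ncol = 2, byrow = TRUE)
    v <- numeric(nrow(nodes)); v[vals[, 1]] <- vals[, 2]
    if (startsWith(name, "set:")) {
      node_sets[[substring(name, 5)]] <- which(v > 0.5)
    } else if (startsWith(name, "landmarks:")) {
      nms <- strsplit(substring(name, 11), ",")[[1]]
      lm <- integer(length(nms)); names(lm) <- nms
      for (k in seq_along(nms)) lm[k] <- which(abs(v - k) < 0.5)[1]
      landmarks <- lm
    }
    i <- i1 + 1L
  }
  ossified <- rep(FALSE, nrow(elems))
  ed0 <- match("$ElementData", lines)
  if (!is.na(ed0)) {
    ed1 <- match("$EndElementData", lines)
    blk <- lines[(ed0 + 1):(ed1 - 1)]
    nv <- as.integer(blk[8])
    vals <- matrix(as.numeric(unlist(strsplit(blk[8 + seq_len(nv)], " +"))),
                   ncol = 2, byrow = TRUE)
    ossified[vals[, 1]] <- vals[, 2] > 0.5
  }
  labeled_mesh(nodes, elems, region, node_sets = node_sets,
               landmarks = landmarks, ossified = ossified)
}
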