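# Per-specimen visualization of a joined, standardized configuration.

#' Plot one specimen of a joined rotated dataset in 3D
#'
#' Draws the two standardized structures of a single specimen as a 3D
#' scatter under an orthographic projection, structure 1 in black and
#' structure 2 in red by default.  The provenance attribute written by
#' [join_arrays()] (and by the rotation procedures) determines which
#' landmark belongs to which structure.
#'
#' @param joined A joined landmark array with a `provenance` attribute.
#' @param specimen Specimen selector: a 1-based index or an id string.
#'   Defaults to the first specimen.
#' @param colors Length-2 vector of colors for structures 1 and 2.
#' @param file Optional path; when given, the plot is written there as a
#'   PNG instead of being drawn on the active device.
#' @param theta,phi Viewing angles in degrees (azimuth, elevation) of the
#'   orthographic projection.
#' @param cex Point size.
#' @return Invisibly, the projected 2D coordinates.
#' @export
plot_rotation_3d <- function(joined, specimen = 1, colors = c("black", "red"),
                             file = NULL, theta = 35, phi = 20, cex = 1) {
  parts <- split_joined(joined)           # validates provenance
  joined <- check_landmark_array(joined, "joined")
  ids <- specimen_ids(joined)
  if (is.character(specimen)) {
    if (!specimen %in% ids)
      abort_index(sprintf("no specimen named '%s'", specimen))
    specimen <- match(specimen, ids)
  }
  specimen <- check_landmark_index(specimen, length(ids), "specimen")
  if (length(colors) < 2L)
    abort_validation("colors must name two colors (structure 1, structure 2)")

  m <- specimen_matrix(joined, specimen)
  prov <- attr(joined, "provenance")
  # orthographic view: spin about z, then tilt about x
  view <- rotation_matrix(c(1, 0, 0), -phi * pi / 180) %*%
    rotation_matrix(c(0, 0, 1), -theta * pi / 180)
  proj <- m %*% t(view)

  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 800)
    on.exit(grDevices::dev.off())
  }
  col <- ifelse(prov == "structure1", colors[1L], colors[2L])
  graphics::plot(proj[, 1L], proj[, 2L], col = col, pch = 19, asp = 1,
                 cex = cex, xlab = "", ylab = "",
                 main = sprintf("specimen %s", ids[specimen]))
  graphics::legend("topright", legend = c("structure 1", "structure 2"),
                   col = colors[1:2], pch = 19, bty = "n")
  invisible(proj[, 1:2])
}
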