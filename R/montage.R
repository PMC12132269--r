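#' Electrode montage with 2-D scalp coordinates
#'
#' A montage holds ordered electrode labels and their positions on the unit
#' head disc (azimuthal-equidistant projection of 10-20 scalp positions:
#' radius = inclination from the vertex / 90 degrees, so Cz projects to the
#' origin and the 90-degree inclination ring to the unit circle).
#'
#' @param channel_names Character vector of unique electrode labels.
#' @param positions_2d Numeric matrix (n x 2) of (x, y) coordinates with
#'   `x^2 + y^2 <= 1`; `+y` is anterior (nose), `+x` is the right ear.
#' @param reference Free-text description of the reference scheme.
#'
#' @return An object of class `gw_montage`.
#' @export
montage <- function(channel_names, positions_2d, reference = "unspecified") {
  positions_2d <- as.matrix(positions_2d)
  if (anyDuplicated(channel_names)) {
    stop_validation("montage: duplicate channel names")
  }
  if (nrow(positions_2d) != length(channel_names) || ncol(positions_2d) != 2) {
    stop_validation(
      "montage: positions must be a %d x 2 matrix", length(channel_names)
    )
  }
  r2 <- rowSums(positions_2d^2)
  if (any(r2 > 1 + 1e-12)) {
    stop_validation(
      "montage: channel(s) %s outside the unit head disc",
      paste(channel_names[r2 > 1 + 1e-12], collapse = ", ")
    )
  }
  rownames(positions_2d) <- channel_names
  colnames(positions_2d) <- c("x", "y")
  structure(
    list(
      channel_names = as.character(channel_names),
      positions_2d = positions_2d,
      reference = reference
    ),
    class = "gw_montage"
  )
}

#' Project 10-20 spherical electrode coordinates to the unit disc
#'
#' Azimuthal-equidistant projection: a point at inclination `incl_deg` from
#' the vertex and azimuth `az_deg` (measured from the nose direction,
#' positive towards the right ear) maps to polar radius `incl_deg / 90` on
#' the plane. The vertex (Cz) maps to the origin; already-projected points
#' are unchanged if re-projected through their spherical preimage.
#'
#' @param incl_deg Inclination from the vertex, degrees (0 = Cz).
#' @param az_deg Azimuth from the anterior midline, degrees (positive right).
#' @return Numeric matrix with columns x, y.
#' @export
project_1020 <- function(incl_deg, az_deg) {
  r <- incl_deg / 90
  cbind(x = r * sin(az_deg * pi / 180), y = r * cos(az_deg * pi / 180))
}

#' Default 8-channel dry-electrode montage
#'
#' The hybrid dry-electrode headset layout used by the pipeline:
#' Fz, C3, Cz, C4, Pz, PO7, Oz, PO8, referenced to linked mastoids. Central
#' channels C3/Cz/C4 overlie sensorimotor cortex; PO7/Oz/PO8 are
#' parieto-occipital.
#'
#' @return A [montage()] object with 8 channels.
#' @export
#' @examples
#' m <- default_montage()
#' m$channel_names
default_montage <- function() {
  # (inclination from vertex, azimuth from nose, degrees)
  sph <- rbind(
    Fz  = c(45, 0),
    C3  = c(45, -90),
    Cz  = c(0, 0),
    C4  = c(45, 90),
    Pz  = c(45, 180),
    PO7 = c(81, -144),
    Oz  = c(90, 180),
    PO8 = c(81, 144)
  )
  montage(
    channel_names = rownames(sph),
    positions_2d = project_1020(sph[, 1], sph[, 2]),
    reference = "linked mastoids"
  )
}

#' @export
print.gw_montage <- function(x, ...) {
  cat(sprintf(
    "<gw_montage> %d channels (%s), reference: %s\n",
    length(x$channel_names), paste(x$channel_names, collapse = ", "),
    x$reference
  ))
  invisible(x)
}
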