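#' Standard 22-channel 10/20 montage
#'
#' Channel names of the wireless cap used throughout the package, in recording
#' order: frontal to occipital plus both mastoids.
#'
#' @return Character vector of 22 channel labels.
#' @export
montage_channels <- function() {
  c("Fp1", "Fp2", "AFz", "F3", "Fz", "F4", "T7", "C3", "Cz", "C4", "T8",
    "CPz", "P7", "P3", "Pz", "P4", "P8", "POz", "O1", "O2", "M1", "M2")
}

#' Idealized spherical electrode positions for the 10/20 montage
#'
#' Unit-sphere coordinates built from the standard 10/20 construction
#' (inclination from the vertex, azimuth from the nasion; x points right,
#' y anterior, z superior). These are idealized positions, not digitized
#' ones; they are used only for spherical-spline interpolation, which is
#' insensitive to millimetre-scale placement error.
#'
#' @param channels Channel labels to return (default: full montage).
#' @return data.frame with columns `channel`, `x`, `y`, `z` (unit radius).
#' @export
montage_positions <- function(channels = montage_channels()) {
  # inclination theta (deg from vertex), azimuth phi (deg from nasion,
  # positive toward the right ear); mastoids sit below the equator
  tab <- rbind(
    Fp1 = c(90, -18),  Fp2 = c(90, 18),   AFz = c(69, 0),
    F3  = c(60, -39),  Fz  = c(45, 0),    F4  = c(60, 39),
    T7  = c(90, -90),  C3  = c(45, -90),  Cz  = c(0, 0),
    C4  = c(45, 90),   T8  = c(90, 90),   CPz = c(22.5, 180),
    P7  = c(90, -126), P3  = c(60, -141), Pz  = c(45, 180),
    P4  = c(60, 141),  P8  = c(90, 126),  POz = c(67.5, 180),
    O1  = c(90, -162), O2  = c(90, 162),  M1  = c(102, -100),
    M2  = c(102, 100)
  )
  missing <- setdiff(channels, rownames(tab))
  if (length(missing) > 0)
    stop("no stored position for channel(s): ", paste(missing, collapse = ", "))
  th <- tab[channels, 1] * pi / 180
  ph <- tab[channels, 2] * pi / 180
  data.frame(
    channel = channels,
    x = sin(th) * sin(ph),
    y = sin(th) * cos(ph),
    z = cos(th),
    stringsAsFactors = FALSE
  )
}
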