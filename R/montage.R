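#' Idealized 64-channel 10-10 montage on the unit sphere
#'
#' Builds the electrode layout used throughout the package: 64 channels of
#' the extended international 10-20 (10-10) system placed on an idealized
#' unit sphere. Midline electrodes sit at 18 degree steps along the
#' nasion-inion arc; lateral electrodes are placed by spherical (great
#' circle) interpolation between the midline electrode and the outer-ring
#' electrode of the same row, which is the standard idealization when no
#' digitized positions are available.
#'
#' @param channels optional character vector selecting a subset (in the
#'   returned order). Default: all 64 channels.
#' @return An object of class `eeg_montage`: a list with
#'   \itemize{
#'     \item `channels`: character vector of channel names,
#'     \item `pos3d`: n x 3 matrix of unit-sphere coordinates
#'       (x = right, y = anterior, z = superior),
#'     \item `pos2d`: n x 2 azimuthal-equidistant projection used for
#'       topographic grids (head circle of radius 1),
#'     \item `lobe`: factor assigning each channel to one of
#'       frontal/central/temporal/parietal/occipital.
#'   }
#' @examples
#' mon <- standard_montage_64()
#' table(mon$lobe)
#' @export
standard_montage_64 <- function(channels = NULL) {
  sph <- .montage_sphere_angles()
  chi <- sph$chi * pi / 180     # arc distance from vertex
  az  <- sph$az * pi / 180      # azimuth, 0 = anterior, positive clockwise (to the right)
  pos3d <- cbind(
    x = sin(chi) * sin(az),
    y = sin(chi) * cos(az),
    z = cos(chi)
  )
  rownames(pos3d) <- sph$channel
  # azimuthal equidistant: radius proportional to arc distance, ear ring at r = 1
  r2 <- sph$chi / 90
  pos2d <- cbind(x = r2 * sin(az), y = r2 * cos(az))
  rownames(pos2d) <- sph$channel
  lobe <- factor(.default_lobe_map()[sph$channel],
                 levels = c("frontal", "central", "temporal", "parietal", "occipital"))
  mon <- structure(
    list(channels = sph$channel, pos3d = pos3d, pos2d = pos2d, lobe = lobe),
    class = "eeg_montage"
  )
  if (!is.null(channels)) mon <- montage_subset(mon, channels)
  mon
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels\n", length(x$channels)))
  print(table(x$lobe))
  invisible(x)
}

#' Restrict a montage to a channel subset
#'
#' @param mon an `eeg_montage`
#' @param channels channel names to keep (order preserved)
#' @export
montage_subset <- function(mon, channels) {
  missing <- setdiff(channels, mon$channels)
  if (length(missing))
    stop("channels not in montage: ", paste(missing, collapse = ", "))
  idx <- match(channels, mon$channels)
  structure(
    list(channels = mon$channels[idx],
         pos3d = mon$pos3d[idx, , drop = FALSE],
         pos2d = mon$pos2d[idx, , drop = FALSE],
         lobe = mon$lobe[idx]),
    class = "eeg_montage"
  )
}

#' Channel-to-lobe mapping
#'
#' Returns the lobe label for each requested channel. The default mapping
#' groups 10-10 rows as frontal (Fp/AF/F), central (FC/C), temporal
#' (FT/T/TP), parietal (CP/P) and occipital (PO/O/I); it can be overridden
#' with a two-column data frame (channel, lobe), e.g. read from a user
#' config file.
#'
#' @param channels character vector of channel names
#' @param mapping optional data.frame with columns `channel` and `lobe`
#' @return named character vector of lobe labels
#' @export
channel_lobes <- function(channels, mapping = NULL) {
  map <- .default_lobe_map()
  if (!is.null(mapping)) {
    stopifnot(all(c("channel", "lobe") %in% names(mapping)))
    map[as.character(mapping$channel)] <- as.character(mapping$lobe)
  }
  out <- map[channels]
  if (anyNA(out)) {
    bad <- channels[is.na(out)]
    stop("no lobe mapping for channel(s): ", paste(bad, collapse = ", "))
  }
  names(out) <- channels
  out
}

#' The five scalp lobes used for regional aggregation
#' @export
lobe_names <- function() c("frontal", "central", "temporal", "parietal", "occipital")

# -- internal ---------------------------------------------------------------

# Explicit per-channel map; FT*/TP* belong to the temporal chain even though
# their names start with F/T+P, so prefix matching is avoided.
.default_lobe_map <- function() {
  frontal  <- c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
                "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")
  central  <- c("FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
                "C5", "C3", "C1", "Cz", "C2", "C4", "C6")
  temporal <- c("FT7", "FT8", "T7", "T8", "TP7", "TP8")
  parietal <- c("CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
                "P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10")
  occipital <- c("PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz")
  map <- c(
    stats::setNames(rep("frontal", length(frontal)), frontal),
    stats::setNames(rep("central", length(central)), central),
    stats::setNames(rep("temporal", length(temporal)), temporal),
    stats::setNames(rep("parietal", length(parietal)), parietal),
    stats::setNames(rep("occipital", length(occipital)), occipital)
  )
  map
}

# chi: arc distance from vertex Cz (degrees); az: azimuth from anterior
# midline, positive to the right. Lateral electrodes interpolate along the
# great circle between the row's midline and outer-ring electrodes.
.montage_sphere_angles <- function() {
  ang <- function(channel, chi, az) data.frame(channel = channel, chi = chi, az = az,
                                               stringsAsFactors = FALSE)
  midline <- ang(c("Fpz", "AFz", "Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz", "Iz"),
                 c(72, 54, 36, 18, 0, 18, 36, 54, 72, 90),
                 c(0, 0, 0, 0, 0, 180, 180, 180, 180, 180))
  # outer ring at chi = 72, azimuth in 18 degree steps front -> back
  ringL <- ang(c("Fp1", "AF7", "F7", "FT7", "T7", "TP7", "P7", "PO7", "O1"),
               rep(72, 9), -c(18, 36, 54, 72, 90, 108, 126, 144, 162))
  ringR <- ringL
  ringR$channel <- c("Fp2", "AF8", "F8", "FT8", "T8", "TP8", "P8", "PO8", "O2")
  ringR$az <- -ringL$az
  # lowest ring at chi = 90 (10% below the ear line)
  low <- ang(c("P9", "P10"), c(90, 90), c(-126, 126))

  base <- rbind(midline, ringL, ringR, low)
  unit <- function(chi, az) {
    chi <- chi * pi / 180; az <- az * pi / 180
    c(sin(chi) * sin(az), sin(chi) * cos(az), cos(chi))
  }
  slerp <- function(a, b, t) {
    va <- unit(a$chi, a$az); vb <- unit(b$chi, b$az)
    om <- acos(pmin(1, pmax(-1, sum(va * vb))))
    v <- (sin((1 - t) * om) * va + sin(t * om) * vb) / sin(om)
    v <- v / sqrt(sum(v^2))
    c(chi = acos(v[3]) * 180 / pi, az = atan2(v[1], v[2]) * 180 / pi)
  }
  rows <- list(
    list(mid = "Fz",  out = "F7",  names = c("F1", "F3", "F5"),    t = c(0.25, 0.5, 0.75)),
    list(mid = "FCz", out = "FT7", names = c("FC1", "FC3", "FC5"), t = c(0.25, 0.5, 0.75)),
    list(mid = "Cz",  out = "T7",  names = c("C1", "C3", "C5"),    t = c(0.25, 0.5, 0.75)),
    list(mid = "CPz", out = "TP7", names = c("CP1", "CP3", "CP5"), t = c(0.25, 0.5, 0.75)),
    list(mid = "Pz",  out = "P7",  names = c("P1", "P3", "P5"),    t = c(0.25, 0.5, 0.75)),
    list(mid = "AFz", out = "AF7", names = "AF3", t = 0.5),
    list(mid = "POz", out = "PO7", names = "PO3", t = 0.5)
  )
  extra <- list()
  for (rw in rows) {
    a <- base[base$channel == rw$mid, ]
    b <- base[base$channel == rw$out, ]
    for (k in seq_along(rw$names)) {
      p <- slerp(a, b, rw$t[k])
      extra[[length(extra) + 1L]] <- ang(rw$names[k], p["chi"], p["az"])
      # mirrored right-hemisphere twin: F1 -> F2 etc.
      twin <- sub("([135])$", "", rw$names[k])
      twin <- paste0(twin, c("1" = "2", "3" = "4", "5" = "6")[sub("^.*([135])$", "\\1", rw$names[k])])
      extra[[length(extra) + 1L]] <- ang(twin, p["chi"], -p["az"])
    }
  }
  out <- rbind(base, do.call(rbind, extra))
  ordered <- c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
               "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
               "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
               "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
               "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
               "P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10",
               "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz")
  out <- out[match(ordered, out$channel), ]
  rownames(out) <- NULL
  out
}
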