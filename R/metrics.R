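#' Geodesic length of an 8-connected pixel path
#'
#' Weighted step length: 1 per orthogonal step, sqrt(2) per diagonal step.
#' The weighted geodesic (rather than a raw pixel count) is what makes the
#' linearity index, contour / Euclidean distance, provably >= 1.
#'
#' @param path n x 2 (row, col) matrix; consecutive rows must be
#'   8-neighbours.
#' @return length in pixels (0 for a single-pixel path).
#' @export
path_length <- function(path) {
  if (!is.matrix(path) || ncol(path) != 2L)
    stop("'path' must be an n x 2 (row, col) matrix")
  n <- nrow(path)
  if (n <= 1L) return(0)
  dr <- abs(diff(path[, 1L])); dc <- abs(diff(path[, 2L]))
  if (any(dr > 1L | dc > 1L | (dr == 0L & dc == 0L)))
    stop("consecutive path pixels must be distinct 8-neighbours")
  sum(ifelse(dr + dc == 2L, sqrt(2), 1))
}

#' Dilation band around an interface
#'
#' The band is the set of pixels within Chebyshev distance `dilation`
#' (1 to 9, the user-set dilation) of any path pixel, clipped to the image
#' bounds. Its pixel count is the interface area; all marker area and
#' intensity measurements happen inside it.
#'
#' @param interface an interface record (from [extract_interfaces()]).
#' @param dilation integer in 1..9.
#' @param image_shape `c(rows, cols)` of the source image.
#' @return a `band_mask`: list with `interface_id`, `pixels` (0/1 matrix),
#'   `dilation`.
#' @export
dilate_interface <- function(interface, dilation, image_shape) {
  if (length(dilation) != 1L || is.na(dilation) ||
      dilation < 1 || dilation > 9)
    stop("'dilation' must be an integer in 1..9")
  m <- matrix(0L, image_shape[1L], image_shape[2L])
  m[interface$path] <- 1L
  band <- dilate_chebyshev(m, as.integer(dilation))
  structure(list(interface_id = interface$id, pixels = band,
                 dilation = as.integer(dilation)),
            class = "band_mask")
}

# Assign every band pixel to its nearest path pixel (Euclidean; ties to the
# lower path index). Returns the path index per band pixel, aligned with
# which(band == 1L).
band_sections <- function(interface, band) {
  bp <- which(band$pixels == 1L, arr.ind = TRUE)
  path <- interface$path
  n <- nrow(path)
  assign_idx <- integer(nrow(bp))
  # chunked distance computation keeps memory flat on long interfaces
  step <- max(1L, floor(2e6 / n))
  for (s in seq(1L, nrow(bp), by = step)) {
    e <- min(s + step - 1L, nrow(bp))
    d2 <- outer(bp[s:e, 1L], path[, 1L], `-`)^2 +
      outer(bp[s:e, 2L], path[, 2L], `-`)^2
    assign_idx[s:e] <- max.col(-d2, ties.method = "first")
  }
  list(band_pixels = bp, path_index = assign_idx)
}

#' Covered runs of an interface under a marker mask
#'
#' Each path pixel owns its perpendicular band cross-section: the band
#' pixels nearest to it (ties to the lower path index). A path pixel is
#' covered when its cross-section contains at least one above-threshold
#' marker pixel. Returns the maximal runs of consecutive covered path
#' indices; any single uncovered pixel splits runs (gap tolerance
#' `gap_tolerance`, default 0, is the most literal reading of individual
#' staining fragments).
#'
#' @param interface interface record.
#' @param band matching `band_mask`.
#' @param marker_mask binary matrix (thresholded marker image).
#' @param gap_tolerance number of consecutive uncovered pixels bridged
#'   within a run.
#' @return data frame with columns `start`, `end` (path indices, inclusive).
#' @export
covered_runs <- function(interface, band, marker_mask, gap_tolerance = 0L) {
  sec <- band_sections(interface, band)
  pos <- marker_mask[sec$band_pixels] > 0
  n <- nrow(interface$path)
  covered <- rep(FALSE, n)
  hit <- unique(sec$path_index[pos])
  covered[hit] <- TRUE
  if (gap_tolerance > 0L && any(covered)) {
    idx <- which(covered)
    gaps <- which(diff(idx) > 1L & diff(idx) <= gap_tolerance + 1L)
    for (g in gaps) covered[idx[g]:idx[g + 1L]] <- TRUE
  }
  runs_from_logical(covered)
}

runs_from_logical <- function(covered) {
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Primary per-junction parameters
#'
#' Measures one interface with its dilation band against a marker image:
#' \describe{
#'   \item{interface_contour}{geodesic length of the full corner-to-corner
#'     path, in pixels.}
#'   \item{straight_interface_length}{Euclidean distance between the two
#'     corners.}
#'   \item{interface_area}{band pixel count, px^2.}
#'   \item{fragmented_junction_contour}{sum of geodesic lengths of the
#'     individual covered runs (staining fragments).}
#'   \item{junction_contour}{geodesic length between the outermost covered
#'     path pixels.}
#'   \item{straight_junction_length}{Euclidean distance between those
#'     outermost covered pixels.}
#'   \item{junction_area}{band pixels whose nearest path index lies between
#'     the outermost covered indices.}
#'   \item{marker_area}{above-threshold pixels inside the band, px^2.}
#'   \item{marker_intensity}{summed intensity of above-threshold pixels
#'     inside the band, A.U.}
#' }
#' All junction fields are 0 when no covered run exists.
#'
#' @param interface interface record.
#' @param band matching `band_mask`.
#' @param image marker [raster_image].
#' @param threshold marker threshold (strict `>`).
#' @param gap_tolerance passed to [covered_runs()].
#' @return named list of class `primary_measures`.
#' @export
measure_primary <- function(interface, band, image, threshold,
                            gap_tolerance = 0L) {
  marker_mask <- apply_threshold(image, threshold)
  sec <- band_sections(interface, band)
  path <- interface$path
  n <- nrow(path)
  in_band_pos <- marker_mask[sec$band_pixels] > 0
  runs <- covered_runs(interface, band, marker_mask, gap_tolerance)
  icontour <- path_length(path)
  slen <- sqrt(sum((path[1L, ] - path[n, ])^2))
  iarea <- nrow(sec$band_pixels)
  marker_area <- sum(in_band_pos)
  marker_intensity <- sum(unclass(image)[sec$band_pixels][in_band_pos])
  if (nrow(runs) == 0L) {
    jc <- fjc <- sjl <- jarea <- 0
  } else {
    fjc <- sum(vapply(seq_len(nrow(runs)), function(i) {
      path_length(path[runs$start[i]:runs$end[i], , drop = FALSE])
    }, numeric(1)))
    lo <- min(runs$start); hi <- max(runs$end)
    jc <- path_length(path[lo:hi, , drop = FALSE])
    sjl <- sqrt(sum((path[lo, ] - path[hi, ])^2))
    jarea <- sum(sec$path_index >= lo & sec$path_index <= hi)
  }
  structure(list(interface_contour = icontour,
                 straight_interface_length = slen,
                 interface_area = iarea,
                 junction_contour = jc,
                 straight_junction_length = sjl,
                 junction_area = jarea,
                 fragmented_junction_contour = fjc,
                 marker_area = marker_area,
                 marker_intensity = marker_intensity),
            class = "primary_measures")
}

#' Secondary (size-normalized) per-junction parameters
#'
#' \describe{
#'   \item{interface_linearity_index}{interface_contour /
#'     straight_interface_length; 1 = taut, > 1 = undulated.}
#'   \item{junction_linearity_index}{junction_contour /
#'     straight_junction_length (`NA` when no staining).}
#'   \item{coverage_index}{100 * fragmented_junction_contour /
#'     interface_contour, percent of the interface length covered by
#'     staining fragments.}
#'   \item{interface_occupancy}{100 * marker_area / interface_area, percent
#'     of the band area occupied by the marker.}
#'   \item{intensity_per_interface_area}{marker_intensity / interface_area.}
#'   \item{cluster_density}{marker_intensity / marker_area — the mean
#'     intensity within the marker's own stained area (`NA` when
#'     marker_area is 0); high values mean receptors packed into dense
#'     clusters.}
#' }
#'
#' @param p a `primary_measures` list.
#' @param cluster_denominator which area divides marker_intensity for
#'   cluster density: `"marker_area"` (default; the area delimited by the
#'   staining itself), `"junction_area"` (band area between outermost
#'   staining).
#' @return named list of class `secondary_measures`.
#' @export
derive_secondary <- function(p, cluster_denominator = c("marker_area",
                                                        "junction_area")) {
  cluster_denominator <- match.arg(cluster_denominator)
  if (p$interface_contour <= 0 || p$interface_area <= 0)
    stop("degenerate interface: zero contour or area")
  jli <- if (p$straight_junction_length > 0)
    p$junction_contour / p$straight_junction_length else NA_real_
  cd_den <- switch(cluster_denominator,
                   marker_area = p$marker_area,
                   junction_area = p$junction_area)
  structure(list(
    interface_linearity_index = p$interface_contour /
      p$straight_interface_length,
    junction_linearity_index = jli,
    coverage_index = 100 * p$fragmented_junction_contour /
      p$interface_contour,
    interface_occupancy = 100 * p$marker_area / p$interface_area,
    intensity_per_interface_area = p$marker_intensity / p$interface_area,
    cluster_density = if (cd_den > 0) p$marker_intensity / cd_den
    else NA_real_),
    class = "secondary_measures")
}

#' Measure a second, co-registered marker inside the first marker's band
#'
#' The interface geometry (path, corners, band) comes from marker 1's
#' skeleton and acts as a mask; marker 2's thresholded pixels inside that
#' band drive all junction, area and intensity fields. Interface-level
#' geometry (contour, straight length, area) is identical to marker 1's.
#'
#' @param interface interface record (from marker 1).
#' @param band marker 1's `band_mask`.
#' @param marker2 co-registered [raster_image] of the second marker.
#' @param threshold2 marker 2 threshold.
#' @param gap_tolerance passed to [covered_runs()].
#' @param cluster_denominator see [derive_secondary()].
#' @return list with elements `primary` and `secondary`.
#' @export
measure_second_marker <- function(interface, band, marker2, threshold2,
                                  gap_tolerance = 0L,
                                  cluster_denominator = "marker_area") {
  if (!identical(dim(band$pixels), dim(marker2)))
    stop("marker 2 shape differs from the band")
  p <- measure_primary(interface, band, marker2, threshold2, gap_tolerance)
  list(primary = p,
       secondary = derive_secondary(p, cluster_denominator))
}
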