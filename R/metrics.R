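#' Label high-canopy patches
#'
#' Connected-component labeling of a binary raster (8-connectivity by
#' default, matching the Moore neighbourhood used for scenario sampling),
#' with per-patch area and perimeter. Perimeter is the exposed cell-edge
#' length: edges bordering non-patch cells, and — when
#' `count_boundary = TRUE` (default) — edges on the raster boundary.
#'
#' @param high_canopy Logical (or 0/1) matrix.
#' @param cell_size Cell side length (m).
#' @param connectivity 8 (default) or 4.
#' @param count_boundary Count raster-boundary edges towards perimeters.
#' @return Object of class `patch_set`: list with `labels` (integer
#'   matrix), `area_ha`, `perimeter_m` (per-patch vectors), `n_patches`,
#'   `cell_size`, `landscape_area_ha`.
#' @export
label_patches <- function(high_canopy, cell_size = 10, connectivity = 8,
                          count_boundary = TRUE) {
  x <- matrix(as.logical(high_canopy), nrow(high_canopy))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  lab <- .label_components(x, as.integer(connectivity))
  np <- max(lab)
  landscape_ha <- length(x) * cell_size^2 / 1e4
  if (np == 0)
    return(structure(list(labels = lab, area_ha = numeric(0),
                          perimeter_m = numeric(0), n_patches = 0L,
                          cell_size = cell_size,
                          landscape_area_ha = landscape_ha),
                     class = "patch_set"))
  sizes <- tabulate(lab[lab > 0], nbins = np)

  # exposed edges per patch: 4-neighbour not in a patch, or raster boundary
  edges <- integer(np)
  nr <- nrow(x); nc <- ncol(x)
  for (s in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- shift_matrix(x, s[1L], s[2L])
    exposed <- x & (if (count_boundary) (is.na(nb) | !nb) else
      (!is.na(nb) & !nb))
    cnt <- tabulate(lab[exposed], nbins = np)
    edges <- edges + cnt
  }
  structure(list(labels = lab,
                 area_ha = sizes * cell_size^2 / 1e4,
                 perimeter_m = edges * cell_size,
                 n_patches = np,
                 cell_size = cell_size,
                 landscape_area_ha = landscape_ha),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches, total %.2f ha in %.2f ha landscape\n",
              x$n_patches, sum(x$area_ha), x$landscape_area_ha))
  invisible(x)
}

#' Percentage of landscape (PLAND)
#'
#' Share of the landscape area occupied by patch pixels, in percent.
#'
#' @param patches A [label_patches()] result.
#' @param landscape_area_ha Landscape area (ha); defaults to the full
#'   raster extent.
#' @return Percentage in `[0, 100]`.
#' @export
pland <- function(patches, landscape_area_ha = patches$landscape_area_ha) {
  if (landscape_area_ha <= 0) stop("landscape area must be positive")
  100 * sum(patches$area_ha) / landscape_area_ha
}

#' Mean patch area (AREA_MN)
#'
#' @param patches A [label_patches()] result.
#' @return Mean patch area in hectares; `NA` when there are no patches.
#' @export
area_mn <- function(patches) {
  if (patches$n_patches == 0) return(NA_real_)
  mean(patches$area_ha)
}

#' Mean shape index (SHAPE_MN)
#'
#' Per-patch shape index `0.25 * perimeter / sqrt(area)` (perimeter in m,
#' area in m^2); 1 for a single square cell, larger for more complex
#' shapes.
#'
#' @param patches A [label_patches()] result.
#' @return Mean shape index; `NA` when there are no patches.
#' @export
shape_mn <- function(patches) {
  if (patches$n_patches == 0) return(NA_real_)
  mean(0.25 * patches$perimeter_m / sqrt(patches$area_ha * 1e4))
}

#' Edge density (ED)
#'
#' Total patch edge length per landscape area, in m/ha.
#'
#' @param patches A [label_patches()] result.
#' @param landscape_area_ha Landscape area (ha).
#' @return Edge density (m/ha).
#' @export
ed <- function(patches, landscape_area_ha = patches$landscape_area_ha) {
  if (landscape_area_ha <= 0) stop("landscape area must be positive")
  sum(patches$perimeter_m) / landscape_area_ha
}

#' Pixel count to area conversion
#'
#' @param n_pixels Number of pixels.
#' @param res Cell side length (m).
#' @return Area in hectares.
#' @export
pixel_area_ha <- function(n_pixels, res = 10) {
  n_pixels * res^2 / 1e4
}

#' The four canopy landscape metrics of a refined grid
#'
#' Computes PLAND, AREA_MN, SHAPE_MN and ED over the 8-connected patches
#' of high-canopy pixels.
#'
#' @param x A [refined_lulc()] object, or a binary high-canopy matrix.
#' @param cell_size Cell side length (m); taken from the grid if `x` is a
#'   `refined_lulc`.
#' @param connectivity 8 (default) or 4.
#' @param count_boundary Count raster-boundary edges towards ED.
#' @return One-row data frame: `pland`, `area_mn`, `shape_mn`, `ed`,
#'   `n_patches`.
#' @export
landscape_metrics <- function(x, cell_size = 10, connectivity = 8,
                              count_boundary = TRUE) {
  if (inherits(x, "refined_lulc")) {
    cell_size <- x$res
    x <- is_high_canopy(x)
  }
  p <- label_patches(x, cell_size, connectivity, count_boundary)
  data.frame(pland = pland(p), area_mn = area_mn(p), shape_mn = shape_mn(p),
             ed = ed(p), n_patches = p$n_patches)
}
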