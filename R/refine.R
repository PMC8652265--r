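#' Block-aggregate a fine raster to a coarse one
#'
#' Each coarse value is the arithmetic mean of its `factor` x `factor` block
#' of fine cells.
#'
#' @param x Numeric matrix (fine resolution).
#' @param factor Integer aggregation ratio; must divide both dimensions.
#' @return Numeric matrix of dimension `dim(x) / factor`.
#' @export
block_aggregate <- function(x, factor) {
  factor <- as.integer(factor)
  if (nrow(x) %% factor != 0 || ncol(x) %% factor != 0)
    stop("raster dimensions not divisible by the aggregation factor")
  nr <- nrow(x) %/% factor
  nc <- ncol(x) %/% factor
  # sum over columns within blocks, then rows
  xr <- rowsum(x, rep(seq_len(nr), each = factor))
  xc <- t(rowsum(t(xr), rep(seq_len(nc), each = factor)))
  xc / (factor * factor)
}

#' Per-coarse-pixel cover fraction of a fine binary mask
#'
#' @param fine_mask Binary matrix at fine resolution.
#' @param factor Integer aggregation ratio (fine cells per coarse cell side).
#' @return Matrix of fractions in `[0, 1]` at coarse resolution.
#' @export
cover_fractions <- function(fine_mask, factor) {
  if (!all(fine_mask %in% c(0, 1)))
    stop("fine_mask must be binary")
  block_aggregate(fine_mask, factor)
}

#' Bin a cover fraction into four equal intervals
#'
#' Bins are `[0, 0.25)`, `[0.25, 0.5)`, `[0.5, 0.75)` and `[0.75, 1]`:
#' half-open below the top bin, which is closed so a fraction of exactly
#' 0.75 counts as high cover. Vectorised.
#'
#' @param frac Fractions in `[0, 1]` (vector or matrix).
#' @param n_bins Number of equal bins (default 4).
#' @return Integer bin indices `0 .. n_bins - 1`, same shape as `frac`.
#' @export
bin_fraction <- function(frac, n_bins = 4L) {
  if (any(frac < 0 | frac > 1, na.rm = TRUE))
    stop("fractions must lie in [0, 1]")
  b <- pmin(as.integer(floor(frac * n_bins)), n_bins - 1L)
  if (is.matrix(frac)) b <- matrix(b, nrow = nrow(frac))
  b
}

#' Shade coefficient of a tree-cover bin
#'
#' The shade coefficient of a refined class is the midpoint of its
#' tree-cover bin interval: 0.125, 0.375, 0.625 and 0.875 for bins 0..3.
#'
#' @param tree_bin Integer bin index in `0 .. n_bins - 1` (vectorised).
#' @param n_bins Number of equal bins (default 4).
#' @return Midpoint fraction(s) in `[0, 1]`.
#' @export
shade_coefficient <- function(tree_bin, n_bins = 4L) {
  if (any(tree_bin < 0 | tree_bin >= n_bins))
    stop("bin index out of range")
  (tree_bin + 0.5) / n_bins
}

#' Albedo coefficient of a refined class
#'
#' Linear interpolation between the base class albedo and the building
#' albedo, weighted by the building-cover bin midpoint: with midpoint m,
#' albedo = (1 - m) * base + m * building.
#'
#' @param base_albedo Albedo of the base class, in `[0, 1]`.
#' @param building_albedo Albedo of full building cover, in `[0, 1]`.
#' @param building_bin Integer bin index `0 .. n_bins - 1` (vectorised).
#' @param n_bins Number of equal bins (default 4).
#' @return Interpolated albedo, bounded by the two endpoints.
#' @export
albedo_coefficient <- function(base_albedo, building_albedo, building_bin,
                               n_bins = 4L) {
  if (any(base_albedo < 0 | base_albedo > 1) ||
      any(building_albedo < 0 | building_albedo > 1))
    stop("albedos must lie in [0, 1]")
  if (any(building_bin < 0 | building_bin >= n_bins))
    stop("bin index out of range")
  m <- (building_bin + 0.5) / n_bins
  (1 - m) * base_albedo + m * building_albedo
}

#' Refine a coarse LULC raster by tree and building cover
#'
#' Joins the per-pixel tree-cover and building-cover histograms: each pixel
#' of base class c with tree bin t and building bin b receives the refined
#' code `c * 100 + t * 10 + b`, e.g. a sidewalk pixel with 80% tree and 10%
#' building cover becomes "sidewalk with high tree / low building cover".
#'
#' @param base Coarse integer raster of base class codes.
#' @param tree_frac,building_frac Matrices of per-pixel cover fractions in
#'   `[0, 1]`, same shape as `base` (from [cover_fractions()]).
#' @param res Cell size in metres (taken from `attr(base, "res")` if
#'   present).
#' @return A [refined_lulc()] object.
#' @export
refine_lulc <- function(base, tree_frac, building_frac,
                        res = attr(base, "res")) {
  if (!all(dim(base) == dim(tree_frac)) ||
      !all(dim(base) == dim(building_frac)))
    stop("raster shapes do not match")
  if (!all(base %in% base_classes))
    stop("unknown base class code: ",
         paste(setdiff(unique(as.vector(base)), base_classes), collapse = ", "))
  if (is.null(res)) res <- 10
  tb <- bin_fraction(tree_frac)
  bb <- bin_fraction(building_frac)
  codes <- matrix(encode_code(base, tb, bb), nrow = nrow(base))
  refined_lulc(codes, res = res)
}

#' High-canopy indicator of a refined grid
#'
#' TRUE exactly where the tree-cover bin is the top bin (cover of at least
#' 75%); adjacent such pixels form a continuous canopy.
#'
#' @param refined A [refined_lulc()] object.
#' @return Logical matrix.
#' @export
is_high_canopy <- function(refined) {
  tree_bin_of(refined) == 3L
}

#' Base biophysical coefficients per class
#'
#' Loads the packaged per-base-class table of albedo, crop coefficient and
#' green-area flag used to build the refined biophysical table. Values are
#' role-consistent defaults for a temperate urban landscape (high crop
#' coefficient for vegetated classes, zero for dry impervious ones;
#' green-area flag for forest, garden and water).
#'
#' @param path CSV file; defaults to the copy shipped with the package.
#' @return Data frame with columns `base_class`, `albedo`, `kc`,
#'   `green_area`.
#' @export
base_biophysical <- function(path = system.file("extdata",
                                                "biophysical_base.csv",
                                                package = "canopycool")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("base_class", "albedo", "kc", "green_area")
  if (!all(need %in% names(tab)))
    stop("biophysical base table must have columns: ",
         paste(need, collapse = ", "))
  tab$green_area <- as.logical(tab$green_area)
  tab
}

#' Biophysical table for a refined codebook
#'
#' Expands the base-class coefficients to every refined code over the full
#' 4 x 4 (tree bin x building bin) grid of each base class present — so
#' codes produced by canopy transformation are always covered. Shade is
#' the tree-bin midpoint ([shade_coefficient()]), albedo is interpolated
#' towards the building albedo by building-cover bin
#' ([albedo_coefficient()]), crop coefficient and green-area flag are
#' inherited from the base class.
#'
#' @param x A [refined_lulc()] object, or its codebook data frame.
#' @param base_table Per-base-class table from [base_biophysical()].
#' @return Data frame with one row per refined code: `code`, `base_class`,
#'   `tree_bin`, `building_bin`, `shade`, `albedo`, `kc`, `green_area`.
#' @export
biophysical_table <- function(x, base_table = base_biophysical()) {
  codebook <- if (inherits(x, "refined_lulc")) x$codebook else x
  bases <- unique(codebook$base_class)
  i0 <- match(bases, base_table$base_class)
  if (anyNA(i0))
    stop("base classes missing from biophysical table: ",
         paste(bases[is.na(i0)], collapse = ", "))
  bld_albedo <- base_table$albedo[base_table$base_class == "building"]
  if (length(bld_albedo) != 1)
    stop("biophysical base table must contain exactly one 'building' row")
  g <- expand.grid(building_bin = 0:3, tree_bin = 0:3, base_class = bases,
                   stringsAsFactors = FALSE)
  i <- match(g$base_class, base_table$base_class)
  out <- data.frame(
    code = encode_code(base_classes[g$base_class], g$tree_bin,
                       g$building_bin),
    base_class = g$base_class,
    tree_bin = g$tree_bin,
    building_bin = g$building_bin,
    shade = shade_coefficient(g$tree_bin),
    albedo = albedo_coefficient(base_table$albedo[i], bld_albedo,
                                g$building_bin),
    kc = base_table$kc[i],
    green_area = base_table$green_area[i],
    stringsAsFactors = FALSE
  )
  out[order(out$code), ]
}
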