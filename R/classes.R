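#' Base land-use/land-cover classes
#'
#' Integer codes for the base LULC classes used throughout the package.
#' The six urban classes plus `garden` are the ones whose pixels may become
#' greening candidates; `forest` and `water` complete the landscape.
#'
#' @format Named integer vector mapping class name to base code.
#' @export
base_classes <- c(
  water            = 1L,
  forest           = 2L,
  garden           = 3L,
  building         = 4L,
  road_path        = 5L,
  sidewalk         = 6L,
  traffic_island   = 7L,
  other_impervious = 8L
)

#' Base classes eligible for canopy transformation
#'
#' The candidate rule only considers these base classes; forest and water
#' are never transformed.
#'
#' @export
candidate_classes <- c("building", "road_path", "sidewalk",
                       "traffic_island", "other_impervious", "garden")

# refined code layout: code = base * 100 + tree_bin * 10 + building_bin
encode_code <- function(base, tree_bin, building_bin) {
  as.integer(base) * 100L + as.integer(tree_bin) * 10L + as.integer(building_bin)
}

decode_code <- function(code) {
  code <- as.integer(code)
  list(base         = code %/% 100L,
       tree_bin     = (code %/% 10L) %% 10L,
       building_bin = code %% 10L)
}

#' Construct a refined LULC grid
#'
#' A refined LULC grid couples an integer raster of refined codes with a
#' codebook decoding each code into (base class, tree-cover bin,
#' building-cover bin). Codes are laid out as
#' `base * 100 + tree_bin * 10 + building_bin`, so decoding is lossless.
#'
#' @param codes Integer matrix of refined codes.
#' @param res Cell size in metres (default 10).
#' @return An object of class `refined_lulc` with elements `codes`,
#'   `codebook` (data frame: code, base_class, tree_bin, building_bin) and
#'   `res`.
#' @export
refined_lulc <- function(codes, res = 10) {
  stopifnot(is.matrix(codes))
  storage.mode(codes) <- "integer"
  uc <- sort(unique(as.vector(codes)))
  dec <- decode_code(uc)
  if (any(!(dec$base %in% base_classes)))
    stop("unknown base class code in raster: ",
         paste(unique(dec$base[!(dec$base %in% base_classes)]), collapse = ", "))
  if (any(dec$tree_bin > 3L) || any(dec$building_bin > 3L))
    stop("tree/building bin out of range 0..3 in codes")
  codebook <- data.frame(
    code         = uc,
    base_class   = names(base_classes)[match(dec$base, base_classes)],
    tree_bin     = dec$tree_bin,
    building_bin = dec$building_bin,
    stringsAsFactors = FALSE
  )
  structure(list(codes = codes, codebook = codebook, res = res),
            class = "refined_lulc")
}

#' @export
print.refined_lulc <- function(x, ...) {
  cat(sprintf("<refined_lulc> %d x %d cells at %g m, %d refined classes\n",
              nrow(x$codes), ncol(x$codes), x$res, nrow(x$codebook)))
  tab <- table(base_class_of(x))
  cat("base classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-pixel base class of a refined grid
#'
#' @param refined A `refined_lulc` object.
#' @return Character matrix of base class names, same shape as the codes.
#' @export
base_class_of <- function(refined) {
  b <- refined$codes %/% 100L
  m <- matrix(names(base_classes)[match(b, base_classes)],
              nrow = nrow(refined$codes))
  m
}

#' Per-pixel tree bin of a refined grid
#' @param refined A `refined_lulc` object.
#' @return Integer matrix of tree bins (0..3).
#' @export
tree_bin_of <- function(refined) {
  m <- (refined$codes %/% 10L) %% 10L
  storage.mode(m) <- "integer"
  m
}

#' Per-pixel building bin of a refined grid
#' @param refined A `refined_lulc` object.
#' @return Integer matrix of building bins (0..3).
#' @export
building_bin_of <- function(refined) {
  m <- refined$codes %% 10L
  storage.mode(m) <- "integer"
  m
}
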