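# Image-level primitives: colour conversion, small-region removal, hole
# filling and mask application.
#
# The "morphological procedure" of the classifier is implemented as
# connected-component area filtering (equivalent to an area opening):
# scale-free via min_area_fraction, connectivity 8 by default.

#' Region filter configuration
#'
#' @param min_area_fraction Minimum connected-component size as a fraction of
#'   total image pixels, in (0,1). The pixel threshold is
#'   `ceiling(min_area_fraction * H * W)`. Default 2e-4 (about 1,000 px at
#'   the native 2448 x 2050 capture resolution, about 13 px at the 256 x 256
#'   synthetic scale).
#' @param connectivity Pixel adjacency, 4 or 8 (default 8).
#' @return A `vineseg_region_cfg` list.
#' @export
region_filter_config <- function(min_area_fraction = 2e-4, connectivity = 8) {
  if (!is.numeric(min_area_fraction) || length(min_area_fraction) != 1 ||
      min_area_fraction <= 0 || min_area_fraction >= 1) {
    stop("min_area_fraction must lie strictly in (0,1)", call. = FALSE)
  }
  if (!connectivity %in% c(4, 8)) {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
  structure(list(min_area_fraction = min_area_fraction,
                 connectivity = as.integer(connectivity)),
            class = "vineseg_region_cfg")
}

#' Convert sRGB to CIE L*a*b*
#'
#' Deterministic conversion under sRGB primaries and the D65 reference
#' white. L* lies in \[0,100\]; a* and b* are unbounded chromaticity axes
#' (red-green and blue-yellow).
#'
#' @param rgb H x W x 3 array with values in \[0,1\].
#' @return H x W x 3 array of (L*, a*, b*).
#' @export
rgb_to_lab <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stop("rgb must be an H x W x 3 array", call. = FALSE)
  }
  if (any(!is.finite(rgb)) || min(rgb) < 0 || max(rgb) > 1) {
    stop("rgb values must be finite and in [0,1]", call. = FALSE)
  }
  hw <- dim(rgb)[1:2]
  m <- cbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
             as.vector(rgb[, , 3]))
  lab <- farver::convert_colour(m * 255, from = "rgb", to = "lab")
  array(c(lab[, 1], lab[, 2], lab[, 3]), dim = c(hw, 3))
}

#' Convert CIE L*a*b* back to sRGB
#'
#' Inverse of [rgb_to_lab()] for in-gamut colours; out-of-gamut results are
#' clipped to \[0,1\].
#'
#' @param lab H x W x 3 array of (L*, a*, b*).
#' @return H x W x 3 sRGB array in \[0,1\].
#' @export
lab_to_rgb <- function(lab) {
  if (!is.array(lab) || length(dim(lab)) != 3 || dim(lab)[3] != 3) {
    stop("lab must be an H x W x 3 array", call. = FALSE)
  }
  hw <- dim(lab)[1:2]
  m <- cbind(as.vector(lab[, , 1]), as.vector(lab[, , 2]),
             as.vector(lab[, , 3]))
  rgb <- farver::convert_colour(m, from = "lab", to = "rgb") / 255
  rgb <- pmin(pmax(rgb, 0), 1)
  array(c(rgb[, 1], rgb[, 2], rgb[, 3]), dim = c(hw, 3))
}

# Connected-component labelling of TRUE pixels via the pixel-adjacency graph
# (igraph components). Returns an integer matrix, 0 for FALSE pixels.
label_components <- function(binary, connectivity = 8) {
  h <- nrow(binary); w <- ncol(binary)
  out <- matrix(0L, h, w)
  on_idx <- which(binary)
  if (length(on_idx) == 0) return(out)
  rank <- integer(h * w)
  rank[on_idx] <- seq_along(on_idx)

  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) {
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  }
  rows <- ((on_idx - 1L) %% h) + 1L
  cols <- ((on_idx - 1L) %/% h) + 1L
  edges <- integer(0)
  for (s in shifts) {
    r2 <- rows + s[1]; c2 <- cols + s[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    src <- on_idx[ok]
    hit <- binary[nb]
    if (any(hit)) {
      edges <- c(edges, rbind(rank[src[hit]], rank[nb[hit]]))
    }
  }
  g <- igraph::make_empty_graph(n = length(on_idx), directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  out[on_idx] <- as.integer(memb)
  out
}

#' Remove small connected components
#'
#' Every connected component of TRUE pixels smaller than
#' `ceiling(min_area_fraction * H * W)` is set FALSE; components at or above
#' the threshold pass unchanged. Idempotent; the output TRUE set is a subset
#' of the input TRUE set.
#'
#' @param binary Logical matrix.
#' @param cfg A [region_filter_config()].
#' @return Logical matrix.
#' @export
remove_small_regions <- function(binary, cfg = region_filter_config()) {
  if (!is.matrix(binary) || !is.logical(binary)) {
    stop("binary must be a logical matrix", call. = FALSE)
  }
  if (anyNA(binary)) stop("binary contains NA", call. = FALSE)
  threshold <- ceiling(cfg$min_area_fraction * length(binary))
  lab <- label_components(binary, cfg$connectivity)
  if (max(lab) == 0) return(binary)
  areas <- tabulate(lab[lab > 0L])
  keep <- areas >= threshold
  out <- binary
  out[lab > 0L] <- keep[lab[lab > 0L]]
  out
}

#' Fill small interior holes
#'
#' FALSE components smaller than `ceiling(min_area_fraction * H * W)` that do
#' not touch the image border are set TRUE. Border-touching background is
#' never filled. Idempotent; the output TRUE set is a superset of the input.
#'
#' @inheritParams remove_small_regions
#' @return Logical matrix.
#' @export
fill_small_holes <- function(binary, cfg = region_filter_config()) {
  if (!is.matrix(binary) || !is.logical(binary)) {
    stop("binary must be a logical matrix", call. = FALSE)
  }
  if (anyNA(binary)) stop("binary contains NA", call. = FALSE)
  threshold <- ceiling(cfg$min_area_fraction * length(binary))
  lab <- label_components(!binary, cfg$connectivity)
  if (max(lab) == 0) return(binary)
  areas <- tabulate(lab[lab > 0L])
  h <- nrow(binary); w <- ncol(binary)
  border_labels <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  border_labels <- border_labels[border_labels > 0L]
  fill <- areas < threshold
  fill[border_labels] <- FALSE
  out <- binary
  sel <- lab > 0L
  out[sel] <- binary[sel] | fill[lab[sel]]
  out
}

#' Apply a stage mask to a raster
#'
#' Pixels where the mask is TRUE are replaced by `fill` (default 0, so
#' previously masked pixels form their own dark cluster in later stages);
#' all other pixels pass through untouched.
#'
#' @param image H x W matrix or H x W x c array.
#' @param mask A `vineseg_mask` or logical matrix of matching dimensions.
#' @param fill Replacement value (default 0).
#' @return Raster of the same shape as `image`.
#' @export
apply_mask <- function(image, mask, fill = 0) {
  m <- mask_values(mask)
  if (!is.logical(m)) stop("mask must be logical", call. = FALSE)
  if (is.matrix(image)) {
    if (!identical(dim(image), dim(m))) {
      stop("shape mismatch between image and mask", call. = FALSE)
    }
    image[m] <- fill
    image
  } else if (is.array(image) && length(dim(image)) == 3) {
    if (!identical(dim(image)[1:2], dim(m))) {
      stop("shape mismatch between image and mask", call. = FALSE)
    }
    for (ch in seq_len(dim(image)[3])) {
      plane <- image[, , ch]
      plane[m] <- fill
      image[, , ch] <- plane
    }
    image
  } else {
    stop("image must be a matrix or H x W x c array", call. = FALSE)
  }
}
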