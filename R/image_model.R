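# Core data types and file I/O for scene bundles, masks and label maps.
#
# Storage is plain-text NetPBM: bands as 16-bit ASCII PGM (P2), RGB and label
# visualisations as ASCII PPM (P3), plus JSON sidecars. Intensities are
# normalised to [0,1] on load; all downstream maths is floating point.
# Coordinates are row-major, origin top-left.

#' The five evaluation classes
#'
#' Class order is fixed everywhere (confusion-matrix axes, palettes,
#' summaries): fruit, stem, leaf, branch, background.
#'
#' @return Character vector of the five class names.
#' @export
vineseg_classes <- function() {
  c("FRUIT", "STEM", "LEAF", "BRANCH", "BACKGROUND")
}

.all_labels <- function() c(vineseg_classes(), "UNLABELED")

#' Label display palette
#'
#' Fixed colour convention for label-map visualisation: fruits magenta, stems
#' orange, leaves green, branches yellow, background white; unlabeled pixels
#' (only written with `allow_partial`) are black.
#'
#' @return A tibble with columns `class`, `index`, `r`, `g`, `b` (0-255).
#' @export
class_palette <- function() {
  tibble::tibble(
    class = .all_labels(),
    index = seq_along(.all_labels()),
    r = c(255L, 255L, 0L, 255L, 255L, 0L),
    g = c(0L, 165L, 128L, 255L, 255L, 0L),
    b = c(255L, 0L, 0L, 0L, 255L, 0L)
  )
}

# ---- validation helpers ----------------------------------------------------

check_raster <- function(x, name, range01 = TRUE) {
  if (!is.numeric(x)) stop(name, ": raster must be numeric", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop(name, ": raster contains NA/NaN/Inf pixels", call. = FALSE)
  }
  if (range01 && (min(x) < 0 || max(x) > 1)) {
    stop(name, ": intensities must lie in [0,1]", call. = FALSE)
  }
  invisible(x)
}

raster_dim <- function(x) dim(x)[1:2]

# ---- label_map -------------------------------------------------------------

#' Construct a label map
#'
#' A per-pixel categorical map over the five classes plus `UNLABELED`. A
#' completed classification contains no `UNLABELED` pixels.
#'
#' @param values Character matrix with entries in
#'   `c(vineseg_classes(), "UNLABELED")`.
#' @return A `vineseg_label_map` object (character matrix subclass).
#' @export
label_map <- function(values) {
  if (!is.matrix(values) || !is.character(values)) {
    stop("label map values must be a character matrix", call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(values)), .all_labels())
  if (length(bad) > 0) {
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(values, class = c("vineseg_label_map", "matrix"))
}

#' @export
print.vineseg_label_map <- function(x, ...) {
  cat("<vineseg_label_map> ", nrow(x), "x", ncol(x), " pixels\n", sep = "")
  print(table(factor(as.vector(x), levels = .all_labels())))
  invisible(x)
}

#' Per-class pixel counts of a label map
#'
#' @param labels A `vineseg_label_map`.
#' @return Tibble with columns `class`, `n`.
#' @export
label_counts <- function(labels) {
  tab <- table(factor(as.vector(labels), levels = .all_labels()))
  tibble::tibble(class = names(tab), n = as.integer(tab))
}

# ---- mask ------------------------------------------------------------------

#' Construct a stage mask
#'
#' TRUE means the pixel is claimed by this stage and excluded from all later
#' clustering stages. Masks compose by logical OR.
#'
#' @param values Logical matrix.
#' @param stage_name One of `"background"`, `"fruit"`, `"stems"`.
#' @return A `vineseg_mask` object.
#' @export
new_mask <- function(values, stage_name) {
  if (!is.matrix(values) || !is.logical(values)) {
    stop("mask values must be a logical matrix", call. = FALSE)
  }
  if (anyNA(values)) stop("mask contains NA", call. = FALSE)
  stage_name <- match.arg(stage_name, c("background", "fruit", "stems"))
  structure(list(values = values, stage_name = stage_name),
            class = "vineseg_mask")
}

#' @export
print.vineseg_mask <- function(x, ...) {
  cat("<vineseg_mask> stage=", x$stage_name, ", ",
      sum(x$values), "/", length(x$values), " pixels claimed\n", sep = "")
  invisible(x)
}

mask_values <- function(mask) {
  if (inherits(mask, "vineseg_mask")) mask$values else mask
}

#' Combine stage masks by logical OR
#'
#' @param ... `vineseg_mask` objects or logical matrices of equal dimensions.
#' @return Logical matrix.
#' @export
combine_masks <- function(...) {
  ms <- lapply(list(...), mask_values)
  out <- Reduce(`|`, ms)
  out
}

# ---- scene_bundle ----------------------------------------------------------

#' Construct a scene bundle
#'
#' A registered RGB image plus three single-channel images acquired through
#' band-pass filters centred at 635, 660 and 880 nm, with an optional
#' ground-truth label map. All rasters must share the same height and width
#' and contain finite intensities in \[0,1\]; the bands are assumed
#' pixel-registered (sequential capture through a filter wheel on a static
#' rig), so no registration is attempted.
#'
#' @param rgb H x W x 3 numeric array in \[0,1\].
#' @param band635,band660,band880 H x W numeric matrices in \[0,1\].
#' @param truth Optional `vineseg_label_map` of the same dimensions.
#' @param scene_id Character scene identifier.
#' @return A `vineseg_scene` object.
#' @export
scene_bundle <- function(rgb, band635, band660, band880,
                         truth = NULL, scene_id = "scene") {
  if (!is.array(rgb) || length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stop("rgb: must be an H x W x 3 array", call. = FALSE)
  }
  check_raster(rgb, "rgb")
  hw <- raster_dim(rgb)
  bands <- list(band635 = band635, band660 = band660, band880 = band880)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!is.matrix(b)) stop(nm, ": must be an H x W matrix", call. = FALSE)
    check_raster(b, nm)
    if (!identical(raster_dim(b), hw)) {
      stop("dimension mismatch: ", nm, " is ", nrow(b), "x", ncol(b),
           " but rgb is ", hw[1], "x", hw[2], call. = FALSE)
    }
  }
  if (!is.null(truth)) {
    if (!inherits(truth, "vineseg_label_map")) truth <- label_map(truth)
    if (!identical(raster_dim(truth), hw)) {
      stop("dimension mismatch: truth is ", nrow(truth), "x", ncol(truth),
           " but rgb is ", hw[1], "x", hw[2], call. = FALSE)
    }
  }
  structure(
    list(rgb = rgb, band635 = band635, band660 = band660, band880 = band880,
         truth = truth, scene_id = as.character(scene_id)),
    class = "vineseg_scene"
  )
}

#' @export
print.vineseg_scene <- function(x, ...) {
  hw <- raster_dim(x$rgb)
  cat("<vineseg_scene> '", x$scene_id, "' ", hw[1], "x", hw[2],
      " px, bands 635/660/880 nm",
      if (!is.null(x$truth)) ", with truth" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.vineseg_scene <- function(x) raster_dim(x$rgb)

# ---- NetPBM I/O ------------------------------------------------------------

# Write an ASCII PGM (P2, matrix) or PPM (P3, HxWx3 array) at a given maxval.
write_pnm <- function(x, path, maxval = 65535L) {
  if (is.matrix(x)) {
    magic <- "P2"
    vals <- as.vector(t(x))
  } else {
    magic <- "P3"
    # interleave channels row-major: r g b per pixel
    vals <- as.vector(aperm(x, c(3, 2, 1)))
  }
  q <- as.integer(round(vals * maxval))
  q <- pmin(pmax(q, 0L), as.integer(maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(magic, paste(dim(x)[2], dim(x)[1]), as.character(maxval)), con)
  writeLines(paste(q[seq_along(q)] , collapse = " "), con)
  invisible(path)
}

read_pnm <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  toks <- scan(text = paste(txt, collapse = " "), what = character(),
               quiet = TRUE)
  magic <- toks[1]
  if (!magic %in% c("P2", "P3")) {
    stop("not an ASCII PGM/PPM image: ", path, call. = FALSE)
  }
  hdr <- suppressWarnings(as.numeric(toks[2:4]))
  if (anyNA(hdr)) stop("corrupt NetPBM header in ", path, call. = FALSE)
  w <- hdr[1]; h <- hdr[2]; maxval <- hdr[3]
  vals <- suppressWarnings(as.numeric(toks[-(1:4)]))
  if (anyNA(vals)) stop("non-numeric pixel payload in ", path, call. = FALSE)
  nch <- if (magic == "P2") 1L else 3L
  if (length(vals) != w * h * nch) {
    stop("pixel count mismatch in ", path, call. = FALSE)
  }
  if (magic == "P2") {
    matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
  } else {
    arr <- array(vals / maxval, dim = c(nch, w, h))
    aperm(arr, c(3, 2, 1))
  }
}

# ---- scene save / load -----------------------------------------------------

#' Save a scene bundle to a directory
#'
#' Writes one 16-bit ASCII PGM per band, a 16-bit ASCII PPM for the RGB
#' image, an indexed truth image plus JSON legend when truth is present, and
#' a JSON sidecar (`scene.json`) recording the scene id, filter wavelengths
#' and channel file names.
#'
#' @param bundle A `vineseg_scene`.
#' @param dir Destination directory (created if absent).
#' @return Invisibly, the sidecar path.
#' @export
save_scene <- function(bundle, dir) {
  if (!inherits(bundle, "vineseg_scene")) {
    stop("save_scene() needs a vineseg_scene", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("unwritable destination: ", dir, call. = FALSE)
  files <- list(rgb = "rgb.ppm", band635 = "band635.pgm",
                band660 = "band660.pgm", band880 = "band880.pgm")
  write_pnm(bundle$rgb, file.path(dir, files$rgb))
  write_pnm(bundle$band635, file.path(dir, files$band635))
  write_pnm(bundle$band660, file.path(dir, files$band660))
  write_pnm(bundle$band880, file.path(dir, files$band880))
  meta <- list(scene_id = bundle$scene_id,
               wavelengths_nm = c(635, 660, 880),
               channel_files = files)
  if (!is.null(bundle$truth)) {
    meta$truth_file <- "truth.ppm"
    write_labelmap(bundle$truth, file.path(dir, "truth.ppm"),
                   allow_partial = TRUE)
  }
  sidecar <- file.path(dir, "scene.json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}

#' Load a scene bundle from a directory
#'
#' Reads the `scene.json` sidecar written by [save_scene()] and the channel
#' files it names. Intensities are normalised to \[0,1\] by the stored bit
#' depth; dimension agreement across channels is enforced and violations are
#' reported naming the offending channel.
#'
#' @param dir Directory containing `scene.json`.
#' @return A `vineseg_scene`.
#' @export
load_scene <- function(dir) {
  sidecar <- file.path(dir, "scene.json")
  if (!file.exists(sidecar)) {
    stop("missing file: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  ch <- meta$channel_files
  rgb <- read_pnm(file.path(dir, ch$rgb))
  bands <- lapply(c(band635 = "band635", band660 = "band660",
                    band880 = "band880"),
                  function(nm) read_pnm(file.path(dir, ch[[nm]])))
  truth <- NULL
  if (!is.null(meta$truth_file)) {
    truth <- read_labelmap(file.path(dir, meta$truth_file))
  }
  scene_bundle(rgb, bands$band635, bands$band660, bands$band880,
               truth = truth,
               scene_id = if (is.null(meta$scene_id)) "scene" else
                 meta$scene_id)
}

# ---- label map I/O ---------------------------------------------------------

#' Write a label map as an indexed colour image
#'
#' Emits an ASCII PPM using the fixed class palette ([class_palette()]) and a
#' machine-readable JSON legend (`<path>.legend.json`) mapping each class to
#' its palette index and RGB triple.
#'
#' @param labels A `vineseg_label_map`.
#' @param path Output image path.
#' @param allow_partial If `FALSE` (default) the presence of `UNLABELED`
#'   pixels is an error; if `TRUE` they are written with the black palette
#'   entry.
#' @return Invisibly, `path`.
#' @export
write_labelmap <- function(labels, path, allow_partial = FALSE) {
  if (!inherits(labels, "vineseg_label_map")) labels <- label_map(labels)
  has_unlab <- any(labels == "UNLABELED")
  if (has_unlab && !allow_partial) {
    stop("label map contains UNLABELED pixels; ",
         "set allow_partial = TRUE to write anyway", call. = FALSE)
  }
  pal <- class_palette()
  idx <- match(as.vector(labels), pal$class)
  h <- nrow(labels); w <- ncol(labels)
  arr <- array(0, dim = c(h, w, 3))
  arr[, , 1] <- matrix(pal$r[idx] / 255, h, w)
  arr[, , 2] <- matrix(pal$g[idx] / 255, h, w)
  arr[, , 3] <- matrix(pal$b[idx] / 255, h, w)
  write_pnm(arr, path, maxval = 255L)
  legend <- purrr::pmap(pal, function(class, index, r, g, b) {
    list(class = class, index = index, rgb = c(r, g, b))
  })
  jsonlite::write_json(legend, paste0(path, ".legend.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a label map written by [write_labelmap()]
#'
#' @param path Path to the indexed PPM image.
#' @return A `vineseg_label_map`.
#' @export
read_labelmap <- function(path) {
  arr <- read_pnm(path)
  if (length(dim(arr)) != 3) stop("label image must be PPM", call. = FALSE)
  pal <- class_palette()
  key <- paste(pal$r, pal$g, pal$b)
  got <- paste(round(arr[, , 1] * 255), round(arr[, , 2] * 255),
               round(arr[, , 3] * 255))
  idx <- match(got, key)
  if (anyNA(idx)) {
    stop("label image contains colours outside the class palette: ", path,
         call. = FALSE)
  }
  label_map(matrix(pal$class[idx], nrow = dim(arr)[1], ncol = dim(arr)[2]))
}
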