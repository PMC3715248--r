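# Synthetic vineyard scene generator with ground truth.
#
# The signature table encodes the qualitative spectral orderings the
# classifier relies on: photosynthetic tissue dark in red (600-700 nm,
# chlorophyll absorption) and bright in NIR; soil reflectance rising with
# wavelength and brightest (with sky) at 635 nm; woody tissue below leaves
# at 880 nm; grapes a dark blue-purple in RGB (lowest b*). Magnitudes are
# stylised model constants, not measurements - the orderings are the
# contract.

.sig_classes <- function() c("LEAF", "STEM", "BRANCH", "SOIL", "SKY", "FRUIT")

# Reflectance control points per material; interpolated piecewise-linearly
# onto the instrument grid.
.sig_control <- list(
  LEAF   = list(wl = c(400, 450, 500, 550, 600, 635, 660, 676, 690, 700,
                       750, 800, 880, 940, 1000),
                r  = c(.05, .05, .09, .15, .12, .09, .10, .07, .09, .25,
                       .70, .76, .82, .82, .80)),
  STEM   = list(wl = c(400, 500, 600, 635, 660, 700, 750, 880, 1000),
                r  = c(.08, .10, .13, .15, .12, .20, .32, .35, .38)),
  BRANCH = list(wl = c(400, 500, 600, 635, 660, 700, 750, 880, 1000),
                r  = c(.08, .14, .22, .24, .26, .33, .48, .55, .56)),
  SOIL   = list(wl = c(400, 450, 500, 550, 600, 635, 660, 700, 750, 880,
                       1000),
                r  = c(.15, .22, .30, .40, .50, .55, .58, .60, .62, .65,
                       .68)),
  SKY    = list(wl = c(400, 500, 635, 660, 750, 880, 1000),
                r  = c(.85, .90, .90, .89, .87, .85, .83)),
  FRUIT  = list(wl = c(400, 500, 600, 635, 660, 700, 750, 880, 1000),
                r  = c(.05, .05, .05, .06, .05, .10, .25, .30, .32))
)

.sig_colours <- list(
  LEAF   = c(0.15, 0.35, 0.10),
  STEM   = c(0.36, 0.28, 0.22),
  BRANCH = c(0.45, 0.36, 0.18),
  SOIL   = c(0.52, 0.42, 0.30),
  SKY    = c(0.78, 0.85, 0.95),
  FRUIT  = c(0.13, 0.08, 0.24)
)

#' Default spectral signature table
#'
#' Per-material reflectance mean and standard deviation on a wavelength grid
#' that unions the 3 nm instrument spacing (400-1000 nm) with the three
#' filter wavelengths 635, 660 and 880 nm, plus per-material RGB colour
#' statistics. Values are stylised model constants chosen to satisfy the
#' physical orderings (vegetation dark in red / bright in NIR, soil bright
#' in red, stems below leaves at 880 nm, grapes lowest in b*).
#'
#' @param noise_sd Per-band reflectance standard deviation (default 0.03).
#' @return A `vineseg_signatures` object with tibbles `spectra`
#'   (`class`, `wavelength`, `mean`, `sd`) and `colours`
#'   (`class`, `channel`, `mean`, `sd`).
#' @export
default_signatures <- function(noise_sd = 0.03) {
  wl <- sort(unique(c(seq(400, 1000, by = 3), 635, 660, 880)))
  spectra <- purrr::map_dfr(.sig_classes(), function(cl) {
    cp <- .sig_control[[cl]]
    tibble::tibble(
      class = cl,
      wavelength = wl,
      mean = stats::approx(cp$wl, cp$r, xout = wl, rule = 2)$y,
      sd = if (cl == "SKY") noise_sd * 2 / 3 else noise_sd
    )
  })
  colours <- purrr::map_dfr(.sig_classes(), function(cl) {
    tibble::tibble(class = cl, channel = c("r", "g", "b"),
                   mean = .sig_colours[[cl]], sd = noise_sd)
  })
  structure(list(spectra = spectra, colours = colours),
            class = "vineseg_signatures")
}

#' @export
print.vineseg_signatures <- function(x, ...) {
  cat("<vineseg_signatures> ", length(unique(x$spectra$class)),
      " materials, ", length(unique(x$spectra$wavelength)),
      " wavelengths (", min(x$spectra$wavelength), "-",
      max(x$spectra$wavelength), " nm)\n", sep = "")
  invisible(x)
}

# Mean reflectance of one material at one wavelength (exact grid hit).
signature_at <- function(sig, class, wavelength) {
  row <- dplyr::filter(sig$spectra, .data$class == !!class,
                       .data$wavelength == !!wavelength)
  if (nrow(row) != 1) {
    stop("signature has no entry for ", class, " at ", wavelength, " nm",
         call. = FALSE)
  }
  row$mean
}

# Per-material sd at a wavelength.
signature_sd_at <- function(sig, class, wavelength) {
  row <- dplyr::filter(sig$spectra, .data$class == !!class,
                       .data$wavelength == !!wavelength)
  row$sd
}

#' Synthetic scene specification
#'
#' Geometry and noise parameters for one rendered vineyard scene. Defaults
#' describe a 256 x 256 scene with one trunk, a handful of thin canes,
#' blob-shaped leaves, three grape bunches and a soil/sky background,
#' independent Gaussian pixel noise (sd 0.03) and a mild horizontal
#' multiplicative illumination ramp (0.9-1.1). Occlusion order is
#' grapes over leaves over branches over stem over background.
#'
#' @param height,width Scene dimensions in pixels (>= 32).
#' @param n_bunches Number of grape bunches.
#' @param bunch_radius Min/max bunch radius in px.
#' @param n_leaves Number of elliptical leaf blobs.
#' @param leaf_radius Min/max leaf semi-axis in px.
#' @param n_branches Number of thin cane segments.
#' @param branch_width Min/max cane half-width in px.
#' @param stem_width Min/max trunk width in px.
#' @param sky_fraction Fraction of image height occupied by sky.
#' @param noise_sd Per-pixel Gaussian noise sd on every channel.
#' @param illumination Length-2 multiplicative ramp across columns.
#' @param seed Integer RNG seed.
#' @return A `vineseg_scene_spec` list.
#' @export
scene_spec <- function(height = 256, width = 256,
                       n_bunches = 3, bunch_radius = c(10, 18),
                       n_leaves = 45, leaf_radius = c(6, 14),
                       n_branches = 7, branch_width = c(1, 3),
                       stem_width = c(8, 12),
                       sky_fraction = 0.3,
                       noise_sd = 0.03,
                       illumination = c(0.9, 1.1),
                       seed = 0) {
  if (height < 32 || width < 32) {
    stop("scene dimensions must be at least 32 px", call. = FALSE)
  }
  counts <- c(n_bunches, n_leaves, n_branches)
  if (any(counts < 0)) stop("shape counts must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(illumination) != 2 || any(illumination <= 0)) {
    stop("illumination must be two positive ramp endpoints", call. = FALSE)
  }
  structure(
    list(height = height, width = width,
         n_bunches = n_bunches, bunch_radius = bunch_radius,
         n_leaves = n_leaves, leaf_radius = leaf_radius,
         n_branches = n_branches, branch_width = branch_width,
         stem_width = stem_width, sky_fraction = sky_fraction,
         noise_sd = noise_sd, illumination = illumination,
         seed = as.integer(seed)),
    class = "vineseg_scene_spec"
  )
}

# ---- geometry painters (in-place on a character material matrix) -----------

paint_ellipse <- function(mat, cy, cx, a, b, theta, value) {
  h <- nrow(mat); w <- ncol(mat)
  rmax <- ceiling(max(a, b))
  r0 <- max(1, floor(cy - rmax)); r1 <- min(h, ceiling(cy + rmax))
  c0 <- max(1, floor(cx - rmax)); c1 <- min(w, ceiling(cx + rmax))
  if (r0 > r1 || c0 > c1) return(mat)   # shape lies entirely off-image
  rr <- r0:r1
  cc <- c0:c1
  ry <- outer(rr - cy, rep(1, length(cc)))
  rx <- outer(rep(1, length(rr)), cc - cx)
  u <- rx * cos(theta) + ry * sin(theta)
  v <- -rx * sin(theta) + ry * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- mat[rr, cc, drop = FALSE]
  sub[inside] <- value
  mat[rr, cc] <- sub
  mat
}

paint_segment <- function(mat, y0, x0, y1, x1, half_width, value) {
  len <- max(abs(y1 - y0), abs(x1 - x0), 1)
  ts <- seq(0, 1, length.out = ceiling(len) * 2 + 1)
  ys <- y0 + ts * (y1 - y0)
  xs <- x0 + ts * (x1 - x0)
  for (i in seq_along(ts)) {
    mat <- paint_ellipse(mat, ys[i], xs[i], half_width, half_width, 0, value)
  }
  mat
}

# Paint the material map (6 materials; truth collapses SOIL/SKY into
# BACKGROUND). Uses the current RNG stream.
paint_materials <- function(spec) {
  h <- spec$height; w <- spec$width
  mat <- matrix("SOIL", h, w)
  sky_rows <- seq_len(max(1, round(spec$sky_fraction * h)))
  mat[sky_rows, ] <- "SKY"

  # trunk: vertical band from the ground into the canopy
  stem_w <- runif(1, spec$stem_width[1], spec$stem_width[2])
  stem_x <- runif(1, 0.35 * w, 0.65 * w)
  stem_top <- round(0.25 * h)
  mat <- paint_segment(mat, h, stem_x, stem_top, stem_x, stem_w / 2, "STEM")

  # canes: thin, roughly horizontal segments branching off the trunk
  canopy_top <- round(0.18 * h)
  for (i in seq_len(spec$n_branches)) {
    y0 <- runif(1, canopy_top, 0.75 * h)
    x0 <- stem_x + runif(1, -0.05 * w, 0.05 * w)
    ang <- runif(1, -pi / 6, pi / 6) + sample(c(0, pi), 1)
    len <- runif(1, 0.15 * w, 0.45 * w)
    y1 <- y0 + sin(ang) * len
    x1 <- x0 + cos(ang) * len
    bw <- runif(1, spec$branch_width[1], spec$branch_width[2])
    mat <- paint_segment(mat, y0, x0, y1, x1, bw / 2, "BRANCH")
  }

  # leaf blobs scattered over the canopy
  for (i in seq_len(spec$n_leaves)) {
    cy <- runif(1, canopy_top, 0.85 * h)
    cx <- runif(1, 0.05 * w, 0.95 * w)
    a <- runif(1, spec$leaf_radius[1], spec$leaf_radius[2])
    b <- a * runif(1, 0.6, 1)
    mat <- paint_ellipse(mat, cy, cx, a, b, runif(1, 0, pi), "LEAF")
  }

  # grape bunches: clusters of overlapping berry discs, painted on top
  for (i in seq_len(spec$n_bunches)) {
    br <- runif(1, spec$bunch_radius[1], spec$bunch_radius[2])
    cy <- runif(1, 0.45 * h, 0.8 * h)
    cx <- runif(1, 0.15 * w, 0.85 * w)
    n_berries <- max(8, round(br * 1.2))
    for (j in seq_len(n_berries)) {
      dy <- rnorm(1, 0, br / 2.2)
      dx <- rnorm(1, 0, br / 2.8)
      rb <- runif(1, 2, 4)
      mat <- paint_ellipse(mat, cy + dy * 1.2, cx + dx, rb, rb, 0, "FRUIT")
    }
  }
  mat
}

render_channel <- function(material, means, sds, ramp) {
  h <- nrow(material); w <- ncol(material)
  mu <- means[material]
  s <- sds[material]
  img <- matrix(mu + rnorm(h * w, 0, s), h, w)
  img <- sweep(img, 2, ramp, `*`)
  pmin(pmax(img, 0), 1)
}

#' Render a synthetic scene with ground truth
#'
#' Paints the truth geometry (background, trunk, canes, leaves, grape
#' bunches, in that occlusion order), then renders each narrow band by
#' sampling the material's reflectance plus Gaussian noise, applies a
#' horizontal multiplicative illumination ramp and clips to \[0,1\]. The RGB
#' image is rendered from the material colours the same way. Fully
#' reproducible from `spec$seed`. A warning reports realised class counts if
#' any of the five evaluation classes vanished from the truth map.
#'
#' @param spec A [scene_spec()].
#' @param sig A signature table from [default_signatures()].
#' @return A `vineseg_scene` whose `truth` is the rendered label map.
#' @export
generate_scene <- function(spec = scene_spec(), sig = default_signatures()) {
  stopifnot(inherits(spec, "vineseg_scene_spec"))
  with_local_seed(spec$seed, {
    material <- paint_materials(spec)
    ramp <- seq(spec$illumination[1], spec$illumination[2],
                length.out = spec$width)

    # spec$noise_sd rescales the signature noise model globally (the
    # per-material sds in the table keep their relative structure)
    noise_scale <- spec$noise_sd / 0.03
    band <- function(wl) {
      means <- vapply(.sig_classes(), signature_at, numeric(1),
                      sig = sig, wavelength = wl)
      sds <- vapply(.sig_classes(), signature_sd_at, numeric(1),
                    sig = sig, wavelength = wl) * noise_scale
      render_channel(material, means, sds, ramp)
    }
    b635 <- band(635)
    b660 <- band(660)
    b880 <- band(880)

    cols <- tidyr::pivot_wider(sig$colours, names_from = "channel",
                               values_from = c("mean", "sd"))
    rgb <- array(0, dim = c(spec$height, spec$width, 3))
    for (ch in c("r", "g", "b")) {
      means <- stats::setNames(cols[[paste0("mean_", ch)]], cols$class)
      sds <- stats::setNames(cols[[paste0("sd_", ch)]], cols$class) *
        noise_scale
      k <- match(ch, c("r", "g", "b"))
      rgb[, , k] <- render_channel(material, means[.sig_classes()],
                                   sds[.sig_classes()], ramp)
    }

    truth_vals <- material
    truth_vals[truth_vals %in% c("SOIL", "SKY")] <- "BACKGROUND"
    truth <- label_map(truth_vals)

    realised <- label_counts(truth)
    missing_cls <- realised$class[realised$n == 0 &
                                    realised$class %in% vineseg_classes()]
    if (length(missing_cls) > 0) {
      warning("scene is so crowded that classes vanished: ",
              paste(missing_cls, collapse = ", "), "; realised counts: ",
              paste(realised$class, realised$n, sep = "=", collapse = ", "),
              call. = FALSE)
    }

    scene_bundle(rgb, b635, b660, b880, truth = truth,
                 scene_id = paste0("synthetic-", spec$seed))
  })
}

#' Render a reproducible set of scenes
#'
#' Scene i uses seed `base_seed + i - 1` and a varied illumination ramp
#' (alternating direction and strength), emulating captures under different
#' lighting conditions and occlusion levels.
#'
#' @param n Number of scenes (>= 1).
#' @param spec Base [scene_spec()]; per-scene seed and illumination override
#'   its values.
#' @param sig Signature table.
#' @param base_seed First seed (default `spec$seed`).
#' @return List of `vineseg_scene` bundles.
#' @export
generate_scene_set <- function(n = 6, spec = scene_spec(),
                               sig = default_signatures(),
                               base_seed = spec$seed) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  ramps <- list(c(0.90, 1.10), c(1.10, 0.90), c(0.85, 1.05),
                c(0.95, 1.15), c(1.05, 0.85), c(0.88, 1.08))
  purrr::map(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- as.integer(base_seed + i - 1)
    sp$illumination <- ramps[[(i - 1) %% length(ramps) + 1]]
    generate_scene(sp, sig)
  })
}

#' Per-wavelength contrast ratio between two materials
#'
#' Elementwise ratio of mean reflectances `a / b` across the wavelength
#' grid, the quantity used to justify the filter choice: the leaf-to-soil
#' ratio deviates most from 1 in the red chlorophyll-absorption window.
#'
#' @param sig Signature table.
#' @param a,b Material names.
#' @return Tibble with columns `wavelength`, `ratio`.
#' @export
contrast_ratio <- function(sig, a, b) {
  sa <- dplyr::filter(sig$spectra, .data$class == a)
  sb <- dplyr::filter(sig$spectra, .data$class == b)
  if (nrow(sa) == 0 || nrow(sb) == 0) {
    stop("unknown material class", call. = FALSE)
  }
  if (any(sb$mean == 0)) {
    stop("zero denominator reflectance for class ", b, call. = FALSE)
  }
  tibble::tibble(wavelength = sa$wavelength, ratio = sa$mean / sb$mean)
}

#' Draw noisy spectra samples from a signature table
#'
#' One row per replicate per material: the mean spectrum plus independent
#' Gaussian noise at the per-band sd. Used to exercise the PCA band ranking.
#'
#' @param sig Signature table.
#' @param n_per_class Replicates per material (default 20).
#' @param seed RNG seed.
#' @return Numeric matrix, rows = samples, columns = wavelengths (named).
#' @export
draw_signature_samples <- function(sig, n_per_class = 20, seed = 0) {
  wl <- sort(unique(sig$spectra$wavelength))
  classes <- unique(sig$spectra$class)
  with_local_seed(seed, {
    rows <- purrr::map(classes, function(cl) {
      s <- dplyr::arrange(dplyr::filter(sig$spectra, .data$class == cl),
                          .data$wavelength)
      t(replicate(n_per_class, s$mean + rnorm(length(wl), 0, s$sd)))
    })
    out <- do.call(rbind, rows)
    colnames(out) <- wl
    rownames(out) <- rep(classes, each = n_per_class)
    out
  })
}

#' Rank wavelengths by principal-component loadings
#'
#' Centres the sample matrix, computes principal axes, and selects one
#' wavelength per leading component: the wavelength with the largest
#' absolute loading not already chosen (ties break toward the lower
#' wavelength). This is the classical PCA band-selection step used to pick
#' a small set of informative filters.
#'
#' @param spectra Samples x wavelengths matrix with numeric-parseable column
#'   names.
#' @param n_bands Number of wavelengths to return (<= ncol).
#' @return Numeric vector of `n_bands` wavelengths, in component order.
#' @export
rank_bands_pca <- function(spectra, n_bands) {
  if (!is.matrix(spectra) || nrow(spectra) < 2) {
    stop("need a matrix with at least 2 sample rows", call. = FALSE)
  }
  if (n_bands > ncol(spectra)) {
    stop("n_bands exceeds the number of wavelengths", call. = FALSE)
  }
  wl <- as.numeric(colnames(spectra))
  if (anyNA(wl)) wl <- seq_len(ncol(spectra))
  pc <- stats::prcomp(spectra, center = TRUE, scale. = FALSE)
  n_comp <- min(n_bands, ncol(pc$rotation))
  chosen <- integer(0)
  for (j in seq_len(n_comp)) {
    load <- abs(pc$rotation[, j])
    load[chosen] <- -Inf
    # which.max returns the first (lowest-wavelength) index on exact ties
    chosen <- c(chosen, which.max(load))
  }
  # degenerate input with fewer components than requested bands: pad by
  # total-loading ranking over the remaining wavelengths
  while (length(chosen) < n_bands) {
    load <- rowSums(abs(pc$rotation))
    load[chosen] <- -Inf
    chosen <- c(chosen, which.max(load))
  }
  wl[chosen]
}
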