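# The sequential masking classifier and the RGB-only baseline.
#
# Stage order is fixed: background (635 nm, K=2), fruit (a*b*, K=4), stems
# (880 nm, K=3), leaves/branches (660 nm, K=3); masks accumulate by OR and
# each stage clusters only what earlier stages left unclaimed. Cluster ->
# class assignment rests on centroid-ordering rules justified by the
# spectral physics: chlorophyll-absorbing canopy is dark at 635 nm so the
# brighter centroid is background; grapes are the blue extreme of b*; woody
# tissue reflects less NIR than leaves so the lowest 880 nm centroid is the
# stems; at 660 nm the masked fill forms the darkest cluster, leaves the
# middle and branches the brightest.

#' Pipeline configuration
#'
#' @param k_background,k_colour,k_stems,k_leaves Cluster counts per stage
#'   (defaults 2, 4, 3, 3).
#' @param background_rule `"brightest"` (default: the brighter 635 nm
#'   centroid is background) or `"darkest"` for inverted-contrast imagery.
#' @param fruit_rule `"lowest_b"` (default: the lowest b* centroid is fruit)
#'   or `"highest_b"`.
#' @param fruit_b_threshold Centroid acceptance threshold on b* (default 0):
#'   under the default rule the candidate fruit cluster is accepted only if
#'   its b* centroid is below this value, i.e. actually blue. Grapes sit
#'   well below 0 while foliage, canes and soil are all yellow-positive, so
#'   a grape-free scene yields an empty fruit mask instead of a false
#'   cluster.
#' @param stems_rule `"lowest"` (default: lowest unmasked 880 nm centroid) or
#'   `"highest"`.
#' @param leaves_rule `"low_masked"` (default: lowest 660 nm centroid is the
#'   masked fill, middle is leaves, highest is branches) or `"high_masked"`
#'   (reversed).
#' @param region_cfg_background,region_cfg_fruit Independent
#'   [region_filter_config()]s for the background small-area removal and the
#'   fruit hole filling.
#' @param seed,n_restarts,max_iter,tol Passed to every [kmeans_fit()] call.
#' @param step9_full_raster If `TRUE` (default) the final 660 nm stage
#'   clusters the whole raster with masked pixels filled to 0, so the fill
#'   forms its own cluster; if `FALSE` only unmasked pixels are clustered.
#' @param baseline_prototypes Optional tibble (`class`, `a`, `b`) of a*b*
#'   prototypes for the RGB-only baseline cluster-to-class assignment;
#'   `NULL` derives them from [default_signatures()] colours.
#' @return A `vineseg_pipeline_cfg` list.
#' @export
pipeline_config <- function(k_background = 2, k_colour = 4, k_stems = 3,
                            k_leaves = 3,
                            background_rule = c("brightest", "darkest"),
                            fruit_rule = c("lowest_b", "highest_b"),
                            fruit_b_threshold = 0,
                            stems_rule = c("lowest", "highest"),
                            leaves_rule = c("low_masked", "high_masked"),
                            region_cfg_background = region_filter_config(),
                            region_cfg_fruit = region_filter_config(),
                            seed = 0, n_restarts = 10, max_iter = 300,
                            tol = 1e-6,
                            step9_full_raster = TRUE,
                            baseline_prototypes = NULL) {
  ks <- c(k_background, k_colour, k_stems, k_leaves)
  if (any(ks < 2)) stop("stage cluster counts must be >= 2", call. = FALSE)
  structure(
    list(k_background = k_background, k_colour = k_colour,
         k_stems = k_stems, k_leaves = k_leaves,
         background_rule = match.arg(background_rule),
         fruit_rule = match.arg(fruit_rule),
         fruit_b_threshold = fruit_b_threshold,
         stems_rule = match.arg(stems_rule),
         leaves_rule = match.arg(leaves_rule),
         region_cfg_background = region_cfg_background,
         region_cfg_fruit = region_cfg_fruit,
         seed = seed, n_restarts = n_restarts, max_iter = max_iter,
         tol = tol,
         step9_full_raster = isTRUE(step9_full_raster),
         baseline_prototypes = baseline_prototypes),
    class = "vineseg_pipeline_cfg"
  )
}

stage_result <- function(mask, model, stage_name) {
  structure(list(mask = mask, model = model, stage_name = stage_name),
            class = "vineseg_stage_result")
}

#' @export
print.vineseg_stage_result <- function(x, ...) {
  cat("<vineseg_stage_result> stage=", x$stage_name, ", claimed=",
      sum(mask_values(x$mask)), " px, J_K=",
      format(x$model$inertia, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Stage 1: background segmentation at 635 nm
#'
#' K-means (K=2) on the 635 nm intensities partitions background from
#' foreground; the background cluster is the brighter centroid (soil and sky
#' are bright where chlorophyll absorbs), then small background areas are
#' removed by the region filter. Returns mask 1.
#'
#' @param band635 H x W matrix in \[0,1\].
#' @param cfg A [pipeline_config()].
#' @return A `vineseg_stage_result` with the background mask and the fitted
#'   cluster model.
#' @export
segment_background <- function(band635, cfg = pipeline_config()) {
  check_raster(band635, "band635")
  if (diff(range(band635)) < 1e-12) {
    stop("no separable clusters: band635 is a single intensity",
         call. = FALSE)
  }
  model <- kmeans_fit(as.vector(band635), cfg$k_background, seed = cfg$seed,
                      n_restarts = cfg$n_restarts, max_iter = cfg$max_iter,
                      tol = cfg$tol)
  bg_cluster <- if (cfg$background_rule == "brightest") {
    which.max(model$centroids[, 1])
  } else {
    which.min(model$centroids[, 1])
  }
  raw <- matrix(model$assignments == bg_cluster, nrow(band635), ncol(band635))
  cleaned <- remove_small_regions(raw, cfg$region_cfg_background)
  stage_result(new_mask(cleaned, "background"), model, "background")
}

#' Stage 2: fruit segmentation in a*b*
#'
#' The RGB image is converted to L*a*b*; K-means (K=4) clusters the (a*, b*)
#' pairs of pixels not claimed by mask 1 (all the colour information lives
#' in the chromaticity plane). The fruit cluster is the one with the lowest
#' b* centroid (dark blue-purple grapes), then tiny holes inside bunches are
#' filled. Returns mask 2.
#'
#' @param rgb H x W x 3 array in \[0,1\].
#' @param mask1 Background mask from [segment_background()].
#' @param cfg A [pipeline_config()].
#' @return A `vineseg_stage_result`.
#' @export
segment_fruit <- function(rgb, mask1, cfg = pipeline_config()) {
  m1 <- mask_values(mask1)
  unmasked <- which(!m1)
  if (length(unmasked) < cfg$k_colour) {
    stop("fewer unmasked pixels than K = ", cfg$k_colour, call. = FALSE)
  }
  lab <- rgb_to_lab(rgb)
  ab <- cbind(as.vector(lab[, , 2])[unmasked],
              as.vector(lab[, , 3])[unmasked])
  model <- kmeans_fit(ab, cfg$k_colour, seed = cfg$seed,
                      n_restarts = cfg$n_restarts, max_iter = cfg$max_iter,
                      tol = cfg$tol)
  fruit_cluster <- if (cfg$fruit_rule == "lowest_b") {
    which.min(model$centroids[, 2])
  } else {
    which.max(model$centroids[, 2])
  }
  centroid_b <- model$centroids[fruit_cluster, 2]
  accepted <- if (cfg$fruit_rule == "lowest_b") {
    centroid_b < cfg$fruit_b_threshold
  } else {
    centroid_b > cfg$fruit_b_threshold
  }
  raw <- matrix(FALSE, nrow(m1), ncol(m1))
  if (accepted) {
    raw[unmasked[model$assignments == fruit_cluster]] <- TRUE
  }
  filled <- fill_small_holes(raw, cfg$region_cfg_fruit)
  frac <- sum(filled) / length(filled)
  if (!accepted || frac < cfg$region_cfg_fruit$min_area_fraction) {
    warning("fruit mask covers only ", signif(100 * frac, 3),
            "% of the image; the scene may contain no grapes",
            call. = FALSE)
  }
  stage_result(new_mask(filled, "fruit"), model, "fruit")
}

#' Stage 3: stem segmentation at 880 nm
#'
#' K-means (K=3) on the 880 nm intensities of pixels not claimed by masks 1
#' or 2 separates stems, branches and leaves by NIR reflectance; the stems
#' are the lowest centroid (woody tissue reflects less NIR than foliage).
#' Returns mask 3.
#'
#' @param band880 H x W matrix in \[0,1\].
#' @param mask12 Logical OR of masks 1 and 2 (see [combine_masks()]).
#' @param cfg A [pipeline_config()].
#' @return A `vineseg_stage_result`.
#' @export
segment_stems <- function(band880, mask12, cfg = pipeline_config()) {
  check_raster(band880, "band880")
  m12 <- mask_values(mask12)
  unmasked <- which(!m12)
  if (length(unmasked) < cfg$k_stems) {
    stop("fewer unmasked pixels than K = ", cfg$k_stems, call. = FALSE)
  }
  model <- kmeans_fit(band880[unmasked], cfg$k_stems, seed = cfg$seed,
                      n_restarts = cfg$n_restarts, max_iter = cfg$max_iter,
                      tol = cfg$tol)
  stem_cluster <- if (cfg$stems_rule == "lowest") {
    which.min(model$centroids[, 1])
  } else {
    which.max(model$centroids[, 1])
  }
  raw <- matrix(FALSE, nrow(m12), ncol(m12))
  raw[unmasked[model$assignments == stem_cluster]] <- TRUE
  frac <- sum(raw) / length(raw)
  if (frac < cfg$region_cfg_background$min_area_fraction) {
    warning("stems cluster holds only ", signif(100 * frac, 3),
            "% of the image; stems may be absent", call. = FALSE)
  }
  stage_result(new_mask(raw, "stems"), model, "stems")
}

#' Stage 4: leaves versus branches at 660 nm
#'
#' The 660 nm raster is clustered into three groups: leaves, branches and
#' the previously masked pixels. By default the whole raster is clustered
#' with masked pixels filled to 0 so the fill forms the darkest cluster
#' (`step9_full_raster = TRUE`); alternatively only unmasked pixels are
#' clustered. The lowest centroid maps to the masked fill, the middle to
#' leaves, the highest to branches. Pixels claimed by masks 1-3 are never
#' labelled here.
#'
#' @param band660 H x W matrix in \[0,1\].
#' @param mask123 Logical OR of masks 1-3.
#' @param cfg A [pipeline_config()].
#' @return A list (`vineseg_stage`) with `labels` (partial
#'   `vineseg_label_map` over LEAF/BRANCH/UNLABELED) and `model`.
#' @export
segment_leaves_branches <- function(band660, mask123,
                                    cfg = pipeline_config()) {
  check_raster(band660, "band660")
  m123 <- mask_values(mask123)
  filled <- apply_mask(band660, m123, fill = 0)
  if (cfg$step9_full_raster) {
    x <- as.vector(filled)
    sel <- seq_along(x)
  } else {
    sel <- which(!m123)
    x <- band660[sel]
  }
  if (length(unique(round(x, 9))) < cfg$k_leaves) {
    stop("fewer than ", cfg$k_leaves,
         " distinct intensity levels at 660 nm", call. = FALSE)
  }
  model <- kmeans_fit(x, cfg$k_leaves, seed = cfg$seed,
                      n_restarts = cfg$n_restarts, max_iter = cfg$max_iter,
                      tol = cfg$tol)
  ord <- order(model$centroids[, 1])
  if (cfg$leaves_rule == "low_masked") {
    roles <- c("UNLABELED", "LEAF", "BRANCH")   # lowest, middle, highest
  } else {
    roles <- c("BRANCH", "LEAF", "UNLABELED")
  }
  role_of_cluster <- character(cfg$k_leaves)
  role_of_cluster[ord] <- roles
  vals <- matrix("UNLABELED", nrow(band660), ncol(band660))
  vals[sel] <- role_of_cluster[model$assignments]
  vals[m123] <- "UNLABELED"   # containment: masked pixels are never relabelled
  structure(list(labels = label_map(vals), model = model,
                 stage_name = "leaves_branches"),
            class = "vineseg_stage")
}

#' Classify a scene with the sequential masking algorithm
#'
#' Composes the four stages in order with precedence background > fruit >
#' stems > leaves/branches: the background mask claims its pixels first,
#' then the fruit mask among the remainder, then the stems, and the final
#' 660 nm clustering labels leaves and branches. Residual pixels that the
#' 660 nm stage put in its masked-fill cluster but that no mask claims are
#' dark outliers and are assigned BACKGROUND (their count is recorded). The
#' result carries a full per-stage audit trail (models, masks, seeds).
#'
#' @param bundle A `vineseg_scene`.
#' @param cfg A [pipeline_config()].
#' @return A `vineseg_classification`: `labels` (complete
#'   `vineseg_label_map`), `stages` (named list of stage results),
#'   `residual_count`, `config`, `scene_id`.
#' @export
classify_scene <- function(bundle, cfg = pipeline_config()) {
  if (!inherits(bundle, "vineseg_scene")) {
    stop("classify_scene() needs a vineseg_scene", call. = FALSE)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  s1 <- run_stage("background",
                  segment_background(bundle$band635, cfg))
  m1 <- mask_values(s1$mask)
  s2 <- run_stage("fruit", segment_fruit(bundle$rgb, s1$mask, cfg))
  m2 <- mask_values(s2$mask) & !m1          # precedence: background first
  m12 <- m1 | m2
  s3 <- run_stage("stems", segment_stems(bundle$band880, m12, cfg))
  m3 <- mask_values(s3$mask) & !m12
  m123 <- m12 | m3
  s4 <- run_stage("leaves_branches",
                  segment_leaves_branches(bundle$band660, m123, cfg))

  vals <- unclass(s4$labels)
  vals[m3] <- "STEM"
  vals[m2] <- "FRUIT"
  vals[m1] <- "BACKGROUND"
  residual <- vals == "UNLABELED"
  vals[residual] <- "BACKGROUND"

  structure(
    list(labels = label_map(vals),
         stages = list(background = s1, fruit = s2, stems = s3,
                       leaves_branches = s4),
         residual_count = sum(residual),
         config = cfg,
         scene_id = bundle$scene_id),
    class = "vineseg_classification"
  )
}

#' @export
print.vineseg_classification <- function(x, ...) {
  cat("<vineseg_classification> scene '", x$scene_id, "', residual=",
      x$residual_count, " px\n", sep = "")
  print(x$labels)
  invisible(x)
}

# a*b* prototypes for the baseline cluster-to-class assignment, derived from
# the signature colours. BACKGROUND keeps two prototypes (soil and sky); the
# matching cost uses the nearer one.
baseline_prototypes_default <- function(sig = default_signatures()) {
  cols <- tidyr::pivot_wider(sig$colours, names_from = "channel",
                             values_from = c("mean", "sd"))
  rgb <- array(0, dim = c(nrow(cols), 1, 3))
  rgb[, 1, 1] <- cols$mean_r; rgb[, 1, 2] <- cols$mean_g
  rgb[, 1, 3] <- cols$mean_b
  lab <- rgb_to_lab(rgb)
  cls <- cols$class
  cls[cls %in% c("SOIL", "SKY")] <- "BACKGROUND"
  tibble::tibble(class = cls, a = lab[, 1, 2], b = lab[, 1, 3])
}

# One-to-one assignment of K=5 cluster centroids to the five classes
# minimising total squared a*b* distance (exhaustive over the 120
# permutations; BACKGROUND's cost is the min over its prototypes).
match_clusters_to_classes <- function(centroids, prototypes) {
  classes <- vineseg_classes()
  cost <- matrix(Inf, nrow = nrow(centroids), ncol = length(classes),
                 dimnames = list(NULL, classes))
  for (j in seq_along(classes)) {
    pr <- prototypes[prototypes$class == classes[j], , drop = FALSE]
    if (nrow(pr) == 0) stop("baseline prototypes missing class ",
                            classes[j], call. = FALSE)
    d <- vapply(seq_len(nrow(pr)), function(r) {
      (centroids[, 1] - pr$a[r])^2 + (centroids[, 2] - pr$b[r])^2
    }, numeric(nrow(centroids)))
    cost[, j] <- apply(matrix(d, nrow = nrow(centroids)), 1, min)
  }
  perms <- permutations_of(seq_along(classes))
  best <- NULL; best_cost <- Inf
  for (p in perms) {
    tc <- sum(cost[cbind(seq_len(nrow(cost)), p)])
    if (tc < best_cost) { best_cost <- tc; best <- p }
  }
  classes[best]
}

permutations_of <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

#' RGB-only baseline classifier
#'
#' The comparison baseline: a single K-means (K=5) over the (a*, b*) values
#' of every pixel, with clusters assigned one-to-one to the five classes by
#' nearest a*b* prototype (total-cost-minimising matching). No multispectral
#' bands and no sequential masking are used.
#'
#' @param rgb H x W x 3 array in \[0,1\].
#' @param cfg A [pipeline_config()].
#' @return A `vineseg_label_map`.
#' @export
classify_scene_rgb_only <- function(rgb, cfg = pipeline_config()) {
  lab <- rgb_to_lab(rgb)
  ab <- cbind(as.vector(lab[, , 2]), as.vector(lab[, , 3]))
  if (nrow(ab) < 5) stop("fewer than 5 pixels", call. = FALSE)
  if (max(stats::sd(ab[, 1]), stats::sd(ab[, 2])) < 0.5) {
    stop("degenerate clusters: image is achromatic (a* and b* carry no ",
         "colour information)", call. = FALSE)
  }
  model <- kmeans_fit(ab, 5, seed = cfg$seed, n_restarts = cfg$n_restarts,
                      max_iter = cfg$max_iter, tol = cfg$tol)
  proto <- cfg$baseline_prototypes
  if (is.null(proto)) proto <- baseline_prototypes_default()
  cls <- match_clusters_to_classes(model$centroids, proto)
  label_map(matrix(cls[model$assignments], dim(rgb)[1], dim(rgb)[2]))
}
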