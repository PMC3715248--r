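test_that("default signatures encode the physical orderings", {
  sig <- default_signatures()
  at <- function(cl, wl) vineseg:::signature_at(sig, cl, wl)

  # vegetation: NIR above red (chlorophyll absorbs in the red)
  expect_gt(at("LEAF", 880), at("LEAF", 635))
  expect_gt(at("BRANCH", 880), at("BRANCH", 635))
  # soil bright where the canopy is dark
  expect_gt(at("SOIL", 635), at("LEAF", 635))
  expect_gt(at("SKY", 635), at("LEAF", 635))
  # woody tissue below leaves in the NIR (the stems stage lever)
  expect_lt(at("STEM", 880), at("LEAF", 880))
  expect_lt(at("BRANCH", 880), at("LEAF", 880))
  expect_lt(at("STEM", 880), at("BRANCH", 880))
  # grapes dark everywhere in the visible
  expect_lt(at("FRUIT", 635), at("SOIL", 635))

  # fruit colour is the b* extreme (dark blue-purple)
  proto <- vineseg:::baseline_prototypes_default(sig)
  expect_equal(proto$class[which.min(proto$b)], "FRUIT")

  # invariants: means in [0,1], sd > 0, filter wavelengths on the grid
  expect_true(all(sig$spectra$mean >= 0 & sig$spectra$mean <= 1))
  expect_true(all(sig$spectra$sd > 0))
  expect_true(all(c(635, 660, 880) %in% sig$spectra$wavelength))
})

test_that("scene generation is deterministic and fully labelled", {
  spec <- small_scene_spec(seed = 4)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$band635, b$band635)
  expect_identical(a$rgb, b$rgb)
  expect_identical(unclass(a$truth), unclass(b$truth))

  counts <- label_counts(a$truth)
  expect_true(all(counts$n[counts$class %in% vineseg_classes()] > 0))
  expect_equal(counts$n[counts$class == "UNLABELED"], 0)

  # all rendered intensities in [0,1]
  for (ch in list(a$rgb, a$band635, a$band660, a$band880)) {
    expect_true(min(ch) >= 0 && max(ch) <= 1)
  }
})

test_that("rendered band means track the signature table", {
  # flat illumination so the per-class sample mean estimates the signature
  spec <- small_scene_spec(seed = 5, illumination = c(1, 1))
  sc <- generate_scene(spec)
  sig <- default_signatures()
  truth <- unclass(sc$truth)
  for (cl in c("LEAF", "STEM", "BRANCH", "FRUIT")) {
    px <- sc$band880[truth == cl]
    mu <- vineseg:::signature_at(sig, cl, 880)
    expect_lt(abs(mean(px) - mu), 3 * spec$noise_sd / sqrt(length(px)) + 1e-3)
  }
})

test_that("a crowded spec that erases a class warns with realised counts", {
  spec <- scene_spec(height = 64, width = 64, n_bunches = 0, n_leaves = 0,
                     n_branches = 0, seed = 6)
  expect_warning(sc <- generate_scene(spec), "vanished")
})

test_that("scene sets vary in seed, lighting and truth geometry", {
  scenes <- generate_scene_set(3, small_scene_spec(seed = 0), base_seed = 0)
  expect_length(scenes, 3)
  ids <- vapply(scenes, function(s) s$scene_id, character(1))
  expect_false(any(duplicated(ids)))
  # truth maps differ pairwise
  expect_false(identical(unclass(scenes[[1]]$truth),
                         unclass(scenes[[2]]$truth)))
  expect_false(identical(unclass(scenes[[2]]$truth),
                         unclass(scenes[[3]]$truth)))
  # regeneration is reproducible
  again <- generate_scene_set(3, small_scene_spec(seed = 0), base_seed = 0)
  expect_identical(scenes[[2]]$band660, again[[2]]$band660)
})

test_that("contrast ratios behave and peak in the red for leaf-to-soil", {
  sig <- default_signatures()
  self <- contrast_ratio(sig, "LEAF", "LEAF")
  expect_true(all(self$ratio == 1))

  ls <- contrast_ratio(sig, "LEAF", "SOIL")
  peak <- ls$wavelength[which.max(abs(ls$ratio - 1))]
  expect_gte(peak, 630); expect_lte(peak, 690)

  ss <- contrast_ratio(sig, "STEM", "SOIL")
  expect_true(all(is.finite(ss$ratio)))
  expect_error(contrast_ratio(sig, "LEAF", "NOPE"), "unknown material")
})

test_that("increasing noise degrades mean accuracy over a fixed seed set", {
  acc_at <- function(noise) {
    scenes <- generate_scene_set(2, small_scene_spec(seed = 0,
                                                     noise_sd = noise),
                                 base_seed = 0)
    mean(vapply(scenes, function(sc) {
      rep <- evaluate_labels(classify_scene(sc)$labels, sc$truth, sc$scene_id)
      rep$accuracy[1]
    }, numeric(1)))
  }
  accs <- vapply(c(0.01, 0.06, 0.12), acc_at, numeric(1))
  expect_true(all(diff(accs) < 0))
})

test_that("PCA band ranking finds variance and breaks ties by wavelength", {
  # variance only in band 1
  X <- cbind(b1 = c(0, 1, 2, 3), b2 = rep(5, 4))
  colnames(X) <- c("500", "600")
  expect_equal(rank_bands_pca(X, 1), 500)

  # duplicated columns tie; the lower wavelength wins
  Y <- cbind(rnorm(6), rnorm(6))
  Y <- cbind(Y, Y[, 1])
  colnames(Y) <- c("500", "600", "700")
  top <- rank_bands_pca(Y, 2)
  expect_false(700 %in% top[1])   # the duplicate at 700 never beats 500

  expect_error(rank_bands_pca(matrix(1, 1, 3), 2), "at least 2")
  expect_error(rank_bands_pca(cbind(1:3, 4:6), 5), "exceeds")
})

test_that("signature draws rank a red and a NIR band among the top three", {
  sig <- default_signatures()
  draws <- draw_signature_samples(sig, n_per_class = 20, seed = 0)
  top3 <- rank_bands_pca(draws, 3)
  expect_true(any(top3 >= 630 & top3 <= 690))
  expect_true(any(top3 >= 850))
})
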