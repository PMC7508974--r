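test_that("rendered plates carry 52 glyph cells and severity-monotone ink", {
  lay <- fx_layout()
  set.seed(101)
  pd <- sample(0:4, 52, replace = TRUE)
  pl <- render_plate(pd, lay)
  expect_s3_class(pl, "vf_plate")
  expect_identical(sum(pl$truth != "blank"), 52L)
  expect_identical(pl$truth_h, diag(3))
  # deterministic rendering
  expect_identical(render_plate(pd, lay)$pixels, pl$pixels)
  # all-">5%" map: 52 identical dot glyphs
  pl0 <- render_plate(rep(0L, 52), lay)
  expect_identical(sum(pl0$truth == ">5%"), 52L)
  # ink area per glyph class increases strictly with severity
  ink <- vapply(0:4, function(code) {
    sum(render_plate(rep(code, 52), lay)$pixels < 0.5)
  }, numeric(1))
  expect_true(all(diff(ink) > 0))
})

test_that("capture simulation is seeded, in-range-checked and identity at zero magnitude", {
  lay <- fx_layout()
  set.seed(102)
  pl <- render_plate(sample(0:4, 52, TRUE), lay)
  p0 <- augment_capture(pl, capture_params(0, 0, 0, 0, 0))
  expect_identical(p0$pixels, pl$pixels)
  expect_identical(p0$truth_cross, pl$truth_cross)
  set.seed(7)
  p1 <- augment_capture(pl)
  set.seed(7)
  p2 <- augment_capture(pl)
  expect_identical(p1$pixels, p2$pixels)
  expect_false(identical(p1$pixels, pl$pixels))
  # out-of-range parameters are rejected
  expect_error(capture_params(persp = 0.1), "documented ranges")
  expect_error(capture_params(blur = -1), "non-negative")
  # recorded homography maps the original cross onto the warped cross
  ns <- asNamespace("vfscreen")
  mapped <- as.numeric(ns$apply_homography(p1$truth_h,
                                           rbind(pl$truth_cross)))
  expect_equal(mapped, p1$truth_cross, tolerance = 1e-9)
})

test_that("cross localization is sub-pixel on clean plates and within tolerance on captures", {
  lay <- fx_layout()
  sty <- plate_style()
  set.seed(103)
  pl <- render_plate(sample(0:4, 52, TRUE), lay, sty)
  loc <- locate_cross(pl$pixels, sty)
  expect_lt(sqrt(sum((loc$center - pl$truth_cross)^2)), 1)
  errs <- replicate(25, {
    p2 <- augment_capture(pl)
    l2 <- locate_cross(p2$pixels, sty)
    sqrt(sum((l2$center - p2$truth_cross)^2))
  })
  expect_true(all(errs <= 0.25 * sty$pitch))
  # blank image and cross-less frame are rejected as unusable captures
  expect_error(locate_cross(matrix(1, sty$height, sty$width), sty),
               class = "vf_detection_error")
  frame_only <- matrix(1, sty$height, sty$width)
  frame_only[33:35, 33:466] <- 0
  frame_only[452:454, 33:466] <- 0
  frame_only[33:454, 33:35] <- 0
  frame_only[33:454, 464:466] <- 0
  expect_error(locate_cross(frame_only, sty), class = "vf_detection_error")
})

test_that("render-then-recognize is the identity on clean plates", {
  lay <- fx_layout()
  sty <- plate_style()
  gm <- fx_glyph()
  set.seed(104)
  for (k in 1:15) {
    pd <- sample(0:4, 52, replace = TRUE)
    pl <- render_plate(pd, lay, sty)
    loc <- locate_cross(pl$pixels, sty)
    rec <- classify_cells(pl$pixels, loc$h, gm, sty, truth = pl$truth)
    expect_identical(rec$overall_accuracy, 1)
    expect_equal(rowSums(rec$confidences), rep(1, 72))
  }
})

test_that("recognition accuracy does not increase along an augmentation severity ladder", {
  lay <- fx_layout()
  sty <- plate_style()
  gm <- fx_glyph()
  set.seed(105)
  maps <- lapply(1:12, function(i) sample(0:4, 52, replace = TRUE))
  acc <- vapply(c(0, 0.5, 1, 1.5, 2), function(sc) {
    hits <- 0; tot <- 0
    for (pd in maps) {
      pl <- augment_capture(render_plate(pd, lay, sty),
                            capture_params(scale = sc))
      loc <- tryCatch(locate_cross(pl$pixels, sty),
                      vf_detection_error = function(e) NULL)
      if (is.null(loc)) { tot <- tot + 72; next }  # failure counts as 0
      rec <- classify_cells(pl$pixels, loc$h, gm, sty, truth = pl$truth)
      hits <- hits + rec$overall_accuracy * 72
      tot <- tot + 72
    }
    hits / tot
  }, numeric(1))
  expect_true(all(diff(acc) <= 0.005))  # non-increasing up to sampling noise
})

test_that("image diagnosis runs end to end and attributes failures to the detection stage", {
  lay <- fx_layout()
  sty <- plate_style()
  gm <- fx_glyph()
  nm <- fx_norm()
  vfm <- fx_small_model()
  truth <- fx_truth()
  set.seed(106)
  # deep arcuate field -> positive call
  rec_pos <- apply_archetype(sample_normal_field(55, truth), "arcuate_sup", 16)
  cat_pos <- deviation_maps(rec_pos, nm)$pd_cat
  pl_pos <- render_plate(cat_pos, lay, sty)
  d_pos <- diagnose_from_image(pl_pos$pixels, gm, vfm, sty, lay)
  expect_identical(d_pos$label, "glaucoma")
  expect_identical(d_pos$pd_cat, cat_pos)
  expect_identical(dim(d_pos$heatmap), c(8L, 9L))
  # clean normal field -> negative call
  rec_neg <- sample_normal_field(50, truth)
  pl_neg <- render_plate(deviation_maps(rec_neg, nm)$pd_cat, lay, sty)
  d_neg <- diagnose_from_image(pl_neg$pixels, gm, vfm, sty, lay)
  expect_identical(d_neg$label, "non_glaucoma")
  # detection failure: structured error, no score
  expect_error(diagnose_from_image(matrix(1, sty$height, sty$width),
                                   gm, vfm, sty, lay),
               class = "vf_detection_error")
  # the map classifier must be the PDP model
  nd_model <- build_vf_model("ND")
  expect_error(diagnose_from_image(pl_pos$pixels, gm, nd_model, sty, lay),
               "PDP")
})

test_that("plate PNG round-trips through the png codec", {
  set.seed(107)
  pl <- render_plate(sample(0:4, 52, TRUE))
  tf <- tempfile(fileext = ".png")
  write_plate_png(pl$pixels, tf)
  back <- read_plate_png(tf)
  expect_identical(dim(back), dim(pl$pixels))
  expect_lt(max(abs(back - pl$pixels)), 1 / 254)
  unlink(tf)
})
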