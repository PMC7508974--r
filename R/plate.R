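# Rendering and recognition of printed pattern-deviation probability
# plates. Images are plain matrices [rows, cols] with values in [0, 1]
# (1 = white); pixel coordinates are (x = column, y = row), 1-based.

#' Glyph class labels of the plate recognizer
#'
#' The six cell patterns on a printed PDP plate: blank (off-grid or
#' blind-spot cell) and the five probability symbols.
#' @return Character vector of length 6.
#' @export
plate_classes <- function() c("blank", vf_categories())

#' Plate rendering style
#'
#' @param pitch cell pitch in pixels.
#' @param margin outer margin around the 9 x 8 cell grid, pixels. The
#'   default margins leave enough white canvas that every in-range
#'   capture warp keeps the whole frame inside the image.
#' @param border_inset distance of the frame rectangle from the canvas
#'   edge, pixels.
#' @param border_width frame line width, pixels.
#' @param glyph_frac glyph box side as a fraction of the pitch.
#' @return A `vf_plate_style` list, including the derived canvas size.
#' @export
plate_style <- function(pitch = 42, margin = 60, border_inset = 32,
                        border_width = 3, glyph_frac = 0.55) {
  width <- 2L * margin + 9L * pitch
  height <- 2L * margin + 8L * pitch
  structure(list(pitch = pitch, margin = margin,
                 border_inset = border_inset, border_width = border_width,
                 glyph_frac = glyph_frac, width = width, height = height),
            class = "vf_plate_style")
}

# canonical pixel centre of grid cell (row, col)
cell_center <- function(style, row, col) {
  cbind(x = style$margin + (col - 0.5) * style$pitch,
        y = style$margin + (row - 0.5) * style$pitch)
}

# canonical centre of the cross (field coordinate (0, 0) lies between
# rows 4/5 and columns 5/6)
cross_center <- function(style) {
  c(x = style$margin + 5 * style$pitch,
    y = style$margin + 4 * style$pitch)
}

canonical_corners <- function(style) {
  i0 <- style$border_inset + 1
  cbind(x = c(i0, style$width - style$border_inset,
              style$width - style$border_inset, i0),
        y = c(i0, i0, style$height - style$border_inset,
              style$height - style$border_inset))
}

fill_rect <- function(img, x0, x1, y0, y1, value = 0) {
  xs <- max(1, round(x0)):min(ncol(img), round(x1))
  ys <- max(1, round(y0)):min(nrow(img), round(y1))
  img[ys, xs] <- value
  img
}

# dot offsets (relative to the cell centre, units of the glyph box
# half-side) for the stippled probability symbols
glyph_offsets <- function(code, half) {
  switch(as.character(code),
    `0` = cbind(0, 0),
    `1` = as.matrix(expand.grid(c(-0.75, 0.75), c(-0.75, 0.75))) * half,
    `2` = as.matrix(expand.grid(c(-0.75, 0, 0.75),
                                c(-0.75, 0, 0.75))) * half,
    `3` = as.matrix(expand.grid(c(-0.9, -0.3, 0.3, 0.9),
                                c(-0.9, -0.3, 0.3, 0.9))) * half
  )
}

#' Render a pattern-deviation probability plate
#'
#' Draws a printout-like grayscale plate: a frame rectangle, the central
#' cross axes, and one glyph per active location — a single dot for
#' ">5%", increasingly dense stipple for "<5%", "<2%" and "<1%", and a
#' solid black square for "<0.5%". Ground truth (per-cell classes, cross
#' centre, identity homography) is recorded for downstream evaluation.
#' Rendering is fully deterministic given the style.
#'
#' @param pd_cat integer category codes 0..4 per active location.
#' @param layout a `vf_layout`.
#' @param style a [plate_style()].
#' @return An object of class `vf_plate`: list with `pixels` (matrix,
#'   1 = white), `truth` (8 x 9 character matrix over [plate_classes()]),
#'   `truth_cross` (pixel x, y), `truth_h` (3 x 3 homography from the
#'   canonical plate to this image; identity when clean), and `style`.
#' @export
render_plate <- function(pd_cat, layout = vf_layout(),
                         style = plate_style()) {
  if (length(pd_cat) != length(layout$active)) {
    stop("`pd_cat` must give a category per active location", call. = FALSE)
  }
  img <- matrix(1, style$height, style$width)
  # frame
  cc <- canonical_corners(style)
  bw <- style$border_width
  img <- fill_rect(img, cc[1, 1], cc[2, 1], cc[1, 2], cc[1, 2] + bw - 1)
  img <- fill_rect(img, cc[1, 1], cc[2, 1], cc[3, 2] - bw + 1, cc[3, 2])
  img <- fill_rect(img, cc[1, 1], cc[1, 1] + bw - 1, cc[1, 2], cc[3, 2])
  img <- fill_rect(img, cc[2, 1] - bw + 1, cc[2, 1], cc[1, 2], cc[3, 2])
  # cross axes spanning the grid area, 3 px wide, centred on the cross
  ctr <- cross_center(style)
  g0 <- style$margin - 6
  img <- fill_rect(img, g0, style$width - g0, ctr["y"] - 1, ctr["y"] + 1)
  img <- fill_rect(img, ctr["x"] - 1, ctr["x"] + 1, g0, style$height - g0)
  # glyphs
  truth <- matrix("blank", 8, 9)
  a <- layout$locations[layout$active, ]
  half <- style$glyph_frac * style$pitch / 2
  for (i in seq_along(layout$active)) {
    code <- pd_cat[i]
    ct <- cell_center(style, a$row[i], a$col[i])
    truth[a$row[i], a$col[i]] <- plate_classes()[code + 2]
    if (code >= 4) {
      img <- fill_rect(img, ct[1] - half, ct[1] + half,
                       ct[2] - half, ct[2] + half)
    } else {
      off <- glyph_offsets(code, half)
      dr <- if (code == 0) 2 else 1  # the lone ">5%" dot is drawn larger
      for (d in seq_len(nrow(off))) {
        img <- fill_rect(img, ct[1] + off[d, 1] - dr, ct[1] + off[d, 1] + dr,
                         ct[2] + off[d, 2] - dr, ct[2] + off[d, 2] + dr)
      }
    }
  }
  structure(list(pixels = img, truth = truth,
                 truth_cross = unname(ctr),
                 truth_h = diag(3), style = style),
            class = "vf_plate")
}

#' @export
print.vf_plate <- function(x, ...) {
  cat(sprintf("PDP plate %dx%d px, %d non-blank cells\n",
              ncol(x$pixels), nrow(x$pixels), sum(x$truth != "blank")))
  invisible(x)
}

# --- homography helpers -----------------------------------------------

# direct linear transform from 4 point correspondences; maps src -> dst
solve_homography <- function(src, dst) {
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

apply_homography <- function(h, pts) {
  pts <- matrix(pts, ncol = 2)
  p <- cbind(pts, 1) %*% t(h)
  p[, 1:2, drop = FALSE] / p[, 3]
}

bilinear_sample <- function(img, x, y, outside = 1) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  gx0 <- pmin(pmax(x0, 1), w); gx1 <- pmin(pmax(x0 + 1, 1), w)
  gy0 <- pmin(pmax(y0, 1), h); gy1 <- pmin(pmax(y0 + 1, 1), h)
  v <- img[cbind(gy0, gx0)] * (1 - fx) * (1 - fy) +
    img[cbind(gy0, gx1)] * fx * (1 - fy) +
    img[cbind(gy1, gx0)] * (1 - fx) * fy +
    img[cbind(gy1, gx1)] * fx * fy
  out <- x < 0.5 | x > w + 0.5 | y < 0.5 | y > h + 0.5
  v[out] <- outside
  v
}

gaussian_blur <- function(img, sigma) {
  if (sigma < 0.05) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  shift_rows <- function(m, d) {
    n <- nrow(m)
    idx <- pmin(pmax(seq_len(n) + d, 1), n)  # replicate edges
    m[idx, , drop = FALSE]
  }
  acc <- img * 0
  for (j in seq_along(k)) acc <- acc + k[j] * shift_rows(img, j - r - 1L)
  img <- acc
  acc <- img * 0
  for (j in seq_along(k)) {
    acc <- acc + k[j] * t(shift_rows(t(img), j - r - 1L))
  }
  acc
}

#' Capture-simulation parameter set
#'
#' Maximum magnitudes of the smartphone-capture augmentation; actual
#' values are drawn uniformly within the ranges at application time.
#' Documented in-range bounds: perspective corner jitter <= 3% of the
#' plate width, rotation <= 3 degrees, Gaussian blur sigma <= 1.2 px,
#' brightness/contrast jitter <= 15%, additive noise SD <= 3 gray levels
#' (3/255).
#'
#' @param persp,rot,blur,photometric,noise maximum magnitudes (see above).
#' @param scale overall multiplier on all five magnitudes, for severity
#'   ladders.
#' @return A `vf_capture_params` list.
#' @export
capture_params <- function(persp = 0.03, rot = 3, blur = 1.2,
                           photometric = 0.15, noise = 3 / 255,
                           scale = 1) {
  p <- list(persp = persp * scale, rot = rot * scale, blur = blur * scale,
            photometric = photometric * scale, noise = noise * scale)
  if (p$persp > 0.03 + 1e-9 || p$rot > 3 + 1e-9 || p$blur > 1.2 + 1e-9 ||
      p$photometric > 0.15 + 1e-9 || p$noise > 3 / 255 + 1e-9) {
    if (scale <= 1) {
      stop("capture parameters exceed the documented ranges", call. = FALSE)
    }
  }
  if (any(unlist(p) < 0)) {
    stop("capture parameters must be non-negative", call. = FALSE)
  }
  structure(p, class = "vf_capture_params")
}

#' Simulate a smartphone capture of a plate
#'
#' Applies a projective warp (small rotation about the canvas centre plus
#' independent corner jitter) followed by Gaussian blur, a
#' brightness/contrast change and additive pixel noise. Magnitudes are
#' drawn uniformly within the parameter ranges from the current RNG
#' state, so a fixed seed reproduces the capture exactly; zero-magnitude
#' parameters return a pixel-identical plate. The recorded ground-truth
#' homography and cross position are composed with the applied warp.
#'
#' @param plate a `vf_plate`.
#' @param params a [capture_params()]; `scale` > 1 is allowed for
#'   stress-testing beyond the documented ranges.
#' @return The warped `vf_plate`.
#' @export
augment_capture <- function(plate, params = capture_params()) {
  stopifnot(inherits(plate, "vf_plate"))
  img <- plate$pixels
  h <- nrow(img); w <- ncol(img)
  theta <- stats::runif(1, -params$rot, params$rot) * pi / 180
  corners <- cbind(x = c(1, w, w, 1), y = c(1, 1, h, h))
  ctr <- c(w, h) / 2
  rotm <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  target <- sweep(sweep(corners, 2, ctr) %*% t(rotm), 2, ctr, "+")
  target <- target + matrix(stats::runif(8, -params$persp * w,
                                         params$persp * w), 4, 2)
  hmat <- solve_homography(corners, target)
  if (max(abs(hmat - diag(3))) > 1e-12) {
    grid <- cbind(rep(seq_len(w), each = h), rep(seq_len(h), times = w))
    src <- apply_homography(solve(hmat), grid)
    img <- matrix(bilinear_sample(img, src[, 1], src[, 2]), h, w)
  }
  img <- gaussian_blur(img, stats::runif(1, 0, params$blur))
  cj <- stats::runif(1, 1 - params$photometric, 1 + params$photometric)
  bj <- stats::runif(1, -params$photometric, params$photometric)
  img <- (img - 0.5) * cj + 0.5 + bj
  if (params$noise > 0) {
    img <- img + stats::rnorm(length(img), 0,
                              stats::runif(1, 0, params$noise))
  }
  plate$pixels <- pmin(pmax(img, 0), 1)
  plate$truth_h <- hmat %*% plate$truth_h
  plate$truth_cross <- as.numeric(apply_homography(hmat,
                                                   plate$truth_cross))
  plate
}

detection_error <- function(msg) {
  stop(structure(class = c("vf_detection_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Locate the central cross and plate geometry
#'
#' Binarizes the image, estimates the four frame corners from the extreme
#' ink pixels (averaged over a small corner neighbourhood for sub-pixel
#' stability), solves the canonical-to-image homography from the corner
#' correspondences, and verifies that ink is actually present along both
#' cross axes. Fails with a `vf_detection_error` condition when no plate
#' structure is found — the signal for an unusable capture.
#'
#' @param image grayscale matrix in `[0, 1]`.
#' @param style the [plate_style()] the plate was printed with (fixed
#'   geometry is assumed known, as for a standardized printout).
#' @return List with `center` (pixel x, y of the cross), `h` (3 x 3
#'   homography mapping canonical plate coordinates into this image) and
#'   `threshold` (the binarization level used).
#' @export
locate_cross <- function(image, style = plate_style()) {
  stopifnot(is.matrix(image))
  thr <- (min(image) + max(image)) / 2
  ink <- which(image < thr, arr.ind = TRUE)
  if (nrow(ink) < 200 || diff(range(image)) < 0.2) {
    detection_error("no plate structure found (image appears blank)")
  }
  x <- ink[, 2]; y <- ink[, 1]
  corner_of <- function(score) {
    sel <- score >= max(score) - 1.5
    c(mean(x[sel]), mean(y[sel]))
  }
  detected <- rbind(corner_of(-x - y), corner_of(x - y),
                    corner_of(x + y), corner_of(-x + y))
  hmat <- solve_homography(canonical_corners(style), detected)
  # verify ink along both cross axes in the rectified frame
  ctr <- cross_center(style)
  g0 <- style$margin
  band <- -3:3  # perpendicular probe window; the axis line is ~2 px wide
  axis_dark <- function(along_x) {
    tpar <- seq(g0, (if (along_x) style$width else style$height) - g0,
                length.out = 60)
    mins <- rep(Inf, length(tpar))
    for (b in band) {
      pts <- if (along_x) cbind(tpar, ctr["y"] + b)
             else cbind(ctr["x"] + b, tpar)
      ipts <- apply_homography(hmat, pts)
      mins <- pmin(mins, bilinear_sample(image, ipts[, 1], ipts[, 2]))
    }
    mean(mins)
  }
  if (axis_dark(TRUE) > thr || axis_dark(FALSE) > thr) {
    detection_error("no cross structure found at the expected position")
  }
  list(center = as.numeric(apply_homography(hmat, rbind(ctr))),
       h = hmat, threshold = thr)
}

# Extract the 72 rectified 32 x 32 cell patches (ink intensity, 0 = paper)
extract_patches <- function(image, hmat, style, patch_px = 32,
                            margin_frac = 0.2) {
  side <- (1 + margin_frac) * style$pitch
  offs <- seq(-side / 2, side / 2, length.out = patch_px)
  cells <- expand.grid(row = 1:8, col = 1:9)
  xall <- array(0, c(nrow(cells), patch_px, patch_px, 1))
  pgrid <- as.matrix(expand.grid(dy = offs, dx = offs))
  for (i in seq_len(nrow(cells))) {
    ct <- cell_center(style, cells$row[i], cells$col[i])
    pts <- cbind(ct[1] + pgrid[, "dx"], ct[2] + pgrid[, "dy"])
    ipts <- apply_homography(hmat, pts)
    if (any(ipts[, 1] < -style$pitch) || any(ipts[, 2] < -style$pitch) ||
        any(ipts[, 1] > ncol(image) + style$pitch) ||
        any(ipts[, 2] > nrow(image) + style$pitch)) {
      stop("cell patch falls outside the image", call. = FALSE)
    }
    v <- bilinear_sample(image, ipts[, 1], ipts[, 2])
    xall[i, , , 1] <- 1 - matrix(v, patch_px, patch_px)
  }
  list(x = xall, cells = cells)
}

#' Build an untrained six-class glyph classifier
#'
#' A small CNN for rectified 32 x 32 cell patches: three 3 x 3
#' convolution + batch-norm + ReLU stages (stride 2, 2, 1), a global
#' average pooling layer and a 6-way fully-connected layer with softmax,
#' trained under cross-entropy loss.
#'
#' @param seed integer; fixes the initialization.
#' @return An object of class `vf_glyph_cnn` (untrained).
#' @export
build_glyph_model <- function(seed = 1L) {
  set.seed(seed)
  layers <- list(
    nn_init_conv(3, 3, 1, 8, stride = 2), nn_init_bn(8),
    list(type = "relu"),
    nn_init_conv(3, 3, 8, 16, stride = 2), nn_init_bn(16),
    list(type = "relu"),
    nn_init_conv(3, 3, 16, 32), nn_init_bn(32), list(type = "relu"),
    list(type = "gap"),
    nn_init_dense(32, 6)
  )
  structure(list(layers = layers, seed = seed, trained = FALSE),
            class = "vf_glyph_cnn")
}

#' Train the glyph classifier on rendered plates
#'
#' Renders `n_plates` plates from uniformly random category maps, passes
#' each through the capture simulation and the cross localizer, extracts
#' the 72 cell patches with the *estimated* homography (so training sees
#' the same localization jitter as deployment), and trains the six-class
#' CNN with Adam under cross-entropy.
#'
#' @param n_plates number of training plates (72 patches each).
#' @param params a [capture_params()] for the training augmentation.
#' @param clean_every every `clean_every`-th plate is left unaugmented so
#'   the classifier also sees sharp, unblurred glyphs (captures drawn
#'   uniformly within the ranges are rarely near-clean).
#' @param style a [plate_style()].
#' @param layout a `vf_layout`.
#' @param epochs,batch,lr optimizer settings.
#' @param seed integer seed for map sampling, augmentation and training.
#' @return A trained `vf_glyph_cnn`.
#' @export
train_glyph_model <- function(n_plates = 40, params = capture_params(),
                              style = plate_style(), layout = vf_layout(),
                              epochs = 12, batch = 64, lr = 1e-3,
                              clean_every = 4, seed = 1L) {
  model <- build_glyph_model(seed)
  set.seed(seed)
  xs <- list(); ys <- list()
  for (p in seq_len(n_plates)) {
    pd_cat <- sample(0:4, length(layout$active), replace = TRUE)
    plate <- render_plate(pd_cat, layout, style)
    if (p %% clean_every != 0) plate <- augment_capture(plate, params)
    loc <- tryCatch(locate_cross(plate$pixels, style),
                    vf_detection_error = function(e) NULL)
    if (is.null(loc)) next
    pp <- extract_patches(plate$pixels, loc$h, style)
    xs[[length(xs) + 1L]] <- pp$x
    ys[[length(ys) + 1L]] <- match(plate$truth[cbind(pp$cells$row,
                                                     pp$cells$col)],
                                   plate_classes())
  }
  n <- sum(vapply(xs, function(a) dim(a)[1], numeric(1)))
  x <- array(0, c(n, 32, 32, 1))
  at <- 0
  for (i in seq_along(xs)) {
    k <- dim(xs[[i]])[1]
    x[(at + 1):(at + k), , , ] <- xs[[i]]
    at <- at + k
  }
  y <- unlist(ys)
  st <- adam_state_new()
  t <- 0
  for (ep in seq_len(epochs)) {
    res <- nn_epoch(model, st, x, y, batch, lr, weight_decay = 1e-4,
                    class_weights = NULL, t0 = t)
    model <- res$model
    t <- res$t
  }
  model$trained <- TRUE
  model
}

#' Recognize the cell patterns of a captured plate
#'
#' Rectifies each of the 72 grid-cell patches through the supplied
#' homography and classifies it into the six pattern classes; assembles
#' the per-cell category map and, when ground truth is available,
#' per-class and overall accuracies.
#'
#' @param image grayscale matrix.
#' @param hmat canonical-to-image homography from [locate_cross()].
#' @param model a trained `vf_glyph_cnn`.
#' @param style a [plate_style()].
#' @param truth optional 8 x 9 character truth matrix (as in
#'   `vf_plate$truth`).
#' @return An object of class `vf_recognition`: `categories` (8 x 9
#'   character), `confidences` (72 x 6, rows sum to 1, cells in
#'   column-major grid order), and when truth is given `overall_accuracy`
#'   and `per_class_accuracy` (named over [plate_classes()]).
#' @export
classify_cells <- function(image, hmat, model, style = plate_style(),
                           truth = NULL) {
  stopifnot(inherits(model, "vf_glyph_cnn"))
  if (!model$trained) stop("glyph model is untrained", call. = FALSE)
  pp <- extract_patches(image, hmat, style)
  conf <- nn_predict(model, pp$x)
  pred <- plate_classes()[max.col(conf)]
  categories <- matrix(NA_character_, 8, 9)
  categories[cbind(pp$cells$row, pp$cells$col)] <- pred
  out <- list(categories = categories, confidences = conf,
              cells = pp$cells)
  if (!is.null(truth)) {
    tr <- truth[cbind(pp$cells$row, pp$cells$col)]
    out$overall_accuracy <- mean(pred == tr)
    out$per_class_accuracy <- vapply(plate_classes(), function(cl) {
      if (!any(tr == cl)) return(NA_real_)
      mean(pred[tr == cl] == cl)
    }, numeric(1))
  }
  structure(out, class = "vf_recognition")
}

#' Diagnose glaucoma from a captured plate image
#'
#' The deployment path: locate the cross and plate geometry, recognize
#' the 72 cell patterns, reconstruct the pattern-deviation probability
#' map (an active cell recognized as blank counts as ">5%"), score it
#' with the PDP map classifier at its fixed operating threshold, and
#' attach the Grad-CAM heat overlay. Detection or classification
#' failures propagate as structured conditions naming the failing stage;
#' no score is emitted on failure.
#'
#' @param image grayscale matrix.
#' @param glyph_model a trained `vf_glyph_cnn`.
#' @param vf_model a trained `vf_cnn` with `map_kind = "PDP"`.
#' @param style a [plate_style()].
#' @param layout a `vf_layout`.
#' @return List with `score`, `label` (`"glaucoma"`/`"non_glaucoma"`),
#'   `threshold`, `pd_cat` (codes per active location), `categories`
#'   (8 x 9) and `heatmap` (8 x 9 Grad-CAM weights).
#' @export
diagnose_from_image <- function(image, glyph_model, vf_model,
                                style = plate_style(),
                                layout = vf_layout()) {
  stopifnot(inherits(vf_model, "vf_cnn"))
  if (vf_model$map_kind != "PDP") {
    stop("image diagnosis uses the PDP map classifier", call. = FALSE)
  }
  loc <- locate_cross(image, style)  # vf_detection_error propagates
  rec <- classify_cells(image, loc$h, glyph_model, style)
  a <- layout$locations[layout$active, ]
  lab <- rec$categories[cbind(a$row, a$col)]
  code <- match(lab, plate_classes()) - 2L
  code[code < 0L] <- 0L  # blank at an active cell counts as ">5%"
  emb_pdp <- vf_embed(layout, code / 4, sentinel = 0)
  x <- array(0, c(1, 8, 9, 4))
  x[1, , , 3] <- emb_pdp$grid
  x[1, , , 4] <- emb_pdp$mask
  xs <- standardize_input(x, vf_model$channels, vf_model$norms)
  score <- nn_predict(vf_model, xs)[1, 2]
  heat <- gradcam_from_input(vf_model, xs)
  list(score = score,
       label = if (score >= vf_model$operating_threshold) "glaucoma"
               else "non_glaucoma",
       threshold = vf_model$operating_threshold,
       pd_cat = code, categories = rec$categories, heatmap = heat)
}

#' Write / read a plate image as PNG
#'
#' @param image grayscale matrix in `[0, 1]`.
#' @param path file path.
#' @return `path` (write) or the image matrix (read).
#' @export
write_plate_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_plate_png
#' @export
read_plate_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
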