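#' The Humphrey 24-2 test-point lattice
#'
#' Builds the 24-2 static perimetry lattice for one eye. Locations sit at odd
#' multiples of 3 degrees on a 6-degree grid: rows at |y| = 21 hold x in
#' {-9,-3,3,9}; |y| = 15 adds x = +/-15; |y| = 9 adds x = +/-21; the rows at
#' |y| = 3 additionally carry the nasal point at x = -27. That gives 54
#' nominal locations per eye, of which the pair at (x = +15, y = +/-3)
#' overlies the physiologic blind spot and is excluded from the active set,
#' leaving 52 active locations. All processing uses a canonical right-eye
#' frame (temporal = +x, superior = +y); a left-eye layout is the x-mirror
#' of the right-eye layout.
#'
#' A location is an *edge* location if it lies on the outer perimeter of the
#' pattern: the entire |y| = 21 rows, the x-extreme points of every other
#' row, and the nasal x = -27 points.
#'
#' @param eye `"right"` or `"left"`.
#' @return An object of class `vf_layout`: a list with
#'   \describe{
#'     \item{eye}{laterality}
#'     \item{locations}{data frame of the 54 nominal locations with columns
#'       `x`, `y` (degrees), `blind_spot`, `edge` (logical), `row`, `col`
#'       (indices into the 8 x 9 grid embedding)}
#'     \item{active}{integer indices (rows of `locations`) of the 52
#'       non-blind-spot locations, in row-major order}
#'     \item{embedding_shape}{`c(8L, 9L)`}
#'   }
#' @examples
#' lay <- vf_layout("right")
#' length(lay$active)  # 52
#' @export
vf_layout <- function(eye = c("right", "left")) {
  eye <- match.arg(eye)
  rows <- list(
    `21` = c(-9, -3, 3, 9),
    `15` = c(-15, -9, -3, 3, 9, 15),
    `9`  = c(-21, -15, -9, -3, 3, 9, 15, 21),
    `3`  = c(-27, -21, -15, -9, -3, 3, 9, 15, 21)
  )
  xs <- ys <- numeric(0)
  for (ay in c(21, 15, 9, 3, -3, -9, -15, -21)) {
    rx <- rows[[as.character(abs(ay))]]
    xs <- c(xs, rx)
    ys <- c(ys, rep(ay, length(rx)))
  }
  loc <- data.frame(x = xs, y = ys)
  if (eye == "left") loc$x <- -loc$x
  # canonical frame is right-eye; geometry columns below are frame-invariant
  # because they are computed from the canonical (right-eye) coordinates
  xc <- if (eye == "left") -loc$x else loc$x
  loc$blind_spot <- xc == 15 & abs(loc$y) == 3
  per_row_ext <- ave(xc, loc$y, FUN = function(v) v == max(v) | v == min(v))
  loc$edge <- abs(loc$y) == 21 | per_row_ext > 0 | xc == -27
  loc$row <- as.integer((21 - loc$y) / 6 + 1)
  loc$col <- as.integer((xc + 27) / 6 + 1)
  structure(
    list(
      eye = eye,
      locations = loc,
      active = which(!loc$blind_spot),
      embedding_shape = c(8L, 9L)
    ),
    class = "vf_layout"
  )
}

#' @export
print.vf_layout <- function(x, ...) {
  cat(sprintf(
    "24-2 layout (%s eye): %d nominal, %d active, %d blind-spot, %d edge\n",
    x$eye, nrow(x$locations), length(x$active),
    sum(x$locations$blind_spot), sum(x$locations$edge)
  ))
  invisible(x)
}

#' Mirror a layout between eyes
#'
#' @param layout a `vf_layout`.
#' @return The layout of the fellow eye (x-negated coordinates). Applying
#'   the mirror twice returns the original layout.
#' @export
vf_mirror <- function(layout) {
  stopifnot(inherits(layout, "vf_layout"))
  vf_layout(if (layout$eye == "right") "left" else "right")
}

#' Lattice neighbours of an active location
#'
#' Contiguity on the 24-2 lattice is 8-connectivity: two active locations are
#' neighbours when |dx| <= 6 and |dy| <= 6 degrees and they are distinct.
#' Blind-spot locations are never returned. With `connectivity = 4` diagonal
#' steps (|dx| = |dy| = 6) are excluded.
#'
#' @param layout a `vf_layout`.
#' @param i nominal location index (row of `layout$locations`); must be
#'   active.
#' @param connectivity 8 (default) or 4.
#' @return Integer vector of active location indices.
#' @export
vf_neighbors <- function(layout, i, connectivity = 8) {
  stopifnot(inherits(layout, "vf_layout"))
  if (length(i) != 1L || !(i %in% layout$active)) {
    stop("`i` must be a single active location index of the layout",
         call. = FALSE)
  }
  adj <- vf_adjacency(layout, connectivity)
  layout$active[adj[match(i, layout$active), ]]
}

#' Adjacency matrix over active locations
#'
#' @param layout a `vf_layout`.
#' @param connectivity 8 (default) or 4.
#' @return A symmetric, irreflexive logical matrix (52 x 52) in `active`
#'   order.
#' @export
vf_adjacency <- function(layout, connectivity = 8) {
  stopifnot(inherits(layout, "vf_layout"), connectivity %in% c(4, 8))
  a <- layout$locations[layout$active, ]
  dx <- abs(outer(a$x, a$x, "-"))
  dy <- abs(outer(a$y, a$y, "-"))
  adj <- dx <= 6 & dy <= 6 & (dx + dy) > 0
  if (connectivity == 4) adj <- adj & (dx == 0 | dy == 0)
  adj
}

#' Embed per-location values into the 8 x 9 grid
#'
#' Each active location occupies a unique cell of an 8-row by 9-column grid
#' (rows y = 21..-21, columns x = -27..21 in the canonical right-eye frame,
#' 6-degree pitch). Cells without an active location (off-pattern or blind
#' spot) carry the sentinel.
#'
#' @param layout a `vf_layout`.
#' @param values numeric vector, one value per active location in `active`
#'   order.
#' @param sentinel value placed in unoccupied cells (default `NA_real_`).
#' @return A list with `grid` (8 x 9 matrix) and `mask` (8 x 9 logical,
#'   `TRUE` at the 52 active cells).
#' @export
vf_embed <- function(layout, values, sentinel = NA_real_) {
  stopifnot(inherits(layout, "vf_layout"))
  if (length(values) != length(layout$active)) {
    stop(sprintf("expected %d values (one per active location), got %d",
                 length(layout$active), length(values)), call. = FALSE)
  }
  g <- matrix(sentinel, 8, 9)
  m <- matrix(FALSE, 8, 9)
  a <- layout$locations[layout$active, ]
  g[cbind(a$row, a$col)] <- values
  m[cbind(a$row, a$col)] <- TRUE
  list(grid = g, mask = m)
}

#' Extract per-location values from an embedded grid
#'
#' Inverse of [vf_embed()]: reads the 52 active cells back into a vector in
#' `active` order.
#'
#' @param layout a `vf_layout`.
#' @param grid 8 x 9 matrix.
#' @return Numeric vector of length 52.
#' @export
vf_extract <- function(layout, grid) {
  stopifnot(inherits(layout, "vf_layout"),
            is.matrix(grid), all(dim(grid) == c(8, 9)))
  a <- layout$locations[layout$active, ]
  grid[cbind(a$row, a$col)]
}

#' Export a layout as JSON
#'
#' Writes the ordered nominal locations (x, y, flags, row, col) so that
#' downstream tools and tests share a single geometry source of truth.
#'
#' @param layout a `vf_layout`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "vf_layout"))
  obj <- list(
    eye = layout$eye,
    embedding_shape = layout$embedding_shape,
    locations = layout$locations
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
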