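#' Build a synthetic bathymetry grid with a known shelf break
#'
#' Constructs a regular planar grid of seafloor depth (metres, positive down)
#' whose 1,500 m contour — the conventional shelf-break isobath — sits at a
#' known, queryable location. The default field is linear in both axes
#' (`depth = offset + gy * y + gx * x`), so bilinear interpolation on the grid
#' reproduces the field exactly; this makes the shelf/oceanic split easy to
#' reason about in tests while still exercising the full interpolation path.
#'
#' @param spec A list with elements `xlim`, `ylim` (extents in metres), `nx`,
#'   `ny` (grid resolution), `offset`, `gx`, `gy` (linear depth field
#'   coefficients, metres and metres per metre). Any element omitted takes the
#'   default of [bathymetry_spec()].
#' @return An object of class `bathy_grid`: a list with `x`, `y` axis vectors
#'   (strictly increasing) and a depth matrix `z` (`length(x)` rows by
#'   `length(y)` columns, metres positive down).
#' @examples
#' b <- make_bathymetry()
#' bathy_depth(b, x = 1e5, y = 1e5)
#' @export
make_bathymetry <- function(spec = bathymetry_spec()) {
  spec <- utils::modifyList(bathymetry_spec(), spec)
  x <- seq(spec$xlim[1], spec$xlim[2], length.out = spec$nx)
  y <- seq(spec$ylim[1], spec$ylim[2], length.out = spec$ny)
  if (any(diff(x) <= 0) || any(diff(y) <= 0)) {
    abort("bathymetry axes must be strictly increasing")
  }
  z <- outer(x, y, function(xx, yy) spec$offset + spec$gx * xx + spec$gy * yy)
  structure(list(x = x, y = y, z = z, spec = spec), class = "bathy_grid")
}

#' Default bathymetry specification
#'
#' The default world is a 2,000 x 2,000 km planar box. Depth rises linearly
#' from 100 m at the southern edge to ~3,900 m at the northern edge, with a
#' slight west-east gradient; the 1,500 m isobath is a near-horizontal line at
#' `y` around 730 km.
#'
#' @return A list understood by [make_bathymetry()].
#' @export
bathymetry_spec <- function() {
  list(
    xlim = c(0, 2e6), ylim = c(0, 2e6),
    nx = 81L, ny = 81L,
    offset = 100, gx = 5e-5, gy = 1.9e-3
  )
}

#' Query seafloor depth by bilinear interpolation
#'
#' @param bathy A `bathy_grid` from [make_bathymetry()] or [read_bathymetry()].
#' @param x,y Planar coordinates (metres), recycled to common length.
#' @return Depth in metres (positive down); `NA` outside the grid extent.
#' @export
bathy_depth <- function(bathy, x, y) {
  stopifnot(inherits(bathy, "bathy_grid"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  gx <- bathy$x; gy <- bathy$y
  out <- rep(NA_real_, n)
  inside <- !is.na(x) & !is.na(y) &
    x >= gx[1] & x <= gx[length(gx)] & y >= gy[1] & y <= gy[length(gy)]
  if (!any(inside)) return(out)
  xi <- x[inside]; yi <- y[inside]
  ix <- pmin(findInterval(xi, gx), length(gx) - 1L)
  iy <- pmin(findInterval(yi, gy), length(gy) - 1L)
  tx <- (xi - gx[ix]) / (gx[ix + 1L] - gx[ix])
  ty <- (yi - gy[iy]) / (gy[iy + 1L] - gy[iy])
  z <- bathy$z
  z11 <- z[cbind(ix, iy)];       z21 <- z[cbind(ix + 1L, iy)]
  z12 <- z[cbind(ix, iy + 1L)];  z22 <- z[cbind(ix + 1L, iy + 1L)]
  out[inside] <- (1 - tx) * (1 - ty) * z11 + tx * (1 - ty) * z21 +
    (1 - tx) * ty * z12 + tx * ty * z22
  out
}

#' Classify a position as shelf or oceanic habitat
#'
#' Waters shallower than the isobath (default 1,500 m, the conventional shelf
#' break) are `"shelf"`; waters at or deeper than it are `"oceanic"` (strict
#' "shallower" reading of the boundary).
#'
#' @inheritParams bathy_depth
#' @param isobath Habitat threshold depth in metres (default 1500).
#' @return Character vector in `{"shelf", "oceanic"}`, `NA` outside the grid.
#' @export
classify_habitat <- function(bathy, x, y, isobath = 1500) {
  d <- bathy_depth(bathy, x, y)
  ifelse(is.na(d), NA_character_, ifelse(d < isobath, "shelf", "oceanic"))
}

#' Write / read a bathymetry grid as a plain-text grid file
#'
#' A self-describing text format: a header of `key value` lines (`nx`, `ny`,
#' `x0`, `y0`, `dx`, `dy`) followed by the depth matrix, one grid row (fixed
#' `x`) per line, columns ordered by increasing `y`. Round-trips exactly at
#' full double precision.
#'
#' @param bathy A `bathy_grid`.
#' @param path File path.
#' @return `write_bathymetry()` returns `path` invisibly; `read_bathymetry()`
#'   returns a `bathy_grid`.
#' @export
write_bathymetry <- function(bathy, path) {
  stopifnot(inherits(bathy, "bathy_grid"))
  hdr <- c(
    sprintf("nx %d", length(bathy$x)),
    sprintf("ny %d", length(bathy$y)),
    sprintf("x0 %.17g", bathy$x[1]),
    sprintf("y0 %.17g", bathy$y[1]),
    sprintf("dx %.17g", diff(bathy$x[1:2])),
    sprintf("dy %.17g", diff(bathy$y[1:2]))
  )
  rows <- apply(bathy$z, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_bathymetry
#' @export
read_bathymetry <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], " ", fixed = TRUE)
  keys <- vapply(hdr, `[`, "", 1L)
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  nx <- as.integer(vals[["nx"]]); ny <- as.integer(vals[["ny"]])
  x <- vals[["x0"]] + vals[["dx"]] * (seq_len(nx) - 1L)
  y <- vals[["y0"]] + vals[["dy"]] * (seq_len(ny) - 1L)
  z <- t(vapply(strsplit(lines[-(1:6)], " ", fixed = TRUE),
                function(r) as.numeric(r), numeric(ny)))
  if (any(diff(x) <= 0) || any(diff(y) <= 0)) {
    abort("bathymetry axes must be strictly increasing")
  }
  structure(list(x = x, y = y, z = z), class = "bathy_grid")
}

#' @export
print.bathy_grid <- function(x, ...) {
  cat(sprintf("<bathy_grid> %d x %d cells, x [%g, %g] m, y [%g, %g] m, depth [%g, %g] m\n",
              length(x$x), length(x$y), min(x$x), max(x$x), min(x$y), max(x$y),
              min(x$z), max(x$z)))
  invisible(x)
}
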