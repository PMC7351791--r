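# Lightweight in-memory raster: numeric matrix + affine georeferencing.
# Row 1 is the TOP row; cell (1,1) centre sits at (xmin + cs/2, ymax - cs/2).
# Point-in-cell lookups are half-open: a cell owns [x0, x0 + cs) x (y0 - cs, y0].

#' Create a grid
#'
#' A `grd` is the package's raster currency: a numeric matrix with an origin
#' and a square cell size in metres. Row 1 is the northernmost row. Missing
#' cells are `NA` (nodata).
#'
#' @param values Numeric matrix of cell values (row 1 = top row).
#' @param cellsize Cell edge length in metres (> 0).
#' @param xmin,ymin Coordinates of the lower-left corner of the grid extent.
#' @return An object of class `grd`.
#' @examples
#' g <- grd(matrix(1:12, 3, 4), cellsize = 90)
#' grd_extent(g)
#' @export
grd <- function(values, cellsize, xmin = 0, ymin = 0) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have positive dimensions", call. = FALSE)
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("cellsize must be a single positive number", call. = FALSE)
  structure(list(values = values, cellsize = as.numeric(cellsize),
                 xmin = as.numeric(xmin), ymin = as.numeric(ymin)),
            class = "grd")
}

#' @export
print.grd <- function(x, ...) {
  v <- x$values
  cat(sprintf("grd: %d x %d cells, %g m resolution\n", nrow(v), ncol(v), x$cellsize))
  e <- grd_extent(x)
  cat(sprintf("extent: x [%g, %g], y [%g, %g]\n", e[1], e[2], e[3], e[4]))
  ok <- !is.na(v)
  if (any(ok))
    cat(sprintf("values: [%.4g, %.4g], %d nodata cells\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  else cat("values: all nodata\n")
  invisible(x)
}

#' Grid extent
#'
#' @param g A `grd`.
#' @return Numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @export
grd_extent <- function(g) {
  v <- g$values
  c(g$xmin, g$xmin + ncol(v) * g$cellsize,
    g$ymin, g$ymin + nrow(v) * g$cellsize)
}

grd_ymax <- function(g) g$ymin + nrow(g$values) * g$cellsize

# centre coordinates of cell (row, col); row counted from the top
cell_xy <- function(g, row, col) {
  cbind(x = g$xmin + (col - 0.5) * g$cellsize,
        y = grd_ymax(g) - (row - 0.5) * g$cellsize)
}

# cell indices containing points (half-open cells); NA outside the extent
xy_cell <- function(g, x, y) {
  cs <- g$cellsize
  col <- floor((x - g$xmin) / cs) + 1L
  row <- floor((grd_ymax(g) - y) / cs) + 1L
  # points exactly on the top/left boundary belong to the first row/col
  row[y == grd_ymax(g)] <- 1L
  bad <- col < 1L | col > ncol(g$values) | row < 1L | row > nrow(g$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = row, col = col)
}

same_spec <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cellsize - b$cellsize) < tol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol
}

stopifnot_aligned <- function(stack) {
  if (length(stack) > 1L)
    for (i in seq_along(stack)[-1L])
      if (!same_spec(stack[[1L]], stack[[i]]))
        stop("grids are not aligned to a common spec", call. = FALSE)
  invisible(TRUE)
}

# 'same'-size linear convolution via FFT with zero padding; kernel dims odd
conv2_fft <- function(a, k) {
  da <- dim(a); dk <- dim(k)
  n1 <- da[1L] + dk[1L] - 1L; n2 <- da[2L] + dk[2L] - 1L
  A <- matrix(0, n1, n2); A[seq_len(da[1L]), seq_len(da[2L])] <- a
  K <- matrix(0, n1, n2); K[seq_len(dk[1L]), seq_len(dk[2L])] <- k
  out <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (n1 * n2)
  r0 <- (dk[1L] - 1L) %/% 2L; c0 <- (dk[2L] - 1L) %/% 2L
  out[r0 + seq_len(da[1L]), c0 + seq_len(da[2L]), drop = FALSE]
}

# circular window mask: offsets whose centre lies within `radius` of the focal centre
circular_kernel <- function(radius, cellsize) {
  m <- max(0L, floor(radius / cellsize))
  d <- outer((-m:m)^2, (-m:m)^2, "+") * cellsize^2
  (d <= radius^2 + 1e-9) * 1
}

#' Circular focal mean
#'
#' Per-cell mean of values within a circular neighbourhood ("scale"). The
#' window contains every cell whose centre lies within `radius` of the focal
#' cell centre; at grid edges only the available cells are averaged, and
#' nodata cells are excluded. A window with no valid cell yields nodata.
#'
#' @param g A `grd`.
#' @param radius Neighbourhood radius in metres. A radius smaller than half a
#'   cell returns the grid unchanged.
#' @return A `grd` on the same spec.
#' @examples
#' g <- grd(matrix(0, 5, 5), 90); g$values[3, 3] <- 1
#' focal_mean(g, 90)$values[3, 3]  # 5-cell plus-shaped window -> 0.2
#' @export
focal_mean <- function(g, radius) {
  if (!inherits(g, "grd")) stop("g must be a grd", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop("radius must be a single non-negative number", call. = FALSE)
  k <- circular_kernel(radius, g$cellsize)
  if (length(k) == 1L) return(g)
  v <- g$values
  ok <- !is.na(v)
  v0 <- v; v0[!ok] <- 0
  s <- conv2_fft(v0, k)
  n <- round(conv2_fft(ok * 1, k))   # counts are integers; kill FFT fuzz
  out <- s / n
  out[n == 0] <- NA_real_
  grd(out, g$cellsize, g$xmin, g$ymin)
}

#' Resample a grid onto a target spec
#'
#' Bilinear interpolation for continuous layers, nearest-neighbour for
#' categorical ones. Target cell centres outside the source extent are an
#' error; centres beyond the outermost source cell centres are clamped to the
#' edge value.
#'
#' @param g Source `grd`.
#' @param target A `grd` (its values are ignored) or a list with elements
#'   `nrow`, `ncol`, `cellsize`, `xmin`, `ymin` defining the output spec.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return A `grd` on the target spec.
#' @export
align_grid <- function(g, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (inherits(target, "grd")) {
    spec <- list(nrow = nrow(target$values), ncol = ncol(target$values),
                 cellsize = target$cellsize, xmin = target$xmin, ymin = target$ymin)
  } else spec <- target
  if (same_spec(g, grd(matrix(0, spec$nrow, spec$ncol), spec$cellsize,
                       spec$xmin, spec$ymin)))
    return(grd(g$values, g$cellsize, g$xmin, g$ymin))
  eg <- grd_extent(g)
  ex <- c(spec$xmin, spec$xmin + spec$ncol * spec$cellsize,
          spec$ymin, spec$ymin + spec$nrow * spec$cellsize)
  if (ex[1] >= eg[2] || ex[2] <= eg[1] || ex[3] >= eg[4] || ex[4] <= eg[3])
    stop("source and target extents are disjoint", call. = FALSE)
  cs <- spec$cellsize
  xc <- spec$xmin + (seq_len(spec$ncol) - 0.5) * cs
  yc <- (spec$ymin + spec$nrow * cs) - (seq_len(spec$nrow) - 0.5) * cs
  # fractional source indices of target centres
  fc <- (xc - g$xmin) / g$cellsize + 0.5
  fr <- (grd_ymax(g) - yc) / g$cellsize + 0.5
  nr <- nrow(g$values); nc <- ncol(g$values)
  out <- matrix(NA_real_, spec$nrow, spec$ncol)
  if (method == "nearest") {
    ri <- pmin(pmax(round(fr), 1L), nr)
    ci <- pmin(pmax(round(fc), 1L), nc)
    out[] <- g$values[cbind(rep(ri, times = spec$ncol),
                            rep(ci, each = spec$nrow))]
  } else {
    fr <- pmin(pmax(fr, 1), nr); fc <- pmin(pmax(fc, 1), nc)  # edge clamp
    r0 <- pmin(floor(fr), nr - 1L); c0 <- pmin(floor(fc), nc - 1L)
    if (nr == 1L) r0 <- rep(1L, length(fr))
    if (nc == 1L) c0 <- rep(1L, length(fc))
    wr <- fr - r0; wc <- fc - c0
    for (j in seq_len(spec$ncol)) {
      v00 <- g$values[cbind(r0, rep(c0[j], spec$nrow))]
      v10 <- g$values[cbind(pmin(r0 + 1L, nr), rep(c0[j], spec$nrow))]
      v01 <- g$values[cbind(r0, rep(pmin(c0[j] + 1L, nc), spec$nrow))]
      v11 <- g$values[cbind(pmin(r0 + 1L, nr), rep(pmin(c0[j] + 1L, nc), spec$nrow))]
      w00 <- (1 - wr) * (1 - wc[j]); w10 <- wr * (1 - wc[j])
      w01 <- (1 - wr) * wc[j];       w11 <- wr * wc[j]
      vals <- cbind(v00, v10, v01, v11)
      w <- cbind(w00, w10, w01, w11)
      w[is.na(vals)] <- 0
      tot <- rowSums(w)
      num <- rowSums(vals * w, na.rm = TRUE)
      out[, j] <- ifelse(tot > 0, num / tot, NA_real_)
    }
  }
  grd(out, cs, spec$xmin, spec$ymin)
}

#' Line density
#'
#' Total polyline length within a circular neighbourhood of each cell centre,
#' divided by the neighbourhood area (m per square metre). Segment-circle
#' intersection lengths are computed exactly.
#'
#' @param lines A list of polylines, each a two-column matrix of x/y vertices
#'   in projected metres (as returned by [read_geojson_lines()]), or an empty
#'   list.
#' @param radius Neighbourhood radius in metres.
#' @param template A `grd` supplying the output spec.
#' @return A `grd` of densities; the attribute `"units"` notes that values in
#'   km per square km are `1000 *` the stored m/m^2 values.
#' @export
line_density <- function(lines, radius, template) {
  if (!inherits(template, "grd")) stop("template must be a grd", call. = FALSE)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  nr <- nrow(template$values); nc <- ncol(template$values)
  out <- matrix(0, nr, nc)
  segs <- list()
  for (ln in lines) {
    ln <- as.matrix(ln)
    if (nrow(ln) >= 2L)
      for (i in seq_len(nrow(ln) - 1L))
        segs[[length(segs) + 1L]] <- c(ln[i, 1:2], ln[i + 1L, 1:2])
  }
  if (length(segs)) {
    cs <- template$cellsize
    ymax <- grd_ymax(template)
    xc <- template$xmin + (seq_len(nc) - 0.5) * cs
    yc <- ymax - (seq_len(nr) - 0.5) * cs
    for (s in segs) {
      x0 <- s[1]; y0 <- s[2]; x1 <- s[3]; y1 <- s[4]
      dx <- x1 - x0; dy <- y1 - y0
      a <- dx * dx + dy * dy
      if (a == 0) next
      cols <- which(xc >= min(x0, x1) - radius & xc <= max(x0, x1) + radius)
      rows <- which(yc >= min(y0, y1) - radius & yc <= max(y0, y1) + radius)
      for (j in cols) for (i in rows) {
        px <- x0 - xc[j]; py <- y0 - yc[i]
        b <- 2 * (px * dx + py * dy)
        cc <- px * px + py * py - radius * radius
        disc <- b * b - 4 * a * cc
        if (disc <= 0) next
        sq <- sqrt(disc)
        t0 <- max(0, (-b - sq) / (2 * a))
        t1 <- min(1, (-b + sq) / (2 * a))
        if (t1 > t0) out[i, j] <- out[i, j] + (t1 - t0) * sqrt(a)
      }
    }
    out <- out / (pi * radius^2)
  }
  g <- grd(out, template$cellsize, template$xmin, template$ymin)
  attr(g, "units") <- "m/m2 (multiply by 1000 for km/km2)"
  g
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows from north to south).
#'
#' @param path File path.
#' @param g A `grd` (for writing).
#' @param nodata Value written for `NA` cells.
#' @return `read_asc` returns a `grd`; `write_asc` returns `path` invisibly.
#' @export
read_asc <- function(path) {
  head <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(head), "\\s+"))
  keys <- tolower(kv[, 1L]); vals <- as.numeric(kv[, 2L])
  names(vals) <- keys
  n_head <- if ("nodata_value" %in% keys) 6L else 5L
  v <- scan(path, skip = n_head, quiet = TRUE)
  m <- matrix(v, nrow = vals[["nrows"]], ncol = vals[["ncols"]], byrow = TRUE)
  if ("nodata_value" %in% keys) m[m == vals[["nodata_value"]]] <- NA_real_
  grd(m, vals[["cellsize"]], vals[["xllcorner"]], vals[["yllcorner"]])
}

#' @rdname read_asc
#' @export
write_asc <- function(g, path, nodata = -9999) {
  v <- g$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
               sprintf("xllcorner %.10g", g$xmin), sprintf("yllcorner %.10g", g$ymin),
               sprintf("cellsize %.10g", g$cellsize),
               sprintf("NODATA_value %g", nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read polylines from a GeoJSON file
#'
#' Supports `LineString` and `MultiLineString` geometries (bare, in a
#' `GeometryCollection`, as a `Feature` or in a `FeatureCollection`).
#' Coordinates are taken as projected metres.
#'
#' @param path GeoJSON file path.
#' @return A list of two-column coordinate matrices, one per line string.
#' @export
read_geojson_lines <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  grab <- function(geom) {
    if (is.null(geom$type)) return()
    if (geom$type == "LineString") {
      out[[length(out) + 1L]] <<- do.call(rbind, lapply(geom$coordinates,
                                                        function(p) as.numeric(p[1:2])))
    } else if (geom$type == "MultiLineString") {
      for (part in geom$coordinates)
        out[[length(out) + 1L]] <<- do.call(rbind, lapply(part,
                                                          function(p) as.numeric(p[1:2])))
    } else if (geom$type == "GeometryCollection") {
      for (sub in geom$geometries) grab(sub)
    }
  }
  if (!is.null(j$type) && j$type == "FeatureCollection") {
    for (f in j$features) grab(f$geometry)
  } else if (!is.null(j$type) && j$type == "Feature") {
    grab(j$geometry)
  } else grab(j)
  out
}
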