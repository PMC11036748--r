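#' Landscape grid of habitat classes with a distance-to-cover surface
#'
#' A `landscape_grid` holds a rectangular raster of habitat classes on a
#' local projected grid (metres) together with the derived distance from
#' every cell centre to the nearest cover (forest/shrubland) cell centre.
#' The study landscape is cropland -- the densest forage source -- with
#' embedded patches of forest and shrubland used as cover, and the model
#' covariate is the distance to that cover at the end of each movement
#' step.
#'
#' Matrices are indexed `[row, col]` with row 1 the southernmost row; the
#' centre of cell `[i, j]` is at
#' `origin + cell_size * (j - 0.5, i - 0.5)`.
#'
#' @param habitat integer matrix, 1 = cover (forest/shrubland),
#'   0 = cropland.
#' @param cell_size cell edge length in metres.
#' @param origin numeric length-2, (x, y) of the lower-left corner of the
#'   grid in metres.
#' @return An object of class `landscape_grid`: a list with elements
#'   `habitat`, `dist_cover` (metres, 0 exactly on cover cells),
#'   `cell_size`, `origin`.
#' @examples
#' hab <- matrix(0L, 5, 5); hab[3, 3] <- 1L
#' ls <- landscape_grid(hab, cell_size = 100)
#' ls$dist_cover[1, 1] # sqrt(8) * 100
#' @export
landscape_grid <- function(habitat, cell_size, origin = c(0, 0)) {
  if (cell_size <= 0) stopf("cell_size must be positive")
  habitat <- matrix(as.integer(habitat), nrow(habitat), ncol(habitat))
  if (!all(habitat %in% c(0L, 1L))) stopf("habitat codes must be 0 (cropland) or 1 (cover)")
  structure(
    list(habitat = habitat,
         dist_cover = dist_to_cover(habitat, cell_size),
         cell_size = cell_size,
         origin = as.numeric(origin)),
    class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("landscape_grid: %d x %d cells, %.0f m resolution, %.1f%% cover\n",
              nrow(x$habitat), ncol(x$habitat), x$cell_size,
              100 * mean(x$habitat == 1L)))
  invisible(x)
}

# 1-D squared-distance transform (lower envelope of parabolas); indices in
# cell units, `f` the per-cell squared distance from the previous pass
dt1d_sq <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * (q - v[k]))
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * (q - v[k]))
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Exact Euclidean distance transform to cover cells
#'
#' Computes, for every cell, the distance (metres) from its centre to the
#' nearest cover-cell centre, by the separable exact squared-distance
#' transform (two passes of a 1-D lower-envelope transform). Distances are
#' exactly 0 on cover cells.
#'
#' @inheritParams landscape_grid
#' @return numeric matrix of distances in metres, same shape as `habitat`.
#' @export
dist_to_cover <- function(habitat, cell_size) {
  if (!any(habitat == 1L)) stopf("landscape has no cover cells; distance to cover is undefined")
  nr <- nrow(habitat); nc <- ncol(habitat)
  big <- (nr * nr + nc * nc) * 4 # finite stand-in for +Inf
  f <- ifelse(habitat == 1L, 0, big)
  g <- apply(f, 2, dt1d_sq)                  # along rows (y) within columns
  d2 <- t(apply(g, 1, dt1d_sq))              # along columns (x) within rows
  sqrt(d2) * cell_size
}

#' Interpolate the distance-to-cover surface at point coordinates
#'
#' Bilinear interpolation of `dist_cover` at arbitrary projected
#' coordinates. Points outside the grid extent return `NA`. Within the
#' half-cell margin along the border, values are clamped to the edge cells.
#'
#' @param landscape a [landscape_grid()].
#' @param x,y numeric vectors of point coordinates in metres.
#' @return numeric vector of distances in metres (`NA` off-grid).
#' @export
lookup_dist_cover <- function(landscape, x, y) {
  bilinear_lookup(landscape$dist_cover, landscape$cell_size, landscape$origin, x, y)
}

bilinear_lookup <- function(mat, cell, origin, x, y) {
  nr <- nrow(mat); nc <- ncol(mat)
  cx <- (x - origin[1]) / cell + 0.5   # fractional column index
  cy <- (y - origin[2]) / cell + 0.5   # fractional row index
  inside <- cx >= 0.5 & cx <= nc + 0.5 & cy >= 0.5 & cy <= nr + 0.5 &
    is.finite(cx) & is.finite(cy)
  cx <- pmin(pmax(cx, 1), nc); cy <- pmin(pmax(cy, 1), nr)
  j0 <- pmin(pmax(floor(cx), 1), max(nc - 1L, 1L))
  i0 <- pmin(pmax(floor(cy), 1), max(nr - 1L, 1L))
  wx <- pmin(pmax(cx - j0, 0), 1); wy <- pmin(pmax(cy - i0, 0), 1)
  i1 <- pmin(i0 + 1L, nr); j1 <- pmin(j0 + 1L, nc)
  v <- (1 - wy) * ((1 - wx) * mat[cbind(i0, j0)] + wx * mat[cbind(i0, j1)]) +
    wy * ((1 - wx) * mat[cbind(i1, j0)] + wx * mat[cbind(i1, j1)])
  v[!inside] <- NA_real_
  unname(v)
}

# TRUE for points inside the grid extent
inside_landscape <- function(landscape, x, y) {
  ox <- landscape$origin[1]; oy <- landscape$origin[2]
  w <- ncol(landscape$habitat) * landscape$cell_size
  h <- nrow(landscape$habitat) * landscape$cell_size
  x >= ox & x <= ox + w & y >= oy & y <= oy + h
}

#' Write or read a habitat grid as an ESRI ASCII raster
#'
#' Plain-text raster exchange for the habitat-class grid. `write_ascii_grid`
#' stores any numeric matrix with the package's south-up row convention
#' (rows in the file run north to south, as the format requires);
#' `read_ascii_grid` inverts it.
#'
#' @param mat numeric matrix (row 1 = southernmost row).
#' @param file path to the `.asc` file.
#' @param cell_size,origin grid geometry, as in [landscape_grid()].
#' @return `read_ascii_grid()` returns a list with `mat`, `cell_size`,
#'   `origin`.
#' @export
write_ascii_grid <- function(mat, file, cell_size, origin = c(0, 0)) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(mat)),
    sprintf("nrows %d", nrow(mat)),
    sprintf("xllcorner %.6f", origin[1]),
    sprintf("yllcorner %.6f", origin[2]),
    sprintf("cellsize %.6f", cell_size),
    "NODATA_value -9999"), con)
  write.table(mat[nrow(mat):1, , drop = FALSE], con, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(file) {
  hdr <- readLines(file, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  val <- setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(read.table(file, skip = 6L))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == val["nrows"], ncol(m) == val["ncols"])
  list(mat = m[nrow(m):1, , drop = FALSE],
       cell_size = unname(val["cellsize"]),
       origin = unname(c(val["xllcorner"], val["yllcorner"])))
}

#' Generate a random cover-in-cropland landscape
#'
#' Builds a synthetic study landscape: a cropland matrix with `n_patches`
#' circular forest/shrubland (cover) patches at uniformly drawn centres,
#' then computes the distance-to-cover surface. This emulates an
#' agricultural mosaic where cover is patchy and cropland is the forage
#' source.
#'
#' @param config a [sim_config()]; its `landscape` element supplies `nx`,
#'   `ny`, `cell_size` (m), `n_patches`, and `patch_radius` (m).
#' @param seed integer seed.
#' @return a [landscape_grid()].
#' @export
make_landscape <- function(config, seed = config$seed) {
  lc <- config$landscape
  with_seed(seed, {
    cs <- lc$cell_size
    xc <- (seq_len(lc$nx) - 0.5) * cs
    yc <- (seq_len(lc$ny) - 0.5) * cs
    hab <- matrix(0L, lc$ny, lc$nx)
    px <- runif(lc$n_patches, 0, lc$nx * cs)
    py <- runif(lc$n_patches, 0, lc$ny * cs)
    for (p in seq_len(lc$n_patches)) {
      d2 <- outer(yc - py[p], xc - px[p], function(a, b) a^2 + b^2)
      hab[d2 <= lc$patch_radius^2] <- 1L
    }
    if (!any(hab == 1L)) stopf("generated landscape has no cover cells; increase patch_radius")
    landscape_grid(hab, cs)
  })
}
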