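#' Categorical land-cover raster
#'
#' A single-band categorical grid over the study area. Cells are square,
#' `cell` meters on a side; `grid` is an integer matrix indexed
#' `[column (x), row (y)]` with values indexing `classes`. The cell center
#' of `grid[i, j]` is at `(x0 + (i - 0.5) * cell, y0 + (j - 0.5) * cell)`.
#'
#' @param x0,y0 coordinates of the grid's lower-left corner (m).
#' @param cell cell size (m), > 0.
#' @param grid integer matrix of class indices (no NAs).
#' @param classes character vector of class names, e.g.
#'   `c("forest", "agricultural", "urban", "water", "other")`.
#' @return object of class `landcover`.
#' @export
landcover <- function(x0, y0, cell, grid, classes) {
  stopifnot(cell > 0, is.matrix(grid), !anyNA(grid),
            all(grid >= 1), all(grid <= length(classes)))
  structure(list(x0 = x0, y0 = y0, cell = cell,
                 grid = grid, classes = classes),
            class = "landcover")
}

#' @export
print.landcover <- function(x, ...) {
  tab <- table(factor(x$classes[x$grid], levels = x$classes))
  cat(sprintf("Land cover: %d x %d cells of %g m\n",
              nrow(x$grid), ncol(x$grid), x$cell))
  print(round(tab / sum(tab), 3))
  invisible(x)
}

# Class index at point coordinates; points outside the grid get NA.
landcover_class_at <- function(lc, px, py) {
  i <- floor((px - lc$x0) / lc$cell) + 1
  j <- floor((py - lc$y0) / lc$cell) + 1
  ok <- i >= 1 & i <= nrow(lc$grid) & j >= 1 & j <= ncol(lc$grid)
  out <- rep(NA_integer_, length(px))
  out[ok] <- lc$grid[cbind(i[ok], j[ok])]
  out
}

# --- ESRI ASCII grid IO -----------------------------------------------------
# Plain-text raster format used for both land cover (integer codes) and UD
# rasters. Rows in the file run north->south, so the matrix y index is
# flipped on read/write.

write_ascii_grid <- function(mat, x0, y0, cell, path, digits = 10) {
  nx <- nrow(mat); ny <- ncol(mat)
  hdr <- c(sprintf("ncols %d", nx), sprintf("nrows %d", ny),
           sprintf("xllcorner %.6f", x0), sprintf("yllcorner %.6f", y0),
           sprintf("cellsize %.6f", cell), "NODATA_value -9999")
  rows <- vapply(ny:1, function(j)
    paste(formatC(mat[, j], digits = digits, format = "g"), collapse = " "),
    character(1))
  writeLines(c(hdr, rows), path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
  mat <- do.call(rbind, vals)             # rows north->south
  mat <- t(mat[nrow(mat):1, , drop = FALSE])  # -> [x, y] with y increasing
  list(mat = mat, x0 = hdr$xllcorner, y0 = hdr$yllcorner,
       cell = hdr$cellsize)
}

#' Read/write a land-cover raster as an ESRI ASCII grid
#'
#' The grid stores integer class codes; the class legend is passed
#' separately (the format has no legend block).
#'
#' @param path file path.
#' @param classes class legend mapping code `k` to `classes[k]`.
#' @return a [landcover()].
#' @export
read_landcover <- function(path, classes = c("forest", "agricultural",
                                             "urban", "water", "other")) {
  g <- read_ascii_grid(path)
  landcover(g$x0, g$y0, g$cell, matrix(as.integer(g$mat), nrow(g$mat)), classes)
}

#' @rdname read_landcover
#' @param lc a [landcover()] to write.
#' @export
write_landcover <- function(lc, path) {
  write_ascii_grid(lc$grid, lc$x0, lc$y0, lc$cell, path, digits = 1)
}
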