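#' Electron-density grid
#'
#' A real-space map sampled on a crystallographic grid covering one unit
#' cell. Voxel `[i, j, k]` (1-based) sits at fractional coordinates
#' `((i-1)/nu, (j-1)/nv, (k-1)/nw)`; the grid is periodic.
#'
#' @param cell A [unit_cell()].
#' @param values 3-D numeric array of voxel values (dims `nu, nv, nw`,
#'   each at least 2).
#' @return Object of class `density_grid`.
#' @export
density_grid <- function(cell, values) {
  if (length(dim(values)) != 3 || any(dim(values) < 2))
    stop("density grid must be a 3-D array with at least 2 voxels per axis")
  structure(list(cell = cell, values = values), class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  st <- grid_stats(x)
  d <- dim(x$values)
  cat(sprintf("<density_grid> %d x %d x %d, mean %.4g, sigma %.4g\n",
              d[1], d[2], d[3], st$mu, st$sigma))
  invisible(x)
}

voxel_volume <- function(grid) grid$cell$volume / prod(dim(grid$values))

#' Map statistics
#'
#' Population mean and standard deviation over all voxels (the
#' normalization used to express peak heights in sigma units).
#'
#' @param grid A [density_grid()].
#' @return List with `mu`, `sigma` and logical `degenerate` (`TRUE` when
#'   sigma is zero, i.e. a constant map).
#' @export
grid_stats <- function(grid) {
  v <- as.numeric(grid$values)
  if (length(v) < 8) stop("grid too small for statistics (need >= 8 voxels)")
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  list(mu = mu, sigma = sigma, degenerate = sigma == 0)
}

#' Read a CCP4/MRC map
#'
#' Supports mode 2 (32-bit float) volumes. Axis order is normalized so
#' that the returned array is indexed along the crystal x, y, z axes
#' regardless of the file's column/row/section assignment.
#'
#' @param path File path.
#' @return A [density_grid()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  sz <- file.info(path)$size
  if (sz < 1024) stop("truncated map file (no header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  w1_10 <- readBin(con, "integer", 10, size = 4)
  cellp <- readBin(con, "numeric", 6, size = 4)
  w17_19 <- readBin(con, "integer", 3, size = 4)
  readBin(con, "numeric", 3, size = 4)          # amin, amax, amean
  w23_24 <- readBin(con, "integer", 2, size = 4)
  readBin(con, "integer", 28, size = 4)          # unused words 25-52
  map_tag <- rawToChar(readBin(con, "raw", 4))
  readBin(con, "integer", 1, size = 4)           # machine stamp
  readBin(con, "numeric", 1, size = 4)           # rms
  readBin(con, "integer", 1, size = 4)           # nlabl
  readBin(con, "raw", 1024 - 56 * 4)             # labels
  mode <- w1_10[4]
  if (mode != 2)
    stop("unsupported map mode ", mode, " (only mode 2, 32-bit float)")
  nc <- w1_10[1]; nr <- w1_10[2]; ns <- w1_10[3]
  nvox <- nc * nr * ns
  if (sz < 1024 + w23_24[2] + 4 * nvox)
    stop("truncated map file: expected ", nvox, " voxels in ", path)
  if (w23_24[2] > 0) readBin(con, "raw", w23_24[2])  # symmetry text block
  vals <- readBin(con, "numeric", nvox, size = 4)
  arr <- array(vals, dim = c(nc, nr, ns))
  axes <- w17_19                                  # crystal axis of col/row/sec
  if (any(sort(axes) != 1:3)) stop("invalid axis assignment in map header")
  perm <- match(1:3, axes)
  arr <- aperm(arr, perm)
  cell <- unit_cell(cellp[1], cellp[2], cellp[3], cellp[4], cellp[5], cellp[6])
  density_grid(cell, arr)
}

#' Write a CCP4/MRC map (mode 2)
#'
#' Values are written in float32 with columns along crystal x, rows
#' along y and sections along z.
#'
#' @param grid A [density_grid()].
#' @param path Output path.
#' @export
write_map <- function(grid, path) {
  d <- dim(grid$values)
  st <- grid_stats(grid)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4)
  writeBin(as.numeric(c(grid$cell$a, grid$cell$b, grid$cell$c,
                        grid$cell$alpha, grid$cell$beta, grid$cell$gamma)),
           con, size = 4)
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4)
  writeBin(as.numeric(c(min(grid$values), max(grid$values), st$mu)), con, size = 4)
  writeBin(as.integer(c(1L, 0L)), con, size = 4)     # ispg, nsymbt
  writeBin(integer(28), con, size = 4)                # words 25-52
  writeBin(charToRaw("MAP "), con)
  writeBin(as.integer(0x00004144), con, size = 4)     # little-endian stamp
  writeBin(as.numeric(st$sigma), con, size = 4)
  writeBin(0L, con, size = 4)                         # nlabl
  writeBin(raw(1024 - 56 * 4), con)
  writeBin(as.numeric(grid$values), con, size = 4)
  invisible(path)
}
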