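#' Tile set container
#'
#' A grid of 8-bit RGB tiles from one scanned section, with the grid layout,
#' overlap, physical pixel size and marker label a slide scanner reports.
#' Tiles are stored row-major (row 1 left to right, then row 2, ...).
#'
#' @param tiles list of `h x w x 3` numeric arrays with values in 0..255.
#' @param grid_layout integer `(rows, cols)`; `rows * cols` must equal
#'   `length(tiles)`.
#' @param overlap tile overlap in px.
#' @param pixel_size micrometres per pixel.
#' @param marker section label, e.g. `"CK7"`, `"NRF2"`, `"KEAP1"`.
#' @return object of class `tile_set`.
#' @export
tile_set <- function(tiles, grid_layout, overlap = 0L, pixel_size = 1,
                     marker = "unknown") {
  stopifnot(is.list(tiles), length(tiles) >= 1L,
            length(grid_layout) == 2L,
            prod(grid_layout) == length(tiles))
  d1 <- dim(tiles[[1]])
  for (t in tiles) {
    if (!identical(dim(t), d1))
      stop("all tiles must share dimensions", call. = FALSE)
    if (min(t) < 0 || max(t) > 255)
      stop("tiles must be 8-bit (values in 0..255)", call. = FALSE)
  }
  structure(list(tiles = tiles,
                 grid_layout = as.integer(grid_layout),
                 overlap = as.integer(overlap),
                 pixel_size = pixel_size, marker = marker,
                 tile_shape = d1[1:2]),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("Tile set [%s]: %d x %d grid of %d x %d px tiles, overlap %d px, %.3f um/px\n",
              x$marker, x$grid_layout[1], x$grid_layout[2],
              x$tile_shape[1], x$tile_shape[2], x$overlap, x$pixel_size))
  invisible(x)
}

#' Write a tile set as numbered TIFF files plus a plain-text layout sidecar
#'
#' Tiles go to `tile_001.tif`, `tile_002.tif`, ... (row-major) as 8-bit RGB;
#' the sidecar `layout.yml` records rows, cols, overlap, pixel size and marker
#' so the set can be re-read without guessing.
#'
#' @param tileset a `tile_set`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_tileset <- function(tileset, dir) {
  stopifnot(inherits(tileset, "tile_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(tileset$tiles)) {
    path <- file.path(dir, sprintf("tile_%03d.tif", i))
    tiff::writeTIFF(tileset$tiles[[i]] / 255, path, bits.per.sample = 8L)
  }
  yaml::write_yaml(list(rows = tileset$grid_layout[1],
                        cols = tileset$grid_layout[2],
                        overlap = tileset$overlap,
                        pixel_size = tileset$pixel_size,
                        marker = tileset$marker,
                        n_tiles = length(tileset$tiles)),
                   file.path(dir, "layout.yml"))
  invisible(dir)
}

#' Read a tile set written by [write_tileset()]
#' @param dir directory holding `tile_*.tif` and `layout.yml`.
#' @return a `tile_set`.
#' @export
read_tileset <- function(dir) {
  side <- file.path(dir, "layout.yml")
  if (!file.exists(side)) stop("missing layout.yml sidecar", call. = FALSE)
  meta <- yaml::read_yaml(side)
  files <- file.path(dir, sprintf("tile_%03d.tif", seq_len(meta$n_tiles)))
  missing <- !file.exists(files)
  if (any(missing))
    stop(sprintf("missing tiles at positions: %s",
                 paste(which(missing), collapse = ", ")), call. = FALSE)
  tiles <- lapply(files, function(f) round(tiff::readTIFF(f) * 255))
  tile_set(tiles, c(meta$rows, meta$cols), meta$overlap,
           meta$pixel_size, meta$marker)
}
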