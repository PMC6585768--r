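#' Channel grid geometry
#'
#' The striatal functional units ("channels") of one hemisphere are arranged
#' on an edge-wrapped (toroidal) grid. Each channel holds a fixed number of
#' D1- and D2-MSNs and represents one candidate action.
#'
#' @param rows,cols Grid dimensions (default 6 x 6 = 36 channels).
#' @param wrap Logical; edges wrap around (torus). Only `TRUE` is supported.
#' @param spacing_um Physical distance between adjacent channels in
#'   micrometres; used to convert channel distances into micrometres.
#' @return An object of class `channel_grid`.
#' @export
channel_grid <- function(rows = 6L, cols = 6L, wrap = TRUE, spacing_um = 40) {
  stopifnot(rows >= 1, cols >= 1)
  if (!isTRUE(wrap)) stop("only edge-wrapped (toroidal) grids are supported")
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         wrap = TRUE, spacing_um = spacing_um),
    class = "channel_grid"
  )
}

#' @export
print.channel_grid <- function(x, ...) {
  cat(sprintf("<channel_grid> %d x %d torus, %g um between channels\n",
              x$rows, x$cols, x$spacing_um))
  invisible(x)
}

n_channels <- function(grid) grid$rows * grid$cols

#' Channel index from (row, col) coordinate
#'
#' Channels are numbered row-major, 1..rows*cols. Coordinates are 1-based.
#' @param row,col Coordinates on the grid.
#' @param grid A [channel_grid()].
#' @return Integer channel index.
#' @export
channel_index <- function(row, col, grid) {
  check_coord(row, col, grid)
  (as.integer(row) - 1L) * grid$cols + as.integer(col)
}

#' Channel (row, col) coordinate from index
#' @param ch Channel index in 1..rows*cols.
#' @param grid A [channel_grid()].
#' @return A two-column matrix with columns `row`, `col`.
#' @export
channel_coords <- function(ch, grid) {
  ch <- as.integer(ch)
  if (any(ch < 1L | ch > n_channels(grid)))
    stop("channel index out of range")
  cbind(row = (ch - 1L) %/% grid$cols + 1L,
        col = (ch - 1L) %% grid$cols + 1L)
}

check_coord <- function(row, col, grid) {
  if (any(row < 1 | row > grid$rows | col < 1 | col > grid$cols) ||
      any(row != round(row)) || any(col != round(col)))
    stop("invalid channel coordinate for this grid")
  invisible(TRUE)
}

#' Wrapped Euclidean distance between channels
#'
#' Each axis difference is wrapped to the shorter way around the torus
#' (`min(|d|, extent - |d|)`) before Euclidean combination. Vectorised over
#' coordinates.
#'
#' @param c1,c2 Length-2 vectors `c(row, col)` or two-column matrices of
#'   coordinates (1-based).
#' @param grid A [channel_grid()].
#' @return Numeric channel distance(s); multiply by `grid$spacing_um` for
#'   micrometres.
#' @export
torus_distance <- function(c1, c2, grid) {
  c1 <- rbind(c1); c2 <- rbind(c2)
  check_coord(c1[, 1], c1[, 2], grid)
  check_coord(c2[, 1], c2[, 2], grid)
  dr <- abs(c1[, 1] - c2[, 1]); dr <- pmin(dr, grid$rows - dr)
  dc <- abs(c1[, 2] - c2[, 2]); dc <- pmin(dc, grid$cols - dc)
  unname(sqrt(dr^2 + dc^2))
}

#' Spatial category of a channel pair
#'
#' Pairs are classified as `within` (same channel), `near` (the immediate
#' neighbourhood) or `far` (everything else). The neighbourhood is the 8
#' surrounding cells by default (wrapped Euclidean distance <= sqrt(2));
#' set `diagonal = FALSE` for the 4-neighbourhood (distance <= 1).
#'
#' @inheritParams torus_distance
#' @param diagonal Logical; include diagonal neighbours in `near`.
#' @return Factor with levels `within`, `near`, `far`.
#' @export
distance_category <- function(c1, c2, grid, diagonal = TRUE) {
  d <- torus_distance(c1, c2, grid)
  cut <- if (diagonal) sqrt(2) + 1e-9 else 1 + 1e-9
  factor(ifelse(d == 0, "within", ifelse(d <= cut, "near", "far")),
         levels = c("within", "near", "far"))
}

# 36 x 36 matrix of category codes (1 = within, 2 = near, 3 = far)
channel_category_matrix <- function(grid, diagonal = TRUE) {
  co <- channel_coords(seq_len(n_channels(grid)), grid)
  dr <- abs(outer(co[, 1], co[, 1], "-")); dr <- pmin(dr, grid$rows - dr)
  dc <- abs(outer(co[, 2], co[, 2], "-")); dc <- pmin(dc, grid$cols - dc)
  d <- sqrt(dr^2 + dc^2)
  cut <- if (diagonal) sqrt(2) + 1e-9 else 1 + 1e-9
  m <- matrix(3L, nrow(d), ncol(d))
  m[d <= cut] <- 2L
  m[d == 0] <- 1L
  m
}

# full channel-distance matrix, used by the recruitment analysis
channel_distance_matrix <- function(grid) {
  co <- channel_coords(seq_len(n_channels(grid)), grid)
  dr <- abs(outer(co[, 1], co[, 1], "-")); dr <- pmin(dr, grid$rows - dr)
  dc <- abs(outer(co[, 2], co[, 2], "-")); dc <- pmin(dc, grid$cols - dc)
  sqrt(dr^2 + dc^2)
}
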