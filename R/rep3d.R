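# Topographic 3D tensors --------------------------------------------------
#
# The channel axis of 2D EEG (N, T) is rearranged onto a W x W scalp grid
# (rows anterior -> posterior, columns left -> right), giving a (W, W, T)
# tensor whose empty cells are exactly zero. T may be time samples or PSD
# bins. The packaged 64-channel 10-20 mapping uses W = 9; the 22-channel
# grid uses W = 5. Both ship as CSVs (columns channel,row,col, 0-based)
# and can be overridden with a user file: every injective placement
# preserves the round-trip and conservation invariants. The lowest ring of
# the 64-channel montage (FT9/FT10, TP9/TP10, PO9/PO10) overflows the nine
# columns of its nominal row and is placed on the free peripheral cells of
# the neighbouring row, the closest available projection on so coarse a
# grid.

#' Channel-to-grid mapping for a packaged montage
#'
#' @param montage `"64ch-1020"` (W = 9) or `"22ch-bciiv2a"` (W = 5).
#' @return A `grid_mapping`: data.frame with columns `channel`, `row`,
#'   `col` (0-based) and attribute `W`.
#' @export
grid_mapping <- function(montage = c("64ch-1020", "22ch-bciiv2a")) {
  montage <- tryCatch(match.arg(montage),
                      error = function(e)
                        stop("unknown montage; supported: 64ch-1020, 22ch-bciiv2a"))
  file <- switch(montage,
                 "64ch-1020" = "montage_64ch_1020_9x9.csv",
                 "22ch-bciiv2a" = "montage_22ch_bciiv2a_5x5.csv")
  W <- switch(montage, "64ch-1020" = 9L, "22ch-bciiv2a" = 5L)
  path <- system.file("extdata", file, package = "mi3deeg", mustWork = TRUE)
  read_grid_mapping(path, W)
}

#' Read a channel-to-grid mapping from a CSV file
#'
#' @param path CSV with columns `channel`, `row`, `col` (0-based cells).
#' @param W grid side length; defaults to `max(row, col) + 1`.
#' @return A `grid_mapping` object.
#' @export
read_grid_mapping <- function(path, W = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "row", "col") %in% names(df)))
    stop("mapping file needs columns channel,row,col")
  if (is.null(W)) W <- max(df$row, df$col) + 1L
  new_grid_mapping(df, as.integer(W))
}

new_grid_mapping <- function(df, W) {
  df$row <- as.integer(df$row); df$col <- as.integer(df$col)
  if (any(df$row < 0L | df$row >= W | df$col < 0L | df$col >= W))
    stop("mapping cells must lie within [0, W)^2")
  if (anyDuplicated(df[, c("row", "col")]))
    stop("mapping must be injective: one channel per cell")
  if (anyDuplicated(df$channel))
    stop("mapping must list each channel once")
  structure(df[, c("channel", "row", "col")], W = W,
            class = c("grid_mapping", "data.frame"))
}

#' @export
print.grid_mapping <- function(x, ...) {
  cat(sprintf("<grid_mapping> %d channels on a %dx%d grid\n",
              nrow(x), attr(x, "W"), attr(x, "W")))
  invisible(x)
}

#' Rearrange 2D EEG into a (W, W, T) topographic tensor
#'
#' Each channel row of `data2d` is copied into its grid cell; cells
#' without an electrode are exactly zero across all T.
#'
#' @param data2d numeric matrix, channels x T (time samples or PSD bins).
#'   If it has rownames they are matched against the mapping's channel
#'   names; otherwise rows are taken in mapping order.
#' @param mapping a [grid_mapping()].
#' @return A `W x W x T` array with attribute `mapping`.
#' @export
to_3d <- function(data2d, mapping) {
  stopifnot(inherits(mapping, "grid_mapping"))
  data2d <- as.matrix(data2d)
  if (nrow(data2d) != nrow(mapping))
    stop(sprintf("channel-count mismatch: data has %d rows, mapping has %d",
                 nrow(data2d), nrow(mapping)))
  ord <- seq_len(nrow(mapping))
  if (!is.null(rownames(data2d))) {
    ord <- match(mapping$channel, rownames(data2d))
    if (anyNA(ord))
      stop("data rownames do not cover mapping channels: ",
           paste(mapping$channel[is.na(ord)], collapse = ", "))
  }
  W <- attr(mapping, "W"); Tn <- ncol(data2d)
  out <- array(0, c(W, W, Tn))
  for (i in seq_len(nrow(mapping)))
    out[mapping$row[i] + 1L, mapping$col[i] + 1L, ] <- data2d[ord[i], ]
  attr(out, "mapping") <- mapping
  out
}

#' Gather a topographic tensor back into 2D channel data
#'
#' The exact inverse of [to_3d()] on the occupied cells.
#'
#' @param tensor a `W x W x T` array from [to_3d()].
#' @param mapping a [grid_mapping()]; defaults to the tensor's own.
#' @return channels x T matrix with channel rownames, in mapping order.
#' @export
from_3d <- function(tensor, mapping = attr(tensor, "mapping")) {
  stopifnot(inherits(mapping, "grid_mapping"))
  Tn <- dim(tensor)[3L]
  out <- matrix(0, nrow(mapping), Tn,
                dimnames = list(mapping$channel, NULL))
  for (i in seq_len(nrow(mapping)))
    out[i, ] <- tensor[mapping$row[i] + 1L, mapping$col[i] + 1L, ]
  out
}

#' Rotate the spatial plane of a topographic tensor by 90 degrees
#'
#' The T axis is untouched; the mapping attribute is rotated consistently.
#' Convention (the rotation oracle): cell `(r, c)` moves to
#' `(c, W - 1 - r)` in 0-based coordinates, so `(0, 0)` moves to
#' `(0, W - 1)`. Four successive rotations are the identity.
#'
#' @param tensor a `W x W x T` array (square spatial plane).
#' @return The rotated tensor, same dimensions.
#' @export
rotate90 <- function(tensor) {
  d <- dim(tensor)
  if (d[1L] != d[2L]) stop("spatial plane must be square")
  W <- d[1L]
  out <- array(0, d)
  for (r in seq_len(W))
    out[, W + 1L - r, ] <- tensor[r, , ]   # (r,c) -> (c, W-1-r), 0-based
  mp <- attr(tensor, "mapping")
  if (!is.null(mp)) {
    df <- as.data.frame(mp)
    newrow <- df$col
    newcol <- W - 1L - df$row
    df$row <- newrow; df$col <- newcol
    attr(out, "mapping") <- new_grid_mapping(df, W)
  }
  out
}

#' Build per-trial 3D tensors from a trialset or PSD features
#'
#' @param x a [trialset()] (time-domain tensors, T = samples) or a
#'   [psd_features()] object (frequency-domain tensors, T = PSD bins).
#' @param mapping a [grid_mapping()] covering the channels of `x`.
#' @return A list with `tensors` (n_trials x W x W x T array), `labels`
#'   and `mapping`.
#' @export
tensor_set <- function(x, mapping) {
  if (inherits(x, "trialset")) {
    dat <- x$trials; labels <- x$labels; chn <- x$channel_names
  } else if (inherits(x, "psd_features")) {
    dat <- x$psd; labels <- x$labels; chn <- x$channel_names
  } else stop("`x` must be a trialset or psd_features")
  d <- dim(dat)
  W <- attr(mapping, "W")
  out <- array(0, c(d[1L], W, W, d[3L]))
  for (i in seq_len(d[1L])) {
    m <- matrix(dat[i, , ], d[2L], d[3L], dimnames = list(chn, NULL))
    out[i, , , ] <- to_3d(m, mapping)
  }
  list(tensors = out, labels = labels, mapping = mapping)
}
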