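#' Assign tracked plants to crop rows
#'
#' Clusters plant positions into rows by 1D gap clustering on the
#' cross-track coordinate: positions are sorted by `X` and a new row starts
#' whenever the gap to the previous plant exceeds `row_gap`. Within each
#' row, members are ordered by the along-track coordinate `Y` (ties by
#' `track_id`). Working in world coordinates makes the partition
#' view-independent; the per-image horizontal strips seen by the camera are
#' the per-frame projection of the same partition.
#'
#' @param positions Data frame with columns `track_id`, `X`, `Y` (world
#'   meters), e.g. the `positions` element of [track_plants()].
#' @param row_gap Minimum cross-track gap separating two rows, in meters.
#' @return `positions` with added `row_id` (1-based, ordered by increasing
#'   `X`) and `order_in_row`, sorted by row then along-track position.
#' @export
assign_rows <- function(positions, row_gap = 0.3) {
  stopifnot(is.data.frame(positions),
            all(c("track_id", "X", "Y") %in% names(positions)))
  if (!is.numeric(row_gap) || row_gap <= 0)
    stop("row_gap must be > 0", call. = FALSE)
  if (nrow(positions) == 0L) {
    positions$row_id <- integer(0)
    positions$order_in_row <- integer(0)
    return(positions)
  }
  ord <- order(positions$X, positions$track_id)
  x <- positions$X[ord]
  row_id <- cumsum(c(1L, as.integer(diff(x) > row_gap)))
  positions$row_id[ord] <- row_id
  out <- positions[order(positions$row_id, positions$Y, positions$track_id), ,
                   drop = FALSE]
  out$order_in_row <- stats::ave(seq_len(nrow(out)), out$row_id,
                                 FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Ordered within-row plant spacings
#'
#' Computes the 3D Euclidean spacing between consecutive plants of each
#' row, in along-track order. Rows with fewer than two members yield no
#' spacing (a notice is emitted).
#'
#' @param positions Data frame with columns `row_id`, `order_in_row`, `X`,
#'   `Y`, `Z`, as returned by [assign_rows()].
#' @return Data frame `row_id`, `order` (1-based interval index along the
#'   row), `spacing_m`.
#' @export
row_spacings <- function(positions) {
  stopifnot(is.data.frame(positions),
            all(c("row_id", "order_in_row", "X", "Y", "Z") %in%
                  names(positions)))
  parts <- lapply(split(positions, positions$row_id), function(g) {
    g <- g[order(g$order_in_row), , drop = FALSE]
    if (nrow(g) < 2L) {
      message("row ", g$row_id[1L], " has fewer than 2 plants; no spacings")
      return(NULL)
    }
    p <- as.matrix(g[, c("X", "Y", "Z")])
    data.frame(row_id = g$row_id[1L],
               order = seq_len(nrow(g) - 1L),
               spacing_m = spacing_3d(p[-nrow(p), , drop = FALSE],
                                      p[-1L, , drop = FALSE]))
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts))
    return(data.frame(row_id = integer(0), order = integer(0),
                      spacing_m = numeric(0)))
  out <- do.call(rbind, parts)
  out <- out[order(out$row_id, out$order), , drop = FALSE]
  rownames(out) <- NULL
  out
}
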