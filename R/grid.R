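#' Electrode grid geometry
#'
#' Lead placements on the rectangular flexible plate. Adjacency is the
#' 4-neighbourhood by default (8-neighbourhood optionally), used both by the
#' generator to grow the core ischemic patch and by the zone classifier to
#' find the border.
#'
#' @param rows,cols grid dimensions.
#' @return data.frame with `lead`, `row`, `col`.
#' @export
lead_grid <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  g <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  data.frame(lead = sprintf("E%02d", seq_len(nrow(g))), row = g$row, col = g$col,
             stringsAsFactors = FALSE)
}

#' @rdname lead_grid
#' @param grid a `lead_grid()` data.frame.
#' @param leads character vector of lead ids whose neighbours are wanted.
#' @param diagonal if `TRUE`, use the 8-neighbourhood.
#' @return character vector of leads adjacent to (and not in) `leads`.
#' @export
grid_adjacent <- function(grid, leads, diagonal = FALSE) {
  stopifnot(all(leads %in% grid$lead))
  inset <- grid$lead %in% leads
  dr <- outer(grid$row, grid$row[inset], "-")
  dc <- outer(grid$col, grid$col[inset], "-")
  near <- if (diagonal) {
    abs(dr) <= 1 & abs(dc) <= 1 & (dr != 0 | dc != 0)
  } else {
    abs(dr) + abs(dc) == 1
  }
  grid$lead[!inset & rowSums(near) > 0]
}

# Contiguous random patch of `size` leads grown by uniform frontier expansion.
.grow_patch <- function(grid, size) {
  patch <- sample(grid$lead, 1)
  while (length(patch) < size) {
    front <- grid_adjacent(grid, patch)
    if (length(front) == 0) break
    patch <- c(patch, sample(front, 1))
  }
  patch
}
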