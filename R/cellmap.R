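#' Assemble a field of view from a contour library
#'
#' Contours are drawn at random from the library and placed at integer
#' positions so that every cell's footprint shares pixels with between
#' `overlap_range[1]` and `overlap_range[2]` other cells, emulating a densely
#' packed field where somata partially overlap. Placement is constructive
#' (each new cell is anchored near an already placed one) with rejection of
#' candidates that violate the degree constraints; the whole map is retried
#' if a constraint cannot be met.
#'
#' @param library list of `cacti_contour` (origin-centered).
#' @param n_cells number of cells to place (default 16).
#' @param overlap_range integer(2), inclusive bounds on the number of
#'   overlapping neighbours per cell; `c(0, 0)` yields disjoint cells.
#' @param field_shape integer(2) `(height, width)` in pixels.
#' @param seed integer RNG seed.
#' @param max_attempts per-cell candidate budget before the map is retried.
#' @return `cacti_cellmap`: placed contours, the field shape and the overlap
#'   graph as a two-column matrix of cell-id pairs.
#' @export
build_cell_map <- function(library, n_cells = 16, overlap_range = c(1, 4),
                           field_shape = c(100, 100), seed = NULL,
                           max_attempts = 500) {
  if (length(library) < 1) stop_config("cell map: contour library is empty")
  if (n_cells < 1) stop_config("cell map: n_cells must be >= 1")
  if (overlap_range[1] > overlap_range[2] || overlap_range[1] < 0)
    stop_config("cell map: invalid overlap_range")
  if (n_cells > 1 && overlap_range[2] == 0 && overlap_range[1] > 0)
    stop_config("cell map: infeasible overlap_range")
  with_seed(seed, {
    for (map_try in 1:25) {
      placed <- try_place_map(library, n_cells, overlap_range, field_shape,
                              max_attempts)
      if (!is.null(placed)) return(placed)
    }
  })
  stop_config(paste0("cell map: could not satisfy overlap degrees in [",
                     overlap_range[1], ", ", overlap_range[2], "] for ",
                     n_cells, " cells in a ", field_shape[1], "x",
                     field_shape[2], " field"))
}

try_place_map <- function(library, n_cells, overlap_range, field_shape,
                          max_attempts) {
  h <- field_shape[1]; w <- field_shape[2]
  contours <- vector("list", n_cells)
  keys <- vector("list", n_cells)    # pixel keys of each placed mask
  deg <- integer(n_cells)
  want_overlap <- overlap_range[2] > 0
  for (i in seq_len(n_cells)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      proto <- library[[sample.int(length(library), 1)]]
      rad <- max(abs(proto$mask))
      if (i == 1 || !want_overlap) {
        cx <- sample(seq(rad, w - 1 - rad), 1)
        cy <- sample(seq(rad, h - 1 - rad), 1)
      } else {
        # anchor near a placed cell, preferring those still short of the
        # minimum degree so no cell is left isolated
        short <- which(deg[seq_len(i - 1)] < overlap_range[1])
        open <- if (length(short)) short else
          which(deg[seq_len(i - 1)] < overlap_range[2])
        if (length(open) == 0) open <- seq_len(i - 1)
        anchor <- contours[[sample(open, 1)]]
        arad <- max(abs(anchor$mask - rep(anchor$center, each = nrow(anchor$mask))))
        d <- stats::runif(1, 0.55, 0.95) * (rad + arad)
        a <- stats::runif(1, 0, 2 * pi)
        cx <- round(anchor$center[1] + d * cos(a))
        cy <- round(anchor$center[2] + d * sin(a))
      }
      if (cx - rad < 0 || cx + rad > w - 1 || cy - rad < 0 || cy + rad > h - 1)
        next
      cand <- translate_contour(proto, cx, cy)
      ck <- pixel_key(cand$mask, w)
      nb <- which(vapply(seq_len(i - 1),
                         function(j) any(ck %in% keys[[j]]), logical(1)))
      ndeg <- length(nb)
      if (!want_overlap) {
        if (ndeg > 0) next
      } else {
        if (ndeg < 1 && i > 1) next      # every later cell must touch someone
        if (ndeg > overlap_range[2]) next
        if (any(deg[nb] + 1 > overlap_range[2])) next
      }
      cand$cell_id <- i
      contours[[i]] <- cand
      keys[[i]] <- ck
      deg[nb] <- deg[nb] + 1L
      deg[i] <- ndeg
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  if (want_overlap && any(deg < overlap_range[1] | deg > overlap_range[2]))
    return(NULL)
  graph <- overlap_graph(contours, w)
  structure(list(contours = contours, field_shape = as.integer(field_shape),
                 overlap_graph = graph),
            class = "cacti_cellmap")
}

# Recompute the overlap graph from pixel intersections.
overlap_graph <- function(contours, width) {
  n <- length(contours)
  keys <- lapply(contours, function(ct) pixel_key(ct$mask, width))
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("cell_a", "cell_b")))
  if (n < 2) return(pairs)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (any(keys[[i]] %in% keys[[j]]))
      pairs <- rbind(pairs, c(contours[[i]]$cell_id, contours[[j]]$cell_id))
  }
  pairs
}

#' Overlap degree of every cell, recomputed from pixel intersections
#' @param cell_map a `cacti_cellmap`.
#' @return named integer vector of neighbour counts.
#' @export
overlap_degrees <- function(cell_map) {
  ids <- vapply(cell_map$contours, `[[`, integer(1), "cell_id")
  deg <- stats::setNames(integer(length(ids)), ids)
  g <- cell_map$overlap_graph
  for (k in seq_len(nrow(g))) {
    deg[as.character(g[k, 1])] <- deg[as.character(g[k, 1])] + 1L
    deg[as.character(g[k, 2])] <- deg[as.character(g[k, 2])] + 1L
  }
  deg
}

#' @export
print.cacti_cellmap <- function(x, ...) {
  cat(sprintf("<cacti_cellmap> %d cells in %dx%d field, %d overlapping pairs\n",
              length(x$contours), x$field_shape[1], x$field_shape[2],
              nrow(x$overlap_graph)))
  invisible(x)
}
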