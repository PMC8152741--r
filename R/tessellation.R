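#' Build a rectangular tract tessellation
#'
#' Creates a `rows` by `cols` grid of unit-square tracts tiling the study
#' rectangle, together with a contiguity adjacency list. The grid stands in
#' for a census-tract map: every statistic downstream (spatial weights,
#' Moran/Geary indices, SAR fits) depends only on the adjacency structure,
#' not on polygon shape.
#'
#' @param rows,cols Number of grid rows and columns (each >= 1).
#' @param contiguity `"queen"` (edge or corner contact, the default) or
#'   `"rook"` (edge contact only).
#' @return An object of class `tessellation`: a list with
#'   \describe{
#'     \item{tracts}{tibble with `tract_id`, grid `row`/`col`, and the
#'       square's `xmin`, `xmax`, `ymin`, `ymax`.}
#'     \item{adjacency}{tibble of unordered neighbouring pairs
#'       (`from` < `to`).}
#'     \item{rows, cols, n_tracts, contiguity}{scalars.}
#'   }
#' @examples
#' tess <- make_tessellation(3, 3)
#' nrow(tess$adjacency)
#' @export
make_tessellation <- function(rows, cols, contiguity = c("queen", "rook")) {
  rows <- assert_scalar_count(rows, "rows")
  cols <- assert_scalar_count(cols, "cols")
  contiguity <- match.arg(contiguity)
  n <- rows * cols
  if (n < 2L) abort("a tessellation needs at least 2 tracts so every tract has a neighbour")

  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  tracts <- tibble(
    tract_id = seq_len(n),
    row = grid$row,
    col = grid$col,
    xmin = grid$col - 1, xmax = grid$col,
    ymin = grid$row - 1, ymax = grid$row
  )

  id <- function(r, c) (r - 1L) * cols + c
  steps <- if (contiguity == "queen") {
    expand.grid(dr = -1:1, dc = -1:1)
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  steps <- steps[!(steps$dr == 0 & steps$dc == 0), , drop = FALSE]
  pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- tracts$row[i]; c <- tracts$col[i]
    rr <- r + steps$dr; cc <- c + steps$dc
    ok <- rr >= 1 & rr <= rows & cc >= 1 & cc <= cols
    j <- id(rr[ok], cc[ok])
    cbind(from = pmin(i, j), to = pmax(i, j))
  }))
  pairs <- unique(as.data.frame(pairs))
  pairs <- pairs[order(pairs$from, pairs$to), , drop = FALSE]

  structure(
    list(
      tracts = tracts,
      adjacency = as_tibble(pairs),
      rows = rows, cols = cols, n_tracts = n, contiguity = contiguity
    ),
    class = "tessellation"
  )
}

#' @export
print.tessellation <- function(x, ...) {
  cat(sprintf(
    "<tessellation> %d x %d grid, %d tracts, %d %s-contiguity pairs\n",
    x$rows, x$cols, x$n_tracts, nrow(x$adjacency), x$contiguity
  ))
  invisible(x)
}

#' Neighbour lists of a tessellation
#'
#' @param tess A [make_tessellation()] object.
#' @return A list, indexed by tract id, of neighbouring tract ids.
#' @export
neighbours <- function(tess) {
  stopifnot(inherits(tess, "tessellation"))
  nb <- vector("list", tess$n_tracts)
  for (k in seq_len(nrow(tess$adjacency))) {
    i <- tess$adjacency$from[k]; j <- tess$adjacency$to[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, sort)
}

#' Write a tessellation as a GeoJSON FeatureCollection
#'
#' Each tract becomes a Polygon feature with a `tract_id` property.
#' Coordinates are abstract planar units (no CRS).
#'
#' @param tess A tessellation.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tessellation_geojson <- function(tess, path) {
  stopifnot(inherits(tess, "tessellation"))
  features <- lapply(seq_len(tess$n_tracts), function(i) {
    t <- tess$tracts[i, ]
    ring <- list(
      c(t$xmin, t$ymin), c(t$xmax, t$ymin), c(t$xmax, t$ymax),
      c(t$xmin, t$ymax), c(t$xmin, t$ymin)
    )
    list(
      type = "Feature",
      properties = list(tract_id = t$tract_id),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write tract adjacency as an edge-list text file
#'
#' @param tess A tessellation.
#' @param path Output file path; one `from to` pair per line.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(tess, path) {
  stopifnot(inherits(tess, "tessellation"))
  write.table(tess$adjacency, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Spatial weights from adjacency
#'
#' Builds the weights matrix used by the spatial statistics: binary
#' contiguity weights for the Moran coefficient and Geary ratio (the
#' classical index definitions), or row-standardized weights for the SAR
#' model (whose autocorrelation parameter space requires them).
#'
#' @param x A `tessellation`, or a data frame of neighbouring pairs with
#'   columns `from` and `to`.
#' @param style `"binary"` or `"row"` (row-standardized).
#' @param n Number of units; required when `x` is a pair list.
#' @return An object of class `spatial_weights`: list with the dense
#'   matrix `w`, the binary matrix `b`, `style`, and `n`.
#' @export
spatial_weights <- function(x, style = c("binary", "row"), n = NULL) {
  style <- match.arg(style)
  if (inherits(x, "tessellation")) {
    pairs <- x$adjacency
    n <- x$n_tracts
  } else {
    pairs <- as.data.frame(x)
    if (!all(c("from", "to") %in% names(pairs))) {
      abort("pair list must have columns `from` and `to`")
    }
    if (is.null(n)) n <- max(pairs$from, pairs$to)
  }
  if (any(pairs$from == pairs$to)) abort("self-neighbours are not allowed")
  b <- matrix(0, n, n)
  b[cbind(pairs$from, pairs$to)] <- 1
  b[cbind(pairs$to, pairs$from)] <- 1
  deg <- rowSums(b)
  if (any(deg == 0)) {
    abort(paste0(
      "every unit needs at least one neighbour; isolated: ",
      paste(which(deg == 0), collapse = ", ")
    ))
  }
  w <- if (style == "row") b / deg else b
  structure(list(w = w, b = b, style = style, n = n, degree = deg),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> n = %d, style = %s, links = %d\n",
              x$n, x$style, sum(x$b) / 2))
  invisible(x)
}
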