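#' Ordered, labelled 3-D point sets
#'
#' A `point_set` is an ordered collection of labelled 3-D coordinates in
#' millimetres, in a single scan space. Axis convention throughout the
#' package: x = sagittal, y = coronal, z = axial. The *order* of the points
#' defines correspondence when two point sets are registered; unordered
#' detections must first be put into reference order with
#' [match_fiducials()].
#'
#' @param coords numeric matrix with `n` rows and 3 columns (x, y, z in mm),
#'   or anything coercible to one (including a data frame with columns
#'   `x_mm`, `y_mm`, `z_mm`).
#' @param labels character vector of unique point identifiers, one per row.
#'   Defaults to `"1"`, `"2"`, ... .
#' @return An object of class `point_set`: a list with elements `labels`
#'   (character) and `coords` (n x 3 numeric matrix, columns `x`, `y`, `z`).
#' @examples
#' ps <- point_set(rbind(c(0, 0, 0), c(10, 0, 0)), labels = c("a", "b"))
#' n_points(ps)
#' @export
point_set <- function(coords, labels = NULL) {
  if (is.data.frame(coords)) {
    cn <- c("x_mm", "y_mm", "z_mm")
    if (all(cn %in% names(coords))) {
      if (is.null(labels) && "label" %in% names(coords)) {
        labels <- as.character(coords$label)
      }
      coords <- as.matrix(coords[, cn])
    } else {
      coords <- as.matrix(coords)
    }
  }
  coords <- matrix(as.numeric(coords), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(coords) < 1L) {
    stop("a point_set needs at least one point", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("point coordinates must be finite", call. = FALSE)
  }
  if (is.null(labels)) labels <- as.character(seq_len(nrow(coords)))
  labels <- as.character(labels)
  if (length(labels) != nrow(coords)) {
    stop("need exactly one label per point", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("point labels must be unique", call. = FALSE)
  }
  structure(list(labels = labels, coords = coords), class = "point_set")
}

#' @rdname point_set
#' @param x a `point_set`.
#' @export
n_points <- function(x) {
  stopifnot(inherits(x, "point_set"))
  nrow(x$coords)
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set: %d points (mm)>\n", n_points(x)))
  print(utils::head(as.data.frame(x), 10L), ...)
  if (n_points(x) > 10L) cat(sprintf("... and %d more\n", n_points(x) - 10L))
  invisible(x)
}

#' @export
as.data.frame.point_set <- function(x, ...) {
  data.frame(label = x$labels,
             x_mm = x$coords[, 1], y_mm = x$coords[, 2], z_mm = x$coords[, 3],
             stringsAsFactors = FALSE)
}

#' Read and write point-set CSV files
#'
#' Point sets are exchanged as CSV with header `label,x_mm,y_mm,z_mm`, one
#' row per fiducial or target, UTF-8, decimal point. Coordinates are written
#' at full double precision.
#'
#' @param path file path.
#' @return `read_point_set()` returns a `point_set`; `write_point_set()`
#'   returns `path` invisibly.
#' @export
read_point_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stop(sprintf("point-set CSV must have columns %s",
                 paste(need, collapse = ",")), call. = FALSE)
  }
  point_set(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]),
            labels = as.character(df$label))
}

#' @rdname read_point_set
#' @param ps a `point_set`.
#' @export
write_point_set <- function(ps, path) {
  stopifnot(inherits(ps, "point_set"))
  df <- as.data.frame(ps)
  # full precision so write/read round-trips are lossless
  df$x_mm <- format(df$x_mm, digits = 17, trim = TRUE, scientific = FALSE)
  df$y_mm <- format(df$y_mm, digits = 17, trim = TRUE, scientific = FALSE)
  df$z_mm <- format(df$z_mm, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
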