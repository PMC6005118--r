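#' Grid geometry for the 8 x 8 cancellation array
#'
#' The display is an 8 x 8 grid addressed two ways: a flat 0-based row-major
#' index (`index = row * 8 + col`, 0..63) and a three-level quadtree address
#' (quadrant, subquadrant, cell, each 0..3). Columns 0-3 form the left
#' hemifield, columns 4-7 the right. Quadrants at every level are ordered
#' upper-left, upper-right, lower-left, lower-right.
#'
#' @param row,col 0-based grid coordinates (0..7).
#' @param index 0-based row-major cell index (0..63). Vectorised.
#' @return `loc_index()` returns the flat index; `loc_rc()` a tibble with
#'   columns `index`, `row`, `col`; `loc_to_factors()` a tibble with columns
#'   `quadrant`, `subquadrant`, `cell`; `factors_to_loc()` the flat index.
#' @examples
#' loc_index(3, 3)
#' loc_to_factors(0:3)
#' factors_to_loc(loc_to_factors(0:63)) # identity
#' @name grid-geometry
NULL

#' @rdname grid-geometry
#' @export
loc_index <- function(row, col) {
  stopifnot(all(row %in% 0:7), all(col %in% 0:7))
  as.integer(row * 8L + col)
}

#' @rdname grid-geometry
#' @export
loc_rc <- function(index) {
  check_index(index)
  tibble::tibble(
    index = as.integer(index),
    row = as.integer(index %/% 8L),
    col = as.integer(index %% 8L)
  )
}

check_index <- function(index) {
  if (length(index) == 0 || anyNA(index) || any(index != floor(index)) ||
      any(index < 0) || any(index > 63)) {
    stop("location index must be an integer in 0..63", call. = FALSE)
  }
  invisible(index)
}

#' @rdname grid-geometry
#' @export
loc_to_factors <- function(index) {
  check_index(index)
  row <- index %/% 8L
  col <- index %% 8L
  tibble::tibble(
    index = as.integer(index),
    quadrant = as.integer(2L * (row %/% 4L) + (col %/% 4L)),
    subquadrant = as.integer(2L * ((row %% 4L) %/% 2L) + ((col %% 4L) %/% 2L)),
    cell = as.integer(2L * (row %% 2L) + (col %% 2L))
  )
}

#' @rdname grid-geometry
#' @param factors tibble (or data frame) with columns `quadrant`,
#'   `subquadrant`, `cell`, as produced by [loc_to_factors()].
#' @export
factors_to_loc <- function(factors) {
  q <- factors$quadrant
  s <- factors$subquadrant
  cc <- factors$cell
  stopifnot(all(q %in% 0:3), all(s %in% 0:3), all(cc %in% 0:3))
  row <- 4L * (q %/% 2L) + 2L * (s %/% 2L) + (cc %/% 2L)
  col <- 4L * (q %% 2L) + 2L * (s %% 2L) + (cc %% 2L)
  loc_index(row, col)
}

# 0-based factor values (length-64 integer vectors, indexed by state + 1)
factor_table <- function() loc_to_factors(0:63)

# TRUE for locations in the given hemifield ("left" = cols 0-3)
hemifield_mask <- function(side = c("left", "right")) {
  side <- match.arg(side)
  col <- 0:63 %% 8L
  if (side == "left") col <= 3L else col >= 4L
}

# TRUE for states on `side` at a given spatial scale of the quadtree.
# At every level the left half corresponds to factor values {0, 2}
# (upper-left, lower-left) and the right half to {1, 3}.
scale_side_mask <- function(scale = c("coarse", "mid", "fine"),
                            side = c("left", "right")) {
  scale <- match.arg(scale)
  side <- match.arg(side)
  ft <- factor_table()
  f <- switch(scale, coarse = ft$quadrant, mid = ft$subquadrant, fine = ft$cell)
  if (side == "left") f %in% c(0L, 2L) else f %in% c(1L, 3L)
}
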