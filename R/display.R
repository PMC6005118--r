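#' Target displays for the cancellation task
#'
#' A display is the ground-truth state of the 8 x 8 array: each cell is
#' empty, an uncancelled target (black), or a cancelled target (red).
#' Targets turn from black to red when fixated and never revert.
#'
#' @param n_targets Number of targets to place (0..64).
#' @param mode `"random"` places targets uniformly at random; `"balanced"`
#'   places `n_targets / 2` in each hemifield; `"csv"` reads an explicit
#'   layout from `file`.
#' @param seed Integer seed for the random modes.
#' @param file CSV layout with 0-based columns `row`,`col` (mode `"csv"`).
#' @return An object of class `neglect_display`: an 8 x 8 integer matrix with
#'   entries 0 (empty), 1 (target), 2 (cancelled).
#' @examples
#' d <- generate_display(16, mode = "balanced", seed = 1)
#' sum(d == 1)
#' @export
generate_display <- function(n_targets = 16,
                             mode = c("random", "balanced", "csv"),
                             seed = 1L, file = NULL) {
  mode <- match.arg(mode)
  grid <- matrix(0L, 8, 8)
  if (mode == "csv") {
    lay <- utils::read.csv(file, comment.char = "#")
    stopifnot(all(c("row", "col") %in% names(lay)))
    idx <- loc_index(lay$row, lay$col)
    if (anyDuplicated(idx)) stop("duplicate target locations in layout", call. = FALSE)
    grid[idx + 1L] <- 1L
    return(new_display(grid))
  }
  stopifnot(n_targets >= 0, n_targets <= 64)
  set.seed(seed)
  if (mode == "random") {
    idx <- sample(0:63, n_targets)
  } else {
    if (n_targets %% 2L != 0L) stop("balanced mode needs an even n_targets", call. = FALSE)
    left <- which(hemifield_mask("left")) - 1L
    right <- which(hemifield_mask("right")) - 1L
    if (n_targets / 2 > 32) stop("overfull hemifield", call. = FALSE)
    idx <- c(sample(left, n_targets / 2), sample(right, n_targets / 2))
  }
  grid[idx + 1L] <- 1L
  new_display(grid)
}

new_display <- function(grid) {
  stopifnot(is.matrix(grid), all(dim(grid) == c(8, 8)), all(grid %in% 0:2))
  # matrix is indexed [row+1, col+1]? No: we store by flat state index for
  # simplicity; grid[index + 1] with index = row*8 + col (row-major), i.e.
  # the matrix is filled column-major by flat index. Accessors below hide this.
  structure(grid, class = "neglect_display")
}

#' @export
print.neglect_display <- function(x, ...) {
  sym <- c("0" = ".", "1" = "X", "2" = "o")
  cat("<neglect_display> ", sum(x == 1L), "targets,", sum(x == 2L), "cancelled\n")
  for (r in 0:7) {
    cat(" ", sym[as.character(x[loc_index(r, 0:7) + 1L])], "\n")
  }
  invisible(x)
}

# cell state at flat index (vectorised)
display_cell <- function(display, index) {
  check_index(index)
  unclass(display)[index + 1L]
}

#' Tidy view of a display
#'
#' @param x A `neglect_display`.
#' @param ... Unused.
#' @return A 64-row tibble with columns `index`, `row`, `col`, `state`
#'   (factor: empty / target / cancelled).
#' @export
tidy.neglect_display <- function(x, ...) {
  out <- loc_rc(0:63)
  out$state <- factor(c("empty", "target", "cancelled")[unclass(x)[out$index + 1L] + 1L],
                      levels = c("empty", "target", "cancelled"))
  out
}

#' Write / read a display layout as CSV
#'
#' One row per target, 0-based `row`,`col` columns; cancelled state is not
#' serialised (layouts describe the start of a trial).
#'
#' @param display A `neglect_display`.
#' @param path CSV path.
#' @return `read_display()` returns a `neglect_display`.
#' @export
write_display <- function(display, path) {
  idx <- which(unclass(display) != 0L) - 1L
  utils::write.csv(loc_rc(idx)[, c("row", "col")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_display
#' @export
read_display <- function(path) generate_display(mode = "csv", file = path)

#' Emit the outcomes generated by fixating a display location
#'
#' Fixating a cell yields an onset observation (the cell as it looked on
#' arrival), then the cancellation rule applies (black -> red), then an
#' offset observation. Proprioception reports the fixated location exactly.
#' In the multiscale model the visual outcome is complemented by target
#' densities of the fixated quadrant (0-16) and subquadrant (0-4); density is
#' colour-blind, counting targets whether cancelled or not, so it is
#' unchanged by the onset/offset transition.
#'
#' @param display A `neglect_display`.
#' @param fixation Flat location index (0..63).
#' @param kind `"flat"` or `"multiscale"` outcome set.
#' @return A list with 1-based outcome index vectors `onset` and `offset`
#'   (named by modality) and the updated display `display` after the
#'   cancellation rule.
#' @export
emit_outcomes <- function(display, fixation, kind = c("flat", "multiscale")) {
  kind <- match.arg(kind)
  check_index(fixation)
  onset_vis <- display_cell(display, fixation) + 1L # 1 white, 2 black, 3 red
  display2 <- step_display(display, fixation)
  offset_vis <- display_cell(display2, fixation) + 1L
  if (kind == "flat") {
    onset <- c(visual = onset_vis, prop = fixation + 1L)
    offset <- c(visual = offset_vis, prop = fixation + 1L)
  } else {
    ft <- loc_to_factors(fixation)
    dens <- display_densities(display, fixation)
    onset <- c(density_coarse = dens$coarse + 1L, density_mid = dens$mid + 1L,
               visual = onset_vis,
               prop_q = ft$quadrant + 1L, prop_s = ft$subquadrant + 1L,
               prop_c = ft$cell + 1L)
    offset <- onset
    offset["visual"] <- offset_vis
  }
  list(onset = onset, offset = offset, display = display2)
}

# target counts (cancelled or not) in the quadrant / subquadrant containing
# `index`
display_densities <- function(display, index) {
  ft <- factor_table()
  at <- loc_to_factors(index)
  present <- unclass(display)[1:64] %in% c(1L, 2L)
  list(
    coarse = sum(present[ft$quadrant == at$quadrant]),
    mid = sum(present[ft$quadrant == at$quadrant & ft$subquadrant == at$subquadrant])
  )
}

#' Apply the cancellation rule
#'
#' Fixating an uncancelled target cancels it; all other cells are unchanged.
#' Cancelling is idempotent and never reverts.
#'
#' @inheritParams emit_outcomes
#' @return The updated `neglect_display`.
#' @export
step_display <- function(display, fixation) {
  check_index(fixation)
  g <- unclass(display)
  if (g[fixation + 1L] == 1L) g[fixation + 1L] <- 2L
  new_display(g)
}
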