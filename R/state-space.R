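#' Define a rectangular state space
#'
#' The state space `S` is the spatial domain over which activity centers may
#' occur. For trap-array studies it is conventionally a rectangle obtained by
#' buffering the bounding box of the traps.
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds (same planar units as the trap
#'   coordinates, e.g. km).
#' @param buffer_mult Optional provenance: the multiple of the within-period
#'   detection scale `sigma_p` used to construct the buffer.
#' @return An object of class `state_space`.
#' @export
#' @examples
#' S <- state_space(0, 10, 0, 10)
#' ss_area(S)
state_space <- function(xmin, xmax, ymin, ymax, buffer_mult = NULL) {
  stopifnot(is.numeric(xmin), is.numeric(xmax), is.numeric(ymin), is.numeric(ymax))
  if (!all(is.finite(c(xmin, xmax, ymin, ymax)))) {
    stop("state-space bounds must be finite", call. = FALSE)
  }
  if (xmax <= xmin || ymax <= ymin) {
    stop("state space must have positive extent (xmax > xmin, ymax > ymin)", call. = FALSE)
  }
  structure(
    list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
         buffer_mult = buffer_mult),
    class = "state_space"
  )
}

#' Build a state space by buffering a trap array
#'
#' Expands the bounding box of the traps by `buffer` on all four sides.
#'
#' @param traps A trap data frame with numeric `x` and `y` columns
#'   (see [make_trap_grid()] / [read_traps()]).
#' @param buffer Non-negative buffer width in coordinate units. Commonly a
#'   multiple of the detection scale, e.g. `4 * sigma_p`.
#' @param buffer_mult Optional provenance tag stored on the result.
#' @return A `state_space` object.
#' @export
#' @examples
#' traps <- make_trap_grid(7, 7, spacing = 1, center = c(5, 5))
#' make_state_space(traps, buffer = 2)  # the 10 x 10 square
make_state_space <- function(traps, buffer, buffer_mult = NULL) {
  stopifnot(is.data.frame(traps), all(c("x", "y") %in% names(traps)))
  if (!is.numeric(buffer) || length(buffer) != 1 || !is.finite(buffer) || buffer < 0) {
    stop("`buffer` must be a single non-negative number", call. = FALSE)
  }
  state_space(
    xmin = min(traps$x) - buffer, xmax = max(traps$x) + buffer,
    ymin = min(traps$y) - buffer, ymax = max(traps$y) + buffer,
    buffer_mult = buffer_mult
  )
}

#' Area of a state space
#' @param S A `state_space`.
#' @return Area in squared coordinate units.
#' @export
ss_area <- function(S) {
  stopifnot(inherits(S, "state_space"))
  (S$xmax - S$xmin) * (S$ymax - S$ymin)
}

#' Test whether points fall inside a state space
#' @param S A `state_space`.
#' @param x,y Numeric vectors of coordinates.
#' @return Logical vector.
#' @export
ss_contains <- function(S, x, y) {
  stopifnot(inherits(S, "state_space"))
  x >= S$xmin & x <= S$xmax & y >= S$ymin & y <= S$ymax
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> [%.3g, %.3g] x [%.3g, %.3g]  (area %.4g)\n",
              x$xmin, x$xmax, x$ymin, x$ymax, ss_area(x)))
  if (!is.null(x$buffer_mult)) {
    cat(sprintf("  buffer: %.3g x sigma_p\n", x$buffer_mult))
  }
  invisible(x)
}
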