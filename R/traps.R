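#' Build a regular trap grid
#'
#' Lays out an `nx` by `ny` rectangular grid of traps with the given spacing,
#' centered at `center`, with uniform sampling effort `K` occasions per
#' primary period.
#'
#' @param nx,ny Number of grid columns/rows, `>= 1`.
#' @param spacing Distance between adjacent traps, `> 0`.
#' @param center Length-2 numeric `(x, y)` grid center.
#' @param K Occasions (trap-days) of effort per trap per primary period.
#' @return A tibble with columns `trap_id`, `x`, `y`, `K`.
#' @export
#' @examples
#' make_trap_grid(7, 7, spacing = 1, center = c(5, 5))
make_trap_grid <- function(nx, ny, spacing = 1, center = c(0, 0), K = 5) {
  stopifnot(nx >= 1, ny >= 1, spacing > 0, length(center) == 2, K >= 0)
  xs <- (seq_len(nx) - (nx + 1) / 2) * spacing + center[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * spacing + center[2]
  g <- expand.grid(x = xs, y = ys)
  tibble::tibble(
    trap_id = paste0("T", seq_len(nrow(g))),
    x = g$x, y = g$y, K = as.integer(K)
  )
}

# Internal: J x T effort matrix from a trap tibble. Accepts either a single
# `K` column (constant effort) or per-period columns K_1 .. K_T.
effort_matrix <- function(traps, n_periods) {
  per_period <- grep("^K_[0-9]+$", names(traps), value = TRUE)
  if (length(per_period) > 0) {
    idx <- as.integer(sub("^K_", "", per_period))
    if (!setequal(idx, seq_len(n_periods))) {
      stop(sprintf("trap effort columns cover periods {%s} but %d periods were requested",
                   paste(sort(idx), collapse = ","), n_periods), call. = FALSE)
    }
    Kmat <- as.matrix(traps[per_period[order(idx)]])
  } else if ("K" %in% names(traps)) {
    Kmat <- matrix(traps$K, nrow = nrow(traps), ncol = n_periods)
  } else {
    stop("traps must have a `K` column or `K_1` .. `K_T` columns", call. = FALSE)
  }
  storage.mode(Kmat) <- "integer"
  if (any(Kmat < 0) || anyNA(Kmat)) stop("trap effort must be non-negative", call. = FALSE)
  if (any(colSums(Kmat) == 0)) {
    stop("each analyzed period needs at least one trap with effort > 0", call. = FALSE)
  }
  dimnames(Kmat) <- NULL
  Kmat
}

# Internal: validate trap table structure shared by readers and fitters.
validate_traps <- function(traps) {
  stopifnot(is.data.frame(traps))
  need <- c("trap_id", "x", "y")
  missing <- setdiff(need, names(traps))
  if (length(missing) > 0) {
    stop("traps missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(traps$trap_id)) stop("duplicate trap_id in trap table", call. = FALSE)
  if (!all(is.finite(traps$x)) || !all(is.finite(traps$y))) {
    stop("trap coordinates must be finite numbers", call. = FALSE)
  }
  invisible(traps)
}
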