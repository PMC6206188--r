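#' Read a trap-deployment table
#'
#' Expects a CSV with columns `trap_id,x,y` and effort given either as a
#' single `K` column (constant across periods) or per-period columns
#' `K_1 .. K_T`. Traps with zero effort in some periods are accepted (they
#' contribute no likelihood there), supporting designs whose trap array
#' expands over the years.
#'
#' @param path CSV file path.
#' @return A validated trap tibble.
#' @export
read_traps <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trap_id", "x", "y")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("trap file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- which(duplicated(raw$trap_id))
  if (length(dup) > 0) {
    stop(sprintf("duplicate trap_id at line %d of %s", dup[1] + 1, path),
         call. = FALSE)
  }
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric %s coordinate at line %d of %s",
                   col, bad[1] + 1, path), call. = FALSE)
    }
    raw[[col]] <- v
  }
  eff_cols <- c(grep("^K(_[0-9]+)?$", names(raw), value = TRUE))
  if (length(eff_cols) == 0) {
    stop("trap file needs a `K` column or `K_1..K_T` columns", call. = FALSE)
  }
  for (col in eff_cols) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad) > 0) {
      stop(sprintf("negative or non-integer effort `%s` at line %d of %s",
                   col, bad[1] + 1, path), call. = FALSE)
    }
    raw[[col]] <- v
  }
  out <- tibble::as_tibble(raw)
  all_zero <- rowSums(as.matrix(out[eff_cols])) == 0
  if (any(all_zero)) {
    warning(sprintf("%d trap(s) have zero effort in every period", sum(all_zero)),
            call. = FALSE)
  }
  validate_traps(out)
  out
}

#' Read a long-format detection table
#'
#' Expects a CSV with columns `individual_id,trap_id,period,count`. Counts
#' are validated against the trap effort (`count <= K[j,t]`, the Binomial
#' support) and trap ids against the trap table.
#'
#' @param path CSV file path.
#' @param traps Trap tibble the detections refer to.
#' @param n_periods Number of primary periods T.
#' @return A detection tibble (rows with positive counts).
#' @export
read_detections <- function(path, traps, n_periods) {
  validate_traps(traps)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "trap_id", "period", "count")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("detection file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(raw)
  out$period <- as.integer(out$period)
  out$count <- as.integer(out$count)
  if (nrow(out) == 0) return(out)
  unknown <- which(!(out$trap_id %in% traps$trap_id))
  if (length(unknown) > 0) {
    stop(sprintf("unknown trap_id '%s' at line %d of %s",
                 out$trap_id[unknown[1]], unknown[1] + 1, path), call. = FALSE)
  }
  if (any(out$period < 1 | out$period > n_periods, na.rm = TRUE)) {
    stop("detection period outside 1..n_periods", call. = FALSE)
  }
  if (any(is.na(out$count) | out$count < 0)) {
    stop("detection counts must be non-negative integers", call. = FALSE)
  }
  Kmat <- effort_matrix(traps, n_periods)
  # aggregate duplicates before checking the Binomial support
  agg <- stats::aggregate(count ~ individual_id + trap_id + period, out, sum)
  j2 <- match(agg$trap_id, traps$trap_id)
  bad <- which(agg$count > Kmat[cbind(j2, agg$period)])
  if (length(bad) > 0) {
    stop(sprintf("count %d exceeds effort K = %d for trap %s, period %d",
                 agg$count[bad[1]], Kmat[j2[bad[1]], agg$period[bad[1]]],
                 agg$trap_id[bad[1]], agg$period[bad[1]]), call. = FALSE)
  }
  out
}

#' Write a simulated dataset to a directory
#'
#' Writes `traps.csv`, `detections.csv`, the ground truth
#' (`truth_abundance.csv`, `truth_params.json`) and a reproducibility
#' manifest (`manifest.json`).
#'
#' @param dataset An `scr_dataset` from [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "scr_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(dataset$traps, file.path(dir, "traps.csv"))
  readr::write_csv(dataset$detections, file.path(dir, "detections.csv"))
  readr::write_csv(dataset$truth$abundance, file.path(dir, "truth_abundance.csv"))
  jsonlite::write_json(
    list(phi = dataset$truth$phi, lambda0 = dataset$truth$lambda0,
         sigma_p = dataset$truth$sigma_p, sigma_s = dataset$truth$sigma_s,
         movement = dataset$truth$movement, gamma = dataset$truth$gamma),
    file.path(dir, "truth_params.json"), auto_unbox = TRUE, digits = NA
  )
  write_manifest(
    run_manifest(config = unclass(dataset$config), seed = dataset$seed,
                 kind = "simulate"),
    file.path(dir, "manifest.json")
  )
  invisible(dir)
}

#' Build a reproducibility manifest
#'
#' A manifest records everything needed to replay a run bit-identically:
#' the configuration snapshot, package version, master seed and any derived
#' seeds, and a timestamp.
#'
#' @param config Configuration list to snapshot.
#' @param seed Master seed.
#' @param kind Short run-type label.
#' @param derived_seeds Optional integer vector of per-replicate seeds.
#' @param extra Optional named list of additional entries.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, kind, derived_seeds = NULL, extra = list()) {
  structure(
    c(list(
      kind = kind,
      package_version = as.character(utils::packageVersion("openscr")),
      seed = seed,
      derived_seeds = derived_seeds,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = config
    ), extra),
    class = "run_manifest"
  )
}

#' Write a manifest as JSON
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Write posterior draws and summaries from a fit
#'
#' Writes `draws.csv` (one row per retained iteration x chain, one column
#' per scalar parameter), `summary.csv` (posterior summaries with
#' \eqn{\hat R} for multi-chain runs) and `manifest.json`.
#'
#' @param fit An `open_scr_fit`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "open_scr_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(fit$draws, file.path(dir, "draws.csv"))
  readr::write_csv(tidy(fit), file.path(dir, "summary.csv"))
  cfg <- fit$config
  cfg$S <- unclass(cfg$S)
  write_manifest(
    run_manifest(config = unclass(cfg), seed = fit$config$seed, kind = "fit",
                 extra = list(model = fit$model, n_obs = fit$n_obs,
                              flags = fit$flags)),
    file.path(dir, "manifest.json")
  )
  invisible(dir)
}
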