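TRAJECTORY_SCHEMA_VERSION <- "1.0"

# matrix-valued fields of a trajectory record, in a fixed order
trajectory_fields <- function(rec) {
  rec$data
}

#' Construct a trajectory record
#'
#' A trajectory record holds the per-frame time series of a closed-loop run:
#' body node positions, oscillator phases, per-oscillator smoothed curvature,
#' binary activations, and per-segment muscle states, plus run metadata. The
#' top-level `time`, `com`, `tail_y` and `L` fields make the record directly
#' consumable by the kinematic metrics ([swimming_speed()],
#' [tailbeat_metrics()]).
#'
#' @param data Named list of equal-row matrices (one row per frame).
#' @param meta Named list of run metadata (must include `L`).
#' @return An object of class `trajectory_record`.
#' @export
trajectory_record <- function(data, meta) {
  nr <- unique(vapply(data, nrow, integer(1)))
  if (length(nr) != 1) stop("trajectory fields have differing frame counts",
                            call. = FALSE)
  structure(
    list(data = data, meta = meta,
         time = as.vector(data$time),
         com = data$com, tail_y = as.vector(data$tail_y), L = meta$L),
    class = "trajectory_record"
  )
}

#' Write a trajectory record to a directory of CSV files
#'
#' One CSV per field plus a JSON manifest holding the schema version, field
#' dimensions and metadata. The round trip through [read_trajectory()] is
#' lossless up to double-precision text formatting.
#'
#' @param rec A `trajectory_record`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    schema_version = TRAJECTORY_SCHEMA_VERSION,
    fields = lapply(rec$data, function(m) list(nrow = nrow(m), ncol = ncol(m))),
    meta = rec$meta
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (f in names(rec$data)) {
    data.table::fwrite(data.table::as.data.table(rec$data[[f]]),
                       file.path(path, paste0(f, ".csv")))
  }
  invisible(path)
}

#' Read a trajectory record, optionally frame-by-frame
#'
#' Validates the manifest's schema version and field dimensions; a truncated
#' file is a clean error, not a partial parse. `frames` selects a subset of
#' frames; a contiguous range is streamed from disk without loading the whole
#' file.
#'
#' @param path Directory written by [write_trajectory()].
#' @param frames Optional integer vector of frame indices (1-based).
#' @return A `trajectory_record`.
#' @export
read_trajectory <- function(path, frames = NULL) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no trajectory manifest at ", path, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$schema_version, TRAJECTORY_SCHEMA_VERSION)) {
    stop("trajectory schema version mismatch: found ",
         manifest$schema_version, ", expected ", TRAJECTORY_SCHEMA_VERSION,
         call. = FALSE)
  }
  contiguous <- !is.null(frames) &&
    all(diff(sort(frames)) == 1)
  data <- list()
  for (f in names(manifest$fields)) {
    dims <- manifest$fields[[f]]
    fp <- file.path(path, paste0(f, ".csv"))
    if (!file.exists(fp)) stop("missing trajectory field file: ", f,
                               call. = FALSE)
    if (contiguous) {
      fr <- sort(frames)
      dt <- data.table::fread(fp, skip = fr[1], nrows = length(fr),
                              header = FALSE)
      if (nrow(dt) != length(fr)) {
        stop("truncated trajectory field '", f, "'", call. = FALSE)
      }
      m <- as.matrix(dt)
    } else {
      dt <- data.table::fread(fp)
      if (nrow(dt) != dims$nrow) {
        stop("truncated trajectory field '", f, "': ", nrow(dt), " of ",
             dims$nrow, " frames present", call. = FALSE)
      }
      m <- as.matrix(dt)
      if (!is.null(frames)) m <- m[frames, , drop = FALSE]
    }
    if (ncol(m) != dims$ncol) {
      stop("truncated trajectory field '", f, "' (column count mismatch)",
           call. = FALSE)
    }
    dimnames(m) <- NULL
    data[[f]] <- m
  }
  trajectory_record(data, manifest$meta)
}
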