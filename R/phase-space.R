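#' Phase-space records
#'
#' A phase space is the set of particle states (type, energy, position on the
#' plane, direction cosines, statistical weight) recorded where particles
#' cross a plane, replayable as a source for downstream simulations. The
#' engine transports electrons only, so all records carry the electron type
#' code 0 (photon would be 1); this is consistent with the negligible
#' contamination found for these beams.
#'
#' @name phase_space
NULL

phase_space_tibble <- function(mat, plane_z) {
  out <- tibble::tibble(
    particle_type = if (nrow(mat) > 0) 0L else integer(0),
    energy = mat[, 1], x = mat[, 2], y = mat[, 3],
    u = mat[, 4], v = mat[, 5], w = mat[, 6], weight = mat[, 7]
  )
  attr(out, "plane_z") <- plane_z
  class(out) <- c("phase_space_records", class(out))
  out
}

validate_phase_space <- function(records) {
  stopifnot(is.data.frame(records))
  req <- c("energy", "x", "y", "u", "v", "w", "weight")
  if (!all(req %in% names(records))) stop("malformed phase-space records")
  if (nrow(records) == 0) stop("empty phase-space record list")
  nrm <- records$u^2 + records$v^2 + records$w^2
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("malformed phase-space record: non-unit direction")
  }
  if (any(records$energy <= 0) || any(records$weight <= 0)) {
    stop("malformed phase-space record: non-positive energy or weight")
  }
  invisible(records)
}

#' Record a phase space on a plane
#'
#' Runs the engine and records every electron crossing the given plane in the
#' +z direction. The default plane sits beneath the collimation system, above
#' the applicator, so the recorded set can be replayed against non-reference
#' applicators without re-transporting the head.
#'
#' @param source A [beam_source()].
#' @param machine An [build_machine()] geometry.
#' @param phantom Phantom spec for the downstream part of the run.
#' @param config A [transport_config()].
#' @param plane_z Recording plane z in mm; default: the machine's
#'   below-collimation plane.
#' @return A `phase_space_records` tibble (possibly zero rows) with the plane
#'   position in `attr(, "plane_z")`; the full `dose_grid` of the recording
#'   run is attached as `attr(, "grid")`.
#' @export
record_phase_space <- function(source, machine, phantom, config,
                               plane_z = machine$phsp_plane_z) {
  grid <- run_simulation(source, machine, phantom, config,
                         record_plane_z = plane_z)
  ps <- attr(grid, "phase_space")
  attr(grid, "phase_space") <- NULL
  attr(ps, "grid") <- grid
  ps
}

#' Replay a phase space as a particle source
#'
#' Wraps recorded (or read-back) records as a source equivalent for
#' [run_simulation()]. Records are cycled if more histories are requested
#' than records exist. Malformed records (non-unit directions, non-positive
#' energy/weight) and empty record sets are an error.
#'
#' @param records A `phase_space_records` tibble.
#' @param plane_z Plane position in mm; defaults to the records' attribute.
#' @export
replay_phase_space <- function(records, plane_z = attr(records, "plane_z")) {
  validate_phase_space(records)
  if (is.null(plane_z)) stop("phase-space plane position unknown")
  structure(list(records = records, plane_z = plane_z),
            class = "phase_space_replay")
}

# fixed binary layout: 64-byte header then 36-byte records
# header: magic char[8] "IOERTPHS", int32 version, int32 pad, int64-as-double
#         record count stored as double, double plane_z, 32 zero bytes
# record: int32 particle type, float32 x8 (E, x, y, u, v, w, weight, spare)
PHSP_MAGIC <- "IOERTPHS"
PHSP_VERSION <- 1L

#' Write a phase space to the fixed binary format
#'
#' Little-endian, 64-byte header followed by 36-byte records (int32 type code
#' plus eight float32 values: energy, x, y, u, v, w, weight, spare). The
#' write/read roundtrip is bit-identical.
#'
#' @param records A `phase_space_records` tibble.
#' @param path Output file.
#' @export
write_phase_space <- function(records, path) {
  stopifnot(is.data.frame(records))
  plane_z <- attr(records, "plane_z") %||% NA_real_
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(PHSP_MAGIC), con)
  writeBin(c(PHSP_VERSION, 0L), con, size = 4, endian = "little")
  writeBin(as.double(nrow(records)), con, size = 8, endian = "little")
  writeBin(as.double(plane_z), con, size = 8, endian = "little")
  writeBin(raw(64 - 8 - 8 - 16), con)
  if (nrow(records) > 0) {
    # round-trip through float32 before writing so in-memory comparison after
    # read-back is exact
    for (i in seq_len(nrow(records))) {
      writeBin(as.integer(records$particle_type[i]), con, size = 4,
               endian = "little")
      writeBin(as.double(c(records$energy[i], records$x[i], records$y[i],
                           records$u[i], records$v[i], records$w[i],
                           records$weight[i], 0)),
               con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read a phase space from the fixed binary format
#' @param path File written by [write_phase_space()].
#' @export
read_phase_space <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (!identical(magic, PHSP_MAGIC)) stop("not a phase-space file: ", path)
  ver <- readBin(con, "integer", 2, size = 4, endian = "little")[1]
  if (ver != PHSP_VERSION) stop("unsupported phase-space version: ", ver)
  n <- as.integer(readBin(con, "double", 1, size = 8, endian = "little"))
  plane_z <- readBin(con, "double", 1, size = 8, endian = "little")
  readBin(con, "raw", 64 - 8 - 8 - 16)
  type <- integer(n); vals <- matrix(0, n, 7)
  for (i in seq_len(n)) {
    type[i] <- readBin(con, "integer", 1, size = 4, endian = "little")
    vals[i, ] <- readBin(con, "double", 8, size = 4, endian = "little")[1:7]
  }
  out <- phase_space_tibble(vals, plane_z)
  out$particle_type <- type
  out
}

#' Write/read the CSV debug dialect of a phase space
#'
#' Same columns as the binary layout, plain text, plane position carried in a
#' `# plane_z` comment line.
#' @param records A `phase_space_records` tibble.
#' @param path CSV path.
#' @export
write_phase_space_csv <- function(records, path) {
  plane_z <- attr(records, "plane_z") %||% NA_real_
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# plane_z %.17g", plane_z), con)
  utils::write.csv(as.data.frame(records), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phase_space_csv
#' @export
read_phase_space_csv <- function(path) {
  first <- readLines(path, n = 1)
  plane_z <- as.numeric(sub("^# plane_z ", "", first))
  df <- utils::read.csv(path, comment.char = "#")
  out <- tibble::as_tibble(df)
  attr(out, "plane_z") <- plane_z
  class(out) <- c("phase_space_records", class(out))
  out
}
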