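#' Write a curve to the curve-CSV dialect
#'
#' Columns `position_mm`, `value`, `sigma`; curve metadata (axis,
#' normalization, energy, applicator) carried as `# key value` header lines.
#' Floats are written at repr-roundtrip precision so write/read roundtrips
#' are lossless.
#'
#' @param curve An `ioert_curve`.
#' @param path Output path.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "ioert_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(axis = curve_axis(curve))
  norm <- attr(curve, "normalization")
  if (!is.null(norm)) {
    hdr <- c(hdr, normalization = sprintf("%.17g %.17g",
                                          norm$position %||% NA_real_,
                                          norm$value %||% NA_real_))
  }
  if (!is.null(attr(curve, "energy"))) {
    hdr <- c(hdr, energy = as.character(attr(curve, "energy")))
  }
  if (!is.null(attr(curve, "applicator"))) {
    hdr <- c(hdr, applicator = as.character(attr(curve, "applicator")))
  }
  writeLines(sprintf("# %s %s", names(hdr), unname(hdr)), con)
  writeLines("position_mm,value,sigma", con)
  writeLines(sprintf("%.17g,%.17g,%.17g", curve$position_mm, curve$value,
                     curve$sigma), con)
  invisible(path)
}

#' Read a curve from the curve-CSV dialect
#'
#' Positions must be strictly increasing. A missing `sigma` column is read
#' as zeros with a warning.
#'
#' @param path Path written by [write_curve_csv()] (or hand-made in the same
#'   dialect).
#' @export
read_curve_csv <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (hl in hdr_lines) {
    parts <- strsplit(sub("^#\\s*", "", hl), "\\s+")[[1]]
    meta[[parts[1]]] <- paste(parts[-1], collapse = " ")
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  if (!"sigma" %in% names(df)) {
    warning("no sigma column; uncertainties read as zeros")
    df$sigma <- 0
  }
  norm <- NULL
  if (!is.null(meta$normalization)) {
    # a missing normalization position is serialized as the literal "NA"
    nv <- suppressWarnings(as.numeric(strsplit(meta$normalization, " ")[[1]]))
    norm <- list(position = if (is.na(nv[1])) NULL else nv[1], value = nv[2])
  }
  ioert_curve(df$position_mm, df$value, df$sigma,
              axis = meta$axis %||% "depth", normalization = norm,
              energy = meta$energy, applicator = meta$applicator)
}

#' Write a dose grid as a MetaImage pair
#'
#' Writes `<stem>.mhd`/`<stem>.raw` (float32, little-endian) for the energy
#' grid, `<stem>_entries.mhd`/`.raw` for the entry counts, and a
#' `<stem>.json` sidecar with run metadata (seed, histories, tallies, config
#' hash).
#'
#' @param grid A `dose_grid`.
#' @param stem Output path stem (no extension).
#' @export
write_dose_grid <- function(grid, stem) {
  stopifnot(inherits(grid, "dose_grid"))
  write_mhd(grid$energy, grid$origin, grid$spacing, paste0(stem, ".mhd"))
  write_mhd(grid$entries, grid$origin, grid$spacing,
            paste0(stem, "_entries.mhd"))
  meta <- list(seed = grid$meta$seed, n_histories = grid$meta$n_histories,
               source = grid$meta$source, applicator = grid$meta$applicator,
               tallies = as.list(grid$tallies),
               config_hash = config_hash(grid$meta))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}

#' Read a dose grid written by [write_dose_grid()]
#' @param stem Path stem used when writing.
#' @export
read_dose_grid <- function(stem) {
  e <- read_mhd(paste0(stem, ".mhd"))
  n <- read_mhd(paste0(stem, "_entries.mhd"))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  tallies <- unlist(meta$tallies)
  new_dose_grid(e$data, as.integer(round(n$data)), e$origin, e$spacing,
                dim(e$data), tallies,
                meta = list(n_histories = meta$n_histories, seed = meta$seed,
                            source = meta$source,
                            applicator = meta$applicator))
}

#' Low-level MetaImage (.mhd + .raw) writer/reader
#'
#' Minimal MetaImage support for 3D float32 volumes: a text header with the
#' standard keys and a separate raw little-endian data file.
#'
#' @param data 3D numeric array.
#' @param origin,spacing Length-3 vectors, mm.
#' @param path Path of the `.mhd` header; the `.raw` sits beside it.
#' @export
write_mhd <- function(data, origin, spacing, path) {
  stopifnot(length(dim(data)) == 3)
  raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image", "NDims = 3", "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(dim(data), collapse = " ")),
    paste("ElementSpacing =", paste(sprintf("%.17g", spacing), collapse = " ")),
    paste("Offset =", paste(sprintf("%.17g", origin), collapse = " ")),
    "ElementType = MET_FLOAT",
    paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.double(as.vector(data)), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_mhd
#' @export
read_mhd <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  getv <- function(k) vals[match(k, keys)]
  dims <- as.integer(strsplit(getv("DimSize"), " ")[[1]])
  spacing <- as.numeric(strsplit(getv("ElementSpacing"), " ")[[1]])
  origin <- as.numeric(strsplit(getv("Offset"), " ")[[1]])
  if (getv("ElementType") != "MET_FLOAT") {
    stop("only MET_FLOAT MetaImage volumes are supported")
  }
  raw_path <- file.path(dirname(path), getv("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  data <- readBin(con, "double", prod(dims), size = 4, endian = "little")
  dim(data) <- dims
  list(data = data, origin = origin, spacing = spacing)
}

config_hash <- function(x) {
  # stable content hash without extra dependencies: sum over serialized bytes
  b <- serialize(x, NULL, version = 2)
  sprintf("%08x", sum(as.integer(b) * (seq_along(b) %% 251)) %% 4294967291)
}

# ---- run configuration ------------------------------------------------

config_schema <- function() {
  list(
    beam = c("nominal_mev", "mean_energy", "sigma_e", "spot_fwhm",
             "divergence"),
    machine = c("ssf_density", "source_z_mm"),
    applicator = c("diameter_cm", "bevel_deg", "length_cm", "gap_cm"),
    phantom = c("type", "size_cm", "spacing_mm", "disk_present",
                "disk_diameter_cm", "disk_thickness_cm", "disk_offset_mm"),
    transport = c("n_histories", "seed", "max_step", "cutoff"),
    analysis = c("gamma_dose_pct", "gamma_dta_mm", "zmax_6", "zmax_9",
                 "zmax_12", "prescription_gy")
  )
}

config_defaults <- function() {
  list(
    beam = list(nominal_mev = 9, mean_energy = NA, sigma_e = NA,
                spot_fwhm = 1.6, divergence = 0),
    machine = list(ssf_density = 2.699, source_z_mm = -450),
    applicator = list(diameter_cm = 10, bevel_deg = 0, length_cm = 30,
                      gap_cm = 0),
    phantom = list(type = "water", size_cm = c(30, 30, 30), spacing_mm = 1,
                   disk_present = TRUE, disk_diameter_cm = 8,
                   disk_thickness_cm = 1, disk_offset_mm = c(0, 0)),
    transport = list(n_histories = 1e6, seed = 1, max_step = 1,
                     cutoff = 0.2),
    analysis = list(gamma_dose_pct = 3, gamma_dta_mm = 3, zmax_6 = 13,
                    zmax_9 = 18, zmax_12 = 22, prescription_gy = 21)
  )
}

#' Load and validate a run configuration
#'
#' TOML-style key-value file with `[section]` headers; values are numbers,
#' quoted strings, booleans, or `[a, b, ...]` arrays. The schema is closed:
#' unknown sections or keys are rejected by name. Defaults are filled in,
#' including the tuned spectrum for the requested nominal energy when
#' `mean_energy`/`sigma_e` are not given.
#'
#' @param path Config file path.
#' @return A validated `run_config` list of sections.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  schema <- config_schema()
  cfg <- config_defaults()
  section <- NULL
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% names(schema)) {
        stop("unknown config section: [", section, "]")
      }
      next
    }
    if (is.null(section)) stop("config key outside any section: ", ln)
    kv <- strsplit(ln, "\\s*=\\s*")[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- kv[1]
    if (!key %in% schema[[section]]) {
      stop("unknown config key: ", section, ".", key)
    }
    cfg[[section]][[key]] <- parse_config_value(kv[2])
  }
  if (is.na(cfg$beam$mean_energy) || is.na(cfg$beam$sigma_e)) {
    p <- beam_presets()
    row <- p[p$nominal_mev == cfg$beam$nominal_mev, ]
    if (nrow(row) != 1) {
      stop("no preset spectrum for nominal energy ", cfg$beam$nominal_mev)
    }
    if (is.na(cfg$beam$mean_energy)) cfg$beam$mean_energy <- row$mean_energy
    if (is.na(cfg$beam$sigma_e)) cfg$beam$sigma_e <- row$sigma_e
  }
  structure(cfg, class = "run_config")
}

parse_config_value <- function(s) {
  s <- trimws(s)
  if (grepl("^\\[.*\\]$", s)) {
    return(vapply(strsplit(sub("^\\[(.*)\\]$", "\\1", s), ",")[[1]],
                  function(x) parse_config_value(x), numeric(1),
                  USE.NAMES = FALSE))
  }
  if (grepl('^".*"$', s)) return(sub('^"(.*)"$', "\\1", s))
  if (s %in% c("true", "TRUE")) return(TRUE)
  if (s %in% c("false", "FALSE")) return(FALSE)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) return(s)
  v
}

#' Serialize a run configuration back to its file dialect
#' @param cfg A `run_config`.
#' @param path Output path.
#' @export
dump_config <- function(cfg, path) {
  out <- character(0)
  for (section in names(cfg)) {
    out <- c(out, sprintf("[%s]", section))
    for (key in names(cfg[[section]])) {
      v <- cfg[[section]][[key]]
      s <- if (is.character(v)) sprintf('"%s"', v)
      else if (is.logical(v)) tolower(as.character(v))
      else if (length(v) > 1) {
        sprintf("[%s]", paste(sprintf("%.17g", v), collapse = ", "))
      } else sprintf("%.17g", v)
      out <- c(out, sprintf("%s = %s", key, s))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
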