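MANIFEST_VERSION <- "cinebands-manifest-1"
SIDECAR_FIELDS <- c("offset_hz", "tr_ms", "te_ms", "flip_deg", "pe_axis")

#' Write a cine movie to NIfTI with a JSON sidecar
#'
#' The movie is stored as a 4D NIfTI (row, col, 1, phase) in double
#' precision so that a write/read round-trip is bitwise lossless; the
#' acquisition metadata (offset, TR, TE, flip angle, PE axis) goes into a
#' `<path>.json` sidecar.
#'
#' @param movie a `cine_movie`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "cine_movie"))
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop("unknown extension for '", path, "': expected .nii or .nii.gz")
  }
  d <- dim(movie$data)
  vol <- array(aperm(movie$data, c(2, 3, 1)), dim = c(d[2], d[3], 1, d[1]))
  RNifti::writeNifti(vol, path, datatype = "double")
  meta <- list(format_version = MANIFEST_VERSION, offset_hz = movie$offset_hz,
               tr_ms = movie$tr_ms, te_ms = movie$te_ms,
               flip_deg = movie$flip_deg, pe_axis = movie$pe_axis)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cine movie written by [write_movie()]
#'
#' Accepts 4D NIfTI (phases in the 4th dimension) or 3D single-phase
#' volumes, which are promoted to one cardiac phase with a warning. The
#' JSON sidecar is required and validated field by field.
#'
#' @param path path to the `.nii`/`.nii.gz` file.
#' @return a `cine_movie`.
#' @export
read_movie <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop("unknown extension for '", path, "': expected .nii or .nii.gz")
  }
  if (!file.exists(path)) stop("no such file: ", path)
  vol <- as.array(RNifti::readNifti(path))
  d <- dim(vol)
  if (length(d) == 2) {
    warning("2D input promoted to a single-phase movie")
    data <- array(vol, dim = c(1, d[1], d[2]))
  } else if (length(d) == 3) {
    if (d[3] != 1) stop("3D volume with ", d[3],
                        " slices: expected single-slice (row, col, 1[, phase]) layout")
    warning("3D single-phase input promoted to (1, H, W)")
    data <- array(vol[, , 1], dim = c(1, d[1], d[2]))
  } else if (length(d) == 4) {
    if (d[3] != 1) stop("expected a single-slice 4D volume (row, col, 1, phase)")
    data <- aperm(array(vol, dim = c(d[1], d[2], d[4])), c(3, 1, 2))
  } else stop("volume must be 2D, 3D or 4D, got ", length(d), "D")
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in SIDECAR_FIELDS) {
    if (is.null(meta[[f]])) stop("sidecar ", sidecar, " is missing field '", f, "'")
  }
  new_cine_movie(data, meta$offset_hz, meta$tr_ms, meta$te_ms, meta$flip_deg,
                 meta$pe_axis)
}

# Tiny FNV-1a content hash for provenance stamping (hex string). The
# 32-bit state is kept in a double, so the xor touches only the low byte
# and the multiply is split to stay inside exact double-integer range.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))  # hex of the low 31 bits
}

#' Save a sweep collection to disk
#'
#' Writes one NIfTI (+ sidecar) per movie and a JSON manifest listing every
#' movie with its subject/slice/offset, the generator seed and a config
#' hash for provenance.
#'
#' @param collection a `sweep_collection`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
save_dataset <- function(collection, dir) {
  stopifnot(inherits(collection, "sweep_collection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- collection$manifest
  man$path <- file.path(dir, paste0(man$movie_id, ".nii.gz"))
  for (r in seq_len(nrow(man))) {
    sw <- collection$sweeps[[man$sweep_index[r]]]
    write_movie(sw$movies[[man$movie_index[r]]], man$path[r])
  }
  manifest <- list(format_version = MANIFEST_VERSION,
                   seed = collection$seed,
                   config_hash = fnv1a_hash(collection$config),
                   records = man)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(mp)
}

#' Load frequency sweeps from a saved manifest
#'
#' Validates the manifest version, that every referenced file exists, and
#' that offsets are unique within each (subject, slice).
#'
#' @param manifest_path path to `manifest.json`.
#' @return list of class `sweep_collection` (without scenes) with `sweeps`
#'   and `manifest`.
#' @export
load_dataset <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(man$format_version, MANIFEST_VERSION)) {
    stop("unrecognized manifest version: ", man$format_version)
  }
  rec <- man$records
  missing <- rec$path[!file.exists(rec$path)]
  if (length(missing) > 0) {
    stop("manifest references missing files: ", paste(missing, collapse = ", "))
  }
  dup <- duplicated(rec[, c("subject", "slice", "offset_hz")])
  if (any(dup)) stop("duplicate offsets within a (subject, slice) sweep")
  sweeps <- lapply(split(seq_len(nrow(rec)), rec$sweep_index), function(ix) {
    new_frequency_sweep(lapply(rec$path[ix], read_movie))
  })
  structure(list(sweeps = unname(sweeps), manifest = rec,
                 seed = man$seed, config = NULL),
            class = "sweep_collection")
}
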