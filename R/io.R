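# Minimal NIfTI-1 and MetaImage readers/writers.
#
# Scope: single-file .nii / .nii.gz (and .mhd/.raw, .mha with LOCAL data),
# 3D scalar volumes plus 3-component displacement fields, little-endian on
# write, either endianness on read.  Geometry: diagonal index->mm affine
# (spacing on the diagonal, origin in the translation column, sform code
# 1); no reorientation logic -- inputs are assumed co-registered.

nifti_datatypes <- c(`2` = "uint8", `4` = "int16", `8` = "int32",
                     `16` = "float32", `64` = "float64")

open_conn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

write_nifti <- function(voxels, spacing, origin, path, datatype = "float32",
                        ncomp = 1L, description = "") {
  d <- dim(voxels)[1:3]
  con <- open_conn(path, "wb")
  on.exit(close(con))
  wB <- function(x, size, what = "integer")
    writeBin(if (what == "integer") as.integer(x) else as.numeric(x),
             con, size = size, endian = "little")
  wB(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  dimv <- c(if (ncomp > 1L) 5L else 3L, d[1], d[2], d[3], 1L,
            if (ncomp > 1L) ncomp else 1L, 1L, 1L)
  wB(dimv, 2)                                   # dim[8]
  wB(c(0, 0, 0), 4, "double")                   # intent_p1..p3
  wB(if (ncomp > 1L) 1007L else 0L, 2)          # intent_code (vector)
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("write_nifti: unsupported datatype ", datatype))
  bitpix <- switch(datatype, uint8 = 8L, int16 = 16L, int32 = 32L,
                   float32 = 32L, float64 = 64L)
  wB(code, 2); wB(bitpix, 2); wB(0L, 2)         # datatype, bitpix, slice_start
  wB(c(1, spacing, 1, 1, 1, 1), 4, "double")    # pixdim[8] (qfac 1)
  wB(352, 4, "double")                          # vox_offset
  wB(c(1, 0), 4, "double")                      # scl_slope, scl_inter
  wB(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt_units
  wB(c(0, 0, 0), 4, "double")                   # cal_max, cal_min, slice_duration
  wB(0, 4, "double"); wB(c(0L, 0L), 4)          # toffset, glmax, glmin
  desc <- charToRaw(substr(description, 1, 79))
  writeBin(c(desc, raw(80 - length(desc))), con)
  writeBin(raw(24), con)                        # aux_file
  wB(c(0L, 1L), 2)                              # qform_code 0, sform_code 1
  wB(rep(0, 6), 4, "double")                    # quatern b,c,d, qoffset x,y,z
  wB(c(spacing[1], 0, 0, origin[1]), 4, "double")
  wB(c(0, spacing[2], 0, origin[2]), 4, "double")
  wB(c(0, 0, spacing[3], origin[3]), 4, "double")
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  writeBin(raw(4), con)                         # extension flag
  dat <- as.numeric(voxels)
  if (datatype %in% c("uint8", "int16", "int32"))
    writeBin(as.integer(round(dat)), con, size = bitpix / 8, endian = "little")
  else
    writeBin(dat, con, size = bitpix / 8, endian = "little")
  invisible(path)
}

read_nifti <- function(path) {
  con <- open_conn(path, "rb")
  on.exit(close(con))
  endian <- "little"
  szh <- readBin(con, "integer", 1, 4, endian = endian)
  if (szh != 348L) {
    if (szh != 1543503872L)  # 348 with swapped bytes
      stop("read_nifti: corrupt header in ", path)
    endian <- "big"
  }
  readBin(con, "raw", 36)
  dimv <- readBin(con, "integer", 8, 2, endian = endian)
  readBin(con, "double", 3, 4, endian = endian)
  readBin(con, "integer", 1, 2, endian = endian)       # intent_code
  dtype <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "integer", 2, 2, endian = endian)       # bitpix, slice_start
  pixdim <- readBin(con, "double", 8, 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, 4, endian = endian)
  scl <- readBin(con, "double", 2, 4, endian = endian)
  readBin(con, "raw", 4)                               # slice_end..xyzt_units
  readBin(con, "double", 4, 4, endian = endian)
  readBin(con, "integer", 2, 4, endian = endian)
  readBin(con, "raw", 104)                             # descrip + aux_file
  readBin(con, "integer", 2, 2, endian = endian)       # qform, sform codes
  readBin(con, "double", 6, 4, endian = endian)
  srow <- matrix(readBin(con, "double", 12, 4, endian = endian), nrow = 3,
                 byrow = TRUE)
  readBin(con, "raw", 16)
  magic <- rawToChar(readBin(con, "raw", 4)[1:3])
  if (!magic %in% c("n+1", "ni1")) stop("read_nifti: bad magic in ", path)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  dtname <- nifti_datatypes[as.character(dtype)]
  if (is.na(dtname)) stop("read_nifti: unsupported datatype code ", dtype)
  d <- dimv[2:4]
  ncomp <- if (dimv[1] >= 5 && dimv[6] > 1) dimv[6] else 1L
  n <- prod(d) * ncomp
  dat <- switch(dtname,
    uint8 = as.numeric(readBin(con, "integer", n, 1, signed = FALSE)),
    int16 = as.numeric(readBin(con, "integer", n, 2, endian = endian)),
    int32 = as.numeric(readBin(con, "integer", n, 4, endian = endian)),
    float32 = readBin(con, "double", n, 4, endian = endian),
    float64 = readBin(con, "double", n, 8, endian = endian))
  if (length(dat) < n) stop("read_nifti: truncated data in ", path)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) dat <- dat * scl[1] + scl[2]
  spacing <- pixdim[2:4]
  origin <- srow[, 4]
  if (all(srow == 0)) origin <- c(0, 0, 0)
  list(data = dat, dim = d, ncomp = ncomp, spacing = spacing, origin = origin)
}

meta_types <- c(MET_UCHAR = "uint8", MET_SHORT = "int16", MET_INT = "int32",
                MET_FLOAT = "float32", MET_DOUBLE = "float64")

write_meta <- function(voxels, spacing, origin, path, datatype = "float32") {
  d <- dim(voxels)[1:3]
  mt <- names(meta_types)[match(datatype, meta_types)]
  is_mha <- grepl("\\.mha$", path)
  datafile <- if (is_mha) "LOCAL" else sub("\\.mhd$", ".raw", basename(path))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =", paste(spacing, collapse = " ")),
           paste("Offset =", paste(origin, collapse = " ")),
           paste("ElementType =", mt),
           paste("ElementDataFile =", datafile))
  size <- switch(datatype, uint8 = 1L, int16 = 2L, int32 = 4L,
                 float32 = 4L, float64 = 8L)
  dat <- as.numeric(voxels)
  write_payload <- function(con) {
    if (datatype %in% c("uint8", "int16", "int32"))
      writeBin(as.integer(round(dat)), con, size = size, endian = "little")
    else writeBin(dat, con, size = size, endian = "little")
  }
  if (is_mha) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    write_payload(con)
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), datafile), "wb"); on.exit(close(con))
    write_payload(con)
  }
  invisible(path)
}

read_meta <- function(path) {
  is_mha <- grepl("\\.mha$", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- character()
    repeat {                     # readLines on binary conn is unreliable; scan bytes
      ch <- readBin(con, "raw", 1)
      if (length(ch) == 0 || ch == as.raw(10)) break
      line <- c(line, rawToChar(ch))
    }
    line <- paste(line, collapse = "")
    if (!nzchar(line) && length(ch) == 0) break
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
  }
  kv <- strsplit(hdr, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " = "), "")
  getv <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  d <- as.integer(strsplit(getv("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(getv("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(getv("Offset", "0 0 0"), "\\s+")[[1]])
  mt <- getv("ElementType")
  dtname <- meta_types[mt]
  if (is.na(dtname)) stop("read_meta: unsupported ElementType ", mt)
  endian <- if (identical(getv("BinaryDataByteOrderMSB", "False"), "True"))
    "big" else "little"
  datafile <- getv("ElementDataFile")
  n <- prod(d)
  read_payload <- function(dcon) {
    switch(dtname,
      uint8 = as.numeric(readBin(dcon, "integer", n, 1, signed = FALSE)),
      int16 = as.numeric(readBin(dcon, "integer", n, 2, endian = endian)),
      int32 = as.numeric(readBin(dcon, "integer", n, 4, endian = endian)),
      float32 = readBin(dcon, "double", n, 4, endian = endian),
      float64 = readBin(dcon, "double", n, 8, endian = endian))
  }
  dat <- if (identical(datafile, "LOCAL")) read_payload(con)
  else {
    dcon <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(dcon), add = TRUE)
    read_payload(dcon)
  }
  if (length(dat) < n) stop("read_meta: truncated data in ", path)
  list(data = dat, dim = d, ncomp = 1L, spacing = spacing, origin = origin)
}

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.(mhd|mha)$", path)) "meta"
  else stop("unsupported volume extension: ", path,
            " (expected .nii, .nii.gz, .mhd or .mha)")
}

#' Read a 3D scalar volume (NIfTI or MetaImage)
#'
#' @param path file ending in `.nii`, `.nii.gz`, `.mhd` or `.mha`.
#' @return An [image3d()] with spacing/origin from the header.
#' @export
read_volume <- function(path) {
  fmt <- volume_format(path)
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  r <- switch(fmt, nifti = read_nifti(path), meta = read_meta(path))
  if (r$ncomp != 1L)
    stop("read_volume: ", path, " has ", r$ncomp,
         " components; use read_field() for vector volumes")
  image3d(array(r$data, dim = r$dim), r$spacing, r$origin)
}

#' Write a 3D scalar volume (NIfTI or MetaImage)
#'
#' Volumes are stored float32 by default; pass `datatype = "uint8"` for
#' masks.
#'
#' @param img an [image3d()] or [binary_mask()].
#' @param path output file (`.nii`, `.nii.gz`, `.mhd`, `.mha`).
#' @param datatype on-disk element type.
#' @export
write_volume <- function(img, path, datatype = NULL) {
  if (is.null(datatype))
    datatype <- if (inherits(img, "binmask")) "uint8" else "float32"
  switch(volume_format(path),
         nifti = write_nifti(img$voxels, img$spacing, img$origin, path,
                             datatype),
         meta = write_meta(img$voxels, img$spacing, img$origin, path,
                           datatype))
  invisible(path)
}

#' Read a displacement field from a 3-component vector NIfTI
#'
#' Components are the x, y, z displacements in mm on the fixed grid, in
#' that order along the 5th NIfTI dimension.
#'
#' @param path `.nii` / `.nii.gz` file written by [write_field()].
#' @return A [displacement_field()].
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("read_field: file not found: ", path)
  if (volume_format(path) != "nifti")
    stop("read_field: displacement fields are stored as vector NIfTI")
  r <- read_nifti(path)
  if (r$ncomp != 3L)
    stop("read_field: expected 3 components, found ", r$ncomp, " in ", path)
  displacement_field(array(r$data, dim = c(r$dim, 3L)), r$spacing, r$origin)
}

#' Write a displacement field as a 3-component vector NIfTI
#'
#' @param field a [displacement_field()].
#' @param path output `.nii` / `.nii.gz`.
#' @export
write_field <- function(field, path) {
  if (volume_format(path) != "nifti")
    stop("write_field: displacement fields are stored as vector NIfTI")
  write_nifti(field$vectors, field$spacing, field$origin, path,
              datatype = "float32", ncomp = 3L,
              description = "displacement x,y,z in mm on the fixed grid")
  invisible(path)
}

#' Read landmarks from CSV (`label,x_mm,y_mm,z_mm`, header required)
#' @param path CSV file.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("read_landmarks: file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("read_landmarks: header must contain ", paste(need, collapse = ","))
  for (cc in c("x_mm", "y_mm", "z_mm"))
    if (nrow(df) && (!is.numeric(df[[cc]]) || any(!is.finite(df[[cc]]))))
      stop("read_landmarks: non-numeric coordinates in column ", cc)
  landmark_set(df$label, df$x_mm, df$y_mm, df$z_mm)
}

#' Write landmarks to CSV
#' @param lm a [landmark_set()].
#' @param path output CSV.
#' @export
write_landmarks <- function(lm, path) {
  write.csv(as.data.frame(lm)[, c("label", "x_mm", "y_mm", "z_mm")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a registration report (and its config) to JSON
#'
#' The resolved configuration, package version and a config hash are
#' embedded so a run is reproducible from the report alone.
#'
#' @param report a `registration_report` or the `report` element of a
#'   [register_hybrid()] result.
#' @param path output `.json`.
#' @param config optional resolved configuration list to embed.
#' @export
write_report <- function(report, path, config = NULL) {
  payload <- unclass(report)
  payload$package_version <- as.character(utils::packageVersion("hybridreg"))
  if (!is.null(config)) {
    payload$config <- config
    payload$config_hash <- config_hash(config)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, force = TRUE)
  invisible(path)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  # tiny polynomial rolling hash; enough to fingerprint a config without
  # extra dependencies
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Export an iteration trace as CSV
#' @param trace data.frame trace from a stage or pipeline result.
#' @param path output CSV.
#' @export
write_trace <- function(trace, path) {
  write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
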