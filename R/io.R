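# Minimal readers/writers for the real-data path. No NIfTI or
# streamline package ships with the target environment, so the package
# carries small, documented implementations of the two formats it needs:
# uncompressed (or gzipped) single-file NIfTI-1 volumes and MRtrix .tck
# streamline files. Both are validated against nibabel in the test suite.

nifti_dtypes <- list(`2` = list(what = "integer", size = 1L, signed = FALSE),
                     `4` = list(what = "integer", size = 2L, signed = TRUE),
                     `8` = list(what = "integer", size = 4L, signed = TRUE),
                     `16` = list(what = "double", size = 4L, signed = TRUE),
                     `64` = list(what = "double", size = 8L, signed = TRUE))

#' Write a 3D volume as a NIfTI-1 file
#'
#' Single-file little-endian NIfTI-1 (`.nii`, or gzipped when the path
#' ends in `.gz`), with a diagonal sform/qform affine of `voxel_size_mm`.
#' Integer arrays are stored as int16 (datatype 4), doubles as float32
#' (datatype 16).
#'
#' @param vol 3D array (numeric or integer/logical).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm voxel edge length in mm.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, voxel_size_mm = 1) {
  dims <- dim(vol)
  assert_that(length(dims) == 3, "expected a 3D volume")
  int_data <- is.logical(vol) || is.integer(vol) ||
    all(vol == round(vol))
  datatype <- if (int_data) 4L else 16L
  bitpix <- if (int_data) 16L else 32L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # unused / dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2)            # dim[8]
  writeBin(raw(14), con)                        # intent_p1..3, intent_code
  wi(datatype, 2); wi(bitpix, 2); wi(0L, 2)     # datatype, bitpix, slice_start
  wf(c(1, rep(voxel_size_mm, 3), 0, 0, 0, 0))   # pixdim[8]
  wf(352); wf(1); wf(0)                         # vox_offset, scl_slope, scl_inter
  wi(0L, 2)                                     # slice_end
  writeBin(as.raw(c(0x00, 0x0a)), con)          # slice_code, xyzt_units mm|s
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4)           # cal_max/min, slice_dur, toffset, glmax/min
  writeBin(charToRaw(sprintf("%-80s", "chacomed")), con)  # descrip
  writeBin(raw(24), con)                        # aux_file
  wi(c(1L, 1L), 2)                              # qform_code, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                       # quaternion b c d, offsets
  wf(c(voxel_size_mm, 0, 0, 0))                 # srow_x
  wf(c(0, voxel_size_mm, 0, 0))                 # srow_y
  wf(c(0, 0, voxel_size_mm, 0))                 # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  writeBin(raw(4), con)                         # extension flag
  if (int_data) wi(as.vector(vol), 2) else wf(as.vector(vol))
  invisible(path)
}

#' Read a single-file NIfTI-1 volume
#'
#' Supports little- and big-endian files with datatypes uint8, int16,
#' int32, float32, float64, no compression or gzip, scl slope/intercept
#' applied when set.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list: `data` (3D array), `voxel_size_mm` (first pixdim),
#'   `dim`, `datatype`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
  }
  assert_that(sz == 348L, "not a NIfTI-1 file (bad sizeof_hdr)",
              class = "chacomed_io")
  rd <- function(off, what, n, size)
    readBin(hdr[(off + 1):length(hdr)], what, n, size, endian = endian,
            signed = !(what == "integer" && size == 1))
  dims_all <- rd(40, "integer", 8, 2)
  ndim <- dims_all[1]
  dims <- dims_all[2:(1 + max(ndim, 3))]
  dims[dims == 0] <- 1L
  datatype <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  spec <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(spec))
    stop_chacomed("unsupported NIfTI datatype ", datatype,
                  class = "chacomed_io")
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims[1:3])
  data <- readBin(con, spec$what, n, spec$size, signed = spec$signed,
                  endian = endian)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 &&
                                               scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, dim = dims[1:3]), voxel_size_mm = pixdim[2],
       dim = dims[1:3], datatype = datatype)
}

#' Write streamlines to an MRtrix .tck file
#'
#' Voxel paths are mapped to mm coordinates with the diagonal affine
#' `(voxel - 1) * voxel_size_mm` (matching [write_nifti()]'s sform) and
#' stored as Float32LE triplets, streamlines separated by NaN triplets and
#' terminated by an Inf triplet.
#'
#' @param tg a [tractogram()] (voxel paths).
#' @param path output `.tck` path.
#' @param voxel_size_mm voxel edge length.
#' @return `path`, invisibly.
#' @export
write_tck <- function(tg, path, voxel_size_mm = 1) {
  hdr <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                length(tg$streamlines), "\nchacomed_subject: ",
                tg$subject_id, "\n")
  # offset must include its own line; fixed-width field keeps it stable
  file_line <- sprintf("file: . %6d\nEND\n", 0L)
  offset <- nchar(hdr) + nchar(file_line)
  hdr <- paste0(hdr, sprintf("file: . %6d\nEND\n", offset))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  for (s in tg$streamlines) {
    mm <- (s - 1) * voxel_size_mm
    writeBin(as.numeric(t(mm)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRtrix .tck file as a voxelized tractogram
#'
#' Streamline mm coordinates are voxelized by rounding under the diagonal
#' affine `voxel = round(mm / voxel_size_mm) + 1` (documented dialect:
#' nearest-voxel, bit-reproducible); consecutive duplicate voxels are
#' collapsed.
#'
#' @param path `.tck` file.
#' @param voxel_size_mm voxel edge length of the target grid.
#' @param subject_id id for the resulting tractogram (default: file name).
#' @return a [tractogram()].
#' @export
read_tck <- function(path, voxel_size_mm = 1, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character(0)
  repeat {
    ln <- readLines(con, 1L)
    if (!length(ln)) stop_chacomed("truncated tck header",
                                   class = "chacomed_io")
    lines <- c(lines, ln)
    if (ln == "END") break
  }
  assert_that(lines[1] == "mrtrix tracks", "not a tck file",
              class = "chacomed_io")
  dt <- sub("^datatype:\\s*", "", grep("^datatype:", lines, value = TRUE))
  assert_that(dt %in% c("Float32LE", "Float32BE"),
              "unsupported tck datatype ", class = "chacomed_io")
  endian <- if (dt == "Float32LE") "little" else "big"
  off <- as.integer(sub("^file:\\s*\\.\\s*", "",
                        grep("^file:", lines, value = TRUE)))
  seek(con, off)
  raw_f <- readBin(con, "double", n = file.size(path), size = 4L,
                   endian = endian)
  pts <- matrix(raw_f, ncol = 3L, byrow = TRUE)
  streamlines <- list()
  cur <- integer(0)
  start <- 1L
  for (i in seq_len(nrow(pts))) {
    if (all(is.infinite(pts[i, ]))) break
    if (all(is.nan(pts[i, ]))) {
      if (i > start) {
        vox <- round(pts[start:(i - 1L), , drop = FALSE] / voxel_size_mm) + 1
        storage.mode(vox) <- "integer"
        keep <- c(TRUE, rowSums(abs(diff(vox))) > 0)
        streamlines[[length(streamlines) + 1L]] <- vox[keep, , drop = FALSE]
      }
      start <- i + 1L
    }
  }
  tractogram(subject_id %||% basename(path), streamlines)
}

#' Write the cohort table as CSV
#'
#' @param cohort a [generate_cohort()] result.
#' @param path output path.
#' @param full include mediator columns (default) or only the compact
#'   clinical table (id, arm, age, nihss, volumes, favorable).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, full = TRUE) {
  tab <- cohort$table
  if (!full)
    tab <- tab[, c("id", "arm", "age", "nihss", "vol_T1", "vol_T2",
                   "favorable")]
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Expects at least `id, arm, age, nihss, vol_T1, vol_T2, favorable`;
#' `log2_growth`, `log_vol_T1` and any `dchaco_*` columns are recomputed
#' or carried through. Returns a `cohort` in tabular mode.
#'
#' @param path CSV path.
#' @return a `cohort` object (without generator params).
#' @export
read_cohort_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "arm", "age", "nihss", "vol_T1", "vol_T2", "favorable")
  assert_that(all(need %in% names(tab)),
              "cohort CSV missing required columns: ",
              paste(setdiff(need, names(tab)), collapse = ", "),
              class = "chacomed_io")
  if (is.null(tab$log2_growth))
    tab$log2_growth <- log2(pmax(tab$vol_T2, 5e-4) / pmax(tab$vol_T1, 5e-4))
  tab$log_vol_T1 <- log(pmax(tab$vol_T1, 5e-4))
  structure(list(table = tab, patients = NULL, mode = "tabular",
                 params = NULL, seed = NA_integer_,
                 parcellation_id = NA, provenance = list(source = path)),
            class = "cohort")
}

#' Write a parcellation as NIfTI labels plus a region table CSV
#'
#' @param parcellation a [make_parcellation()] result.
#' @param nii_path label volume output (`.nii`).
#' @param csv_path region table output.
#' @return invisibly, both paths.
#' @export
write_parcellation <- function(parcellation, nii_path, csv_path) {
  write_nifti(parcellation$labels, nii_path, parcellation$voxel_size_mm)
  write.csv(parcellation$regions, csv_path, row.names = FALSE)
  invisible(c(nii_path, csv_path))
}

#' Read a parcellation from NIfTI labels plus a region table CSV
#'
#' Voxel hemisphere assignment for unlabelled voxels is by midline split on
#' the first axis; labelled voxels inherit their region's hemisphere.
#'
#' @param nii_path label volume (`.nii`/`.nii.gz`).
#' @param csv_path region table with `id`, `name`, `hemisphere`, `lobe`.
#' @return a `parcellation` object.
#' @export
read_parcellation_nifti <- function(nii_path, csv_path) {
  vol <- read_nifti(nii_path)
  regions <- read.csv(csv_path, stringsAsFactors = FALSE)
  assert_that(all(c("id", "name", "hemisphere") %in% names(regions)),
              "region table missing id/name/hemisphere",
              class = "chacomed_io")
  labels <- array(as.integer(vol$data), dim = vol$dim)
  dims <- dim(labels)
  hemi <- array("R", dims)
  hemi[seq_len(dims[1] %/% 2), , ] <- "L"
  lab_pos <- labels > 0
  hemi[lab_pos] <- regions$hemisphere[match(labels[lab_pos], regions$id)]
  structure(list(labels = labels, regions = regions,
                 voxel_size_mm = vol$voxel_size_mm, hemi_of_voxel = hemi),
            class = "parcellation")
}

#' Write per-subject ChaCo profiles as a long CSV
#'
#' @param profiles list of [chaco_score()] results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chaco_csv <- function(profiles, path) {
  rows <- lapply(profiles, function(pr)
    data.frame(subject = pr$subject_id, time = pr$time,
               region = names(pr$scores), score = unname(pr$scores),
               stringsAsFactors = FALSE))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
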