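#' Read a dynamic 2D+t image series
#'
#' Accepts a NIfTI file (frames stacked on the third axis, frame interval
#' taken from the third pixdim when positive) or a directory of
#' single-frame DICOM files (uncompressed, explicit VR little endian),
#' ordered temporally by instance number.
#'
#' @param path NIfTI file or DICOM directory.
#' @param dt Fallback frame interval in seconds when the metadata carries
#'   none.
#' @return An [image_series()].
#' @export
read_image_series <- function(path, dt = NULL) {
  if (dir.exists(path)) return(read_dicom_series(path, dt = dt))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim(arr))  # strip niftiImage attributes
  if (length(dim(arr)) < 3) {
    stop_pv("image at ", path, " has no time axis (needs >= 3 dimensions)")
  }
  if (length(dim(arr)) > 3) dim(arr) <- dim(arr)[1:3]
  pd <- RNifti::pixdim(img)
  file_dt <- if (length(pd) >= 3 && is.finite(pd[3]) && pd[3] > 0) pd[3] else NULL
  dt_use <- if (!is.null(file_dt)) file_dt else dt
  if (is.null(dt_use)) {
    stop_pv("no frame interval in ", path, " and no `dt` fallback given")
  }
  ps <- if (length(pd) >= 1 && is.finite(pd[1]) && pd[1] > 0) pd[1] else NA_real_
  image_series(arr, dt = dt_use, pixel_spacing = ps)
}

#' Write an image or mask series as NIfTI
#'
#' Frames are stacked on the third axis; the in-plane pixel spacing goes in
#' the first two pixdim slots and the frame interval in seconds in the
#' third. Masks are stored as uint8.
#'
#' @param series An [image_series()], or a 3D array (then `dt` is required).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param dt,pixel_spacing Used when `series` is a bare array.
#' @return `path`, invisibly.
#' @export
write_image_series <- function(series, path, dt = NULL, pixel_spacing = NA) {
  if (inherits(series, "image_series")) {
    arr <- series$data; dt <- series$dt; pixel_spacing <- series$pixel_spacing
  } else {
    arr <- series
    if (is.null(dt)) stop_pv("`dt` is required for a bare array")
  }
  mask <- is.logical(arr)
  if (mask) arr <- array(as.integer(arr), dim(arr))
  img <- RNifti::asNifti(arr, internal = FALSE)
  ps <- if (is.finite(pixel_spacing)) pixel_spacing else 1
  RNifti::pixdim(img) <- c(ps, ps, dt)
  RNifti::writeNifti(img, path, datatype = if (mask) "uint8" else "float")
  invisible(path)
}

#' Write a phantom to disk
#'
#' Images and both truth-mask series as NIfTI plus the generative truth
#' parameters as a JSON sidecar.
#'
#' @param phantom A `lung_phantom` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "lung_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image_series(phantom$images, file.path(dir, "images.nii.gz"))
  dt <- phantom$images$dt; ps <- phantom$images$pixel_spacing
  write_image_series(phantom$lung_truth, file.path(dir, "lung_truth.nii.gz"),
                     dt = dt, pixel_spacing = ps)
  write_image_series(phantom$vessel_truth, file.path(dir, "vessel_truth.nii.gz"),
                     dt = dt, pixel_spacing = ps)
  jsonlite::write_json(
    c(unclass(phantom$truth),
      list(n_frames = phantom$config$n_frames, dt = phantom$config$dt,
           matrix = phantom$config$matrix,
           pixel_spacing = phantom$config$pixel_spacing)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# ---- minimal DICOM support (uncompressed, explicit VR little endian) -----

dicom_tags <- list(
  instance_number = c(0x0020L, 0x0013L),
  rows = c(0x0028L, 0x0010L),
  cols = c(0x0028L, 0x0011L),
  pixel_spacing = c(0x0028L, 0x0030L),
  frame_time = c(0x0018L, 0x1063L),
  pixel_data = c(0x7FE0L, 0x0010L))

read_dicom_frame <- function(file) {
  raw <- readBin(file, "raw", n = file.info(file)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    stop_pv(file, " is not a DICOM file (missing DICM magic)")
  }
  pos <- 133L
  u16 <- function(p) readBin(raw[p:(p + 1)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(p) readBin(raw[p:(p + 3)], "integer", size = 4,
                             endian = "little")
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop_pv(file, ": implicit VR transfer syntax is not supported")
    }
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    val <- if (len > 0) raw[vstart:(vstart + len - 1L)] else raw(0)
    for (nm in names(dicom_tags)) {
      tg <- dicom_tags[[nm]]
      if (group == tg[1] && elem == tg[2]) {
        out[[nm]] <- switch(nm,
          instance_number = as.integer(trimws(rawToChar(val))),
          rows = , cols = readBin(val, "integer", size = 2,
                                  endian = "little", signed = FALSE),
          pixel_spacing = as.numeric(strsplit(trimws(rawToChar(val)),
                                              "\\\\")[[1]])[1],
          frame_time = as.numeric(trimws(rawToChar(val))),
          pixel_data = readBin(val, "integer", n = len / 2, size = 2,
                               endian = "little", signed = FALSE))
      }
    }
    pos <- vstart + len
    if (group == 0x7FE0L && elem == 0x0010L) break
  }
  for (nm in c("rows", "cols", "pixel_data")) {
    if (is.null(out[[nm]])) stop_pv(file, ": missing required DICOM tag ", nm)
  }
  out$frame <- matrix(out$pixel_data, nrow = out$rows, ncol = out$cols,
                      byrow = TRUE)
  out
}

#' Read a DICOM series as a dynamic image series
#'
#' Minimal reader for uncompressed single-frame MR DICOM files (explicit VR
#' little endian). Frames are ordered by instance number regardless of file
#' name; the frame interval comes from the frame-time tag (0018,1063, in
#' ms) when present, else from `dt`.
#'
#' @param dir Directory containing one DICOM file per frame.
#' @param dt Fallback frame interval in seconds.
#' @return An [image_series()].
#' @export
read_dicom_series <- function(dir, dt = NULL) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2) stop_pv("need at least 2 DICOM frames in ", dir)
  frames <- lapply(files, read_dicom_frame)
  inst <- vapply(frames, function(f) {
    if (is.null(f$instance_number)) NA_integer_ else f$instance_number
  }, integer(1))
  if (anyNA(inst)) stop_pv("DICOM frame without instance number in ", dir)
  frames <- frames[order(inst)]
  dims <- vapply(frames, function(f) c(f$rows, f$cols), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_pv("inconsistent frame shapes in ", dir)
  }
  ft <- frames[[1]]$frame_time
  dt_use <- if (!is.null(ft) && is.finite(ft) && ft > 0) ft / 1000 else dt
  if (is.null(dt_use)) {
    stop_pv("no frame time in DICOM headers and no `dt` fallback given")
  }
  arr <- array(0, c(dims[1, 1], dims[2, 1], length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]$frame
  ps <- frames[[1]]$pixel_spacing
  image_series(arr, dt = dt_use,
               pixel_spacing = if (is.null(ps)) NA_real_ else ps)
}

#' Write a series as single-frame DICOM files
#'
#' Minimal writer (uncompressed, explicit VR little endian, uint16 pixels;
#' intensities are rounded and clamped to \[0, 65535\]). Mainly intended
#' for constructing small synthetic test series.
#'
#' @param series An [image_series()].
#' @param dir Output directory.
#' @param instance_numbers Instance number per frame (default `1..n`); the
#'   file on disk is named after its position, not its instance number.
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(series, dir,
                               instance_numbers = seq_len(dim(series$data)[3])) {
  stopifnot(inherits(series, "image_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- dim(series$data)[3]
  if (length(instance_numbers) != nt) stop_pv("one instance number per frame")
  u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  elem_short <- function(group, el, vr, val) {
    if (length(val) %% 2 == 1) {
      val <- c(val, if (vr %in% c("IS", "DS", "CS", "UI")) charToRaw(" ") else as.raw(0))
    }
    c(u16raw(group), u16raw(el), charToRaw(vr), u16raw(length(val)), val)
  }
  elem_ow <- function(group, el, val) {
    c(u16raw(group), u16raw(el), charToRaw("OW"), as.raw(c(0, 0)),
      writeBin(length(val), raw(), size = 4, endian = "little"), val)
  }
  for (i in seq_len(nt)) {
    fr <- series$data[, , i]
    px <- as.integer(pmin(pmax(round(t(fr)), 0), 65535))  # row-major order
    pxraw <- writeBin(px, raw(), size = 2, endian = "little")
    ps <- if (is.finite(series$pixel_spacing)) series$pixel_spacing else 1
    body <- c(
      elem_short(0x0008L, 0x0060L, "CS", charToRaw("MR")),
      elem_short(0x0018L, 0x1063L, "DS",
                 charToRaw(format(series$dt * 1000, digits = 10))),
      elem_short(0x0020L, 0x0013L, "IS", charToRaw(as.character(instance_numbers[i]))),
      elem_short(0x0028L, 0x0010L, "US", u16raw(nrow(fr))),
      elem_short(0x0028L, 0x0011L, "US", u16raw(ncol(fr))),
      elem_short(0x0028L, 0x0030L, "DS", charToRaw(paste0(ps, "\\", ps))),
      elem_short(0x0028L, 0x0100L, "US", u16raw(16L)),
      elem_ow(0x7FE0L, 0x0010L, pxraw))
    con <- file(file.path(dir, sprintf("frame%04d.dcm", i)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), body), con)
    close(con)
  }
  invisible(dir)
}

# ---- metric and table serialisation --------------------------------------

#' Write dynamic metrics as JSON
#'
#' Versioned schema with units recorded per field (`%`, `% of RR-interval`,
#' `min^-1`).
#'
#' @param metrics A [dynamic_metrics()] (or `vessel_dynamics`) object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  if (inherits(metrics, "vessel_dynamics")) metrics <- metrics$metrics
  stopifnot(inherits(metrics, "dynamic_metrics"))
  u <- attr(metrics, "units")
  payload <- list(schema_version = "1.0",
                  metrics = lapply(names(metrics), function(nm) {
                    list(name = nm, value = metrics[[nm]], units = u[[nm]])
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  payload <- jsonlite::read_json(path)
  vals <- setNames(
    lapply(payload$metrics, function(m) m$value),
    vapply(payload$metrics, function(m) m$name, character(1)))
  do.call(dynamic_metrics, vals)
}

#' Write the per-frame time series of an analysis as CSV
#'
#' Columns: frame, time_s, vessel_area, lung_area, vessel_signal,
#' filtered_vessel_area, filtered_vessel_signal.
#'
#' @param fit A `vessel_dynamics` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(fit, path) {
  stopifnot(inherits(fit, "vessel_dynamics"))
  ts <- fit$series
  df <- data.frame(frame = seq_along(ts$vessel_area), time_s = ts$time,
                   vessel_area = ts$vessel_area, lung_area = ts$lung_area,
                   vessel_signal = ts$vessel_signal,
                   filtered_vessel_area = fit$filtered$vessel_area,
                   filtered_vessel_signal = fit$filtered$vessel_signal)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a repeatability table as CSV
#'
#' One row per metric with the standard repeatability-table columns:
#' `Parameter`, `SEM Intra`, `SEM Inter`, `MDC Intra`, `MDC Inter`,
#' `ICC Intra`, `ICC Inter`.
#'
#' @param rt A [repeatability_table()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_repeatability_csv <- function(rt, path) {
  stopifnot(inherits(rt, "repeatability_table"))
  tab <- rt$table
  out <- data.frame(
    Parameter = tab$metric,
    `SEM Intra` = tab$sem_intra, `SEM Inter` = tab$sem_inter,
    `MDC Intra` = tab$mdc_intra, `MDC Inter` = tab$mdc_inter,
    `ICC Intra` = tab$icc_intra, `ICC Inter` = tab$icc_inter,
    check.names = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# ---- pipeline configuration ----------------------------------------------

pipeline_defaults <- function() {
  list(
    acquisition = list(n_frames = 250L, dt = 0.384, matrix = c(128L, 128L),
                       pixel_spacing = 1.95),
    truth = list(heart_rate = 78, resp_rate = 15, vessel_area_mean = 250,
                 vessel_area_cv = 3, vessel_signal_mean = 150,
                 vessel_signal_cv = 4, lung_area_cv = 8,
                 se_delay_frac = 0.63, noise_sd = 7.5),
    segmentation = list(dark_frac = 0.4, min_area = 200L,
                        vessel_percentile = 97, vessel_min_size = 3L,
                        margin = 0L),
    filter = list(cutoff = 0.6),
    stats = list(bonferroni_family = 5L),
    seed = 1L)
}

#' Pipeline configuration
#'
#' Assembles the configuration for the simulate/segment/analyze pipeline
#' from defaults overridden by a YAML file and/or named arguments. Unknown
#' keys are rejected rather than silently ignored.
#'
#' @param path Optional YAML file of overrides.
#' @param ... Named overrides (nested lists for the sections).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- pipeline_defaults()
  apply_over <- function(base, over, where) {
    for (nm in names(over)) {
      if (!nm %in% names(base)) {
        stop_pv("unknown configuration key `", nm, "`",
                if (nzchar(where)) paste0(" in ", where) else "")
      }
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- apply_over(base[[nm]], over[[nm]], nm)
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  if (!is.null(path)) cfg <- apply_over(cfg, yaml::read_yaml(path), "")
  over <- list(...)
  if (length(over) > 0) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop_pv("overrides must be named")
    }
    cfg <- apply_over(cfg, over, "")
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
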