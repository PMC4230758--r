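# Minimal uncompressed NIfTI-1 I/O.  Only what the phantom/dose export
# needs: 3D volumes, float32 or uint8, an axes-aligned sform carrying
# spacing and origin.  (No NIfTI package is assumed to be available.)

#' Write a 3D volume as an uncompressed NIfTI-1 file
#'
#' @param vol numeric or logical 3D array.
#' @param geom the volume's [grid_geometry()].
#' @param path output file, conventionally `.nii`.
#' @param datatype `"float32"` (default) or `"uint8"` (for masks).
#' @return `path`, invisibly.
#' @export
nifti_write <- function(vol, geom, path, datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(vol)) == 3L, all(dim(vol) == geom$dim))
  con <- file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L)
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L)
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L)
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348)                       # sizeof_hdr
  w_raw(10 + 18 + 4 + 2 + 1 + 1)   # data_type..dim_info
  w_i16(c(3, geom$dim, 1, 1, 1, 1))           # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0)                 # intent
  w_i16(if (datatype == "float32") 16 else 2) # datatype
  w_i16(if (datatype == "float32") 32 else 8) # bitpix
  w_i16(0)                                    # slice_start
  w_f32(c(1, geom$spacing, 0, 0, 0, 0))       # pixdim[8]
  w_f32(352)                                  # vox_offset
  w_f32(1); w_f32(0)                          # scl_slope, scl_inter
  w_i16(0); w_raw(1)                          # slice_end, slice_code
  writeBin(as.raw(2L), con)                   # xyzt_units: mm
  w_f32(c(0, 0, 0, 0))                        # cal_max..toffset
  w_i32(c(0, 0))                              # glmax, glmin
  w_raw(80 + 24)                              # descrip, aux_file
  w_i16(0); w_i16(1)                          # qform_code, sform_code
  w_f32(c(0, 0, 0)); w_f32(c(0, 0, 0))        # quatern, qoffset
  w_f32(c(geom$spacing[1], 0, 0, geom$origin[1]))  # srow_x
  w_f32(c(0, geom$spacing[2], 0, geom$origin[2]))  # srow_y
  w_f32(c(0, 0, geom$spacing[3], geom$origin[3]))  # srow_z
  w_raw(16)                                   # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  w_raw(1)                                    # magic terminator
  w_raw(4)                                    # extension flag
  if (datatype == "float32") {
    w_f32(as.numeric(vol))
  } else {
    writeBin(as.integer(as.numeric(vol)), con, size = 1L)
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by [nifti_write()]
#'
#' @param path `.nii` file path.
#' @return list: `vol` (array), `geom` ([grid_geometry()]).
#' @export
nifti_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r_i32 <- function(n = 1) readBin(con, "integer", n, size = 4L)
  r_i16 <- function(n = 1) readBin(con, "integer", n, size = 2L)
  r_f32 <- function(n = 1) readBin(con, "numeric", n, size = 4L)
  hdr_size <- r_i32()
  if (hdr_size != 348) stop("not a NIfTI-1 file: ", path)
  invisible(readBin(con, "raw", 36))
  dims <- r_i16(8)
  invisible(r_f32(3)); invisible(r_i16(1))
  datatype <- r_i16(); invisible(r_i16(2))
  pixdim <- r_f32(8)
  vox_offset <- r_f32()
  invisible(readBin(con, "raw", 280 - 112))
  srow <- matrix(r_f32(12), nrow = 3, byrow = TRUE)
  invisible(readBin(con, "raw", 16))
  magic <- rawToChar(readBin(con, "raw", 3))
  if (magic != "n+1") stop("unsupported NIfTI magic: ", magic)
  d <- dims[2:4]
  geom <- grid_geometry(d, pixdim[2:4], srow[, 4])
  seek(con, vox_offset)
  n <- prod(d)
  vol <- switch(as.character(datatype),
                "16" = readBin(con, "numeric", n, size = 4L),
                "64" = readBin(con, "numeric", n, size = 8L),
                "2" = as.numeric(readBin(con, "integer", n, size = 1L,
                                         signed = FALSE)),
                stop("unsupported NIfTI datatype ", datatype))
  list(vol = array(vol, d), geom = geom)
}

#' Export a phantom as NIfTI volumes plus a JSON sidecar
#'
#' One density file and one deformation-component file per phase, uint8
#' masks per structure and phase, and a JSON sidecar with the trace and
#' motion metadata.
#'
#' @param phantom a `phantom4d`.
#' @param dir output directory (created if needed).
#' @return the sidecar path, invisibly.
#' @export
export_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- phantom$geom
  for (p in phantom$phases) {
    nifti_write(phantom$density[[p]], g,
                file.path(dir, sprintf("density_%s.nii", p)))
    def <- phantom$deformation_to_ref[[p]]
    for (ax in c("x", "y", "z"))
      nifti_write(def[[ax]], g,
                  file.path(dir, sprintf("def_%s_%s.nii", ax, p)))
    for (s in names(phantom$structures))
      nifti_write(phantom$structures[[s]][[p]], g,
                  file.path(dir, sprintf("mask_%s_%s.nii", s, p)),
                  datatype = "uint8")
  }
  side <- file.path(dir, "phantom.json")
  jsonlite::write_json(list(
    grid_dim = g$dim, spacing_mm = g$spacing, origin_mm = g$origin,
    trace = unclass(phantom$trace), motion = unclass(phantom$motion),
    tumor_center_mm = phantom$tumor_center_mm, seed = phantom$seed),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(side)
}

#' Export a spot map as CSV
#' @param spots a `spot_map`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
export_spot_map <- function(spots, path) {
  write.csv(as.data.frame(spots)[, c("layer", "range_wepl_mm", "u_mm",
                                     "v_mm", "weight", "path_order")],
            path, row.names = FALSE)
  invisible(path)
}

#' Export a delivery schedule event log as CSV
#'
#' Adds the respiratory phase at each event start.
#'
#' @param schedule a [schedule_pcr()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
export_schedule <- function(schedule, path) {
  ev <- schedule$events
  ev$phase <- phase_at_time(schedule$config$trace, ev$t_start_s,
                            schedule$config$strategy)
  write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' Export an FTV as a mask plus per-ray WEPL bounds
#' @param ftv a [build_ftv()] result.
#' @param geom the phantom grid geometry.
#' @param mask_path NIfTI path for the uint8 mask.
#' @param rays_path CSV path for (u, v, proximal, distal) per ray.
#' @return `rays_path`, invisibly.
#' @export
export_ftv <- function(ftv, geom, mask_path, rays_path) {
  nifti_write(ftv$mask, geom, mask_path, datatype = "uint8")
  write.csv(ftv$rays, rays_path, row.names = FALSE)
  invisible(rays_path)
}
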