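# Minimal MRC2014 reader/writer (little-endian, modes 0/1/2/6).
# The 1024-byte header is parsed field-by-field; extended headers are
# skipped on read and never written.

.mrc_modes <- list(
  int8    = list(mode = 0L, size = 1L, what = "integer", signed = TRUE),
  int16   = list(mode = 1L, size = 2L, what = "integer", signed = TRUE),
  float32 = list(mode = 2L, size = 4L, what = "numeric", signed = TRUE),
  uint16  = list(mode = 6L, size = 2L, what = "integer", signed = FALSE)
)

.mrc_read_header <- function(raw1024) {
  int_at <- function(w, n = 1, endian) {
    readBin(raw1024[(4 * (w - 1) + 1):(4 * (w + n - 1))], "integer",
            n = n, size = 4L, endian = endian)
  }
  float_at <- function(w, n = 1, endian) {
    readBin(raw1024[(4 * (w - 1) + 1):(4 * (w + n - 1))], "numeric",
            n = n, size = 4L, endian = endian)
  }
  machst <- raw1024[213:214]
  endian <- if (identical(as.integer(machst), c(17L, 17L))) "big" else "little"
  nxyz <- int_at(1, 3, endian)
  if (any(nxyz <= 0) || any(nxyz > 1e5)) {
    # machine stamp missing or wrong; retry with the other byte order
    endian <- if (endian == "little") "big" else "little"
    nxyz <- int_at(1, 3, endian)
  }
  list(
    endian = endian,
    nx = nxyz[1], ny = nxyz[2], nz = nxyz[3],
    mode = int_at(4, 1, endian),
    nstart = int_at(5, 3, endian),          # x, y, z
    m = int_at(8, 3, endian),               # sampling grid
    cella = float_at(11, 3, endian),        # cell edges, Angstrom
    map_axes = int_at(17, 3, endian),       # mapc, mapr, maps
    nsymbt = int_at(24, 1, endian),
    origin = float_at(50, 3, endian)        # x, y, z, Angstrom
  )
}

.mrc_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw1024 <- readBin(con, "raw", 1024L)
  if (length(raw1024) < 1024L) stop("truncated MRC header in ", path)
  h <- .mrc_read_header(raw1024)
  spec <- Filter(function(m) m$mode == h$mode, .mrc_modes)
  if (length(spec) == 0) stop("unsupported MRC data mode ", h$mode)
  spec <- spec[[1]]
  if (h$nsymbt > 0) invisible(readBin(con, "raw", h$nsymbt))
  nvox <- as.double(h$nx) * h$ny * h$nz
  vals <- readBin(con, spec$what, n = nvox, size = spec$size,
                  signed = spec$signed, endian = h$endian)
  if (length(vals) < nvox) stop("truncated MRC data block in ", path)
  if (!all(h$map_axes == c(1L, 2L, 3L)))
    stop("non-standard MRC axis mapping (mapc,mapr,maps) = ",
         paste(h$map_axes, collapse = ","), " is not supported")
  # file order is x fastest, z slowest; internal order is (z, y, x)
  arr <- aperm(array(vals, dim = c(h$nx, h$ny, h$nz)), c(3L, 2L, 1L))
  voxel <- ifelse(h$m > 0, h$cella / h$m, NA_real_)
  list(data = arr, voxel_size_xyz = voxel,
       origin_voxel_xyz = h$nstart, mode = h$mode)
}

.mrc_write <- function(data_zyx, voxel_size, origin_voxel_zyx, path,
                       mode = "float32") {
  spec <- .mrc_modes[[mode]]
  if (is.null(spec)) stop("unsupported MRC write mode: ", mode)
  dz <- dim(data_zyx)
  nx <- dz[3]; ny <- dz[2]; nz <- dz[1]
  vals <- as.vector(aperm(data_zyx, c(3L, 2L, 1L)))
  if (mode != "float32") {
    vals <- as.integer(round(vals))
    lim <- if (mode == "int8") c(-128, 127)
           else if (mode == "int16") c(-32768, 32767) else c(0, 65535)
    if (any(vals < lim[1] | vals > lim[2]))
      stop("data exceed the dynamic range of MRC mode ", mode)
  }
  ox <- origin_voxel_zyx[3]; oy <- origin_voxel_zyx[2]; oz <- origin_voxel_zyx[1]

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(nx, ny, nz))
  wi(spec$mode)
  wi(c(ox, oy, oz))                          # nxstart, nystart, nzstart
  wi(c(nx, ny, nz))                          # mx, my, mz
  wf(c(nx, ny, nz) * voxel_size)             # cella
  wf(c(90, 90, 90))                          # cellb
  wi(c(1L, 2L, 3L))                          # mapc, mapr, maps
  wf(c(min(vals), max(vals), mean(vals)))    # dmin, dmax, dmean
  wi(1L)                                     # ispg (volume)
  wi(0L)                                     # nsymbt
  wi(rep(0L, 2))                             # extra words 25-26
  writeBin(charToRaw("MRC "), con)           # exttyp
  wi(20140L)                                 # nversion
  wi(rep(0L, 21))                            # extra words 29-49
  wf(c(ox, oy, oz) * voxel_size)             # origin (Angstrom)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  wf(sd(vals))                               # rms
  wi(0L)                                     # nlabl
  writeBin(raw(800L), con)                   # label block
  if (mode == "float32") {
    writeBin(vals, con, size = 4L, endian = "little")
  } else {
    writeBin(vals, con, size = spec$size, endian = "little")
  }
  invisible(NULL)
}
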