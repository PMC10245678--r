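#' Read an MRC2014 density map
#'
#' Supports mode-2 (float32) maps. The voxel size is taken from the cell
#' dimensions over the sampling grid; the origin from the ORIGIN header
#' words (Angstrom).
#'
#' @param path MRC/CCP4 map file.
#' @return a \linkS4class{DensityMap}.
#' @export
readMap <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  seek(con, 208)
  magic <- rawToChar(readBin(con, "raw", n = 4))
  if (substr(magic, 1, 3) != "MAP")
    stopf("%s is not an MRC2014 map (magic '%s')", path, magic)
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  if (mode != 2L) stopf("unsupported MRC mode %d (only mode 2/float32)", mode)
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  cella <- hdr_num[11:13]
  voxel <- cella / c(mx, my, mz)
  origin <- hdr_num[50:52]
  nsymbt <- hdr_int[24]
  seek(con, 1024 + nsymbt)
  vals <- readBin(con, "numeric", n = nx * ny * nz, size = 4,
                  endian = "little")
  if (length(vals) < nx * ny * nz) stopf("truncated MRC data in %s", path)
  DensityMap(array(vals, dim = c(nx, ny, nz)), voxelSize = voxel,
             origin = origin)
}

#' Write a DensityMap as an MRC2014 file
#'
#' Values are stored as float32 (mode 2), x fastest.
#'
#' @param map a \linkS4class{DensityMap}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeMap <- function(map, path) {
  d <- dim(map@grid)
  vx <- map@voxelSize
  g <- as.numeric(map@grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2)                      # mode: float32
  wi(c(0, 0, 0))             # nxstart
  wi(d)                      # mx my mz
  wf(d * vx)                 # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1, 2, 3))             # mapc mapr maps
  wf(c(min(g), max(g), mean(g)))
  wi(1)                      # ispg
  wi(0)                      # nsymbt
  wi(rep(0, 3))              # extra words 25-27
  wi(20140)                  # nversion (word 28)
  wi(rep(0, 21))             # extra words 29-49
  wf(map@origin)             # origin x y z
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  wf(sd(g))                  # rms
  wi(0)                      # nlabl
  writeBin(raw(800), con)    # labels
  wf(g)
  invisible(path)
}
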