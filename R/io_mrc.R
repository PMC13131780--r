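# MRC2014 volume I/O.
#
# The header is the standard 1024-byte layout; voxel size is CELLA / M*, the
# real-space origin comes from the ORIGIN words, and MAPC/MAPR/MAPS record
# which of x/y/z varies along columns, rows and sections. On read the data
# array is permuted into canonical [x, y, z] order and the header permutation
# is kept on the volume so that a write restores the original on-disk layout.

MRC_MODES <- c(`0` = "int8", `1` = "int16", `2` = "float32", `6` = "uint16")

#' Read an MRC volume
#'
#' Reads an MRC2014 density or label volume, returning the data in canonical
#' `[x, y, z]` order together with voxel size, origin and the header axis
#' mapping. Modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16) are
#' supported.
#'
#' @param path path to an MRC file.
#' @return A [new_volume()] object.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_ints <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  if (length(hdr_ints) < 256) stop("corrupt MRC header (truncated): ", path)
  seek(con, 0)
  hdr_flts <- readBin(con, "numeric", n = 256, size = 4, endian = "little")

  nd <- hdr_ints[1:3]
  mode <- hdr_ints[4]
  if (any(nd <= 0) || any(nd > 1e5))
    stop("corrupt MRC header (bad dimensions): ", path)
  if (!as.character(mode) %in% names(MRC_MODES))
    stop("unsupported MRC mode ", mode, " in ", path)
  m <- pmax(hdr_ints[8:10], 1L)
  cella <- hdr_flts[11:13]
  axis_map_disk <- hdr_ints[17:19]
  if (!identical(sort(axis_map_disk), 1:3)) axis_map_disk <- 1:3
  nsymbt <- hdr_ints[24]
  origin <- hdr_flts[50:52]

  seek(con, 1024 + max(0, nsymbt))
  n <- prod(nd)
  data <- switch(as.character(mode),
    `0` = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE,
                             endian = "little")),
    `1` = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    `2` = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    `6` = as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                             endian = "little")))
  if (length(data) < n) stop("truncated MRC data section: ", path)
  dim(data) <- nd

  vox_disk <- cella / m
  vox_disk[!is.finite(vox_disk) | vox_disk <= 0] <- 1

  # permute disk layout (axes axis_map_disk) into canonical x,y,z order
  perm <- match(1:3, axis_map_disk)
  data <- aperm(data, perm)
  voxel_size <- vox_disk[perm]

  new_volume(data, voxel_size = voxel_size, origin = origin,
             axis_map = axis_map_disk)
}

#' Write an MRC volume
#'
#' Writes a volume as MRC2014 mode 2 (float32), restoring the on-disk axis
#' order recorded in the volume's `axis_map` and preserving voxel size and
#' origin exactly. Integer label volumes round-trip bit-exactly (all label
#' values are far below float32's exact-integer range).
#'
#' @param v a [new_volume()] object.
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_volume <- function(v, path) {
  validate_volume(v)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  data <- aperm(v$data, v$axis_map)
  nd <- dim(data)
  vox <- v$voxel_size[v$axis_map]

  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))

  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")

  wi(nd)                      # 1-3   NX NY NZ
  wi(2L)                      # 4     MODE float32
  wi(c(0L, 0L, 0L))           # 5-7   N*START
  wi(nd)                      # 8-10  MX MY MZ
  wf(vox * nd)                # 11-13 CELLA
  wf(c(90, 90, 90))           # 14-16 CELLB
  wi(v$axis_map)              # 17-19 MAPC MAPR MAPS
  wf(c(min(data), max(data), mean(data)))  # 20-22 DMIN DMAX DMEAN
  wi(c(1L, 0L))               # 23-24 ISPG NSYMBT
  wi(rep(0L, 2))              # 25-26 EXTRA
  writeChar("MRCO", con, nchars = 4, eos = NULL)  # 27 EXTTYP
  wi(20140L)                  # 28 NVERSION
  wi(rep(0L, 21))             # 29-49 EXTRA
  wf(v$origin)                # 50-52 ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)  # 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # 54 MACHST
  wf(stats::sd(as.vector(data)))  # 55 RMS
  wi(0L)                      # 56 NLABL
  writeBin(raw(200 * 4), con) # 57-256 labels
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}
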