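# Minimal DICOM I/O (explicit VR little endian, uncompressed monochrome).
# Covers the tags the pipeline needs: geometry (rows/columns, pixel
# spacing, slice position/thickness) and 16-bit pixel data.  This is not a
# general DICOM implementation; it reads standard single-frame CT slices
# with those tags present and writes the phantom generator's output.

.dcm_string <- function(x, vr = "LO") {
  b <- charToRaw(x)
  # UI values are null-padded, text values space-padded, to even length
  if (length(b) %% 2 == 1) b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
  b
}

.dcm_element <- function(group, element, vr, value_raw) {
  con <- raw(0)
  hdr <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
           writeBin(as.integer(element), raw(), size = 2, endian = "little"),
           charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    hdr <- c(hdr, as.raw(c(0, 0)),
             writeBin(length(value_raw), raw(), size = 4, endian = "little"))
  } else {
    hdr <- c(hdr, writeBin(length(value_raw), raw(), size = 2,
                           endian = "little"))
  }
  c(con, hdr, value_raw)
}

.dcm_us <- function(group, element, value)
  .dcm_element(group, element, "US",
               writeBin(as.integer(value), raw(), size = 2, endian = "little"))

.dcm_str <- function(group, element, vr, value)
  .dcm_element(group, element, vr, .dcm_string(value, vr))

#' Write an image volume as a DICOM series
#'
#' One explicit-VR little-endian file per slice with the geometry tags
#' (rows, columns, pixel spacing, slice thickness, image position) and
#' 16-bit unsigned pixel data.  Intensities are rounded and clipped to
#' \[0, 65535\].
#'
#' @param vol an [image_volume()].
#' @param dir output directory (created when missing).
#' @return invisibly, the written file paths.
#' @export
write_dicom_series <- function(vol, dir) {
  stopifnot(inherits(vol, "image_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(vol$voxels)
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    sl <- vol$voxels[, , k]
    px <- as.integer(pmin(pmax(round(t(sl)), 0), 65535))   # row-major
    z <- vol$origin[3] + (k - 1) * vol$spacing[3]
    meta <- c(
      .dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
    meta <- c(.dcm_element(0x0002, 0x0000, "UL",
                           writeBin(length(meta), raw(), size = 4,
                                    endian = "little")), meta)
    body <- c(
      .dcm_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      .dcm_str(0x0008, 0x0018, "UI",
               sprintf("1.2.826.0.1.3680043.2.1.%d", k)),
      .dcm_str(0x0018, 0x0050, "DS", format(vol$spacing[3])),
      .dcm_str(0x0020, 0x0013, "IS", as.character(k)),
      .dcm_str(0x0020, 0x0032, "DS",
               sprintf("%s\\%s\\%s", format(vol$origin[2]),
                       format(vol$origin[1]), format(z))),
      .dcm_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      .dcm_us(0x0028, 0x0002, 1),
      .dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcm_us(0x0028, 0x0010, d[1]),
      .dcm_us(0x0028, 0x0011, d[2]),
      .dcm_str(0x0028, 0x0030, "DS",
               sprintf("%s\\%s", format(vol$spacing[1]),
                       format(vol$spacing[2]))),
      .dcm_us(0x0028, 0x0100, 16),
      .dcm_us(0x0028, 0x0101, 16),
      .dcm_us(0x0028, 0x0102, 15),
      .dcm_us(0x0028, 0x0103, 0),
      .dcm_element(0x7FE0, 0x0010, "OW",
                   writeBin(px, raw(), size = 2, endian = "little")))
    path <- file.path(dir, sprintf("slice_%04d.dcm", k))
    con <- file(path, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}

# parse one DICOM file into a tag list
.dcm_parse <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(raw_all) > 132 &&
      rawToChar(raw_all[129:132]) == "DICM") pos <- 133L
  u16 <- function(at) sum(as.integer(raw_all[at:(at + 1)]) * c(1, 256))
  u32 <- function(at) sum(as.integer(raw_all[at:(at + 3)]) *
                            c(1, 256, 65536, 16777216))
  tags <- list()
  n <- length(raw_all)
  while (pos + 7 <= n) {
    group <- u16(pos); element <- u16(pos + 2)
    vr <- rawToChar(raw_all[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported DICOM encoding (implicit VR?) in ", path)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8); pos <- pos + 12L
    } else {
      len <- u16(pos + 6); pos <- pos + 8L
    }
    val <- raw_all[pos:(pos + len - 1)]
    pos <- pos + len
    key <- sprintf("%04X,%04X", group, element)
    tags[[key]] <- list(vr = vr, value = val)
  }
  tags
}

.dcm_num <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  if (t$vr == "US") {
    sum(as.integer(t$value[1:2]) * c(1, 256))
  } else {
    as.numeric(strsplit(trimws(rawToChar(t$value)), "\\\\")[[1]])
  }
}

#' Read a DICOM series as an image volume
#'
#' Reads every `.dcm` file in `dir`, sorts slices by their z position,
#' checks geometric consistency (identical in-plane grids, slice spacing
#' uniform within 5%) and window-normalises intensities to \[0, 255\].
#'
#' @param dir directory containing one file per slice.
#' @param window intensity window mapped to \[0, 255\]; the default
#'   `c(0, 255)` is the identity for 8-bit-valued data.
#' @return an [image_volume()].
#' @export
read_dicom_series <- function(dir, window = c(0, 255)) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no DICOM slices found in ", dir)
  slices <- lapply(files, function(f) {
    tags <- .dcm_parse(f)
    rows <- .dcm_num(tags, "0028,0010")
    cols <- .dcm_num(tags, "0028,0011")
    sp <- .dcm_num(tags, "0028,0030")
    pos <- .dcm_num(tags, "0020,0032")
    if (is.null(rows) || is.null(cols) || is.null(sp))
      stop("missing geometry tags in ", f)
    if (is.null(pos)) stop("missing image position tag in ", f)
    px <- tags[["7FE0,0010"]]
    if (is.null(px)) stop("missing pixel data in ", f)
    ints <- readBin(px$value, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = FALSE)
    list(m = matrix(ints, nrow = rows, byrow = TRUE),
         spacing = sp, z = pos[3], origin_xy = pos[1:2])
  })
  z <- vapply(slices, `[[`, numeric(1), "z")
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  d1 <- nrow(slices[[1]]$m); d2 <- ncol(slices[[1]]$m)
  for (s in slices)
    if (nrow(s$m) != d1 || ncol(s$m) != d2)
      stop("inconsistent slice dimensions in series")
  dz <- diff(z)
  if (length(dz)) {
    if (any(dz <= 0)) stop("duplicate slice positions in series")
    if ((max(dz) - min(dz)) / stats::median(dz) > 0.05)
      stop(sprintf("inconsistent slice spacing beyond 5%% (%.3f-%.3f mm)",
                   min(dz), max(dz)))
  }
  vox <- array(0, c(d1, d2, length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$m
  sp <- slices[[1]]$spacing
  spacing <- c(sp[1], sp[2], if (length(dz)) stats::median(dz) else 1)
  origin <- c(slices[[1]]$origin_xy[2], slices[[1]]$origin_xy[1], z[1])
  normalize_volume(image_volume(vox, spacing, origin), window)
}
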