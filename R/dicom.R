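# Minimal DICOM codec: explicit-VR little-endian only, enough for CT image
# series and RT structure sets (nested sequences supported, defined or
# undefined lengths on read; defined lengths on write). Not a general DICOM
# implementation -- unknown elements are carried as raw bytes and ignored.

DCM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
DCM_SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
DCM_UID_ROOT <- "2.25"   # UUID-derived style root for generated UIDs

dcm_uid <- function() {
  # deterministic-enough unique suffix; uniqueness within a run is all we need
  paste0(DCM_UID_ROOT, ".",
         paste0(sample.int(9, 1), paste(sample.int(10, 30, TRUE) - 1, collapse = "")))
}

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

enc_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
enc_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

pad_even <- function(r, pad = as.raw(0)) {
  if (length(r) %% 2 == 1) c(r, pad) else r
}

dcm_str <- function(s, vr) {
  r <- charToRaw(paste(s, collapse = "\\"))
  pad_even(r, if (vr == "UI") as.raw(0) else charToRaw(" "))
}

# one encoded element; value must already be a raw vector of even length
dcm_element <- function(group, elem, vr, value_raw) {
  hdr <- c(enc_u16(group), enc_u16(elem), charToRaw(vr))
  if (vr %in% .long_vrs) {
    c(hdr, as.raw(c(0, 0)), enc_u32(length(value_raw)), value_raw)
  } else {
    if (length(value_raw) > 65534) stop("value too long for short-form VR")
    c(hdr, enc_u16(length(value_raw)), value_raw)
  }
}

el_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, dcm_str(s, vr))
el_us  <- function(group, elem, x) dcm_element(group, elem, "US", enc_u16(x))
el_ds  <- function(group, elem, x)
  el_str(group, elem, "DS", paste(sprintf("%.10g", x), collapse = "\\"))
el_is  <- function(group, elem, x)
  el_str(group, elem, "IS", paste(sprintf("%d", as.integer(x)), collapse = "\\"))

# sequence with defined lengths; items is a list of raw vectors (item payloads)
el_sq <- function(group, elem, items) {
  body <- raw()
  for (it in items)
    body <- c(body, enc_u16(0xFFFE), enc_u16(0xE000), enc_u32(length(it)), it)
  dcm_element(group, elem, "SQ", body)
}

dcm_file <- function(sop_class, sop_instance, dataset_raw) {
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    el_str(0x0002, 0x0002, "UI", sop_class),
    el_str(0x0002, 0x0003, "UI", sop_instance),
    el_str(0x0002, 0x0010, "UI", DCM_TS_EXPLICIT_LE),
    el_str(0x0002, 0x0012, "UI", paste0(DCM_UID_ROOT, ".999"))
  )
  c(raw(128), charToRaw("DICM"),
    dcm_element(0x0002, 0x0000, "UL", enc_u32(length(meta))),
    meta, dataset_raw)
}

## ---- reader -------------------------------------------------------------

dcm_parse_file <- function(path) {
  buf <- readBin(path, "raw", file.info(path)$size)
  if (length(buf) < 136 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  st <- dcm_parse_dataset(buf, 133L, length(buf))
  ds <- st$elements
  ts <- ds[["0002,0010"]]
  if (!is.null(ts) && trimws(ts) != DCM_TS_EXPLICIT_LE)
    stop("unsupported transfer syntax: ", ts)
  ds
}

rd_u16 <- function(buf, pos)
  as.integer(buf[pos]) + 256L * as.integer(buf[pos + 1L])
rd_u32 <- function(buf, pos)
  rd_u16(buf, pos) + 65536 * rd_u16(buf, pos + 2L)

# parse elements in buf[pos..end]; stops at end or at an item delimiter.
# returns list(elements = named list, pos = next position)
dcm_parse_dataset <- function(buf, pos, end) {
  out <- list()
  while (pos + 7L <= end + 1L && pos < end) {
    group <- rd_u16(buf, pos); elem <- rd_u16(buf, pos + 2L)
    if (group == 0xFFFE && elem %in% c(0xE00D, 0xE0DD)) {  # delimiter
      pos <- pos + 8L
      return(list(elements = out, pos = pos, delimiter = elem))
    }
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% .long_vrs) {
      len <- rd_u32(buf, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- rd_u16(buf, pos + 6L)
      pos <- pos + 8L
    }
    key <- sprintf("%04x,%04x", group, elem)
    if (vr == "SQ") {
      sq_end <- if (len == 0xFFFFFFFF) end else pos + len
      items <- list()
      while (pos < sq_end) {
        ig <- rd_u16(buf, pos); ie <- rd_u16(buf, pos + 2L)
        il <- rd_u32(buf, pos + 4L)
        pos <- pos + 8L
        if (ig == 0xFFFE && ie == 0xE0DD) break      # sequence delimiter
        if (!(ig == 0xFFFE && ie == 0xE000)) stop("malformed sequence item")
        if (il == 0xFFFFFFFF) {
          st <- dcm_parse_dataset(buf, pos, sq_end)
          items[[length(items) + 1L]] <- st$elements
          pos <- st$pos
        } else {
          st <- dcm_parse_dataset(buf, pos, pos + il)
          items[[length(items) + 1L]] <- st$elements
          pos <- pos + il
        }
      }
      out[[key]] <- items
    } else {
      val <- buf[seq_len(len) + pos - 1L]
      pos <- pos + len
      out[[key]] <- dcm_decode_value(vr, val)
    }
  }
  list(elements = out, pos = pos, delimiter = NA)
}

dcm_decode_value <- function(vr, val) {
  switch(vr,
    US = readBin(val, "integer", length(val) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    UL = readBin(val, "integer", length(val) / 4, size = 4, endian = "little"),
    DS = as.numeric(strsplit(trimws(rawToChar(val)), "\\\\")[[1]]),
    IS = as.integer(strsplit(trimws(rawToChar(val)), "\\\\")[[1]]),
    UI = , CS = , LO = , SH = , PN = , DA = , TM =
      trimws(rawToChar(val[val != as.raw(0)])),
    val)   # OB/OW/unknown: raw
}

## ---- CT series ----------------------------------------------------------

#' Write a CT volume as a single-phase DICOM series
#'
#' One explicit-VR little-endian CT image file per axial slice, 16-bit
#' signed stored values with the given rescale slope/intercept.
#'
#' @param volume a [ct_volume()]
#' @param directory output directory (created if needed)
#' @param slope,intercept HU = slope * stored + intercept
#' @return invisibly, the written file paths
#' @export
write_ct_series <- function(volume, directory, slope = 1, intercept = -1024) {
  stopifnot(inherits(volume, "ct_volume"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  d <- dim(volume$voxels)
  series_uid <- dcm_uid(); study_uid <- dcm_uid()
  files <- character(d[3])
  for (k in seq_len(d[3])) {
    z <- volume$origin[3] + (k - 1) * volume$spacing[3]
    stored <- round((volume$voxels[, , k] - intercept) / slope)
    if (any(stored < -32768 | stored > 32767)) stop("stored value overflow")
    sop_uid <- dcm_uid()
    ds <- c(
      el_str(0x0008, 0x0016, "UI", DCM_SOP_CT),
      el_str(0x0008, 0x0018, "UI", sop_uid),
      el_str(0x0008, 0x0060, "CS", "CT"),
      el_str(0x0020, 0x000D, "UI", study_uid),
      el_str(0x0020, 0x000E, "UI", series_uid),
      el_is(0x0020, 0x0013, k),
      el_ds(0x0020, 0x0032, c(volume$origin[1], volume$origin[2], z)),
      el_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
      el_ds(0x0020, 0x1041, z),
      el_ds(0x0018, 0x0050, volume$spacing[3]),
      el_us(0x0028, 0x0002, 1),
      el_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      el_us(0x0028, 0x0010, d[2]),                  # Rows = ny
      el_us(0x0028, 0x0011, d[1]),                  # Columns = nx
      el_ds(0x0028, 0x0030, c(volume$spacing[2], volume$spacing[1])),
      el_us(0x0028, 0x0100, 16), el_us(0x0028, 0x0101, 16),
      el_us(0x0028, 0x0102, 15), el_us(0x0028, 0x0103, 1),
      el_ds(0x0028, 0x1052, intercept),
      el_ds(0x0028, 0x1053, slope),
      dcm_element(0x7FE0, 0x0010, "OW",
                  writeBin(as.integer(stored), raw(), size = 2,
                           endian = "little"))
    )
    files[k] <- file.path(directory, sprintf("ct_%04d.dcm", k))
    writeBin(dcm_file(DCM_SOP_CT, sop_uid, ds), files[k])
  }
  invisible(files)
}

#' Read a single-phase DICOM CT series
#'
#' @param directory directory holding exactly one CT series (`.dcm` files)
#' @param phase phase index to record on the volume
#' @return a [ct_volume()] with HU rescale applied
#' @export
read_ct_series <- function(directory, phase = NA_integer_) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) stop("no .dcm files in ", directory)
  slices <- lapply(files, dcm_parse_file)
  series <- vapply(slices, function(s) s[["0020,000e"]], character(1))
  if (length(unique(series)) != 1)
    stop("directory contains mixed series (", length(unique(series)), " found)")
  z <- vapply(slices, function(s) s[["0020,0032"]][3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  dz <- diff(z)
  if (length(dz) > 0) {
    if (any(abs(dz - stats::median(dz)) > 0.01 * stats::median(dz)))
      stop("missing slice: gap in slice positions")
  }
  s1 <- slices[[1]]
  nx <- s1[["0028,0011"]]; ny <- s1[["0028,0010"]]
  px <- s1[["0028,0030"]]   # (row spacing = y, col spacing = x)
  spacing <- c(px[2], px[1],
               if (length(dz) > 0) stats::median(dz) else s1[["0018,0050"]])
  vox <- array(0, c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    stored <- readBin(s[["7fe0,0010"]], "integer", nx * ny, size = 2,
                      signed = TRUE, endian = "little")
    slope <- s[["0028,1053"]]; inter <- s[["0028,1052"]]
    if (is.null(slope)) slope <- 1
    if (is.null(inter)) inter <- 0
    vox[, , k] <- array(stored * slope + inter, c(nx, ny))
  }
  origin <- c(s1[["0020,0032"]][1:2], z[1])
  ct_volume(vox, spacing, origin, phase = phase)
}

## ---- RT structure set ---------------------------------------------------

#' Write an RT structure set
#'
#' @param rois named list: each element is a list of contour matrices
#'   (n x 3, world mm, closed planar polygons, one per slice crossing);
#'   names are the ROI names
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_rtstruct <- function(rois, path) {
  stopifnot(length(rois) > 0, !is.null(names(rois)))
  sop_uid <- dcm_uid()
  ssr_items <- list(); rcs_items <- list()
  for (i in seq_along(rois)) {
    ssr_items[[i]] <- c(el_is(0x3006, 0x0022, i),
                        el_str(0x3006, 0x0026, "LO", names(rois)[i]))
    contour_items <- lapply(rois[[i]], function(m) {
      m <- matrix(m, ncol = 3)
      c(el_str(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        el_is(0x3006, 0x0046, nrow(m)),
        el_ds(0x3006, 0x0050, as.numeric(t(m))))
    })
    rcs_items[[i]] <- c(el_sq(0x3006, 0x0040, contour_items),
                        el_is(0x3006, 0x0084, i))
  }
  ds <- c(
    el_str(0x0008, 0x0016, "UI", DCM_SOP_RTSTRUCT),
    el_str(0x0008, 0x0018, "UI", sop_uid),
    el_str(0x0008, 0x0060, "CS", "RTSTRUCT"),
    el_str(0x3006, 0x0002, "SH", "StructSet"),
    el_sq(0x3006, 0x0020, ssr_items),
    el_sq(0x3006, 0x0039, rcs_items)
  )
  writeBin(dcm_file(DCM_SOP_RTSTRUCT, sop_uid, ds), path)
  invisible(path)
}

#' Rasterize one ROI of an RT structure set onto a CT volume
#'
#' Each closed planar contour is assigned to the volume slice whose z is
#' within half a slice spacing of the contour plane, and rasterized by the
#' even-odd voxel-center-inside rule; multiple polygons on a slice are
#' unioned (multi-component ROIs allowed).
#'
#' @param structure_file RT-STRUCT path
#' @param volume the aligned [ct_volume()]
#' @param roi_name ROI to extract (default `"GTV"`)
#' @return a [gtv_mask()]
#' @export
extract_gtv_mask <- function(structure_file, volume, roi_name = "GTV") {
  stopifnot(inherits(volume, "ct_volume"))
  ds <- dcm_parse_file(structure_file)
  ssr <- ds[["3006,0020"]]
  if (is.null(ssr) || length(ssr) == 0) stop("structure set has no ROIs")
  names_ <- vapply(ssr, function(it) it[["3006,0026"]], character(1))
  nums <- vapply(ssr, function(it) it[["3006,0022"]][1], integer(1))
  hit <- which(names_ == roi_name)
  if (length(hit) != 1) stop("ROI '", roi_name, "' not found")
  roi_num <- nums[hit]
  rcs <- ds[["3006,0039"]]
  ref <- vapply(rcs, function(it) it[["3006,0084"]][1], integer(1))
  contours <- rcs[[which(ref == roi_num)]][["3006,0040"]]
  if (is.null(contours) || length(contours) == 0) stop("ROI has no contours")

  d <- dim(volume$voxels)
  ax <- voxel_axes(volume)
  msk <- array(FALSE, d)
  for (it in contours) {
    pts <- matrix(it[["3006,0050"]], ncol = 3, byrow = TRUE)
    zc <- mean(pts[, 3])
    k <- which.min(abs(ax[[3]] - zc))
    if (abs(ax[[3]][k] - zc) > volume$spacing[3] / 2)
      stop("contour plane z=", zc, " matches no slice within half spacing")
    xr <- range(pts[, 1]); yr <- range(pts[, 2])
    is <- which(ax[[1]] >= xr[1] - volume$spacing[1] &
                ax[[1]] <= xr[2] + volume$spacing[1])
    js <- which(ax[[2]] >= yr[1] - volume$spacing[2] &
                ax[[2]] <= yr[2] + volume$spacing[2])
    if (length(is) == 0 || length(js) == 0) next
    gx <- rep(ax[[1]][is], times = length(js))
    gy <- rep(ax[[2]][js], each = length(is))
    inside <- pracma::inpolygon(gx, gy, pts[, 1], pts[, 2], boundary = TRUE)
    msk[cbind(rep(is, times = length(js)),
              rep(js, each = length(is)), k)] <-
      msk[cbind(rep(is, times = length(js)), rep(js, each = length(is)), k)] |
      inside
  }
  gtv_mask(msk, volume$spacing, volume$origin, phase = volume$phase)
}
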