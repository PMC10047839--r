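#' Region-of-interest set
#'
#' Labelled polygons (spines, axons) tied to one image and, optionally, an
#' experimental round. Polygon coordinates follow the package-wide
#' convention: continuous, 0-based `(row, col)`, with the centre of pixel
#' `(i, j)` at coordinate `(i, j)`. ImageJ's `(x, y)` corner-based
#' coordinates are converted on read/write.
#'
#' @param rois List of ROIs; each a list with elements `id` (unique string),
#'   `label` (`"spine"` or `"axon"`), `polygon` (n x 2 numeric matrix of
#'   `(row, col)` vertices, n >= 3, simple), and optional `round`.
#' @param image_id Identifier of the image the ROIs were drawn on.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(rois = list(), image_id = "img") {
  ids <- vapply(rois, function(r) as.character(r$id), character(1))
  if (anyDuplicated(ids)) stop("duplicate roi ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rois <- lapply(rois, function(r) {
    r$id <- as.character(r$id)
    if (is.null(r$label) || !r$label %in% c("spine", "axon"))
      stop("roi ", r$id, ": label must be 'spine' or 'axon'")
    r$polygon <- validate_polygon(r$polygon, r$id)
    if (is.null(r$round)) r$round <- NA_character_
    r$round <- as.character(r$round)
    r[c("id", "label", "polygon", "round")]
  })
  structure(list(image_id = image_id, rois = rois), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  labs <- vapply(x$rois, `[[`, character(1), "label")
  cat(sprintf("<roi_set> image %s: %d ROIs (%d spine, %d axon)\n",
              x$image_id, length(x$rois), sum(labs == "spine"),
              sum(labs == "axon")))
  invisible(x)
}

#' @export
length.roi_set <- function(x) length(x$rois)

validate_polygon <- function(poly, roi_id = "?") {
  poly <- as.matrix(poly)
  if (!is.numeric(poly) || ncol(poly) != 2)
    stop("roi ", roi_id, ": polygon must be an n x 2 numeric matrix")
  if (anyNA(poly)) stop("roi ", roi_id, ": polygon has NA vertices")
  # drop a duplicated closing vertex if present
  n <- nrow(poly)
  if (n >= 2 && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3)
    stop("roi ", roi_id, ": polygon needs at least 3 vertices")
  if (polygon_self_intersects(poly))
    stop("roi ", roi_id, ": polygon is self-intersecting")
  unname(poly)
}

# Proper-crossing test between non-adjacent edges (shared endpoints of
# neighbouring edges are not crossings). Vectorized over all edge pairs.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  nxt <- c(seq_len(n)[-1], 1L)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  keep <- nxt[i] != j & nxt[j] != i
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0) return(FALSE)
  ax <- poly[i, 1]; ay <- poly[i, 2]
  bx <- poly[nxt[i], 1]; by <- poly[nxt[i], 2]
  cx <- poly[j, 1]; cy <- poly[j, 2]
  dx <- poly[nxt[j], 1]; dy <- poly[nxt[j], 2]
  o1 <- sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  o2 <- sign((bx - ax) * (dy - ay) - (by - ay) * (dx - ax))
  o3 <- sign((dx - cx) * (ay - cy) - (dy - cy) * (ax - cx))
  o4 <- sign((dx - cx) * (by - cy) - (dy - cy) * (bx - cx))
  any(o1 * o2 < 0 & o3 * o4 < 0)
}

#' Read ROIs from the JSON dialect or ImageJ .roi/.zip files
#'
#' The JSON dialect is
#' `{"image_id": ..., "rois": [{"id", "label", "round", "polygon": [[r,c],...]}]}`.
#' ImageJ files store polygon vertices as `(x, y)` in corner-based
#' coordinates (the centre of pixel `(row, col)` is `(x, y) = (col + 0.5,
#' row + 0.5)`); both the axis order and the half-pixel offset are
#' normalized on read. Sub-pixel float coordinates are used when present.
#'
#' @param path A `.json`, `.roi`, or `.zip` file.
#' @param image_id Image identifier to attach (JSON files carry their own).
#' @return A [roi_set()].
#' @export
read_rois <- function(path, image_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    rois <- lapply(doc$rois, function(r) {
      list(id = r$id, label = r$label,
           polygon = do.call(rbind, lapply(r$polygon, unlist)),
           round = if (is.null(r$round)) NA_character_ else r$round)
    })
    roi_set(rois, image_id = if (!is.null(image_id)) image_id
            else if (!is.null(doc$image_id)) doc$image_id else "img")
  } else if (ext == "roi") {
    r <- read_imagej_roi_bytes(readBin(path, "raw", file.size(path)),
                               name = sub("\\.roi$", "", basename(path),
                                          ignore.case = TRUE))
    roi_set(list(r), image_id = image_id %||% "img")
  } else if (ext == "zip") {
    exdir <- tempfile("ijroi")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
    files <- utils::unzip(path, exdir = exdir)
    files <- sort(files[grepl("\\.roi$", files, ignore.case = TRUE)])
    rois <- lapply(files, function(f)
      read_imagej_roi_bytes(readBin(f, "raw", file.size(f)),
                            name = sub("\\.roi$", "", basename(f),
                                       ignore.case = TRUE)))
    roi_set(rois, image_id = image_id %||% "img")
  } else {
    stop("unsupported ROI format: ", path)
  }
}

#' Write ROIs to the JSON dialect or ImageJ .roi/.zip
#'
#' @param rois A [roi_set()].
#' @param path Output path; format chosen by extension (`.json`, `.zip`, or
#'   `.roi` for a single-ROI set).
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    doc <- list(
      image_id = rois$image_id,
      rois = lapply(rois$rois, function(r) list(
        id = r$id, label = r$label, round = r$round,
        polygon = lapply(seq_len(nrow(r$polygon)),
                         function(i) as.numeric(r$polygon[i, ]))))
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else if (ext == "roi") {
    if (length(rois$rois) != 1)
      stop("a .roi file holds exactly one ROI; use .zip for ", length(rois))
    writeBin(imagej_roi_bytes(rois$rois[[1]]), path)
  } else if (ext == "zip") {
    entries <- lapply(rois$rois, imagej_roi_bytes)
    names(entries) <- vapply(rois$rois, function(r)
      paste0(imagej_roi_name(r), ".roi"), character(1))
    write_store_zip(entries, path)
  } else {
    stop("unsupported ROI format: ", path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ROI names encode label, id and round so the ImageJ dialect round-trips:
# "<label>__<id>__<round>" (round omitted when NA).
imagej_roi_name <- function(r) {
  if (is.na(r$round)) paste(r$label, r$id, sep = "__")
  else paste(r$label, r$id, r$round, sep = "__")
}

parse_imagej_roi_name <- function(name) {
  parts <- strsplit(name, "__", fixed = TRUE)[[1]]
  if (length(parts) >= 2 && parts[1] %in% c("spine", "axon")) {
    list(label = parts[1], id = parts[2],
         round = if (length(parts) >= 3) parts[3] else NA_character_)
  } else {
    list(label = "spine", id = name, round = NA_character_)
  }
}

# --- ImageJ .roi binary format (polygon subtype), big-endian ----------------
# Layout follows ImageJ's RoiDecoder: "Iout", version, type, bounding box,
# nCoordinates, options; int16 vertex offsets from (left, top), then float
# absolute coordinates when the sub-pixel option bit (128) is set.

imagej_roi_bytes <- function(r) {
  poly <- r$polygon
  x <- poly[, 2] + 0.5            # corner-based x from col
  y <- poly[, 1] + 0.5            # corner-based y from row
  left <- floor(min(x)); top <- floor(min(y))
  right <- ceiling(max(x)); bottom <- ceiling(max(y))
  n <- nrow(poly)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  wi2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "big")
  wi4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "big")
  writeBin(charToRaw("Iout"), con)
  wi2(228)                        # version
  writeBin(as.raw(c(0, 0)), con)  # type = 0 (polygon), pad
  wi2(c(top, left, bottom, right, n))
  writeBin(numeric(4), con, size = 4, endian = "big")  # x1,y1,x2,y2 floats
  wi2(0)                          # stroke width
  wi4(0)                          # shape roi size
  wi4(c(0, 0))                    # stroke / fill colour
  wi2(c(0, 128))                  # subtype, options (SUB_PIXEL_RESOLUTION)
  writeBin(as.raw(c(0, 0)), con)  # arrow style, head size
  wi2(0)                          # rounded rect arc size
  wi4(0)                          # position
  hdr2_offset <- 64L + 12L * n    # after int16 and float coordinates
  wi4(hdr2_offset)
  wi2(floor(x) - left)            # int16 x offsets
  wi2(floor(y) - top)             # int16 y offsets
  writeBin(x, con, size = 4, endian = "big")
  writeBin(y, con, size = 4, endian = "big")
  # header2 block carrying the ROI name (label/id/round encoding)
  name <- imagej_roi_name(r)
  h2 <- integer(16)
  h2[5] <- hdr2_offset + 64L      # name offset
  h2[6] <- nchar(name)            # name length
  writeBin(h2, con, size = 4, endian = "big")
  writeBin(as.integer(utf8ToInt(name)), con, size = 2, endian = "big")
  rawConnectionValue(con)
}

read_imagej_roi_bytes <- function(bytes, name = "roi") {
  if (length(bytes) < 64 || rawToChar(bytes[1:4]) != "Iout")
    stop("not an ImageJ ROI file (", name, ")")
  ri2 <- function(off, n = 1)
    readBin(bytes[(off + 1):(off + 2 * n)], "integer", n = n, size = 2,
            endian = "big")
  type <- as.integer(bytes[7])
  if (!type %in% c(0L, 7L))  # polygon or freehand
    stop("unsupported ImageJ ROI type ", type, " in ", name,
         " (only polygon ROIs are supported)")
  top <- ri2(8); left <- ri2(10)
  n <- ri2(16)
  if (n < 3) stop("roi ", name, ": polygon needs at least 3 vertices")
  options <- ri2(50)
  xi <- ri2(64, n) + left
  yi <- ri2(64 + 2 * n, n) + top
  if (bitwAnd(options, 128L) != 0L &&
      length(bytes) >= 64 + 4 * n + 8 * n) {
    off <- 64 + 4 * n
    x <- readBin(bytes[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
                 endian = "big")
    y <- readBin(bytes[(off + 4 * n + 1):(off + 8 * n)], "numeric", n = n,
                 size = 4, endian = "big")
  } else {
    x <- xi; y <- yi
  }
  ri4 <- function(off) readBin(bytes[(off + 1):(off + 4)], "integer",
                               size = 4, endian = "big")
  h2 <- ri4(60)
  if (h2 > 0 && length(bytes) >= h2 + 24) {
    name_off <- ri4(h2 + 16); name_len <- ri4(h2 + 20)
    if (name_len > 0 && length(bytes) >= name_off + 2 * name_len) {
      chars <- readBin(bytes[(name_off + 1):(name_off + 2 * name_len)],
                       "integer", n = name_len, size = 2, endian = "big",
                       signed = FALSE)
      name <- intToUtf8(chars)
    }
  }
  meta <- parse_imagej_roi_name(name)
  list(id = meta$id, label = meta$label, round = meta$round,
       polygon = cbind(y - 0.5, x - 0.5))
}
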