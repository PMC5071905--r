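#' Grayscale B-mode image container
#'
#' Wraps a 2-D matrix of 8-bit gray values (0--255) together with a free-text
#' provenance string. The coordinate convention throughout the package is
#' `(row, col)`, 0-based, origin at the top-left corner, so that "above"
#' always means a smaller row index -- matching the B-mode display, where the
#' transducer (and the anterior neck) is at the top of the image.
#'
#' @param pixels integer or numeric matrix of gray values in `[0, 255]`.
#' @param source free-text provenance (e.g. a file path).
#' @return An object of class `gray_image` with elements `pixels` (integer
#'   matrix), `height`, `width` and `source`.
#' @export
gray_image <- function(pixels, source = "in-memory") {
  if (!is.matrix(pixels)) eq_error("echoquant_format", "pixels must be a matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    eq_error("echoquant_format", "image must be at least 2 x 2 pixels")
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255))
    eq_error("echoquant_format", "gray values must lie in [0, 255]")
  # file loaders always yield 8-bit integers; continuous values in [0, 255]
  # are tolerated for in-memory analysis (e.g. averaged frames)
  if (all(pixels == floor(pixels))) storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         source = as.character(source)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, gray range [%s, %s], source: %s\n",
              x$height, x$width, format(min(x$pixels)), format(max(x$pixels)),
              x$source))
  invisible(x)
}

#' Read an 8-bit grayscale image from PNG or single-frame DICOM
#'
#' PNG files may be 8-bit gray, gray+alpha, RGB or RGBA; colour inputs are
#' converted by ITU-R BT.601 luminance (0.299 R + 0.587 G + 0.114 B) and
#' rounded half-up. DICOM files must be uncompressed single-frame 8-bit
#' grayscale; `MONOCHROME1` images are inverted on load so that a larger
#' stored value is always brighter (the `MONOCHROME2` convention assumed by
#' all echogenicity computations).
#'
#' @param path path to a `.png` or DICOM file.
#' @return A [gray_image].
#' @export
load_grayscale_image <- function(path) {
  if (!file.exists(path)) eq_error("echoquant_format", paste("file not found:", path))
  if (is_dicom_file(path)) return(read_dicom_gray(path))
  if (!grepl("\\.png$", path, ignore.case = TRUE))
    eq_error("echoquant_format", paste("unrecognised image format:", path))
  arr <- tryCatch(png::readPNG(path), error = function(e)
    eq_error("echoquant_format", paste("unreadable PNG:", conditionMessage(e))))
  px <- if (length(dim(arr)) == 2L) {
    arr * 255
  } else {
    nch <- dim(arr)[3]
    if (nch >= 3L) {
      lum <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
      lum * 255
    } else {
      arr[, , 1] * 255  # gray + alpha
    }
  }
  gray_image(matrix(as.integer(floor(px + 0.5)), nrow(px), ncol(px)), source = path)
}

#' Named region outlines for one nodule image
#'
#' @param nodule numeric n x 2 matrix of `(row, col)` polygon vertices,
#'   0-based, in pixel-center units (the center of pixel `(i, j)` is the
#'   point `(i, j)`). Required, at least 3 vertices, simple polygon.
#' @param thyroid,muscle optional polygons with the same convention.
#' @param image optional name of the associated image file.
#' @return An object of class `region_set`.
#' @export
region_set <- function(nodule, thyroid = NULL, muscle = NULL, image = NULL) {
  nodule <- check_polygon(nodule, "nodule")
  if (!is.null(thyroid)) thyroid <- check_polygon(thyroid, "thyroid")
  if (!is.null(muscle)) muscle <- check_polygon(muscle, "muscle")
  structure(list(image = image, nodule = nodule, thyroid = thyroid, muscle = muscle),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  here <- function(p) if (is.null(p)) "absent" else sprintf("%d vertices", nrow(p))
  cat(sprintf("<region_set> nodule: %s; thyroid: %s; muscle: %s\n",
              here(x$nodule), here(x$thyroid), here(x$muscle)))
  invisible(x)
}

check_polygon <- function(poly, name) {
  if (is.list(poly) && !is.matrix(poly)) poly <- do.call(rbind, lapply(poly, as.numeric))
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || anyNA(poly))
    eq_error("echoquant_validation", sprintf("%s polygon must be an n x 2 numeric matrix", name))
  # drop a repeated closing vertex
  n <- nrow(poly)
  if (n >= 2L && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3L)
    eq_error("echoquant_validation", sprintf("%s polygon needs at least 3 vertices", name))
  if (!polygon_is_simple(poly))
    eq_error("echoquant_validation", sprintf("%s polygon is self-intersecting", name))
  dimnames(poly) <- list(NULL, c("row", "col"))
  poly
}

# non-adjacent edge pairs must not intersect
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (segments_cross(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

orient2 <- function(p, q, r) {
  v <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  sign(v)
}

on_segment <- function(p, q, r) {
  min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
    min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
}

segments_cross <- function(p1, p2, p3, p4) {
  d1 <- orient2(p3, p4, p1); d2 <- orient2(p3, p4, p2)
  d3 <- orient2(p1, p2, p3); d4 <- orient2(p1, p2, p4)
  if (d1 != d2 && d3 != d4) return(TRUE)
  (d1 == 0 && on_segment(p3, p4, p1)) || (d2 == 0 && on_segment(p3, p4, p2)) ||
    (d3 == 0 && on_segment(p1, p2, p3)) || (d4 == 0 && on_segment(p1, p2, p4))
}

#' Read a region JSON file
#'
#' Schema: `{"image": "<file>", "regions": {"nodule": [[r,c],...],
#' "thyroid": [[r,c],...]?, "muscle": [[r,c],...]?}}` with 0-based
#' `(row, col)` float coordinates. The nodule polygon is required; thyroid
#' and muscle are optional (the automatic-reference workflow needs neither).
#'
#' @param path path to the JSON file.
#' @return A [region_set].
#' @export
load_region_file <- function(path) {
  if (!file.exists(path)) eq_error("echoquant_schema", paste("file not found:", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyMatrix = TRUE),
                  error = function(e) eq_error("echoquant_schema",
                    paste("unreadable region JSON:", conditionMessage(e))))
  regs <- doc$regions
  if (is.null(regs) || is.null(regs$nodule))
    eq_error("echoquant_schema", "region file must contain regions$nodule")
  region_set(nodule = regs$nodule, thyroid = regs$thyroid, muscle = regs$muscle,
             image = doc$image)
}

#' Write a region set back to the JSON schema read by [load_region_file]
#' @param regions a [region_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_region_file <- function(regions, path) {
  regs <- list(nodule = unname(regions$nodule))
  if (!is.null(regions$thyroid)) regs$thyroid <- unname(regions$thyroid)
  if (!is.null(regions$muscle)) regs$muscle <- unname(regions$muscle)
  doc <- list(image = regions$image, regions = regs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Rasterize a polygon to a pixel mask
#'
#' A pixel is selected iff its center lies inside the polygon under the
#' even-odd rule. The center of pixel `(i, j)` (0-based) is the point
#' `(row = i, col = j)` in region coordinates. Centers exactly on the
#' boundary are resolved half-open: top and left edges inclusive, bottom and
#' right edges exclusive, so that abutting polygons tile without overlap.
#'
#' @param poly numeric n x 2 `(row, col)` vertex matrix (0-based).
#' @param height,width image dimensions in pixels.
#' @return A logical `height x width` matrix; `sum()` of it is the pixel
#'   count. Errors with class `echoquant_empty_mask` if no pixel center is
#'   covered (degenerate or sub-pixel polygon).
#' @export
rasterize_polygon <- function(poly, height, width) {
  poly <- check_polygon(poly, "polygon")
  rmin <- max(0L, floor(min(poly[, 1])));  rmax <- min(height - 1L, ceiling(max(poly[, 1])))
  cmin <- max(0L, floor(min(poly[, 2])));  cmax <- min(width - 1L, ceiling(max(poly[, 2])))
  mask <- matrix(FALSE, height, width)
  if (rmin <= rmax && cmin <= cmax) {
    rows <- rmin:rmax
    cols <- cmin:cmax
    pts <- cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))
    inside <- points_in_polygon(pts[, 1], pts[, 2], poly)
    mask[cbind(pts[, 1] + 1L, pts[, 2] + 1L)] <- inside
  }
  if (!any(mask))
    eq_error("echoquant_empty_mask", "polygon covers no pixel center")
  mask
}

# Even-odd ray casting: a ray is cast in the +col direction from each point;
# an edge counts as crossed when the point row lies in the edge's half-open
# row span and the point col is strictly left of the edge at that row. This
# yields the top/left-inclusive half-open boundary rule.
points_in_polygon <- function(pr, pc, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(pr))
  r1 <- poly[, 1]; c1 <- poly[, 2]
  r2 <- poly[c(2:n, 1), 1]; c2 <- poly[c(2:n, 1), 2]
  for (k in seq_len(n)) {
    if (r1[k] == r2[k]) next  # horizontal edge never crossed
    spans <- (r1[k] > pr) != (r2[k] > pr)
    if (!any(spans)) next
    xint <- c1[k] + (pr[spans] - r1[k]) * (c2[k] - c1[k]) / (r2[k] - r1[k])
    idx <- which(spans)[pc[spans] < xint]
    inside[idx] <- !inside[idx]
  }
  inside
}
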