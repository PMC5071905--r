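# Independent brute-force oracles, written directly from the definitions
# with explicit loops, deliberately sharing no code with the package.

# random convex polygon (row, col), jittered so no pixel center lies on an
# edge; convexity makes an independent containment test trivial
random_convex_polygon <- function(height, width, n_pts = 8) {
  r <- stats::runif(n_pts, 0.5, height - 1.5) + pi * 1e-4
  c <- stats::runif(n_pts, 0.5, width - 1.5) + exp(1) * 1e-4
  hull <- grDevices::chull(c, r)   # chull takes (x, y)
  cbind(row = r[hull], col = c[hull])
}

# convex containment: point is inside iff all edge cross-products share sign
convex_contains <- function(poly, pr, pc) {
  n <- nrow(poly)
  s <- 0
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    cr <- (poly[k2, 1] - poly[k, 1]) * (pc - poly[k, 2]) -
          (poly[k2, 2] - poly[k, 2]) * (pr - poly[k, 1])
    if (cr == 0) return(NA)    # on an edge: jitter should prevent this
    if (s == 0) s <- sign(cr)
    else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

rasterize_oracle <- function(poly, height, width) {
  mask <- matrix(FALSE, height, width)
  for (i in 0:(height - 1)) for (j in 0:(width - 1))
    mask[i + 1, j + 1] <- isTRUE(convex_contains(poly, i, j))
  mask
}

# automatic-reference chain computed with explicit loops from the verbal
# definitions: anterior = outside nodule and above the nodule center row;
# L = mean of non-zero anterior grays; reference = 0 < gray < L; the index
# is (ei_n - mu_ref)/mu_ref.
auto_reference_oracle <- function(pixels, nodule_mask, ei_n) {
  h <- nrow(pixels); w <- ncol(pixels)
  rows0 <- c()
  for (i in 1:h) for (j in 1:w) if (nodule_mask[i, j]) rows0 <- c(rows0, i - 1)
  center <- mean(rows0)
  ant <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w)
    if ((i - 1) < center && !nodule_mask[i, j]) ant[i, j] <- TRUE
  if (!any(ant)) return(list(error = "no_reference"))
  vals <- c()
  for (i in 1:h) for (j in 1:w)
    if (ant[i, j] && pixels[i, j] > 0) vals <- c(vals, pixels[i, j])
  if (length(vals) == 0) return(list(error = "no_reference"))
  L <- sum(vals) / length(vals)
  ref <- c()
  for (i in 1:h) for (j in 1:w)
    if (ant[i, j] && pixels[i, j] > 0 && pixels[i, j] < L)
      ref <- c(ref, pixels[i, j])
  if (length(ref) == 0) return(list(error = "no_reference"))
  mu_ref <- sum(ref) / length(ref)
  list(center = center, L = L, mu_ref = mu_ref,
       ei_auto = (ei_n - mu_ref) / mu_ref)
}

# two-sided Fisher p by full enumeration with log-binomial coefficients
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  logp <- function(x) lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)
  support <- max(0, k - n2):min(k, m)
  lp <- sapply(support, logp)
  p_obs <- logp(a)
  sum(exp(lp[lp <= p_obs + 1e-10]))
}

# AUC by looping over every positive x negative pair
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# hand-built implicit-VR little-endian DICOM byte stream, independent of
# the package's writer
le16 <- function(x) as.raw(c(x %% 256, x %/% 256))
le32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                             (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
implicit_el <- function(group, elem, value) {
  if (length(value) %% 2 == 1) value <- c(value, as.raw(0))
  c(le16(group), le16(elem), le32(length(value)), value)
}
explicit_short_el <- function(group, elem, vr, value) {
  if (length(value) %% 2 == 1) value <- c(value, as.raw(0))
  c(le16(group), le16(elem), charToRaw(vr), le16(length(value)), value)
}
dicom_bytes_implicit <- function(pixels, photometric = "MONOCHROME2",
                                 n_frames = NULL) {
  meta <- c(
    explicit_short_el(2, 16, "UI", charToRaw("1.2.840.10008.1.2"))  # transfer syntax
  )
  meta <- c(explicit_short_el(2, 0, "UL", le32(length(meta))), meta)
  ds <- c(
    implicit_el(0x28, 0x02, le16(1)),
    implicit_el(0x28, 0x04, charToRaw(photometric)),
    if (!is.null(n_frames)) implicit_el(0x28, 0x08, charToRaw(as.character(n_frames))),
    implicit_el(0x28, 0x10, le16(nrow(pixels))),
    implicit_el(0x28, 0x11, le16(ncol(pixels))),
    implicit_el(0x28, 0x100, le16(8)),
    implicit_el(0x7FE0, 0x10, as.raw(as.vector(t(pixels))))
  )
  c(as.raw(rep(0, 128)), charToRaw("DICM"), meta, ds)
}

# small helpers shared by several test files
tiny_image <- function(m) gray_image(m, source = "test")

rasterize_polygon_or_empty <- function(poly, h, w) {
  tryCatch(rasterize_polygon(poly, h, w),
           echoquant_empty_mask = function(e) matrix(FALSE, h, w))
}

rect_poly <- function(r1, c1, r2, c2) {
  rbind(c(r1, c1), c(r1, c2), c(r2, c2), c(r2, c1))
}

expand_2x2 <- function(tp, fn, fp, tn) {
  data.frame(
    truth_bin = c(rep(1L, tp + fn), rep(0L, fp + tn)),
    truth = c(rep("malignant", tp + fn), rep("benign", fp + tn)),
    x = c(rep(1L, tp), rep(0L, fn), rep(1L, fp), rep(0L, tn))
  )
}
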