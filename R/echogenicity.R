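#' Outlier-trimming policy for nodule pixels
#'
#' Before the nodule mean is taken, anechoic pixels (cystic fluid, near-black)
#' and hyperechoic foci (calcifications, near-saturation) are removed: they
#' reflect structures, not the echogenicity of the solid nodule tissue.
#'
#' Two policies are offered:
#' \describe{
#'   \item{`"fence"` (default)}{Robust Tukey fences on the nodule's gray
#'     distribution. Zero-valued pixels are always anechoic (zero marks the
#'     outside of the imaging field / pure fluid). Quartiles are computed on
#'     the non-zero values (type-7); a pixel is anechoic when its value is
#'     strictly below `Q1 - k * IQR` and a hyperechoic focus when strictly
#'     above `Q3 + k * IQR`, with `k = 1.5`. Strict comparisons mean a
#'     constant region is never trimmed.}
#'   \item{`"absolute"`}{Fixed gray cut-offs: anechoic when `value <= a_low`
#'     (default 5), hyperechoic when `value >= a_high` (default 250).}
#'   \item{`"none"`}{No trimming at all. For continuous-valued test images
#'     and for phantoms known to contain no cystic or calcified structure,
#'     where every pixel carries echogenicity information.}
#' }
#'
#' @param method `"fence"`, `"absolute"` or `"none"`.
#' @param k fence multiplier (fence policy).
#' @param a_low,a_high absolute gray cut-offs (absolute policy).
#' @return An object of class `trim_policy`.
#' @export
trim_policy <- function(method = c("fence", "absolute", "none"), k = 1.5,
                        a_low = 5, a_high = 250) {
  method <- match.arg(method)
  structure(list(method = method, k = k, a_low = a_low, a_high = a_high),
            class = "trim_policy")
}

#' Remove anechoic and hyperechoic outlier pixels
#'
#' @param values numeric vector of gray values (non-empty).
#' @param policy a [trim_policy].
#' @return List with `retained` (values kept), `n_low` (anechoic pixels
#'   removed) and `n_high` (hyperechoic foci removed). Errors with class
#'   `echoquant_degenerate_nodule` if nothing survives trimming.
#' @export
trim_outlier_pixels <- function(values, policy = trim_policy()) {
  if (length(values) == 0L) eq_error("echoquant_empty_region", "no pixel values supplied")
  if (policy$method == "none") {
    low <- rep(FALSE, length(values))
    high <- low
  } else if (policy$method == "absolute") {
    low <- values <= policy$a_low
    high <- !low & values >= policy$a_high
  } else {
    nz <- values[values > 0]
    if (length(nz) == 0L)
      eq_error("echoquant_degenerate_nodule", "nodule is entirely anechoic after trimming")
    q <- stats::quantile(nz, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    low <- values == 0 | values < q[1] - policy$k * iqr
    high <- !low & values > q[2] + policy$k * iqr
  }
  retained <- values[!low & !high]
  if (length(retained) == 0L)
    eq_error("echoquant_degenerate_nodule", "all nodule pixels removed as outliers")
  list(retained = retained, n_low = sum(low), n_high = sum(high))
}

#' Mean gray level of a masked region
#'
#' @param image a [gray_image].
#' @param mask logical matrix congruent with the image.
#' @return Arithmetic mean of the gray values under the mask (double).
#' @export
region_mean <- function(image, mask) {
  check_mask(image, mask)
  if (!any(mask)) eq_error("echoquant_empty_region", "mask selects no pixels")
  mean(image$pixels[mask])
}

check_mask <- function(image, mask) {
  if (!is.logical(mask) || !identical(dim(mask), dim(image$pixels)))
    eq_error("echoquant_validation", "mask must be a logical matrix with the image's shape")
  invisible(TRUE)
}

#' Nodule echogenicity index EI_N (trimmed mean gray level)
#'
#' @inheritParams region_mean
#' @param nodule_mask logical nodule mask.
#' @param policy a [trim_policy].
#' @return List with `ei_n`, `n_low`, `n_high`.
#' @export
compute_ei_n <- function(image, nodule_mask, policy = trim_policy()) {
  check_mask(image, nodule_mask)
  if (!any(nodule_mask)) eq_error("echoquant_empty_region", "nodule mask is empty")
  tr <- trim_outlier_pixels(as.numeric(image$pixels[nodule_mask]), policy)
  list(ei_n = mean(tr$retained), n_low = tr$n_low, n_high = tr$n_high)
}

#' Reference-adjusted echogenicity indices
#'
#' `EI_N-T = EI_N - mu_thyroid` (nodule vs thyroid parenchyma) and
#' `EI_N-M = EI_N - mu_muscle` (nodule vs strap muscle). Negative values mean
#' the nodule is darker than the reference tissue.
#'
#' @param ei_n trimmed nodule mean gray.
#' @param mu_thyroid,mu_muscle reference region means.
#' @return List with `ei_nt` and `ei_nm`.
#' @export
compute_adjusted_eis <- function(ei_n, mu_thyroid, mu_muscle) {
  list(ei_nt = ei_n - mu_thyroid, ei_nm = ei_n - mu_muscle)
}

#' Anterior region of a nodule
#'
#' The anterior region is everything outside the contoured nodule and above
#' its center: anatomically, the tissue between the transducer and the
#' nodule, which is dominated by the strap muscles. "Above" is a strictly
#' smaller row index than the nodule center row.
#'
#' @inheritParams compute_ei_n
#' @param center `"centroid"` (mean row of the nodule mask, default) or
#'   `"bbox"` (midpoint of the mask's row range). Fractional center rows are
#'   allowed; the comparison `row < center_row` is strict.
#' @param lateral `"full"` (default, whole image width) or `"nodule-width"`
#'   (restrict to the nodule mask's column range).
#' @return List with `mask` (logical anterior mask) and `center_row`
#'   (0-based, possibly fractional).
#' @export
anterior_region_mask <- function(image, nodule_mask,
                                 center = c("centroid", "bbox"),
                                 lateral = c("full", "nodule-width")) {
  center <- match.arg(center); lateral <- match.arg(lateral)
  check_mask(image, nodule_mask)
  if (!any(nodule_mask)) eq_error("echoquant_empty_region", "nodule mask is empty")
  rows0 <- row(nodule_mask)[nodule_mask] - 1L   # 0-based rows of nodule pixels
  center_row <- if (center == "centroid") mean(rows0) else mean(range(rows0))
  above <- (row(nodule_mask) - 1L) < center_row
  mask <- above & !nodule_mask
  if (lateral == "nodule-width") {
    cols0 <- col(nodule_mask)[nodule_mask] - 1L
    inwidth <- (col(nodule_mask) - 1L) >= min(cols0) & (col(nodule_mask) - 1L) <= max(cols0)
    mask <- mask & inwidth
  }
  if (!any(mask))
    eq_error("echoquant_no_reference", "anterior region is empty")
  list(mask = mask, center_row = center_row)
}

#' Anterior brightness level L
#'
#' `L` is the mean of the strictly positive gray values in the anterior
#' region; zeros are outside the imaging field and carry no echo information.
#'
#' @inheritParams region_mean
#' @param anterior_mask logical anterior-region mask.
#' @return `L` (double).
#' @export
compute_anterior_L <- function(image, anterior_mask) {
  check_mask(image, anterior_mask)
  v <- image$pixels[anterior_mask]
  v <- v[v > 0]
  if (length(v) == 0L)
    eq_error("echoquant_no_reference", "anterior region has no non-zero pixels")
  mean(v)
}

#' Automatic outside-reference selection
#'
#' A pixel `(i, j)` of the anterior region belongs to the outside reference
#' iff `0 < GR_ij < L` (strict at both ends): darker than the anterior
#' average, so that the reference resembles the strap muscle, but not
#' zero-valued. `mu_ref` is the mean gray of the reference pixels.
#'
#' @inheritParams compute_anterior_L
#' @param L anterior brightness level from [compute_anterior_L].
#' @return List with `reference_mask`, `mu_ref`, `L`.
#' @export
select_reference <- function(image, anterior_mask, L) {
  check_mask(image, anterior_mask)
  if (!is.finite(L) || L <= 0) eq_error("echoquant_no_reference", "L must be positive")
  ref <- anterior_mask & image$pixels > 0 & image$pixels < L
  if (!any(ref))
    eq_error("echoquant_no_reference", "no anterior pixel lies strictly below L")
  list(reference_mask = ref, mu_ref = mean(image$pixels[ref]), L = L)
}

#' Automatic ratio-normalised echogenicity index EI_(N-R)/R
#'
#' @param ei_n trimmed nodule mean gray.
#' @param mu_ref automatic outside-reference mean.
#' @return `(ei_n - mu_ref) / mu_ref` (dimensionless, signed).
#' @export
compute_ei_auto <- function(ei_n, mu_ref) {
  if (!is.finite(mu_ref) || mu_ref <= 0)
    eq_error("echoquant_undefined_index", "mu_ref must be positive")
  (ei_n - mu_ref) / mu_ref
}

#' Classify nodule echogenicity from the adjusted indices
#'
#' "Marked hypoechogenicity" means the nodule is darker than strap muscle
#' (`EI_N-M < 0`); "hypoechogenicity" darker than thyroid parenchyma
#' (`EI_N-T < 0`); otherwise iso- or hyperechoic. Both comparisons are
#' strict. When the comparator needed to settle the label is absent the
#' class is `"undetermined"`.
#'
#' @param ei_nt,ei_nm signed adjusted indices; `NULL`/`NA` marks absent.
#' @return One of `"marked_hypo"`, `"hypo"`, `"iso_or_hyper"`,
#'   `"undetermined"`.
#' @export
classify_echogenicity <- function(ei_nt = NULL, ei_nm = NULL) {
  has_nt <- !is.null(ei_nt) && !is.na(ei_nt)
  has_nm <- !is.null(ei_nm) && !is.na(ei_nm)
  if (!has_nt && !has_nm)
    eq_error("echoquant_classification", "both adjusted indices are absent")
  if (has_nm && ei_nm < 0) return("marked_hypo")
  if (has_nt && ei_nt < 0) return("hypo")
  if (has_nt) return("iso_or_hyper")
  "undetermined"
}

#' Full echogenicity analysis of one nodule image
#'
#' Rasterizes the region outlines, computes the trimmed nodule index EI_N,
#' the adjusted indices EI_N-T / EI_N-M where the corresponding reference
#' region was outlined, always attempts the automatic outside reference
#' (EI_(N-R)/R), and classifies the nodule. Indices whose manual reference
#' region is absent are reported as `NA`, never as zero. If no valid
#' automatic reference exists (e.g. a constant image, where no anterior
#' pixel is strictly darker than the anterior average), `mu_ref`, `L` and
#' `ei_auto` are `NA`.
#'
#' @param image a [gray_image].
#' @param regions a [region_set] (nodule required).
#' @param policy a [trim_policy] for the nodule pixels; thyroid and muscle
#'   means are untrimmed raw means.
#' @param center,lateral options forwarded to [anterior_region_mask].
#' @return An object of class `echo_result`: a list with `mu_nodule`,
#'   `mu_thyroid`, `mu_muscle`, `mu_ref`, `L`, `ei_n`, `ei_nt`, `ei_nm`,
#'   `ei_auto`, `n_trimmed_low`, `n_trimmed_high`, `echo_class`,
#'   `n_nodule_px`, `center_row`.
#' @export
analyze_image <- function(image, regions, policy = trim_policy(),
                          center = c("centroid", "bbox"),
                          lateral = c("full", "nodule-width")) {
  center <- match.arg(center); lateral <- match.arg(lateral)
  if (is.null(regions$nodule))
    eq_error("echoquant_validation", "nodule region is required")
  h <- image$height; w <- image$width
  nod_mask <- rasterize_polygon(regions$nodule, h, w)
  ein <- compute_ei_n(image, nod_mask, policy)
  mu_thyroid <- if (!is.null(regions$thyroid))
    region_mean(image, rasterize_polygon(regions$thyroid, h, w)) else NA_real_
  mu_muscle <- if (!is.null(regions$muscle))
    region_mean(image, rasterize_polygon(regions$muscle, h, w)) else NA_real_

  ei_nt <- if (is.na(mu_thyroid)) NA_real_ else ein$ei_n - mu_thyroid
  ei_nm <- if (is.na(mu_muscle)) NA_real_ else ein$ei_n - mu_muscle

  mu_ref <- L <- ei_auto <- NA_real_
  center_row <- NA_real_
  auto <- tryCatch({
    ant <- anterior_region_mask(image, nod_mask, center = center, lateral = lateral)
    Lv <- compute_anterior_L(image, ant$mask)
    sel <- select_reference(image, ant$mask, Lv)
    list(center_row = ant$center_row, L = Lv, mu_ref = sel$mu_ref)
  }, echoquant_no_reference = function(e) NULL)
  if (!is.null(auto)) {
    center_row <- auto$center_row
    L <- auto$L
    mu_ref <- auto$mu_ref
    ei_auto <- compute_ei_auto(ein$ei_n, mu_ref)
  }

  echo_class <- if (is.na(ei_nt) && is.na(ei_nm)) "undetermined" else
    classify_echogenicity(ei_nt, ei_nm)

  structure(list(
    mu_nodule = ein$ei_n, mu_thyroid = mu_thyroid, mu_muscle = mu_muscle,
    mu_ref = mu_ref, L = L,
    ei_n = ein$ei_n, ei_nt = ei_nt, ei_nm = ei_nm, ei_auto = ei_auto,
    n_trimmed_low = ein$n_low, n_trimmed_high = ein$n_high,
    echo_class = echo_class, n_nodule_px = sum(nod_mask),
    center_row = center_row, source = image$source
  ), class = "echo_result")
}

#' @export
print.echo_result <- function(x, ...) {
  fmt <- function(v, d = 2) if (is.na(v)) "absent" else formatC(v, format = "f", digits = d)
  cat("Echogenicity analysis\n")
  cat(sprintf("  EI_N        (nodule mean)     : %s\n", fmt(x$ei_n)))
  cat(sprintf("  EI_N-T      (vs thyroid)      : %s\n", fmt(x$ei_nt)))
  cat(sprintf("  EI_N-M      (vs muscle)       : %s\n", fmt(x$ei_nm)))
  cat(sprintf("  EI_(N-R)/R  (automatic)       : %s\n", fmt(x$ei_auto, 4)))
  cat(sprintf("  mu_ref = %s, L = %s; trimmed %d anechoic + %d hyperechoic of %d px\n",
              fmt(x$mu_ref), fmt(x$L), x$n_trimmed_low, x$n_trimmed_high,
              x$n_nodule_px))
  cat(sprintf("  class: %s\n", x$echo_class))
  invisible(x)
}

#' @export
as.data.frame.echo_result <- function(x, ...) {
  data.frame(
    mu_nodule = x$mu_nodule, mu_thyroid = x$mu_thyroid, mu_muscle = x$mu_muscle,
    mu_ref = x$mu_ref, L = x$L,
    ei_n = x$ei_n, ei_nt = x$ei_nt, ei_nm = x$ei_nm, ei_auto = x$ei_auto,
    n_trimmed_low = x$n_trimmed_low, n_trimmed_high = x$n_trimmed_high,
    echo_class = x$echo_class, n_nodule_px = x$n_nodule_px,
    stringsAsFactors = FALSE
  )
}
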