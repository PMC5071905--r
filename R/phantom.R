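# Synthetic B-mode-like phantoms and cohorts. The phantom emulates the
# gross anatomy of a transverse neck sonogram: a dark strap-muscle band at
# the top (anterior), brighter thyroid parenchyma below it, and an
# elliptical nodule embedded in the parenchyma, with multiplicative gamma
# speckle, optional anechoic cyst disks and hyperechoic calcification foci.

#' Configuration for a synthetic speckle phantom
#'
#' Region mean gray levels default to the anatomy-typical levels of a
#' thyroid sonogram: strap muscle ~19, thyroid parenchyma ~41, and a
#' hypoechoic nodule at 25. Speckle is multiplicative gamma noise with unit
#' mean; `speckle_shape` controls its variance (variance of the multiplier
#' is `1/speckle_shape`, so the default 4 gives a coefficient of variation
#' of 0.5, a right-skewed texture typical of log-compressed B-mode).
#'
#' @param height,width canvas size in pixels.
#' @param mu_nodule,mu_thyroid,mu_muscle,mu_background target region mean
#'   gray levels in `[0, 255]`.
#' @param speckle_shape gamma shape of the unit-mean speckle multiplier.
#' @param cyst_fraction fraction of the nodule area replaced by a central
#'   anechoic disk (values 0--2), in `[0, 1)`.
#' @param calc_count number of hyperechoic foci (values 250--255) placed
#'   inside the nodule.
#' @param nodule_center,nodule_axes ellipse center `(row, col)` and
#'   semi-axes `(a_row, b_col)` in pixels (0-based center coordinates);
#'   defaults place the nodule in the lower middle of the canvas.
#' @param seed RNG seed; identical seeds give byte-identical phantoms.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(height = 256, width = 256,
                           mu_nodule = 25, mu_thyroid = 41.31,
                           mu_muscle = 18.59, mu_background = 41.31,
                           speckle_shape = 4, cyst_fraction = 0,
                           calc_count = 0,
                           nodule_center = NULL, nodule_axes = NULL,
                           seed = 1L) {
  if (is.null(nodule_center)) nodule_center <- c(0.62 * height, 0.5 * width)
  if (is.null(nodule_axes)) nodule_axes <- c(0.16 * height, 0.22 * width)
  mus <- c(mu_nodule, mu_thyroid, mu_muscle, mu_background)
  if (any(mus < 0) || any(mus > 255))
    eq_error("echoquant_config", "region means must lie in [0, 255]")
  if (cyst_fraction < 0 || cyst_fraction >= 1)
    eq_error("echoquant_config", "cyst_fraction must lie in [0, 1)")
  if (speckle_shape <= 0) eq_error("echoquant_config", "speckle_shape must be positive")
  # layout: muscle band rows [0, 0.14h); thyroid band rows [0.16h, 0.34h)
  muscle_rows <- c(0.02 * height, 0.14 * height)
  thyroid_rows <- c(0.18 * height, 0.34 * height)
  if (nodule_center[1] - nodule_axes[1] <= thyroid_rows[2] ||
      nodule_center[1] + nodule_axes[1] >= height - 1 ||
      nodule_center[2] - nodule_axes[2] <= 0 ||
      nodule_center[2] + nodule_axes[2] >= width - 1)
    eq_error("echoquant_layout", "nodule ellipse does not fit below the thyroid band")
  structure(list(height = height, width = width,
                 mu_nodule = mu_nodule, mu_thyroid = mu_thyroid,
                 mu_muscle = mu_muscle, mu_background = mu_background,
                 speckle_shape = speckle_shape, cyst_fraction = cyst_fraction,
                 calc_count = calc_count,
                 nodule_center = nodule_center, nodule_axes = nodule_axes,
                 muscle_rows = muscle_rows, thyroid_rows = thyroid_rows,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

ellipse_polygon <- function(center, axes, n = 72) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(row = center[1] + axes[1] * sin(th), col = center[2] + axes[2] * cos(th))
}

#' Generate a synthetic speckle phantom with known ground truth
#'
#' Pixel values are `round(clip(mu_region * G, 0, 255))` with `G` a
#' unit-mean gamma multiplier (shape `speckle_shape`). A central anechoic
#' disk covering `cyst_fraction` of the nodule mask is set to gray values
#' 0--2, and `calc_count` small foci inside the nodule are set to 250--255.
#'
#' @param config a [phantom_config].
#' @return List with `image` (a [gray_image]), `regions` (a [region_set]
#'   with nodule/thyroid/muscle polygons) and `truth`: the configured means
#'   and the implied indices `ei_nt_true = mu_nodule - mu_thyroid`,
#'   `ei_nm_true = mu_nodule - mu_muscle`, and
#'   `ei_auto_true = (mu_nodule - mu_muscle)/mu_muscle` (approximate: the
#'   automatic reference resembles, but is not exactly, the muscle level),
#'   plus the cyst and calcification pixel index lists.
#' @export
make_phantom <- function(config = phantom_config()) {
  set.seed(config$seed)
  h <- config$height; w <- config$width
  r0 <- row(matrix(0, h, w)) - 1L  # 0-based pixel-center coordinates
  c0 <- col(matrix(0, h, w)) - 1L

  mu <- matrix(config$mu_background, h, w)
  mu[r0 >= config$muscle_rows[1] & r0 < config$muscle_rows[2]] <- config$mu_muscle
  mu[r0 >= config$thyroid_rows[1] & r0 < config$thyroid_rows[2]] <- config$mu_thyroid
  ell <- ((r0 - config$nodule_center[1]) / config$nodule_axes[1])^2 +
         ((c0 - config$nodule_center[2]) / config$nodule_axes[2])^2 <= 1
  mu[ell] <- config$mu_nodule

  g <- matrix(stats::rgamma(h * w, shape = config$speckle_shape,
                            rate = config$speckle_shape), h, w)
  px <- pmin(255, pmax(0, round(mu * g)))

  nod_poly <- ellipse_polygon(config$nodule_center, config$nodule_axes)
  nod_mask <- rasterize_polygon(nod_poly, h, w)

  cyst_idx <- integer(0)
  if (config$cyst_fraction > 0) {
    n_target <- config$cyst_fraction * sum(nod_mask)
    d2 <- (r0 - config$nodule_center[1])^2 + (c0 - config$nodule_center[2])^2
    inside <- which(nod_mask)
    cyst_idx <- inside[order(d2[inside])][seq_len(round(n_target))]
    px[cyst_idx] <- sample(0:2, length(cyst_idx), replace = TRUE)
  }
  calc_idx <- integer(0)
  if (config$calc_count > 0) {
    candidates <- setdiff(which(ell), cyst_idx)
    centers <- sample(candidates, config$calc_count)
    for (ct in centers) {
      cr <- (ct - 1L) %% h; cc <- (ct - 1L) %/% h
      spot <- which(abs(r0 - cr) <= 1 & abs(c0 - cc) <= 1 & nod_mask)
      calc_idx <- union(calc_idx, spot)
    }
    px[calc_idx] <- sample(250:255, length(calc_idx), replace = TRUE)
  }

  thy_poly <- rbind(
    c(config$thyroid_rows[1] + 1, 0.1 * w), c(config$thyroid_rows[1] + 1, 0.9 * w),
    c(config$thyroid_rows[2] - 1, 0.9 * w), c(config$thyroid_rows[2] - 1, 0.1 * w))
  mus_poly <- rbind(
    c(config$muscle_rows[1] + 1, 0.1 * w), c(config$muscle_rows[1] + 1, 0.9 * w),
    c(config$muscle_rows[2] - 1, 0.9 * w), c(config$muscle_rows[2] - 1, 0.1 * w))

  img <- gray_image(matrix(as.integer(px), h, w),
                    source = sprintf("phantom(seed=%d)", config$seed))
  regs <- region_set(nodule = nod_poly, thyroid = thy_poly, muscle = mus_poly)
  truth <- list(
    mu_nodule = config$mu_nodule, mu_thyroid = config$mu_thyroid,
    mu_muscle = config$mu_muscle,
    ei_nt_true = config$mu_nodule - config$mu_thyroid,
    ei_nm_true = config$mu_nodule - config$mu_muscle,
    ei_auto_true = (config$mu_nodule - config$mu_muscle) / config$mu_muscle,
    cyst_pixels = cyst_idx, calc_pixels = calc_idx
  )
  list(image = img, regions = regs, truth = truth)
}

#' Default per-class cohort parameters
#'
#' The defaults encode a 411-nodule study population: class sizes 254
#' benign / 157 malignant, normal echogenicity-index distributions per
#' class, and Bernoulli prevalences of the binary US features.
#'
#' @return A list with components `benign` and `malignant`, each holding
#'   `ei_mean`, `ei_sd` (named vectors over `ei_n`, `ei_nt`, `ei_nm`,
#'   `ei_auto`) and `prevalence` (named vector over the binary features).
#' @export
cohort_params <- function() {
  list(
    benign = list(
      ei_mean = c(ei_n = 39.84, ei_nt = -1.64, ei_nm = 22.45, ei_auto = 1.04),
      ei_sd   = c(ei_n = 16.23, ei_nt = 18.44, ei_nm = 15.41, ei_auto = 0.90),
      prevalence = c(size_ge_2cm = 0.7008, us_e_hypo = 0.6811,
                     irregular_margin = 0.6811, microcalcification = 0.1811,
                     heterogeneous = 0.9055)
    ),
    malignant = list(
      ei_mean = c(ei_n = 27.39, ei_nt = -13.65, ei_nm = 6.86, ei_auto = 0.22),
      ei_sd   = c(ei_n = 14.76, ei_nt = 14.88, ei_nm = 15.69, ei_auto = 0.71),
      prevalence = c(size_ge_2cm = 0.4395, us_e_hypo = 0.8981,
                     irregular_margin = 0.8217, microcalcification = 0.4331,
                     heterogeneous = 0.9682)
    )
  )
}

#' Simulate a cohort of nodule records
#'
#' Draws benign and malignant records with normally distributed
#' echogenicity indices and Bernoulli binary US features, per class.
#'
#' @param n total number of nodules (>= 10).
#' @param n_malignant number of malignant nodules (default: the benign :
#'   malignant split 254 : 157 scaled to `n`).
#' @param params per-class parameters as returned by [cohort_params].
#' @param seed RNG seed.
#' @return A data frame of nodule records: `id`, `truth`
#'   (benign/malignant), `truth_bin`, the five binary features, and the
#'   four EI columns.
#' @export
make_cohort <- function(n = 411, n_malignant = NULL, params = cohort_params(),
                        seed = 1L) {
  if (n < 10) eq_error("echoquant_config", "cohort size must be >= 10")
  if (is.null(n_malignant)) n_malignant <- round(n * 157 / 411)
  if (n_malignant < 1 || n_malignant >= n)
    eq_error("echoquant_config", "n_malignant must be in [1, n)")
  for (cl in params) {
    if (any(cl$prevalence < 0) || any(cl$prevalence > 1))
      eq_error("echoquant_config", "feature prevalences must lie in [0, 1]")
    if (any(cl$ei_sd < 0)) eq_error("echoquant_config", "EI SDs must be non-negative")
  }
  set.seed(seed)
  draw_class <- function(m, cl, label) {
    df <- data.frame(truth = rep(label, m), stringsAsFactors = FALSE)
    for (f in names(cl$prevalence))
      df[[f]] <- stats::rbinom(m, 1L, cl$prevalence[[f]])
    for (e in names(cl$ei_mean))
      df[[e]] <- stats::rnorm(m, cl$ei_mean[[e]], cl$ei_sd[[e]])
    df
  }
  out <- rbind(draw_class(n - n_malignant, params$benign, "benign"),
               draw_class(n_malignant, params$malignant, "malignant"))
  out <- cbind(id = sprintf("N%04d", seq_len(n)), out, stringsAsFactors = FALSE)
  out$truth_bin <- as.integer(out$truth == "malignant")
  out
}

#' Write a phantom image to an 8-bit grayscale PNG
#' @param image a [gray_image].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}
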