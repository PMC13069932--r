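# Synthetic brightfield field images with known staining ground truth.
#
# A field is an 8-bit grayscale matrix: near-white background, darker stained
# pixels. The default pattern paints elliptical membrane rings (annuli) to
# mimic the circumferential membrane staining of ERBB2; filled blobs are
# offered as an alternative geometry for robustness checks. The generator
# records the realized stained fraction and stained-pixel mean gray value as
# ground truth, so the quantification stage can be tested against a known
# answer without any patient material.

#' Specification of a synthetic stained field image
#'
#' @param width,height image size in pixels.
#' @param background_level gray value of unstained tissue/background
#'   (near-white; default 245).
#' @param stain_level gray value painted on stained pixels; must be darker
#'   (smaller) than `background_level`. Default 103, a moderate DAB-like tone.
#' @param target_area_fraction fraction of pixels to stain, in `[0, 1]`.
#' @param noise_sd standard deviation of additive Gaussian pixel noise, in
#'   gray-value units; 3 mimics mild acquisition noise, 0 gives an exact image.
#' @param pattern stain geometry: `"membrane-rings"` (elliptical annuli,
#'   default) or `"blobs"` (filled discs).
#' @param seed integer seed making the image reproducible; `NULL` uses the
#'   ambient RNG stream.
#' @return an object of class `image_spec`.
#' @seealso [generate_field_image()]
#' @export
image_spec <- function(width = 128, height = 128,
                       background_level = 245, stain_level = 103,
                       target_area_fraction = 0.068, noise_sd = 3,
                       pattern = c("membrane-rings", "blobs"),
                       seed = NULL) {
  pattern <- match.arg(pattern)
  spec <- list(width = as.integer(width), height = as.integer(height),
               background_level = background_level, stain_level = stain_level,
               target_area_fraction = target_area_fraction,
               noise_sd = noise_sd, pattern = pattern, seed = seed)
  validate_image_spec(spec)
  structure(spec, class = "image_spec")
}

validate_image_spec <- function(spec) {
  if (spec$width < 1 || spec$height < 1)
    stop("image dimensions must be positive")
  if (spec$stain_level >= spec$background_level)
    stop("degenerate image spec: stain_level (", spec$stain_level,
         ") must be darker than background_level (", spec$background_level, ")")
  if (spec$background_level > 255 || spec$stain_level < 0)
    stop("gray levels must lie in [0, 255]")
  if (spec$target_area_fraction < 0 || spec$target_area_fraction > 1)
    stop("target_area_fraction must lie in [0, 1]")
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative")
  invisible(spec)
}

# Pixel indices of one random elliptical annulus (membrane ring) or filled
# ellipse (blob). Cells are drawn at scales typical of x10 fields.
random_cell_pixels <- function(width, height, filled) {
  cx <- stats::runif(1, 1, width)
  cy <- stats::runif(1, 1, height)
  rx <- stats::runif(1, 5, 12)
  ry <- stats::runif(1, 5, 12)
  thick <- stats::runif(1, 0.25, 0.4) # ring thickness as fraction of radius
  x0 <- max(1L, floor(cx - rx)); x1 <- min(width, ceiling(cx + rx))
  y0 <- max(1L, floor(cy - ry)); y1 <- min(height, ceiling(cy + ry))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1
  ys <- y0:y1
  d2 <- outer((ys - cy)^2 / ry^2, (xs - cx)^2 / rx^2, "+")
  inside <- if (filled) d2 <= 1 else d2 <= 1 & d2 >= (1 - thick)^2
  if (!any(inside)) return(integer(0))
  rows <- row(d2)[inside] + y0 - 1L
  cols <- col(d2)[inside] + x0 - 1L
  (cols - 1L) * height + rows # linear index into a height x width matrix
}

#' Generate a synthetic field image with ground truth
#'
#' Paints stained structures (rings or blobs) at `stain_level` over a uniform
#' background until the requested area fraction is reached (the last structure
#' is trimmed so the stained pixel count equals
#' `round(target_area_fraction * width * height)` exactly), then adds optional
#' Gaussian noise, clips to `[0, 255]` and rounds to integers.
#'
#' With `noise_sd = 0` the image takes exactly two gray values, so the
#' min/max-midpoint threshold recovers the painted pattern pixel-for-pixel.
#'
#' @param spec an [image_spec()].
#' @return an object of class `synthetic_field`: a list with
#'   \describe{
#'     \item{image}{`height x width` integer matrix of gray values (class
#'       `gray_image`).}
#'     \item{ground_truth}{list with `stain_fraction` (realized fraction of
#'       stained pixels) and `stain_mean_intensity` (realized mean gray value
#'       over stained pixels, after noise; `NA` if no pixel is stained).}
#'     \item{spec}{the generating spec.}
#'   }
#' @examples
#' fld <- generate_field_image(image_spec(seed = 1))
#' fld$ground_truth
#' @export
generate_field_image <- function(spec) {
  if (!inherits(spec, "image_spec")) spec <- do.call(image_spec, spec)
  validate_image_spec(spec)
  with_seed_if(spec$seed, {
    n_px <- spec$width * spec$height
    k <- round(spec$target_area_fraction * n_px)
    stained <- logical(n_px)
    n_have <- 0L
    guard <- 0L
    while (n_have < k) {
      idx <- random_cell_pixels(spec$width, spec$height,
                                filled = spec$pattern == "blobs")
      new <- idx[!stained[idx]]
      need <- k - n_have
      if (length(new) > need) new <- new[seq_len(need)]
      stained[new] <- TRUE
      n_have <- n_have + length(new)
      guard <- guard + 1L
      if (guard > 5000L) { # near-total coverage: finish with loose pixels
        fill <- sample(which(!stained), k - n_have)
        stained[fill] <- TRUE
        n_have <- k
      }
    }
    img <- matrix(spec$background_level, nrow = spec$height, ncol = spec$width)
    img[stained] <- spec$stain_level
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(n_px, 0, spec$noise_sd)
    img <- matrix(as.integer(round(pmin(pmax(img, 0), 255))),
                  nrow = spec$height, ncol = spec$width)
    class(img) <- c("gray_image", class(img))
    gt <- list(
      stain_fraction = n_have / n_px,
      stain_mean_intensity = if (n_have > 0) mean(img[stained]) else NA_real_
    )
    structure(list(image = img, ground_truth = gt, spec = spec),
              class = "synthetic_field")
  })
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("<synthetic_field> %dx%d px, pattern=%s, stained %.2f%%, mean gray %.1f\n",
              x$spec$width, x$spec$height, x$spec$pattern,
              100 * x$ground_truth$stain_fraction,
              x$ground_truth$stain_mean_intensity))
  invisible(x)
}

#' Simulate a directory of field images with a ground-truth sidecar
#'
#' Writes `fields_per_slide` PNG fields for each of `n_slides` slides, named
#' `<slide>_f<field>.png`, plus `ground_truth.csv` recording the realized
#' stained fraction and stained-pixel mean intensity of every field. The
#' sidecar carries the generator's ground truth for validation only; the
#' quantification stage never reads it.
#'
#' @param dir output directory (created if absent).
#' @param n_slides number of slides.
#' @param fields_per_slide fields per slide (default 3).
#' @param spec an [image_spec()] used as template; its seed is ignored in
#'   favor of `seed`.
#' @param seed integer seed for the whole set.
#' @return invisibly, the ground-truth data frame.
#' @export
simulate_field_set <- function(dir, n_slides = 2, fields_per_slide = 3,
                               spec = image_spec(), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in seq_len(n_slides)) {
    for (f in seq_len(fields_per_slide)) {
      sub <- spec
      sub$seed <- as.integer(seed) + 1000L * s + f
      fld <- generate_field_image(sub)
      slide_id <- sprintf("slide%02d", s)
      field_id <- sprintf("%s_f%d", slide_id, f)
      write_gray_image(fld$image, file.path(dir, paste0(field_id, ".png")))
      rows[[field_id]] <- data.frame(
        slide_id = slide_id, field_id = field_id,
        stain_fraction = fld$ground_truth$stain_fraction,
        stain_mean_intensity = fld$ground_truth$stain_mean_intensity,
        seed = sub$seed)
    }
  }
  gt <- do.call(rbind, rows)
  rownames(gt) <- NULL
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(gt)
}
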