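# ImageJ-style quantification of brightfield IHC fields.
#
# Convention throughout: gray value 0 = black (most intense stain), 255 =
# white (unstained). A field is thresholded at the midpoint of its min and
# max gray values; pixels strictly below the threshold form the stain mask
# (ties at the threshold count as unstained, the conservative direction).
# Two numbers summarize a field: the mean gray value of stained pixels and
# the percent of the analyzed area that is stained.

as_gray_image <- function(image) {
  if (inherits(image, "synthetic_field")) image <- image$image
  if (!is.matrix(image)) stop("image must be a matrix of gray values")
  if (length(image) == 0) stop("image is empty")
  if (anyNA(image) || min(image) < 0 || max(image) > 255)
    stop("gray values must lie in [0, 255]")
  image
}

#' Read an image file as an 8-bit grayscale matrix
#'
#' Reads PNG, JPEG or TIFF. RGB images are collapsed to one channel by
#' Rec. 709 luminance weighting (0.2126 R + 0.7152 G + 0.0722 B); images with
#' more than 8 bits per sample are rescaled to the 0-255 range with a warning.
#'
#' @param path file path.
#' @return `height x width` integer matrix of gray values in `[0, 255]`,
#'   class `gray_image`.
#' @export
read_gray_image <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3) {
    if (dim(dat)[3] >= 3) {
      dat <- 0.2126 * dat[, , 1] + 0.7152 * dat[, , 2] + 0.0722 * dat[, , 3]
    } else {
      dat <- dat[, , 1]
    }
  }
  if (max(dat) > 1) {
    warning("sample depth exceeds 8 bits; rescaling to [0, 255]")
    dat <- dat / max(dat)
  }
  # EBImage stores width x height; transpose to the row-major convention used
  # by the rest of the package (and by png::writePNG).
  out <- t(round(dat * 255))
  mode(out) <- "integer"
  class(out) <- c("gray_image", class(out))
  out
}

#' Write a grayscale matrix as an 8-bit PNG
#'
#' @param image gray-value matrix in `[0, 255]`.
#' @param path output path.
#' @export
write_gray_image <- function(image, path) {
  image <- as_gray_image(image)
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

#' Midpoint threshold of a field
#'
#' The staining threshold is the mean of the minimum and maximum gray values
#' over the analyzed pixels (the whole field, or a region of interest when a
#' tumor-region mask is supplied).
#'
#' @param image gray-value matrix.
#' @param roi optional logical matrix, same shape, marking the analyzed
#'   region; `NULL` analyzes the whole field.
#' @return threshold gray value; attribute `degenerate` is `TRUE` when the
#'   analyzed pixels are constant (min = max), in which case the strict-below
#'   mask is necessarily empty.
#' @examples
#' compute_threshold(matrix(c(0, 255), 1)) # 127.5
#' @export
compute_threshold <- function(image, roi = NULL) {
  image <- as_gray_image(image)
  px <- roi_pixels(image, roi)
  lo <- min(px)
  hi <- max(px)
  thr <- (lo + hi) / 2
  if (lo == hi) {
    warning("degenerate field: constant gray value ", lo,
            "; segmentation will be empty")
    attr(thr, "degenerate") <- TRUE
  }
  thr
}

roi_pixels <- function(image, roi) {
  if (is.null(roi)) return(as.vector(image))
  if (!is.logical(roi) || !identical(dim(roi), dim(image)))
    stop("roi must be a logical matrix with the same dimensions as the image")
  if (!any(roi)) stop("roi is empty")
  image[roi]
}

#' Segment stained pixels at a threshold
#'
#' @param image gray-value matrix.
#' @param threshold gray value in `[0, 255]`.
#' @return logical matrix, `TRUE` exactly where the pixel value is strictly
#'   below the threshold; attribute `threshold` records the value used.
#' @export
segment_stain <- function(image, threshold) {
  image <- as_gray_image(image)
  if (threshold < 0 || threshold > 255) stop("threshold must lie in [0, 255]")
  mask <- unclass(image) < as.numeric(threshold)
  attr(mask, "threshold") <- as.numeric(threshold)
  mask
}

#' Quantify one field: mean stain intensity and percent area stained
#'
#' Thresholds the field at the min/max midpoint, segments the stained area,
#' and measures the two per-field statistics the HScore consumes: the mean
#' gray value over stained pixels and the stained percentage of the analyzed
#' area. An all-background field (empty mask) yields `pct_area = 0` and
#' `mean_intensity = NA`.
#'
#' @param image gray-value matrix (or a `synthetic_field`, whose image is
#'   used and whose ground truth is ignored).
#' @param roi optional logical region-of-interest mask; both the threshold
#'   and the area denominator are restricted to it.
#' @param field_id identifier carried into the output row.
#' @return one-row data frame: `field_id`, `threshold`, `mean_intensity`,
#'   `pct_area` (percent units), `n_stained`, `n_total`.
#' @export
quantify_field <- function(image, roi = NULL, field_id = NA_character_) {
  image <- as_gray_image(image)
  thr <- compute_threshold(image, roi)
  mask <- segment_stain(image, as.numeric(thr))
  if (!is.null(roi)) mask <- mask & roi
  n_total <- if (is.null(roi)) length(image) else sum(roi)
  n_stained <- sum(mask)
  data.frame(
    field_id = field_id,
    threshold = as.numeric(thr),
    mean_intensity = if (n_stained > 0) mean(image[mask]) else NA_real_,
    pct_area = 100 * n_stained / n_total,
    n_stained = n_stained,
    n_total = n_total,
    stringsAsFactors = FALSE
  )
}

#' Aggregate per-field measurements to one slide
#'
#' A slide is summarized by the unweighted mean of its per-field mean
#' intensities (over fields with a non-empty stain mask) and of its per-field
#' percent areas. A slide whose every field has an empty mask cannot be
#' scored and is flagged unquantifiable.
#'
#' @param fields data frame of [quantify_field()] rows (typically 3).
#' @param slide_id identifier carried into the output row.
#' @return one-row data frame: `slide_id`, `n_fields`, `mean_intensity`,
#'   `pct_area`, `quantifiable`.
#' @export
aggregate_slide <- function(fields, slide_id = NA_character_) {
  if (!is.data.frame(fields) || nrow(fields) == 0)
    stop("fields must be a non-empty data frame of per-field measurements")
  check_columns(fields, c("mean_intensity", "pct_area", "n_stained"),
                "per-field table")
  ok <- fields$n_stained > 0
  if (!any(ok))
    warning("slide ", slide_id, " is unquantifiable: all fields have empty stain masks")
  data.frame(
    slide_id = slide_id,
    n_fields = nrow(fields),
    mean_intensity = if (any(ok)) mean(fields$mean_intensity[ok]) else NA_real_,
    pct_area = mean(fields$pct_area),
    quantifiable = any(ok),
    stringsAsFactors = FALSE
  )
}

#' Quantify a directory of field images
#'
#' Reads every PNG/JPEG/TIFF under `dir`, quantifies each field, and
#' aggregates fields into slides. Slide membership is taken from file names:
#' everything before the last `_f<digits>` suffix is the slide id; files
#' without the suffix are treated as single-field slides.
#'
#' @param dir directory of field images.
#' @param roi optional region-of-interest mask applied to every field.
#' @return list with data frames `fields` (per-field rows) and `slides`
#'   (per-slide aggregates).
#' @export
quantify_images <- function(dir, roi = NULL) {
  paths <- list.files(dir, pattern = "\\.(png|jpe?g|tiff?)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(paths) == 0) stop("no PNG/JPEG/TIFF images found in ", dir)
  ids <- sub("\\.[^.]+$", "", basename(paths))
  slide_ids <- sub("_f[0-9]+$", "", ids)
  fields <- do.call(rbind, lapply(seq_along(paths), function(i) {
    quantify_field(read_gray_image(paths[i]), roi = roi, field_id = ids[i])
  }))
  fields <- cbind(slide_id = slide_ids, fields, stringsAsFactors = FALSE)
  slides <- do.call(rbind, lapply(split(fields, fields$slide_id), function(g) {
    aggregate_slide(g, slide_id = g$slide_id[1])
  }))
  rownames(slides) <- NULL
  list(fields = fields, slides = slides)
}
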