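#' Multi-channel image stack
#'
#' A named list of intensity grids (2-D matrices or 3-D arrays with z as
#' the third dimension) sharing a common shape. Pixel coordinates are
#' 0-based `(row, col)` throughout the image operators.
#'
#' @param ... named channels (matrices or 3-D arrays)
#' @return object of class `image_stack`
#' @export
image_stack <- function(...) {
  ch <- list(...)
  if (length(ch) == 1L && is.list(ch[[1]]) && !is.matrix(ch[[1]])) ch <- ch[[1]]
  if (length(ch) == 0L || is.null(names(ch)) || any(names(ch) == ""))
    stop_param("image_stack needs named channels")
  shapes <- lapply(ch, function(x) dim(x)[1:2])
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]])))
    stop_param("all channels must share the same (row, col) shape")
  if (any(vapply(ch, function(x) any(x < 0), logical(1))))
    stop_param("intensities must be non-negative")
  structure(ch, class = "image_stack")
}

#' Sum-project an image stack along z
#'
#' Z-stacks are collapsed with the "sum" method: each output pixel is
#' the per-pixel sum over slices. 2-D channels are returned unchanged.
#'
#' @param stack an [image_stack()] or a single matrix / 3-D array
#' @return an `image_stack` of 2-D channels (or a matrix if a bare
#'   array was supplied)
#' @export
sum_project <- function(stack) {
  project1 <- function(x) {
    if (length(dim(x)) == 3L) {
      if (dim(x)[3] == 0L) stop_param("empty stack")
      apply(x, c(1, 2), sum)
    } else if (length(dim(x)) == 2L) {
      x
    } else stop_param("channel must be 2-D or 3-D")
  }
  if (inherits(stack, "image_stack"))
    return(image_stack(lapply(stack, project1)))
  project1(stack)
}

as_roi_mask <- function(roi, shape) {
  m <- if (is.list(roi) && !is.null(roi$mask)) roi$mask else roi
  if (!is.matrix(m) || !is.logical(m)) stop_param("ROI must be a logical matrix")
  if (!is.null(shape) && !identical(dim(m), shape))
    stop_param("ROI shape does not match the image")
  if (!any(m)) stop_param("empty ROI")
  m
}

#' Background-corrected ROI quantification
#'
#' Sums the fluorescence within an ROI and subtracts the sum within an
#' equal-area background ROI placed over an adjacent unstained region
#' (the moved-ROI convention). A negative corrected value is reported
#' with a warning rather than clipped.
#'
#' @param image 2-D intensity matrix
#' @param roi,bg_roi logical masks of the same shape as `image`; must
#'   cover equal pixel counts unless `area_normalize = TRUE`
#' @param area_normalize if `TRUE`, unequal areas are allowed and the
#'   background is scaled to the ROI area via its mean
#' @return list of class `roi_quant`: `raw_sum`, `background_sum`,
#'   `corrected` (= raw - background, exactly), `area_px`
#' @export
roi_quant <- function(image, roi, bg_roi, area_normalize = FALSE) {
  stopifnot(is.matrix(image))
  m <- as_roi_mask(roi, dim(image))
  b <- as_roi_mask(bg_roi, dim(image))
  if (sum(m) != sum(b) && !area_normalize)
    stop_param("ROI and background ROI cover different areas (",
               sum(m), " vs ", sum(b),
               " px); set area_normalize = TRUE to scale by area")
  raw <- sum(image[m])
  bg <- if (area_normalize) mean(image[b]) * sum(m) else sum(image[b])
  corrected <- raw - bg
  if (corrected < 0)
    warning("background exceeds ROI signal; corrected value is negative")
  structure(list(raw_sum = raw, background_sum = bg,
                 corrected = corrected, area_px = sum(m)),
            class = "roi_quant")
}

#' Ratio of two background-corrected quantifications
#'
#' The ratiometric normalization used for CaLexA/Bursicon and
#' GCaMP/tdTomato measurements: the corrected signal divided by the
#' corrected reference.
#'
#' @param signal,reference `roi_quant` objects (or bare numbers)
#' @return the ratio `signal / reference`
#' @export
ratiometric <- function(signal, reference) {
  val <- function(x) if (inherits(x, "roi_quant")) x$corrected else as.numeric(x)
  s <- val(signal); r <- val(reference)
  if (!is.finite(r) || r <= 0)
    stop(errorCondition(
      paste0("reference corrected value must be positive (got ", r,
             "); ratio undefined"),
      class = c("hsdquant_undefined_ratio", "error")))
  s / r
}

# bilinear sample of image (0-based row/col coords); NA outside
bilinear_sample <- function(image, rows, cols) {
  pracma::interp2(x = seq_len(ncol(image)) - 1, y = seq_len(nrow(image)) - 1,
                  Z = image, xp = cols, yp = rows)
}

#' Extract an averaged line profile between two points
#'
#' Samples the image along the segment from `p0` to `p1` at
#' approximately one-pixel spacing. At each position, `width_px`
#' perpendicular samples (one-pixel spacing, symmetric about the
#' segment) are averaged via bilinear interpolation, reducing noise the
#' same way a wide line selection does. Positions are rescaled to
#' `[0, 1]`.
#'
#' @param image 2-D intensity matrix
#' @param p0,p1 segment endpoints as `c(row, col)`, 0-based, inside the
#'   image
#' @param width_px width of the averaged band in pixels (default 15)
#' @return list of class `line_profile` with `positions` (in `[0, 1]`,
#'   including both endpoints), `intensities`, `width_px`, `length_px`
#' @export
extract_line_profile <- function(image, p0, p1, width_px = 15) {
  stopifnot(is.matrix(image), length(p0) == 2L, length(p1) == 2L)
  width_px <- check_count(width_px, "width_px")
  inside <- function(p) all(p >= 0) && p[1] <= nrow(image) - 1 && p[2] <= ncol(image) - 1
  if (!inside(p0) || !inside(p1)) stop_param("line endpoints must lie inside the image")
  d <- c(p1[1] - p0[1], p1[2] - p0[2])
  len <- sqrt(sum(d^2))
  if (len == 0) stop_param("zero-length line")
  u <- d / len                      # unit vector along the line
  perp <- c(-u[2], u[1])            # unit normal
  tpos <- seq(0, 1, length.out = max(2L, ceiling(len) + 1L))
  offs <- seq_len(width_px) - (width_px + 1) / 2
  prof <- vapply(tpos, function(t) {
    r <- p0[1] + t * d[1] + offs * perp[1]
    cc <- p0[2] + t * d[2] + offs * perp[2]
    v <- bilinear_sample(image, r, cc)
    mean(v, na.rm = TRUE) # offsets falling outside the image are dropped
  }, numeric(1))
  structure(list(positions = tpos, intensities = prof,
                 width_px = width_px, length_px = len),
            class = "line_profile")
}

#' Membrane-enrichment center:surround ratio of a line profile
#'
#' For a nucleus-to-nucleus profile with the membrane at its midpoint:
#' the mean intensity over the middle 10% of the line
#' (0.45 <= x <= 0.55, the "center") divided by the mean over a further
#' 10% on each side (0.35 <= x < 0.45 and 0.55 < x <= 0.65, the
#' "surround"). The ratio reads out plasma-membrane enrichment of the
#' reporter. Endpoint membership follows the stated inequalities
#' exactly; samples outside [0.35, 0.65] are ignored.
#'
#' @param profile a [extract_line_profile()] result (or a list with
#'   `positions` and `intensities`)
#' @return the center:surround ratio
#' @export
tgph_membrane_ratio <- function(profile) {
  x <- profile$positions
  y <- profile$intensities
  if (is.null(x) || is.null(y) || length(x) != length(y))
    stop_param("profile must have matching positions and intensities")
  center <- x >= 0.45 & x <= 0.55
  surround <- (x >= 0.35 & x < 0.45) | (x > 0.55 & x <= 0.65)
  if (!any(center) || !any(surround))
    stop_param("profile has no samples in the center or surround window")
  mean(y[center]) / mean(y[surround])
}

#' Lipid-droplet area fraction within a cell mask
#'
#' Fraction of cell-mask pixels whose droplet-channel intensity exceeds
#' a threshold. By default the threshold is Otsu's method computed on
#' the in-mask intensities (requires the EBImage package); a numeric
#' threshold on the original intensity scale may be supplied instead.
#' A mask with no intensity contrast yields 0.
#'
#' @param droplet_channel 2-D intensity matrix
#' @param cell_mask logical matrix, same shape
#' @param threshold `"otsu"` (default) or a numeric intensity cut-off;
#'   pixels strictly above it count as droplet
#' @return fraction in `[0, 1]`
#' @export
droplet_area_fraction <- function(droplet_channel, cell_mask,
                                  threshold = "otsu") {
  stopifnot(is.matrix(droplet_channel))
  m <- as_roi_mask(cell_mask, dim(droplet_channel))
  vals <- droplet_channel[m]
  if (is.numeric(threshold)) return(mean(vals > threshold))
  if (!identical(threshold, "otsu")) stop_param("unknown threshold method")
  rng <- range(vals)
  if (diff(rng) == 0) return(0) # no contrast: nothing above threshold
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop_param("threshold = \"otsu\" requires the EBImage package; ",
               "alternatively pass a numeric threshold")
  scaled <- (vals - rng[1]) / diff(rng)
  thr <- EBImage::otsu(matrix(scaled, ncol = 1), range = c(0, 1))
  mean(scaled > thr)
}

#' Per-frame GCaMP/tdTomato ratio series
#'
#' For each frame, the mean GCaMP intensity within each soma ROI is
#' divided by the mean tdTomato intensity in the same ROI, and the
#' per-neuron ratios are averaged (unweighted) into one value per
#' timepoint.
#'
#' @param frames list of [image_stack()]s, time-ordered, each with the
#'   two channels named in `signal` and `reference`
#' @param soma_rois list of logical masks, one per neuron, fixed across
#'   frames
#' @param signal,reference channel names
#' @return numeric vector of length `length(frames)`
#' @export
gcamp_ratio_series <- function(frames, soma_rois, signal = "gcamp",
                               reference = "tdtomato") {
  if (length(soma_rois) < 1L) stop_param("at least one soma ROI required")
  shape <- dim(frames[[1]][[signal]])[1:2]
  masks <- lapply(soma_rois, as_roi_mask, shape = shape)
  vapply(frames, function(fr) {
    if (is.null(fr[[signal]]) || is.null(fr[[reference]]))
      stop_param("frame lacks channel '", signal, "' or '", reference, "'")
    ratios <- vapply(masks, function(m) {
      ratiometric(mean(fr[[signal]][m]), mean(fr[[reference]][m]))
    }, numeric(1))
    mean(ratios)
  }, numeric(1))
}
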