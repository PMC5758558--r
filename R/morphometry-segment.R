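#' Segmentation parameters for the micrograph pipeline
#'
#' @param blur_sigma sigma (px) of the Gaussian blur whose subtraction
#'   flattens the background; large relative to a cell, small relative to
#'   the image.
#' @param threshold_method automatic histogram threshold: `"default"` (the
#'   IsoData-style iterative intermeans algorithm), `"intermodes"` or
#'   `"yen"`.
#' @param saturated_fraction proportion of pixels saturated during
#'   contrast enhancement (half in each tail), in [0, 0.5).
#' @param min_object_area smallest object kept (px^2).
#' @param closing_radius radius (px) of the disc structuring element for
#'   morphological closing.
#' @param separate_touching split touching objects with a distance-map
#'   watershed.
#' @param watershed_tolerance minimum depth (in distance-map units)
#'   between two catchment basins for them to stay separate objects.
#' @param exclude_border drop objects touching the image border.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(blur_sigma = 20,
                                threshold_method = c("default",
                                                     "intermodes", "yen"),
                                saturated_fraction = 0.0035,
                                min_object_area = 100,
                                closing_radius = 2,
                                separate_touching = TRUE,
                                watershed_tolerance = 1,
                                exclude_border = TRUE) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(blur_sigma > 0, saturated_fraction >= 0,
            saturated_fraction < 0.5, min_object_area >= 0,
            closing_radius >= 0)
  structure(list(blur_sigma = blur_sigma,
                 threshold_method = threshold_method,
                 saturated_fraction = saturated_fraction,
                 min_object_area = min_object_area,
                 closing_radius = closing_radius,
                 separate_touching = separate_touching,
                 watershed_tolerance = watershed_tolerance,
                 exclude_border = exclude_border),
            class = "segmentation_params")
}

# 256-bin histogram of an image scaled to [0,1]
.hist256 <- function(img) {
  idx <- pmin(pmax(floor(img * 256), 0), 255)
  tabulate(idx + 1L, nbins = 256L)
}

# IsoData-style iterative intermeans threshold (bin index in 0..255)
.thr_isodata <- function(h) {
  lev <- 0:255
  t_old <- -1
  # start midway across the occupied range: the intermeans iteration has a
  # degenerate fixed point inside the background cluster when the
  # foreground fraction is small, which a mean start can fall into
  occ <- range(lev[h > 0])
  t_new <- mean(occ)
  it <- 0
  while (abs(t_new - t_old) > 0.5 && it < 100) {
    t_old <- t_new
    lo <- lev <= t_old
    m1 <- if (sum(h[lo]) > 0) sum(h[lo] * lev[lo]) / sum(h[lo]) else 0
    m2 <- if (sum(h[!lo]) > 0) sum(h[!lo] * lev[!lo]) / sum(h[!lo]) else 255
    t_new <- (m1 + m2) / 2
    it <- it + 1
  }
  t_new
}

# Intermodes threshold: smooth until bimodal, midpoint of the two modes
.thr_intermodes <- function(h) {
  hh <- as.numeric(h)
  is_bimodal <- function(v) {
    peaks <- which(diff(sign(diff(v))) == -2) + 1
    length(peaks) == 2
  }
  it <- 0
  while (!is_bimodal(hh) && it < 10000) {
    hh <- stats::filter(c(hh[1], hh, hh[256]), rep(1 / 3, 3))[2:257]
    it <- it + 1
  }
  peaks <- which(diff(sign(diff(hh))) == -2) + 1
  if (length(peaks) < 2) return(.thr_isodata(h))  # unimodal fallback
  mean(peaks - 1)
}

# Yen's maximum correlation threshold
.thr_yen <- function(h) {
  p <- h / sum(h)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- rev(cumsum(rev(p^2))) - p^2
  crit <- -log(pmax(P1sq * P2sq, 1e-300)) +
    2 * log(pmax(P1 * (1 - P1), 1e-300))
  which.max(crit) - 1
}

.auto_threshold <- function(img, method) {
  h <- .hist256(img)
  t_bin <- switch(method,
                  default = .thr_isodata(h),
                  intermodes = .thr_intermodes(h),
                  yen = .thr_yen(h),
                  stop("unknown threshold method: ", method))
  (t_bin + 0.5) / 256
}

#' Segment a micrograph into labelled cell objects
#'
#' The pipeline mirrors the standard bright-cells-on-dark-background
#' protocol: (1) subtract a heavily blurred copy of the image to flatten
#' the background, (2) rescale to 8-bit, (3) stretch contrast with a small
#' saturated-pixel fraction, (4) binarize with an automatic histogram
#' threshold, (5) morphological closing, (6) hole filling, (7) optional
#' separation of touching objects by a distance-map watershed, (8) removal
#' of small objects and of objects touching the border.
#'
#' @param image numeric matrix in [0, 1] (or an RGB array, averaged to
#'   grayscale).
#' @param params a [segmentation_params()].
#' @return list of class `labeled_mask` with `labels` (integer matrix, 0 =
#'   background), `components` (integer matrix labelling 8-connected
#'   components before watershed separation), `areas` (px per label) and
#'   `params`.  A blank image yields zero labels.
#' @export
segment_image <- function(image, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  if (length(dim(image)) == 3)
    image <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  img <- EBImage::imageData(EBImage::Image(image))

  if (stats::sd(img) == 0) {
    z <- matrix(0L, nrow(img), ncol(img))
    return(structure(list(labels = z, components = z,
                          areas = integer(0), params = params),
                     class = "labeled_mask"))
  }

  # (1) background flattening
  blur <- EBImage::gblur(EBImage::Image(img), sigma = params$blur_sigma)
  sub <- img - EBImage::imageData(blur)
  # (2) 8-bit rescale
  rng <- range(sub)
  sub <- (sub - rng[1]) / (rng[2] - rng[1])
  sub <- round(sub * 255) / 255
  # (3) contrast enhancement with pixel saturation
  if (params$saturated_fraction > 0) {
    q <- stats::quantile(sub, c(params$saturated_fraction / 2,
                                1 - params$saturated_fraction / 2))
    if (q[2] > q[1]) {
      sub <- (sub - q[1]) / (q[2] - q[1])
      sub[sub < 0] <- 0; sub[sub > 1] <- 1
    }
  }
  # (4) automatic threshold
  thr <- .auto_threshold(sub, params$threshold_method)
  bin <- sub > thr
  if (!any(bin)) {
    z <- matrix(0L, nrow(img), ncol(img))
    return(structure(list(labels = z, components = z,
                          areas = integer(0), params = params),
                     class = "labeled_mask"))
  }
  bw <- EBImage::Image(bin * 1)
  # (5) closing, (6) hole filling
  if (params$closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * params$closing_radius + 1, "disc")
    bw <- EBImage::closing(bw, brush)
  }
  bw <- EBImage::fillHull(bw)

  comp <- EBImage::imageData(EBImage::bwlabel(bw))
  # (7) separation of touching objects
  if (params$separate_touching) {
    dm <- EBImage::distmap(bw)
    lab <- EBImage::imageData(
      EBImage::watershed(dm, tolerance = params$watershed_tolerance))
  } else {
    lab <- comp
  }
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  comp <- matrix(as.integer(comp), nrow(comp), ncol(comp))

  # (8) small-object and border filters
  drop <- integer(0)
  tab <- tabulate(lab[lab > 0])
  drop <- which(tab < params$min_object_area & tab > 0)
  if (params$exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, border[border > 0])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  # relabel to contiguous positive integers
  keep <- sort(unique(lab[lab > 0]))
  if (length(keep)) {
    remap <- integer(max(keep)); remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  comp[lab == 0] <- 0L
  keepc <- sort(unique(comp[comp > 0]))
  if (length(keepc)) {
    remc <- integer(max(keepc)); remc[keepc] <- seq_along(keepc)
    comp[comp > 0] <- remc[comp[comp > 0]]
  }
  structure(list(labels = lab, components = comp,
                 areas = tabulate(lab[lab > 0]), params = params),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat("labeled_mask:", length(x$areas), "objects,",
      paste(dim(x$labels), collapse = " x "), "px\n")
  invisible(x)
}
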