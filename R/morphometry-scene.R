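#' Describe one synthetic cell for scene rendering
#'
#' Cells are bright ellipses on a dark background; a budded cell is a
#' circular mother with a smaller tangent circular bud.  Coordinates and
#' radii are in pixels; `theta` is the orientation of the major axis in
#' radians.
#'
#' @param cx,cy center (px).
#' @param a,b ellipse semi-axes (px), `a >= b`.
#' @param theta orientation (rad).
#' @param intensity foreground intensity in [0, 1].
#' @param bud_r bud radius (px); 0 for an unbudded cell.  Budded cells are
#'   rendered with a circular mother (`a == b` required) so that the
#'   analytic ground truth of the union is exact tangent-circle geometry.
#' @param bud_angle attachment direction of the bud (rad).
#' @param bud_overlap overlap (px) between mother and bud rims, so the two
#'   discs form one 8-connected object; default 1.
#' @return a `scene_object` list.
#' @export
scene_object <- function(cx, cy, a, b = a, theta = 0, intensity = 0.8,
                         bud_r = 0, bud_angle = 0, bud_overlap = 1) {
  if (a < b) stop("semi-axis a must be >= b")
  if (bud_r > 0) {
    if (a != b) stop("budded objects use a circular mother (a == b)")
    if (bud_r >= b) stop("bud radius must be smaller than the mother's")
  }
  structure(list(cx = cx, cy = cy, a = a, b = b, theta = theta,
                 intensity = intensity, bud_r = bud_r,
                 bud_angle = bud_angle, bud_overlap = bud_overlap),
            class = "scene_object")
}

#' Specify a synthetic micrograph-like scene
#'
#' Stands in for non-deposited bright-field micrographs: bright
#' elliptical/doublet cells of roughly 5-12 um diameter at the default
#' 0.0975 um/px calibration, on a noisy dark background.
#'
#' @param objects list of [scene_object()]s.
#' @param width,height image size in pixels.
#' @param background background intensity in [0, 1].
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @param seed integer seed making rendering deterministic.
#' @param pixel_size calibration (um/px).
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(objects, width = 512, height = 512,
                       background = 0.1, noise_sd = 0.01, seed = 1,
                       pixel_size = 0.0975) {
  stopifnot(length(objects) >= 1, width > 0, height > 0, noise_sd >= 0,
            pixel_size > 0)
  for (ob in objects) {
    reach <- ob$a + ifelse(ob$bud_r > 0, 2 * ob$bud_r, 0)
    if (ob$cx - reach < 1 || ob$cx + reach > width ||
        ob$cy - reach < 1 || ob$cy + reach > height)
      stop("object extends outside the image bounds")
  }
  # reject scenes where objects overlap beyond a recognizable limit
  n <- length(objects)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      oi <- objects[[i]]; oj <- objects[[j]]
      d <- sqrt((oi$cx - oj$cx)^2 + (oi$cy - oj$cy)^2)
      if (d < 0.5 * max(oi$b, oj$b))
        stop("objects ", i, " and ", j, " overlap beyond the limit")
    }
  }
  structure(list(objects = objects, width = width, height = height,
                 background = background, noise_sd = noise_sd, seed = seed,
                 pixel_size = pixel_size),
            class = "scene_spec")
}

# fill an ellipse into the image matrix (dims: x, y), returning the matrix
.render_ellipse <- function(img, cx, cy, a, b, theta, val) {
  reach <- ceiling(max(a, b)) + 1
  xs <- max(1, floor(cx - reach)):min(nrow(img), ceiling(cx + reach))
  ys <- max(1, floor(cy - reach)):min(ncol(img), ceiling(cy + reach))
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- img[xs, ys]
  sub[inside] <- pmax(sub[inside], val)
  img[xs, ys] <- sub
  img
}

# analytic perimeter of an ellipse (Ramanujan's second approximation)
.ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Render a synthetic scene and its analytic ground truth
#'
#' Deterministic for a given spec (the spec carries the seed).  The ground
#' truth lists, per object, the analytic area, perimeter, major and minor
#' diameter (calibrated to micrometres) and the budded flag.  For budded
#' doublets the truth is exact tangent-circle geometry:
#' `A = pi (R_m^2 + R_b^2)`, `P = 2 pi (R_m + R_b)`,
#' `D_MAX = 2 (R_m + R_b)`, `D_MIN = 2 R_m`.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (numeric matrix in [0, 1], dims x by y) and
#'   `truth` (data frame, one row per object).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  img <- matrix(spec$background, nrow = spec$width, ncol = spec$height)
  truth <- NULL
  for (k in seq_along(spec$objects)) {
    ob <- spec$objects[[k]]
    img <- .render_ellipse(img, ob$cx, ob$cy, ob$a, ob$b, ob$theta,
                           ob$intensity)
    ps <- spec$pixel_size
    if (ob$bud_r > 0) {
      d <- ob$a + ob$bud_r - ob$bud_overlap
      bx <- ob$cx + d * cos(ob$bud_angle)
      by <- ob$cy + d * sin(ob$bud_angle)
      img <- .render_ellipse(img, bx, by, ob$bud_r, ob$bud_r, 0,
                             ob$intensity)
      truth <- rbind(truth, data.frame(
        object = k,
        area_um2 = pi * (ob$a^2 + ob$bud_r^2) * ps^2,
        perimeter_um = 2 * pi * (ob$a + ob$bud_r) * ps,
        dmax_um = 2 * (ob$a + ob$bud_r) * ps,
        dmin_um = 2 * ob$a * ps,
        budded = TRUE))
    } else {
      truth <- rbind(truth, data.frame(
        object = k,
        area_um2 = pi * ob$a * ob$b * ps^2,
        perimeter_um = .ellipse_perimeter(ob$a, ob$b) * ps,
        dmax_um = 2 * ob$a * ps,
        dmin_um = 2 * ob$b * ps,
        budded = FALSE))
    }
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                        nrow = nrow(img))
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, truth = truth)
}

#' Read a micrograph from TIFF or PNG
#'
#' 8/16-bit grayscale or RGB images are accepted; RGB is converted to
#' luminance.  Returns a numeric matrix in [0, 1] (dims x by y).
#'
#' @param path image file path.
#' @return numeric matrix.
#' @export
read_micrograph <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 3) img <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  m <- EBImage::imageData(img)
  m[m < 0] <- 0; m[m > 1] <- 1
  m
}

#' Write an image matrix to TIFF or PNG (by file extension)
#'
#' @param image numeric matrix in [0, 1].
#' @param path output path ending in .tif/.tiff/.png.
#' @export
write_micrograph <- function(image, path) {
  EBImage::writeImage(EBImage::Image(image), path)
  invisible(path)
}
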