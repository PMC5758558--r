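#' Pixel calibration
#'
#' @param pixel_size physical size of one pixel (um/px); the default
#'   0.0975 corresponds to the 50x bright-field setup the pipeline was
#'   designed around.
#' @return a `pixel_calibration` list.
#' @export
pixel_calibration <- function(pixel_size = 0.0975) {
  stopifnot(is.finite(pixel_size), pixel_size > 0)
  structure(list(pixel_size = pixel_size), class = "pixel_calibration")
}

# chain-code perimeter with the Vossepoel-Smeulders bias correction:
# 0.980 per axial step, 1.406 per diagonal step, -0.091 per corner
# (direction change).  Accurate to well under 1% for convex objects of
# the sizes measured here.
.contour_perimeter <- function(xy) {
  n <- nrow(xy)
  if (n < 4) return(NA_real_)
  nxt <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  d <- nxt - xy
  # guard: ocontour should give unit 8-connected steps
  stepmax <- pmax(abs(d[, 1]), abs(d[, 2]))
  d <- d[stepmax > 0, , drop = FALSE]
  diag_step <- abs(d[, 1]) == 1 & abs(d[, 2]) == 1
  code <- d[, 1] + 10 * d[, 2]
  corners <- sum(code != c(code[-1], code[1]))
  0.980 * sum(!diag_step) + 1.406 * sum(diag_step) - 0.091 * corners
}

# second-moment (best-fit ellipse) axis lengths in pixels
.moment_axes <- function(xs, ys) {
  mx <- mean(xs); my <- mean(ys)
  # 1/12 term: second moment of the unit square pixel footprint
  cxx <- mean((xs - mx)^2) + 1 / 12
  cyy <- mean((ys - my)^2) + 1 / 12
  cxy <- mean((xs - mx) * (ys - my))
  tr <- cxx + cyy
  det <- cxx * cyy - cxy^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  c(dmax = 4 * sqrt(max(l1, 0)), dmin = 4 * sqrt(max(l2, 0)))
}

#' Measure raw morphometrics of labelled objects
#'
#' Per label: area (pixel count x pixel_size^2), perimeter (chain-code
#' boundary length with the Vossepoel-Smeulders bias correction), and
#' major/minor diameters from the second-moment best-fit ellipse.  Labels
#' with fewer than 4 pixels are excluded with a warning.
#'
#' @param mask a `labeled_mask` from [segment_image()] (or a list with an
#'   integer `labels` matrix).
#' @param calibration a [pixel_calibration()].
#' @return data frame with columns `label`, `area_um2`, `perimeter_um`,
#'   `dmax_um`, `dmin_um`.
#' @export
measure_objects <- function(mask, calibration = pixel_calibration()) {
  lab <- mask$labels
  nlab <- max(lab)
  if (nlab == 0) {
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), dmax_um = numeric(0),
                      dmin_um = numeric(0)))
  }
  ps <- calibration$pixel_size
  contours <- EBImage::ocontour(EBImage::Image(lab))
  idx <- which(lab > 0)
  l <- lab[idx]
  xs <- ((idx - 1) %% nrow(lab)) + 1
  ys <- ((idx - 1) %/% nrow(lab)) + 1
  out <- NULL
  dropped <- 0L
  for (k in seq_len(nlab)) {
    sel <- l == k
    npx <- sum(sel)
    if (npx < 4) {
      dropped <- dropped + 1L
      next
    }
    per <- .contour_perimeter(contours[[k]])
    ax <- .moment_axes(xs[sel], ys[sel])
    out <- rbind(out, data.frame(
      label = k,
      area_um2 = npx * ps^2,
      perimeter_um = per * ps,
      dmax_um = unname(ax["dmax"]) * ps,
      dmin_um = unname(ax["dmin"]) * ps))
  }
  if (dropped > 0)
    warning(dropped, " label(s) with fewer than 4 pixels excluded")
  if (is.null(out))
    out <- data.frame(label = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), dmax_um = numeric(0),
                      dmin_um = numeric(0))
  out
}

#' Derived shape parameters: circularity and elongation
#'
#' Circularity `C = 4 pi A / P^2` (1 for a perfect circle; rasterization
#' overshoot is clipped to 1) and elongation (aspect ratio)
#' `AR = D_MAX / D_MIN`.
#'
#' @param A area, `P` perimeter, `dmax`/`dmin` major/minor diameters; all
#'   positive, `dmax >= dmin`.  Units cancel but must be consistent.
#' @param P,dmax,dmin see `A`.
#' @return data frame with `circularity` and `elongation`.
#' @export
derive_shape <- function(A, P, dmax, dmin) {
  if (any(c(A, P, dmax, dmin) <= 0)) stop("all inputs must be positive")
  if (any(dmax < dmin)) stop("dmax must be >= dmin")
  data.frame(circularity = pmin(4 * pi * A / P^2, 1),
             elongation = dmax / dmin)
}

#' Classify budding from lobe decomposition
#'
#' A connected component split into two lobes by the watershed is one
#' budded cell when the smaller lobe's area is less than
#' `similarity_ratio` times the larger lobe's area (the smaller attached
#' cell is the bud); lobes of similar size are treated as two separate
#' unbudded cells.  Single-lobe components are unbudded.  Components with
#' more than two lobes are kept but flagged for manual review
#' (`budded = NA`).
#'
#' @param mask a `labeled_mask` from [segment_image()] with
#'   `separate_touching = TRUE`.
#' @param similarity_ratio area ratio below which the smaller lobe is a
#'   bud; default 0.8.
#' @return a `labeled_mask` whose labels are final cell records (bud lobes
#'   merged with their mothers), with a `budded` logical vector (NA =
#'   flagged for review) aligned with labels 1..n.
#' @export
classify_budding <- function(mask, similarity_ratio = 0.8) {
  lab <- mask$labels
  comp <- mask$components
  if (max(lab) == 0) {
    mask$budded <- logical(0)
    return(mask)
  }
  idx <- which(lab > 0)
  lobes <- lab[idx]
  comps <- comp[idx]
  # lobe -> component map and lobe areas
  lobe_comp <- tapply(comps, lobes, function(v) v[1])
  lobe_area <- tabulate(lobes)
  new_id <- integer(max(lobes))   # lobe label -> final record id
  budded <- logical(0)
  nid <- 0L
  for (cc in sort(unique(comps))) {
    members <- which(lobe_comp == cc)
    if (length(members) == 1) {
      nid <- nid + 1L
      new_id[members] <- nid
      budded[nid] <- FALSE
    } else if (length(members) == 2) {
      a <- lobe_area[members]
      if (min(a) < similarity_ratio * max(a)) {
        nid <- nid + 1L             # one budded record, lobes merged
        new_id[members] <- nid
        budded[nid] <- TRUE
      } else {                      # similar sizes: two separate cells
        for (m in members) {
          nid <- nid + 1L
          new_id[m] <- nid
          budded[nid] <- FALSE
        }
      }
    } else {                        # >2 lobes: keep merged, flag
      nid <- nid + 1L
      new_id[members] <- nid
      budded[nid] <- NA
    }
  }
  out <- lab
  out[idx] <- new_id[lobes]
  structure(list(labels = out, components = comp,
                 areas = tabulate(out[out > 0]),
                 params = mask$params, budded = budded),
            class = "labeled_mask")
}

#' Full image-to-cell-records pipeline
#'
#' Segment, classify budding, measure, and derive shape parameters,
#' producing one row per cell on the standard cell-record schema.
#'
#' @param image numeric matrix in [0, 1].
#' @param params a [segmentation_params()].
#' @param calibration a [pixel_calibration()].
#' @param similarity_ratio see [classify_budding()].
#' @param replicate,condition,time_h labels stored in the records.
#' @return cell-record data frame with columns `id`, `replicate`,
#'   `condition`, `time_h`, `area_um2`, `perimeter_um`, `dmax_um`,
#'   `dmin_um`, `circularity`, `elongation`, `budded`, `phase`.
#' @export
cell_records <- function(image, params = segmentation_params(),
                         calibration = pixel_calibration(),
                         similarity_ratio = 0.8,
                         replicate = 1L, condition = NA_character_,
                         time_h = NA_real_) {
  mask <- segment_image(image, params)
  mask <- classify_budding(mask, similarity_ratio)
  meas <- measure_objects(mask, calibration)
  if (nrow(meas) == 0) return(empty_cell_records())
  shp <- derive_shape(meas$area_um2, meas$perimeter_um, meas$dmax_um,
                      meas$dmin_um)
  data.frame(id = meas$label, replicate = replicate, condition = condition,
             time_h = time_h,
             area_um2 = meas$area_um2, perimeter_um = meas$perimeter_um,
             dmax_um = meas$dmax_um, dmin_um = meas$dmin_um,
             circularity = shp$circularity, elongation = shp$elongation,
             budded = mask$budded[meas$label],
             phase = "unassigned")
}

#' Empty cell-record table with the standard schema
#' @return zero-row data frame.
#' @export
empty_cell_records <- function() {
  data.frame(id = integer(0), replicate = integer(0),
             condition = character(0), time_h = numeric(0),
             area_um2 = numeric(0), perimeter_um = numeric(0),
             dmax_um = numeric(0), dmin_um = numeric(0),
             circularity = numeric(0), elongation = numeric(0),
             budded = logical(0), phase = character(0))
}

#' Remove extreme outlier records
#'
#' Optional debugging filter: within each replicate x condition x time
#' sample, records whose area lies more than `k` interquartile ranges from
#' the sample median are dropped.
#'
#' @param records cell-record data frame.
#' @param k IQR multiplier (default 3).
#' @return filtered records.
#' @export
filter_outliers <- function(records, k = 3) {
  if (nrow(records) == 0) return(records)
  key <- interaction(records$replicate, records$condition, records$time_h,
                     drop = TRUE)
  keep <- rep(TRUE, nrow(records))
  for (g in levels(key)) {
    i <- which(key == g)
    a <- records$area_um2[i]
    med <- stats::median(a)
    iqr <- stats::IQR(a)
    if (iqr > 0) keep[i] <- abs(a - med) <= k * iqr
  }
  records[keep, , drop = FALSE]
}
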