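#' Projected morphometrics of a spherical mother-bud pair
#'
#' The simulator treats the mother (mass `M - M_inc`) and the bud (mass
#' `M_inc`) as spheres; their 2-D projection is a pair of externally
#' tangent circles of radii `R_m >= R_b`.  The projected measurements are
#' closed forms of the two radii: `A = pi (R_m^2 + R_b^2)`,
#' `P = 2 pi (R_m + R_b)`, `D_MAX = 2 (R_m + R_b)`, `D_MIN = 2 R_m`,
#' `C = (R_m^2 + R_b^2) / (R_m + R_b)^2` and `AR = (R_m + R_b) / R_m`.
#' An unbudded cell (`R_b = 0`) projects to a perfect circle (C = 1,
#' AR = 1); an equal-size pair gives C = 0.5, AR = 2.
#'
#' @param R_m mother radius (um).
#' @param R_b bud radius (um), 0 for unbudded; must satisfy `R_b <= R_m`.
#' @return data frame with `area_um2`, `perimeter_um`, `dmax_um`,
#'   `dmin_um`, `circularity`, `elongation`.
#' @export
project_morphometry <- function(R_m, R_b = 0) {
  if (any(R_m <= 0)) stop("R_m must be positive")
  if (any(R_b < 0) || any(R_b > R_m)) stop("need 0 <= R_b <= R_m")
  data.frame(
    area_um2 = pi * (R_m^2 + R_b^2),
    perimeter_um = 2 * pi * (R_m + R_b),
    dmax_um = 2 * (R_m + R_b),
    dmin_um = 2 * R_m,
    circularity = (R_m^2 + R_b^2) / (R_m + R_b)^2,
    elongation = (R_m + R_b) / R_m)
}

#' Sample individual cells from a simulation state
#'
#' Draws up to `n` living cells without replacement (all of them if the
#' population is smaller), converts masses to sphere radii with the
#' mass-to-volume factor (`R = (3 M v / 4 pi)^(1/3)`), and returns their
#' projected morphometrics on the standard cell-record schema.
#'
#' @param state a `sim_state`.
#' @param n sample size (default 500, the usual per-time sample used when
#'   mimicking microscopy counts).
#' @param seed optional seed for the sampling draw only.
#' @return cell-record data frame with an extra `R_m`/`R_b` pair (um).
#' @export
sample_snapshot <- function(state, n = 500, seed = NULL) {
  cl <- state$cells
  p <- state$params
  idx <- which(cl$alive)
  if (length(idx) == 0) stop("population is empty")
  if (!is.null(seed)) set.seed(seed)
  if (length(idx) > n) idx <- sample(idx, n)
  M_bud <- cl$M_inc[idx] * (cl$Ph[idx] == 2L)
  M_moth <- cl$M[idx] - M_bud
  v <- p$mass_to_volume
  R_m <- (3 * M_moth * v / (4 * pi))^(1 / 3)
  R_b <- (3 * M_bud * v / (4 * pi))^(1 / 3)
  # a bud grown past its mother is still reported as the larger lobe
  swap <- R_b > R_m
  if (any(swap)) {
    tmp <- R_m[swap]; R_m[swap] <- R_b[swap]; R_b[swap] <- tmp
  }
  mm <- project_morphometry(R_m, R_b)
  time_h <- state$step * p$step_min / 60
  out <- data.frame(
    id = seq_along(idx), replicate = NA_integer_,
    condition = p$condition, time_h = time_h,
    area_um2 = mm$area_um2, perimeter_um = mm$perimeter_um,
    dmax_um = mm$dmax_um, dmin_um = mm$dmin_um,
    circularity = mm$circularity, elongation = mm$elongation,
    budded = cl$Ph[idx] == 2L, phase = "unassigned",
    R_m = R_m, R_b = R_b)
  out
}

#' Run a batch-culture simulation
#'
#' Steps the model for `duration_h` simulated hours, recording the
#' population-level time series every step and an individual-level
#' snapshot on the sampling schedule (default every 90 simulated
#' minutes).  The time series doubles as a growth curve (log10 viable
#' count, arbitrary volume scaling) directly consumable by
#' [fit_buchanan()].
#'
#' @param params a [sim_params()].
#' @param duration_h simulated hours.
#' @param seed integer seed; two runs with the same seed are identical.
#' @param sample_every_h snapshot schedule (h); NA disables snapshots.
#' @param sample_n cells per snapshot.
#' @return list of class `sim_run` with `time_series` (data frame:
#'   `time_h`, `viable_count`, `glu`, `o2`, `ethanol`, `co2`,
#'   `carbon_drift`), `growth_curve` (time_h/value data frame),
#'   `snapshots` (list of cell-record data frames), `final_state`,
#'   `params` and `seed`.
#' @export
run_simulation <- function(params, duration_h = 30, seed = 1,
                           sample_every_h = 1.5, sample_n = 500) {
  stopifnot(inherits(params, "sim_params"))
  st <- initialize_simulation(params, seed = seed)
  nstep <- as.integer(round(duration_h * 60 / params$step_min))
  snap_every <- if (is.na(sample_every_h)) NA_integer_
                else max(1L, as.integer(round(sample_every_h * 60 /
                                              params$step_min)))
  rec_every <- max(1L, as.integer(round(5 / params$step_min)))  # 5-min grid
  ts <- vector("list", nstep %/% rec_every + 1L)
  snaps <- list()
  record <- function(st) {
    m <- st$medium
    data.frame(
      time_h = st$step * params$step_min / 60,
      viable_count = sum(st$cells$alive),
      glu = sum(m$glu), o2 = sum(m$o2),
      ethanol = sum(m$eth), co2 = sum(m$co2),
      carbon_drift = abs(total_carbon(st) - st$carbon0) /
        st$carbon0)
  }
  ts[[1]] <- record(st)
  ri <- 1L
  if (!is.na(snap_every))
    snaps[[sprintf("t%.2f", 0)]] <- sample_snapshot(st, sample_n)
  for (k in seq_len(nstep)) {
    st <- step_simulation(st)
    if (k %% rec_every == 0L) {
      ri <- ri + 1L
      ts[[ri]] <- record(st)
    }
    if (!is.na(snap_every) && k %% snap_every == 0L &&
        sum(st$cells$alive) > 0) {
      snaps[[sprintf("t%.2f", st$step * params$step_min / 60)]] <-
        sample_snapshot(st, sample_n)
    }
  }
  ts <- do.call(rbind, ts[seq_len(ri)])
  gc_df <- data.frame(time_h = ts$time_h,
                      value = log10(pmax(ts$viable_count, 1)))
  structure(list(time_series = ts, growth_curve = gc_df,
                 snapshots = snaps, final_state = st,
                 params = params, seed = seed),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  n <- nrow(x$time_series)
  cat(sprintf("sim_run (%s): %.1f h, %d -> %d viable cells, %d snapshots\n",
              x$params$condition, x$time_series$time_h[n],
              x$time_series$viable_count[1], x$time_series$viable_count[n],
              length(x$snapshots)))
  invisible(x)
}
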