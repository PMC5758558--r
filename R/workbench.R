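#' Write / read cell-record tables
#'
#' The cell-record CSV schema (`id`, `replicate`, `condition`, `time_h`,
#' `area_um2`, `perimeter_um`, `dmax_um`, `dmin_um`, `circularity`,
#' `elongation`, `budded`, `phase`) is shared by the image pipeline and
#' the simulator's snapshots, so every downstream analysis consumes both
#' unchanged.
#'
#' @param records cell-record data frame.
#' @param path CSV path.
#' @return `read_cell_records` returns the data frame.
#' @export
write_cell_records <- function(records, path) {
  cols <- names(empty_cell_records())
  utils::write.csv(records[, intersect(cols, names(records))], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_records
#' @export
read_cell_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a growth-curve CSV
#'
#' Expected columns: `time_h`, `value`, and optionally `scale` (`log10`
#' or `linear`), `replicate`, `condition`.  Linear-scale values are
#' log10-transformed.
#'
#' @param path CSV path.
#' @return growth-curve data frame on the log10 scale.
#' @export
read_growth_curve <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "value") %in% names(d)))
    stop("growth curve CSV needs columns time_h and value")
  if (!is.null(d$scale) && any(d$scale == "linear")) {
    i <- d$scale == "linear"
    if (any(d$value[i] <= 0)) stop("linear-scale values must be positive")
    d$value[i] <- log10(d$value[i])
    d$scale <- "log10"
  }
  d
}

#' Compare a simulated snapshot with a reference cell table
#'
#' Per budded/unbudded stratum and per morphometric variable: difference
#' of means and standard deviations and the two-sample
#' Kolmogorov-Smirnov distance.  Optionally writes overlay histograms
#' (one PNG per stratum x variable) to `plot_dir`.
#'
#' @param simulated,reference data frames on the cell-record schema.
#' @param variables columns to compare.
#' @param plot_dir optional directory for overlay histogram PNGs.
#' @return data frame with one row per stratum x variable: `n_sim`,
#'   `n_ref`, `mean_delta`, `sd_delta`, `ks_distance`.
#' @export
compare_distributions <- function(simulated, reference,
                                  variables = c("area_um2",
                                                "perimeter_um",
                                                "dmax_um", "dmin_um",
                                                "circularity",
                                                "elongation"),
                                  plot_dir = NULL) {
  variables <- intersect(intersect(variables, names(simulated)),
                         names(reference))
  out <- NULL
  for (budval in c(FALSE, TRUE)) {
    si <- simulated[simulated$budded %in% budval, , drop = FALSE]
    re <- reference[reference$budded %in% budval, , drop = FALSE]
    if (nrow(si) == 0 || nrow(re) == 0) next
    for (v in variables) {
      x <- si[[v]]; y <- re[[v]]
      ks <- suppressWarnings(stats::ks.test(x, y)$statistic)
      out <- rbind(out, data.frame(
        stratum = if (budval) "budded" else "unbudded", variable = v,
        n_sim = length(x), n_ref = length(y),
        mean_delta = mean(x) - mean(y),
        sd_delta = stats::sd(x) - stats::sd(y),
        ks_distance = unname(ks)))
      if (!is.null(plot_dir)) {
        dir.create(plot_dir, showWarnings = FALSE, recursive = TRUE)
        f <- file.path(plot_dir, sprintf("%s_%s.png",
                                         out$stratum[nrow(out)], v))
        grDevices::png(f, width = 640, height = 480)
        br <- pretty(range(c(x, y)), 30)
        h1 <- graphics::hist(x, breaks = br, plot = FALSE)
        h2 <- graphics::hist(y, breaks = br, plot = FALSE)
        ymax <- max(h1$density, h2$density)
        graphics::plot(h1, freq = FALSE, col = grDevices::rgb(0, 0, 1, .4),
                       ylim = c(0, ymax), main = paste(v, "-",
                       out$stratum[nrow(out)]), xlab = v)
        graphics::plot(h2, freq = FALSE, col = grDevices::rgb(1, 0, 0, .4),
                       add = TRUE)
        graphics::legend("topright", c("simulated", "reference"),
                         fill = c(grDevices::rgb(0, 0, 1, .4),
                                  grDevices::rgb(1, 0, 0, .4)))
        grDevices::dev.off()
      }
    }
  }
  out
}

# schema of the end-to-end configuration; every key must be present
.e2e_required <- c("seed", "duration_h", "conditions")

#' Read and validate an end-to-end configuration
#'
#' YAML with keys `seed`, `duration_h`, `conditions` (a list whose names
#' are `aerobic` / `microaerophilic`; each entry may override
#' [sim_params()] fields), and optional `sample_every_h`, `sample_n`,
#' `out_dir`.
#'
#' @param path YAML file path, or a list already in that shape.
#' @return validated config list.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  missing <- setdiff(.e2e_required, names(cfg))
  if (length(missing))
    stop("config schema error: missing key(s): ",
         paste(missing, collapse = ", "))
  if (!is.list(cfg$conditions) || is.null(names(cfg$conditions)))
    stop("config schema error: 'conditions' must be a named list")
  bad <- setdiff(names(cfg$conditions), c("aerobic", "microaerophilic"))
  if (length(bad))
    stop("config schema error: unknown condition(s): ",
         paste(bad, collapse = ", "))
  cfg$sample_every_h <- cfg$sample_every_h %||% 1.5
  cfg$sample_n <- cfg$sample_n %||% 500
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of the canonical YAML serialization of a config
.config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

#' Run the full simulate-fit-label-compare workflow
#'
#' For each configured condition: run the individual-based simulation,
#' fit the Buchanan model to the simulated growth curve, label every
#' snapshot cell with its growth phase, and summarize morphometrics by
#' phase and budding state.  With both conditions configured, the two
#' fitted maximum growth rates are compared.  A run manifest (config
#' hash, seeds, package version, timestamp, outputs) makes every
#' artifact reproducible.
#'
#' @param config path to a YAML config or an equivalent list (see
#'   [read_config()]).
#' @param out_dir optional output directory for CSV reports (defaults to
#'   `config$out_dir`; no files are written when both are NULL).
#' @return list of class `e2e_report`: per-condition `runs` (fits,
#'   phase-labelled records, group summaries), `mu_comparison` (when two
#'   conditions), and `manifest`.
#' @export
end_to_end <- function(config, out_dir = NULL) {
  cfg <- read_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  runs <- list()
  for (cond in names(cfg$conditions)) {
    ov <- cfg$conditions[[cond]]
    pars <- do.call(sim_params,
                    c(list(condition = cond),
                      if (is.list(ov)) ov else list()))
    run <- run_simulation(pars, duration_h = cfg$duration_h,
                          seed = cfg$seed,
                          sample_every_h = cfg$sample_every_h,
                          sample_n = cfg$sample_n)
    fit <- fit_buchanan(run$growth_curve)
    recs <- do.call(rbind, run$snapshots)
    recs$phase <- as.character(assign_phase(fit, recs$time_h))
    runs[[cond]] <- list(run = run, fit = fit, records = recs,
                         summary = summarize_groups(recs))
  }
  mu_comparison <- NULL
  if (length(runs) == 2) {
    mus <- vapply(runs, function(r) r$fit$mu, 1)
    mu_comparison <- list(mu = mus, faster = names(which.max(mus)))
  }
  manifest <- list(
    config_hash = .config_hash(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("yeastlab")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    conditions = names(cfg$conditions),
    outputs = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (cond in names(runs)) {
      r <- runs[[cond]]
      tsf <- file.path(out_dir, paste0("timeseries_", cond, ".csv"))
      utils::write.csv(r$run$time_series, tsf, row.names = FALSE)
      rcf <- file.path(out_dir, paste0("cells_", cond, ".csv"))
      write_cell_records(r$records, rcf)
      fitf <- file.path(out_dir, paste0("fit_", cond, ".csv"))
      utils::write.csv(data.frame(parameter = c("P0", "Pmax", "t_lag",
                                                "mu", "t_max", "sse"),
                                  value = unlist(r$fit[c("P0", "Pmax",
                                    "t_lag", "mu", "t_max", "sse")])),
                       fitf, row.names = FALSE)
      manifest$outputs <- c(manifest$outputs, tsf, rcf, fitf)
    }
    mf <- file.path(out_dir, "manifest.yaml")
    yaml::write_yaml(manifest, mf)
  }
  structure(list(runs = runs, mu_comparison = mu_comparison,
                 manifest = manifest), class = "e2e_report")
}

#' @export
print.e2e_report <- function(x, ...) {
  cat("end-to-end report:", paste(names(x$runs), collapse = ", "), "\n")
  for (cond in names(x$runs)) {
    f <- x$runs[[cond]]$fit
    cat(sprintf("  %s: mu = %.3f, t_lag = %.2f h, t_max = %.2f h\n",
                cond, f$mu, f$t_lag, f$t_max))
  }
  if (!is.null(x$mu_comparison))
    cat("  faster growth:", x$mu_comparison$faster, "\n")
  invisible(x)
}
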