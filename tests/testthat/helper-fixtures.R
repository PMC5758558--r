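# shared builders for synthetic inputs

# five well-separated ellipses, minor axes >= 20 px
five_ellipse_scene <- function(noise_sd = 0.01, seed = 5) {
  objs <- list(
    scene_object(100, 100, 40, 30, 0.3),
    scene_object(300, 100, 35, 25, 1.0),
    scene_object(100, 300, 45, 28, 2.0),
    scene_object(300, 300, 30, 30, 0),
    scene_object(200, 420, 50, 25, 0.5))
  list(spec = scene_spec(objs, 512, 512, noise_sd = noise_sd, seed = seed),
       objects = objs)
}

# aerobic replicate-1 Buchanan parameters of the embedded kinetics fixture
aerobic_r1_fit <- function() {
  k <- load_fixture("kinetic_parameters")
  r1 <- k[k$condition == "aerobic" & k$replicate == 1, ]
  buchanan_params(P0 = r1$log10_N0, Pmax = r1$log10_Nmax,
                  t_lag = r1$t_lag, mu = r1$mu)
}

# a small, fast simulation parameter set (tiny medium, short lag) used
# where the test exercises mechanics rather than the batch scenario
fast_sim_params <- function(condition = "aerobic", ...) {
  args <- utils::modifyList(
    list(condition = condition, inoculum = 50, lattice_size = 10,
         glucose_total = 2e3, nh4_total = 2e3, cn_total = 500,
         lag_mean_h = 0.5, lag_sd_h = 0.2),
    list(...))
  do.call(sim_params, args)
}

# label -> object matching by scene centre pixel
label_at_center <- function(mask, object) {
  mask$labels[round(object$cx), round(object$cy)]
}
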