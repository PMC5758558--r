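test_that("initialization is seeded and draws the configured inoculum", {
  p <- fast_sim_params()
  a <- initialize_simulation(p, seed = 4)
  b <- initialize_simulation(p, seed = 4)
  expect_identical(a, b)
  expect_equal(length(a$cells$M), 50)
  expect_true(all(a$cells$Ph == 1L))
  expect_true(all(a$cells$B == 0L))
  expect_error(initialize_simulation(sim_params(lattice_size = 2,
                                                inoculum = 1e6), 1),
               "capacity")
})

test_that("Start-mass draws centre on the critical mass", {
  p <- sim_params(inoculum = 1e4, lag_mean_h = 0)
  st <- initialize_simulation(p, seed = 8)
  m <- st$cells$M_Start
  se <- sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - p$m_C), 2 * se)
})

test_that("uptake follows the min rule and surface-area scaling", {
  p <- sim_params()
  mkcell <- function(M) list(M = M, C_GLUin = 0, R_CN = 0, lag = 0L)
  rich <- list(glu = 1e6, cn = 1e6, nh4 = 1e6, o2 = 1e6)
  # empty site
  expect_equal(unlist(uptake(mkcell(10),
                             list(glu = 0, cn = 0, nh4 = 0, o2 = 0), p)),
               c(glu = 0, cn = 0, nh4 = 0, o2 = 0))
  # lag cells take nothing
  lagcell <- mkcell(10); lagcell$lag <- 5L
  expect_equal(uptake(lagcell, rich, p)$glu, 0)
  # abundant substrate: uptake proportional to M^(2/3)
  u1 <- uptake(mkcell(5), rich, p)$glu
  u2 <- uptake(mkcell(40), rich, p)$glu
  expect_equal(u2 / u1, (40 / 5)^(2 / 3), tolerance = 1e-12)
  # site holding less than demand is drained to exactly 0
  poor <- list(glu = 1e-6, cn = 0, nh4 = 0, o2 = 0)
  expect_equal(uptake(mkcell(10), poor, p)$glu, 1e-6)
})

test_that("within-site contention honours the acting order", {
  avail <- c(1, 100)
  site <- c(1L, 1L, 1L, 2L)
  demand <- c(0.6, 0.6, 0.6, 5)
  r <- yeastlab:::.site_alloc(avail, site, demand, ord = c(3L, 1L, 2L, 4L))
  # order 3,1,2: cell 3 takes 0.6, cell 1 the remaining 0.4, cell 2 none
  expect_equal(r$taken, c(0.4, 0, 0.6, 5))
  expect_equal(r$avail, c(0, 95))
})

test_that("metabolism respects the published stoichiometries", {
  p <- sim_params()
  cell <- list(M = 10, R_GLU = 0, R_CN = 0, C_GLUin = 0, D = 0, lag = 0L)
  # glucose exactly covering maintenance, ample O2: no growth, no
  # ethanol, CO2 = 6 x respired glucose
  g_m <- p$k_maint * 10 / p$e_resp
  r <- metabolize(cell, list(glu = g_m, cn = 0, nh4 = 0, o2 = 1), p)
  expect_equal(r$dm, 0)
  expect_equal(r$eth_out, 0)
  expect_equal(r$co2_out, 6 * g_m, tolerance = 1e-12)
  expect_equal(r$M, 10)
  # no oxygen: all catabolism fermentative, ethanol = 2 x fermented
  g <- 0.05
  r2 <- metabolize(cell, list(glu = g, cn = 0, nh4 = 1, o2 = 0), p)
  ferm_glu <- g - r2$C_GLUin - r2$R_GLU - r2$dm * p$c_per_cn / 6
  expect_equal(r2$eth_out, 2 * ferm_glu, tolerance = 1e-9)
  expect_gt(r2$dm, 0)
  # nothing at all: maintenance catabolizes structural mass, D stays 0
  # until the cell reaches its shrinkage floor
  r3 <- metabolize(cell, list(glu = 0, cn = 0, nh4 = 0, o2 = 0), p)
  expect_equal(r3$M, 10 - p$k_maint * 10 / p$e_ferm * 6 / p$c_per_cn,
               tolerance = 1e-12)
  expect_equal(r3$dm, 0)
  floor_cell <- cell; floor_cell$M <- 0.2 * p$m_C
  r4 <- metabolize(floor_cell, list(glu = 0, cn = 0, nh4 = 0, o2 = 0), p)
  expect_equal(r4$D, p$d_increment)
})

test_that("reproduction gates on mass, growth and time thresholds", {
  p <- fast_sim_params(sigma_mB2 = 0.02, dt2 = 2, k_maint = 0)
  st <- initialize_simulation(p, seed = 5)
  cl <- st$cells
  n <- length(cl$M)
  # force two candidate mothers: one below Start mass, one above
  cl$lag[] <- 0L
  cl$M[1] <- cl$M_Start[1] - 1        # must not start budding
  cl$M[2] <- cl$M_Start[2] + 1
  cl$M_since[] <- p$dm_B1 + 1
  st$cells <- cl
  st2 <- step_simulation(st)
  expect_equal(st2$cells$Ph[1], 1L)
  expect_equal(st2$cells$Ph[2], 2L)
  # drive the budding cell to release: bud mass and time both satisfied
  cl2 <- st2$cells
  cl2$M_inc[2] <- cl2$thr_B2[2] + 0.5
  cl2$M[2] <- cl2$M[2] + cl2$M_inc[2]
  cl2$T_inc[2] <- 100L
  st2$cells <- cl2
  # drain the medium so the release step involves no growth at all
  for (nm in c("glu", "cn", "nh4", "o2")) st2$medium[[nm]][] <- 0
  pre_mass <- cl2$M[2]
  pre_n <- sum(cl2$alive)
  st3 <- step_simulation(st2)
  expect_equal(sum(st3$cells$alive), pre_n + 1)
  expect_equal(st3$cells$Ph[2], 1L)
  expect_equal(st3$cells$B[2], 1L)
  # mass is conserved at division: mother + daughter = pre-release mass
  daughter <- length(st3$cells$M)
  expect_equal(st3$cells$M[2] + st3$cells$M[daughter], pre_mass,
               tolerance = 1e-9)
  expect_equal(st3$cells$B[daughter], 0L)
})

test_that("released bud masses track the configured threshold mean", {
  p <- sim_params(condition = "aerobic", inoculum = 400,
                  lag_mean_h = 0, lag_sd_h = 0)
  st <- initialize_simulation(p, seed = 9)
  births <- numeric(0)
  for (i in 1:240) {
    n0 <- length(st$cells$M)
    st <- step_simulation(st)
    n1 <- length(st$cells$M)
    if (n1 > n0) births <- c(births, st$cells$M[(n0 + 1):n1])
  }
  expect_gt(length(births), 50)
  se <- sd(births) / sqrt(length(births))
  # a bud is released at the first step its mass clears the drawn
  # threshold, so the mean release mass sits just above dm_B2 by at most
  # one step of growth
  overshoot <- p$r_growth * mean(st$cells$M)
  expect_gt(mean(births), p$dm_B2 - 2 * se)
  expect_lt(mean(births), p$dm_B2 + overshoot + 2 * se)
})

test_that("lifespan rules kill by scars or mortality index only", {
  p <- fast_sim_params()
  expect_true(viability(list(D = 0, B = 0), p))
  expect_true(viability(list(D = p$d_threshold, B = p$max_B), p))
  expect_false(viability(list(D = p$d_threshold + 1, B = 0), p))
  expect_false(viability(list(D = 0, B = p$max_B + 1), p))
})

test_that("starved populations never grow and eventually shrink", {
  p <- fast_sim_params(glucose_total = 0, nh4_total = 0, cn_total = 0,
                       d_threshold = 40, lag_mean_h = 0, lag_sd_h = 0,
                       condition = "microaerophilic", o2_sat_site = 0)
  st <- initialize_simulation(p, seed = 6)
  counts <- integer(0)
  for (i in 1:300) {
    st <- step_simulation(st)
    counts <- c(counts, sum(st$cells$alive))
  }
  expect_true(all(diff(counts) <= 0))
  expect_lt(counts[300], counts[1])
})

test_that("cells in their individual lag do not change", {
  p <- fast_sim_params(lag_mean_h = 10, lag_sd_h = 0.1)
  st <- initialize_simulation(p, seed = 7)
  M0 <- st$cells$M
  st2 <- st
  for (i in 1:20) st2 <- step_simulation(st2)
  expect_identical(st2$cells$M, M0)
  expect_identical(st2$cells$Ph, st$cells$Ph)
  expect_equal(st2$cells$lag, st$cells$lag - 20L)
})

test_that("carbon is conserved through growth, death and fermentation", {
  p <- fast_sim_params(condition = "microaerophilic")
  st <- initialize_simulation(p, seed = 2)
  drift <- 0
  for (i in 1:400) {
    st <- step_simulation(st)
    drift <- max(drift, abs(total_carbon(st) - st$carbon0) / st$carbon0)
  }
  expect_lt(drift, 1e-9)
  expect_gt(sum(st$cells$alive), 50)   # the population actually grew
})

test_that("an empty population is a fixed point except for aeration", {
  p <- fast_sim_params()
  st <- initialize_simulation(p, seed = 3)
  st$cells$alive[] <- FALSE
  st$medium$o2[] <- 0                  # degassed, so aeration is visible
  med0 <- st$medium
  st2 <- step_simulation(st)
  expect_identical(st2$medium[c("glu", "cn", "nh4", "eth", "co2")],
                   med0[c("glu", "cn", "nh4", "eth", "co2")])
  expect_true(all(st2$medium$o2 > 0))  # re-aerated
})

test_that("projected morphometrics follow tangent-circle geometry", {
  # unbudded: perfect circle
  u <- project_morphometry(2.5, 0)
  expect_equal(u$circularity, 1)
  expect_equal(u$elongation, 1)
  expect_equal(u$area_um2, pi * 2.5^2)
  # equal mother and bud
  e <- project_morphometry(2, 2)
  expect_equal(e$circularity, 0.5)
  expect_equal(e$elongation, 2)
  # algebraic identity with the shape definitions
  m <- project_morphometry(3.1, 1.4)
  expect_equal(m$circularity, 4 * pi * m$area_um2 / m$perimeter_um^2,
               tolerance = 1e-12)
  expect_error(project_morphometry(1, 2), "R_b")
})

test_that("snapshots sample without replacement and scale as mass^(1/3)", {
  p <- fast_sim_params(inoculum = 10)
  st <- initialize_simulation(p, seed = 5)
  sn <- sample_snapshot(st, n = 500)
  expect_equal(nrow(sn), 10)
  expect_true(all(sn$R_b == 0))
  expect_true(all(sn$elongation == 1 & sn$circularity == 1))
  # doubling M at fixed M_inc scales the mother radius by 2^(1/3)
  st2 <- st
  st2$cells$M <- 2 * st2$cells$M
  sn2 <- sample_snapshot(st2, n = 500)
  expect_equal(sn2$R_m / sn$R_m, rep(2^(1 / 3), 10), tolerance = 1e-12)
})

test_that("simulated shape invariants hold for budded and unbudded cells", {
  p <- fast_sim_params()
  r <- run_simulation(p, duration_h = 4, seed = 12, sample_every_h = 1,
                      sample_n = 200)
  snap <- do.call(rbind, r$snapshots)
  un <- snap[!snap$budded, ]
  bd <- snap[snap$budded & snap$R_b > 0, ]  # nascent buds are still circles
  expect_true(all(un$elongation == 1 & un$circularity == 1))
  if (nrow(bd)) {
    expect_true(all(bd$elongation > 1 & bd$elongation <= 2))
    expect_true(all(bd$circularity >= 0.5 & bd$circularity < 1))
  }
})

test_that("runs are reproducible and auditable", {
  p <- fast_sim_params()
  a <- run_simulation(p, duration_h = 2, seed = 17, sample_every_h = 1)
  b <- run_simulation(p, duration_h = 2, seed = 17, sample_every_h = 1)
  expect_identical(a$time_series, b$time_series)
  expect_identical(a$snapshots, b$snapshots)
  # zero-duration run echoes the initial state
  z <- run_simulation(p, duration_h = 0, seed = 17, sample_every_h = NA)
  expect_equal(nrow(z$time_series), 1)
  expect_equal(z$time_series$viable_count, 50)
  # births/deaths audit: growth only through bud release
  st <- a$final_state
  expect_equal(sum(st$cells$alive), p$inoculum + st$births - st$deaths)
  if (st$deaths == 0)
    expect_equal(sum(st$cells$B), st$births)
})
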