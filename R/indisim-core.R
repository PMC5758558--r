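# Individual-based simulator core.  Cell state lives in parallel vectors;
# each step shuffles the acting order and performs move -> uptake ->
# metabolism -> reproduction -> viability per cell, then medium actions.
# Within-site substrate contention honours the shuffled order: each cell
# takes min(demand, what is left at its site), implemented with a grouped
# cumulative sum rather than an explicit loop.

.site_index <- function(x, y, z, L) x + L * (y - 1L) + L * L * (z - 1L)

# sequential min-rule allocation: cells (in shuffled order `ord`) draw
# `demand` from `avail[site]`; returns per-cell amounts taken and the
# updated availability vector
.site_alloc <- function(avail, site, demand, ord) {
  take <- numeric(length(demand))
  act <- ord[demand[ord] > 0]
  if (length(act)) {
    s <- site[act]
    oo <- order(s)                      # stable: keeps shuffled order
    so <- s[oo]; d <- demand[act][oo]
    first <- !duplicated(so)
    gid <- cumsum(first)
    cs <- cumsum(d)
    before <- cs - d - (cs[first] - d[first])[gid]
    tk <- pmin(d, pmax(avail[so] - before, 0))
    take[act[oo]] <- tk
    cst <- cumsum(tk)
    last <- c(which(first)[-1] - 1L, length(so))
    usite <- so[first]
    avail[usite] <- pmax(avail[usite] -
                         (cst[last] - (cst[first] - tk[first])), 0)
  }
  list(taken = take, avail = avail)
}

# grouped sum into a full-length site vector, via one sort shared by the
# caller (rowsum's character rownames are too slow at this call rate)
.group_sum <- function(v, site, nsite, ord) {
  so <- site[ord]; vo <- v[ord]
  first <- !duplicated(so)
  cs <- cumsum(vo)
  last <- c(which(first)[-1] - 1L, length(so))
  out <- numeric(nsite)
  out[so[first]] <- cs[last] - (cs[first] - vo[first])
  out
}

.draw_mstart <- function(p, k) {
  pmax(p$m_C * (1 + stats::rnorm(k, 0, p$sigma_mC)), 0.1 * p$m_C)
}

.aerate <- function(med, p) {
  if (p$condition == "aerobic" && p$k_aeration > 0)
    med$o2 <- med$o2 + p$k_aeration * (p$o2_sat_site - med$o2)
  med
}

.append_cells <- function(cl, add) {
  for (nm in names(cl)) cl[[nm]] <- c(cl[[nm]], add[[nm]])
  cl
}

#' Initialize the simulation state
#'
#' Places the inoculum uniformly at random on the lattice, draws each
#' cell's Start mass `M_Start ~ m_C (1 + N(0, sigma_mC))` (truncated
#' positive) and its individual lag time, and loads the medium with the
#' initial substrate amounts.  Under the aerobic policy oxygen starts at
#' saturation and is replenished each step; under the microaerophilic
#' policy only the initially dissolved oxygen is available.
#'
#' @param params a [sim_params()].
#' @param seed integer seed; the whole simulation is deterministic given
#'   the seed.
#' @return a `sim_state` list with `cells` (parallel state vectors),
#'   `medium` (per-site substrate vectors), `params`, `step` counter and
#'   the initial total-carbon audit `carbon0`.
#' @export
initialize_simulation <- function(params, seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  L <- as.integer(params$lattice_size)
  nsite <- L^3
  n <- as.integer(params$inoculum)
  if (n > nsite * 100) stop("inoculum exceeds lattice capacity")

  lag_h <- pmax(stats::rnorm(n, params$lag_mean_h, params$lag_sd_h), 0)
  cells <- list(
    x = sample.int(L, n, replace = TRUE),
    y = sample.int(L, n, replace = TRUE),
    z = sample.int(L, n, replace = TRUE),
    M = pmax(params$m_C * (1 + stats::rnorm(n, 0, 0.1)),
             0.2 * params$m_C),
    B = integer(n),
    Ph = rep(1L, n),                       # 1 unbudded, 2 budding
    M_Start = .draw_mstart(params, n),
    M_inc = numeric(n),
    T_inc = integer(n),
    M_since = numeric(n),                  # growth since birth/last release
    thr_B2 = numeric(n),                   # per-cycle release threshold
    R_GLU = numeric(n),
    R_CN = numeric(n),
    C_GLUin = numeric(n),
    D = numeric(n),
    lag = as.integer(round(lag_h * 60 / params$step_min)),
    alive = rep(TRUE, n))

  medium <- list(
    glu = rep(params$glucose_total / nsite, nsite),
    cn = rep(params$cn_total / nsite, nsite),
    nh4 = rep(params$nh4_total / nsite, nsite),
    o2 = rep(params$o2_sat_site, nsite),
    eth = numeric(nsite),
    co2 = numeric(nsite),
    dead_c = numeric(nsite))

  st <- structure(list(cells = cells, medium = medium, params = params,
                       step = 0L, seed = seed, births = 0L, deaths = 0L),
                  class = "sim_state")
  st$carbon0 <- total_carbon(st)
  st
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("sim_state (%s): step %d, %d living cells\n",
              x$params$condition, x$step, sum(x$cells$alive)))
  invisible(x)
}

#' Total carbon in the system
#'
#' Sums carbon over every pool: medium glucose (6 C per pmol), organic N
#' (1 C), ethanol (2 C), CO2 (1 C), dead-cell organic carbon, and for
#' each living cell its structural mass, carbohydrate reserve, organic-N
#' reserve and internal glucose.  In a sealed run this is invariant.
#'
#' @param state a `sim_state`.
#' @return total carbon (C-pmol).
#' @export
total_carbon <- function(state) {
  m <- state$medium
  cl <- state$cells
  p <- state$params
  a <- cl$alive
  sum(m$glu) * 6 + sum(m$cn) + sum(m$eth) * 2 + sum(m$co2) +
    sum(m$dead_c) +
    sum(cl$M[a]) * p$c_per_cn + sum(cl$R_GLU[a]) * 6 + sum(cl$R_CN[a]) +
    sum(cl$C_GLUin[a]) * 6
}

#' Substrate uptake of one cell from its local site
#'
#' Uptake of each substrate is `min(available at the site, rate x
#' surface)` with surface proportional to `M^(2/3)`.  Glucose uptake is
#' scaled down as the internal free-carbon pool fills (internal C:N above
#' target) and nitrogen-source uptake as the organic-N reserve fills
#' (N-replete), via saturating feedback factors.  Cells still in their
#' individual lag take up nothing.
#'
#' @param cell list with at least `M`, `C_GLUin`, `R_CN`, `lag`.
#' @param site list with `glu`, `cn`, `nh4`, `o2` amounts at the site.
#' @param params a [sim_params()].
#' @return list of amounts taken (`glu`, `cn`, `nh4`, `o2`).
#' @export
uptake <- function(cell, site, params) {
  if (cell$lag > 0)
    return(list(glu = 0, cn = 0, nh4 = 0, o2 = 0))
  surf <- cell$M^(2 / 3)
  f_glu <- 1 / (1 + cell$C_GLUin / (params$glu_feedback * cell$M))
  f_n <- 1 / (1 + cell$R_CN / (params$n_feedback * cell$M))
  list(glu = min(site$glu, params$u_glu * surf * f_glu),
       cn = min(site$cn, params$u_n * surf * f_n),
       nh4 = min(site$nh4, params$u_n * surf * f_n),
       o2 = min(site$o2, params$u_o2 * surf))
}

# vectorized uptake demands; mirrors uptake() exactly
.uptake_demands <- function(cl, p, active) {
  surf <- cl$M^(2 / 3)
  f_glu <- 1 / (1 + cl$C_GLUin / (p$glu_feedback * cl$M))
  f_n <- 1 / (1 + cl$R_CN / (p$n_feedback * cl$M))
  list(glu = p$u_glu * surf * f_glu * active,
       n = p$u_n * surf * f_n * active,
       o2 = p$u_o2 * surf * active)
}

# Vectorized metabolism kernel shared by step_simulation() and the
# single-cell metabolize() wrapper.  Inputs are parallel vectors; returns
# updated pools, mass increment and per-cell releases.  Carbon balance:
# glucose either becomes biomass carbon, CO2 (respiration, 6 CO2 per
# glucose), or ethanol + CO2 (fermentation, 2 + 2 per glucose); consumed
# organic-N carbon leaves as CO2; nothing is created or lost.
.metabolize_vec <- function(M, R_GLU, R_CN, C_GLUin, D,
                            up_glu, up_cn, up_nh4, up_o2, active, p) {
  glu_pool <- C_GLUin + up_glu
  n_pool <- R_CN + up_cn + up_nh4
  o2_left <- up_o2

  # maintenance: respiration first, then fermentation, then the reserve;
  # unmet maintenance raises the mortality index
  e_need <- p$k_maint * M * active
  g_resp <- pmin(glu_pool, o2_left / 6, e_need / p$e_resp)
  e_need <- e_need - g_resp * p$e_resp
  glu_pool <- glu_pool - g_resp
  o2_left <- o2_left - 6 * g_resp
  co2_out <- 6 * g_resp
  g_ferm <- pmin(glu_pool, pmax(e_need, 0) / p$e_ferm)
  e_need <- e_need - g_ferm * p$e_ferm
  glu_pool <- glu_pool - g_ferm
  eth_out <- 2 * g_ferm
  co2_out <- co2_out + 2 * g_ferm
  # reserve draw-down, respiring while oxygen lasts
  r_resp <- pmin(R_GLU, o2_left / 6, pmax(e_need, 0) / p$e_resp)
  e_need <- e_need - r_resp * p$e_resp
  R_GLU <- R_GLU - r_resp
  o2_left <- o2_left - 6 * r_resp
  co2_out <- co2_out + 6 * r_resp
  g_res <- pmin(R_GLU, pmax(e_need, 0) / p$e_ferm)
  e_need <- e_need - g_res * p$e_ferm
  R_GLU <- R_GLU - g_res
  eth_out <- eth_out + 2 * g_res
  co2_out <- co2_out + 2 * g_res
  # last resort: catabolize structural mass itself (cells shrink in deep
  # starvation), down to a floor of 0.2 m_C; only then does D rise
  bio_avail <- pmax(M - 0.2 * p$m_C, 0) * p$c_per_cn / 6
  b_resp <- pmin(bio_avail, o2_left / 6, pmax(e_need, 0) / p$e_resp)
  e_need <- e_need - b_resp * p$e_resp
  bio_avail <- bio_avail - b_resp
  o2_left <- o2_left - 6 * b_resp
  co2_out <- co2_out + 6 * b_resp
  b_ferm <- pmin(bio_avail, pmax(e_need, 0) / p$e_ferm)
  e_need <- e_need - b_ferm * p$e_ferm
  eth_out <- eth_out + 2 * b_ferm
  co2_out <- co2_out + 2 * b_ferm
  shrink <- (b_resp + b_ferm) * 6 / p$c_per_cn
  M <- M - shrink
  starved <- active & e_need > 1e-12
  D <- pmax(D + p$d_increment * starved -
              p$d_recovery * (active & !starved), 0)

  # synthesis at up to r_growth * M: carbon from the glucose pool, energy
  # by respiration while oxygen lasts, fermentation for the remainder,
  # nitrogen from NH4/organic-N/reserve
  dm_cap <- p$r_growth * M * (active & !starved)
  q_c <- p$c_per_cn / 6                   # glucose-pmol carbon per unit
  q_er <- p$e_synth / p$e_resp            # glucose respired per unit
  dm_resp <- pmax(pmin(dm_cap,
                       glu_pool / (q_c + q_er),
                       (o2_left / 6) / q_er,
                       n_pool / p$n_per_cn), 0)
  glu_pool <- glu_pool - dm_resp * (q_c + q_er)
  o2_left <- o2_left - 6 * dm_resp * q_er
  co2_out <- co2_out + 6 * dm_resp * q_er
  n_pool <- n_pool - dm_resp * p$n_per_cn
  q_ef <- p$e_synth / p$e_ferm            # glucose fermented per unit
  dm_ferm <- pmax(pmin(dm_cap - dm_resp,
                       glu_pool / (q_c + q_ef),
                       n_pool / p$n_per_cn), 0)
  glu_pool <- glu_pool - dm_ferm * (q_c + q_ef)
  eth_out <- eth_out + 2 * dm_ferm * q_ef
  co2_out <- co2_out + 2 * dm_ferm * q_ef
  n_pool <- n_pool - dm_ferm * p$n_per_cn
  dm <- dm_resp + dm_ferm

  # nitrogen bookkeeping: N preferentially from NH4; consumed organic-N
  # carbon is released as CO2 (energy-neutral deamination); leftover
  # organic N is stored in the reserve, leftover NH4 goes back to the site
  n_used <- dm * p$n_per_cn
  cn_used <- pmax(n_used - up_nh4, 0)
  co2_out <- co2_out + cn_used
  nh4_back <- pmax(up_nh4 - n_used, 0)
  R_CN <- n_pool - nh4_back

  M <- M + dm
  # surplus glucose refills the reserve up to its cap, rest stays internal
  cap <- p$reserve_frac * M * p$c_per_cn / 6
  to_res <- pmin(pmax(cap - R_GLU, 0), glu_pool) * active
  R_GLU <- R_GLU + to_res
  C_GLUin <- glu_pool - to_res

  list(M = M, R_GLU = R_GLU, R_CN = R_CN, C_GLUin = C_GLUin, D = D,
       dm = dm, shrink = shrink, starved = starved, eth_out = eth_out,
       co2_out = co2_out, o2_left = o2_left, nh4_back = nh4_back)
}

#' Metabolize one cell for one time step
#'
#' Applies the maintenance-then-synthesis metabolism to a single cell
#' given the amounts it took up this step.  Respiration (1 glucose : 6 O2
#' -> 6 CO2) is used while oxygen lasts; the remainder ferments
#' (1 glucose -> 2 ethanol + 2 CO2).  Unmet maintenance draws down the
#' carbohydrate reserve and then raises the mortality index `D`.
#'
#' @param cell list with `M`, `R_GLU`, `R_CN`, `C_GLUin`, `D`, `lag`.
#' @param uptaken list of amounts taken this step (`glu`, `cn`, `nh4`,
#'   `o2`), e.g. from [uptake()].
#' @param params a [sim_params()].
#' @return list with the updated cell fields, the mass increment `dm` and
#'   the site releases (`eth_out`, `co2_out`, `o2_left`, `nh4_back`).
#' @export
metabolize <- function(cell, uptaken, params) {
  r <- .metabolize_vec(cell$M, cell$R_GLU, cell$R_CN, cell$C_GLUin,
                       cell$D, uptaken$glu, uptaken$cn, uptaken$nh4,
                       uptaken$o2, active = cell$lag == 0, params)
  lapply(r, function(v) v[1])
}

#' Advance the simulation by one time step
#'
#' Shuffles the acting order; each living, adapted cell then moves to a
#' random neighbouring site, takes up substrates (sequentially, honouring
#' what previous cells left at its site), metabolizes, reproduces and is
#' checked for viability; finally the medium is re-aerated under the
#' aerobic policy.  Cells still in their individual lag do nothing and do
#' not change.  Total carbon is conserved exactly.
#'
#' @param state a `sim_state`.
#' @return the updated `sim_state`.
#' @export
step_simulation <- function(state) {
  cl <- state$cells
  p <- state$params
  L <- as.integer(p$lattice_size)
  n <- length(cl$M)
  alive <- cl$alive
  if (!any(alive)) {
    state$medium <- .aerate(state$medium, p)
    state$step <- state$step + 1L
    return(state)
  }
  ord <- sample.int(n)                 # random acting order
  active <- alive & cl$lag == 0L

  ## (i) random motion: one-site hop in a random direction, reflecting
  mv <- which(active)
  if (length(mv)) {
    dim3 <- sample.int(3, length(mv), replace = TRUE)
    dir <- sample(c(-1L, 1L), length(mv), replace = TRUE)
    for (d in 1:3) {
      sel <- mv[dim3 == d]
      if (!length(sel)) next
      co <- switch(d, cl$x, cl$y, cl$z)
      co[sel] <- pmin(pmax(co[sel] + dir[dim3 == d], 1L), L)
      if (d == 1) cl$x <- co else if (d == 2) cl$y <- co else cl$z <- co
    }
  }
  site <- .site_index(cl$x, cl$y, cl$z, L)
  med <- state$medium

  ## (ii) uptake, honouring the shuffled order within each site
  dem <- .uptake_demands(cl, p, active)
  al <- .site_alloc(med$glu, site, dem$glu, ord)
  up_glu <- al$taken; med$glu <- al$avail
  al <- .site_alloc(med$cn, site, dem$n, ord)
  up_cn <- al$taken; med$cn <- al$avail
  al <- .site_alloc(med$nh4, site, dem$n, ord)
  up_nh4 <- al$taken; med$nh4 <- al$avail
  al <- .site_alloc(med$o2, site, dem$o2, ord)
  up_o2 <- al$taken; med$o2 <- al$avail

  ## (iii) metabolism
  mb <- .metabolize_vec(cl$M, cl$R_GLU, cl$R_CN, cl$C_GLUin, cl$D,
                        up_glu, up_cn, up_nh4, up_o2, active, p)
  dm <- mb$dm
  cl$M <- mb$M
  cl$R_GLU <- mb$R_GLU
  cl$R_CN <- mb$R_CN
  cl$C_GLUin <- mb$C_GLUin
  cl$D <- mb$D
  cl$M_since <- cl$M_since + dm
  bud <- cl$Ph == 2L
  cl$M_inc[bud] <- cl$M_inc[bud] + dm[bud]
  cl$M_inc <- pmin(cl$M_inc, cl$M)       # shrinkage cannot exceed the bud
  cl$T_inc[active & bud] <- cl$T_inc[active & bud] + 1L

  so_ord <- order(site)
  nsite <- length(med$eth)
  med$eth <- med$eth + .group_sum(mb$eth_out, site, nsite, so_ord)
  med$co2 <- med$co2 + .group_sum(mb$co2_out, site, nsite, so_ord)
  med$o2 <- med$o2 + .group_sum(mb$o2_left, site, nsite, so_ord)
  med$nh4 <- med$nh4 + .group_sum(mb$nh4_back, site, nsite, so_ord)

  ## (iv) reproduction: unbudded -> budding at M >= M_Start with enough
  ## growth; bud release after enough bud growth and time
  start <- active & cl$Ph == 1L & cl$M >= cl$M_Start &
    cl$M_since >= p$dm_B1
  if (any(start)) {
    k <- sum(start)
    cl$Ph[start] <- 2L
    cl$M_inc[start] <- 0
    cl$T_inc[start] <- 0L
    cl$thr_B2[start] <- pmax(p$dm_B2 *
      (1 + stats::rnorm(k, 0, p$sigma_mB2)), 0.1 * p$dm_B2)
  }
  rel <- active & cl$Ph == 2L & cl$M_inc >= cl$thr_B2 &
    cl$T_inc >= as.integer(p$dt2)
  if (any(rel)) {
    k <- sum(rel)
    bm <- cl$M_inc[rel]
    cl$M[rel] <- cl$M[rel] - bm
    cl$B[rel] <- cl$B[rel] + 1L
    cl$Ph[rel] <- 1L
    cl$M_inc[rel] <- 0
    cl$T_inc[rel] <- 0L
    cl$M_since[rel] <- 0
    cl <- .append_cells(cl, list(
      x = cl$x[rel], y = cl$y[rel], z = cl$z[rel],
      M = bm, B = integer(k), Ph = rep(1L, k),
      M_Start = .draw_mstart(p, k), M_inc = numeric(k),
      T_inc = integer(k), M_since = numeric(k), thr_B2 = numeric(k),
      R_GLU = numeric(k), R_CN = numeric(k), C_GLUin = numeric(k),
      D = numeric(k), lag = integer(k), alive = rep(TRUE, k)))
    state$births <- state$births + k
  }

  ## (v) viability: replicative and chronological lifespan; dead cells
  ## release their carbon to the site as organic carbon
  die <- cl$alive & (cl$B > p$max_B | cl$D > p$d_threshold)
  if (any(die)) {
    s <- .site_index(cl$x[die], cl$y[die], cl$z[die], L)
    creleased <- cl$M[die] * p$c_per_cn + cl$R_GLU[die] * 6 +
      cl$R_CN[die] + cl$C_GLUin[die] * 6
    med$dead_c <- med$dead_c + .group_sum(creleased, s,
                                          length(med$dead_c), order(s))
    cl$alive[die] <- FALSE
    cl$M[die] <- 1e-12                   # emptied; excluded from audits
    cl$R_GLU[die] <- 0
    cl$R_CN[die] <- 0
    cl$C_GLUin[die] <- 0
    state$deaths <- state$deaths + sum(die)
  }

  in_lag <- cl$alive & cl$lag > 0L
  cl$lag[in_lag] <- cl$lag[in_lag] - 1L

  ## medium actions
  med <- .aerate(med, p)

  state$cells <- cl
  state$medium <- med
  state$step <- state$step + 1L
  state
}

#' Check viability of one cell
#'
#' A cell dies when its mortality index `D` exceeds the chronological
#' threshold or its genealogical age `B` exceeds the replicative limit.
#'
#' @param cell list with `D` and `B`.
#' @param params a [sim_params()].
#' @return TRUE if the cell is alive.
#' @export
viability <- function(cell, params) {
  cell$D <= params$d_threshold && cell$B <= params$max_B
}
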