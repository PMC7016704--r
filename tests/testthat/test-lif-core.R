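test_that("input current follows the initialisation contract", {
  m <- peak_map()
  lif <- defaults$lif
  ## zero noise: I = Ginput * S exactly
  st <- init_input_current(m, lif, zero_noise, seed = 1)
  expect_equal(st$I, lif$Ginput * m$values)
  expect_true(all(st$V == lif$Eleak))
  ## constant noise only, on a zero map
  m0 <- synthetic_saliency_map(4, 4, list())
  stc <- init_input_current(m0, lif, noise_params(0, 3e-10, 1e-9), seed = 1)
  expect_equal(stc$I, matrix(lif$Ginput * 3e-10, 4, 4))
  ## uniform noise is bounded: Ginput*S <= I <= Ginput*(S + const + ampl)
  nz <- noise_params(2e-10, 1e-10, 1e-9)
  for (s in c(2, 99)) {
    sti <- init_input_current(m, lif, nz, seed = s)
    expect_true(all(sti$I >= lif$Ginput * m$values))
    expect_true(all(sti$I <= lif$Ginput * (m$values + 3e-10)))
  }
  ## map_range rescales the map the current sees
  st2 <- init_input_current(m, lif, noise_params(0, 0, 2e-9), seed = 1)
  expect_equal(st2$I, 2 * st$I)
})

test_that("euler_step matches hand-computed updates", {
  mk_state <- function(V, I) {
    structure(list(V = matrix(V, 1, 1), I = matrix(I, 1, 1),
                   fired = matrix(FALSE, 1, 1), t = 0),
              class = "neuron_field_state")
  }
  ## fixed point: V = Eleak, I = 0
  lp <- lif_params(Gexc = 0)
  st <- euler_step(mk_state(lp$Eleak, 0), lp)
  expect_equal(st$V[1, 1], lp$Eleak)
  expect_false(st$fired[1, 1])
  ## pure integrator: Gleak = 0 increments by dt*I/C exactly
  lp0 <- lif_params(Gleak = 0, Gexc = 0)
  st <- euler_step(mk_state(0, 3e-9), lp0)
  expect_equal(st$V[1, 1], lp0$dt * 3e-9 / lp0$C)
  ## single-step hand computation:
  ## V=0, I=2e-9, Gleak=1e-8, C=1e-9, dt=1e-4 -> Vnew = 2e-4
  lp1 <- lif_params(dt = 1e-4, Eleak = 0, Gleak = 1e-8, C = 1e-9, Gexc = 0)
  st <- euler_step(mk_state(0, 2e-9), lp1)
  expect_equal(st$V[1, 1], 2e-4)
  ## time advances by dt (in ms) and threshold crossing resets to Eleak
  expect_equal(st$t, 0.1)
  lp2 <- lif_params(Vthresh = 1e-4)
  st2 <- euler_step(mk_state(0, 2e-9), lp2)
  expect_true(st2$fired[1, 1])
  expect_equal(st2$V[1, 1], lp2$Eleak)
  ## the printed dt*C variant is selectable and differs by C^2
  stl <- euler_step(mk_state(0, 2e-9), lp1, literal_dtC = TRUE)
  expect_equal(stl$V[1, 1], 2e-4 * lp1$C^2)
})

test_that("unstable parameter scales raise an instability error", {
  st <- structure(list(V = matrix(0, 1, 1), I = matrix(1e300, 1, 1),
                       fired = matrix(FALSE, 1, 1), t = 0),
                  class = "neuron_field_state")
  lp <- lif_params(C = 1e-300, Vthresh = 1e10)
  expect_error(euler_step(st, lp), "instability")
})

test_that("zero-noise simulation is deterministic with the argmax winner", {
  m <- peak_map()
  s1 <- first_spike(m, defaults$lif, defaults$wta, zero_noise, seed = 1)
  s2 <- first_spike(m, defaults$lif, defaults$wta, zero_noise, seed = 424242)
  expect_identical(s1$latency_ms, s2$latency_ms)
  expect_identical(s1$winner, s2$winner)
  expect_equal(unname(s1$winner), c(6, 8))
  ## winner equals the map argmax on random maps with a unique maximum
  maps <- synthetic_map_set(25, 10, 12, seed = 77)
  for (m2 in maps) {
    s <- first_spike(m2, defaults$lif, defaults$wta, zero_noise)
    expect_equal(unname(s$winner), unname(saliency_argmax(m2)))
  }
})

test_that("an undriven map is censored at the timeout, not an error", {
  m0 <- synthetic_saliency_map(6, 6, list())
  s <- first_spike(m0, defaults$lif, defaults$wta, zero_noise,
                   timeout_ms = 2000)
  expect_true(s$censored)
  expect_true(is.na(s$latency_ms))
})

test_that("a higher saliency peak never fires later", {
  hs <- seq(0.3, 1, by = 0.1)
  lat <- vapply(hs, function(h) {
    first_spike(peak_map(h = h), defaults$lif, defaults$wta,
                zero_noise)$latency_ms
  }, numeric(1))
  expect_true(all(diff(lat) <= 0))
  expect_lt(lat[length(lat)], lat[1])
})

test_that("compiled loop agrees with an euler_step reference simulation", {
  ## independent two-layer reference built from the exported R step
  m <- peak_map(6, 8, loc = c(3, 5))
  lif <- defaults$lif
  wta <- defaults$wta
  ref_first_spike <- function(map, lif, wta, max_steps = 20000) {
    sm <- init_input_current(map, lif, noise_params(0, 0, 1e-9))
    wl <- structure(list(V = matrix(lif$Eleak, nrow(map$values),
                                    ncol(map$values)),
                         I = matrix(0, nrow(map$values), ncol(map$values)),
                         fired = sm$fired, t = 0),
                    class = "neuron_field_state")
    wp <- lif_params(dt = lif$dt, Eleak = lif$Eleak, Eexc = lif$Eexc,
                     Einh = lif$Einh, Gleak = wta$Gleak, Gexc = lif$Gexc,
                     Vthresh = lif$Vthresh, C = wta$C)
    for (step in seq_len(max_steps)) {
      sm <- euler_step(sm, lif)
      wl <- euler_step(wl, wp, Gexc_field = lif$Gexc * sm$fired)
      if (any(wl$fired)) {
        return(list(step = step, winner = which(wl$fired, arr.ind = TRUE)[1, ]))
      }
    }
    NULL
  }
  ref <- ref_first_spike(m, lif, wta)
  cpp <- first_spike(m, lif, wta, zero_noise)
  expect_equal(cpp$latency_ms, ref$step * lif$dt * 1000)
  expect_equal(unname(cpp$winner), unname(ref$winner))
})

test_that("simulated spike times match the closed-form crossing time", {
  ## single-neuron leaky integrator, random parameter draws with I above
  ## the firing threshold current
  set.seed(88)
  for (k in 1:10) {
    tau <- runif(1, 0.01, 0.2)            # C / Gleak, seconds
    Gleak <- 10^runif(1, -9, -7)
    C <- tau * Gleak
    Vth <- 10^runif(1, -4, -2)
    lp <- lif_params(dt = 1e-4, Gleak = Gleak, C = C, Vthresh = Vth,
                     Gexc = 0, Ginput = 1)
    I <- Vth * Gleak * runif(1, 1.2, 6)
    tstar <- lif_crossing_time(I, lp)
    st <- structure(list(V = matrix(0, 1, 1), I = matrix(I, 1, 1),
                         fired = matrix(FALSE, 1, 1), t = 0),
                    class = "neuron_field_state")
    n <- 0
    repeat {
      st <- euler_step(st, lp)
      n <- n + 1
      if (st$fired[1, 1] || n > 5e5) break
    }
    expect_lt(abs(n * lp$dt - tstar), lp$dt + 1e-12)
  }
})

test_that("batch simulation is seed-reproducible with the right shape", {
  maps <- synthetic_map_set(5, 8, 8, seed = 3)
  s1 <- batch_simulate(maps, defaults, runs_per_image = 2, seed = 10)
  s2 <- batch_simulate(maps, defaults, runs_per_image = 2, seed = 10)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 10L)
  expect_identical(sort(unique(s1$image_id)), 1:5)
  s3 <- batch_simulate(maps, defaults, runs_per_image = 1, seed = 11)
  expect_identical(nrow(s3), 5L)
})

test_that("distinct latency counting follows its contract", {
  d <- data.frame(image_id = 1L, latency_ms = c(150, 150, 151),
                  censored = FALSE)
  expect_identical(count_distinct_latencies(d), 2L)
  expect_error(count_distinct_latencies(d[0, ]), "no saccades")
  d2 <- rbind(d, data.frame(image_id = 2L, latency_ms = c(100, NA),
                            censored = c(FALSE, TRUE)))
  expect_error(count_distinct_latencies(d2), "multiple")
  expect_identical(unname(count_distinct_latencies(d2, by_image = TRUE)),
                   c(2L, 1L))
})
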