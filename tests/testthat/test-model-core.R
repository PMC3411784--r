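test_that("external input is a circular Gaussian peaking at the stimulus", {
  stim <- av_stimulus("visual", position = 120, strength = 15, width = 4)
  e <- external_input(stim, basal)
  expect_equal(e[121], 15)                      # unit at 120 deg
  expect_equal(e[125], 15 * exp(-1 / 2))        # one sigma away (124 deg)
  # wrap symmetry: stimulus at 0 reaches units 178 and 2 equally
  e0 <- external_input(av_stimulus("visual", 0, 15, width = 4), basal)
  expect_equal(e0[179], e0[3])
  expect_error(av_stimulus("auditory", 10, strength = -1), "nonnegative")
})

test_that("initial lateral weights form a Mexican hat without self-loops", {
  w <- lateral_weights(basal)
  expect_equal(diag(w$L_ex), rep(0, 180))
  expect_equal(diag(w$L_in), rep(0, 180))
  expect_true(all(w$L_ex >= 0) && all(w$L_in >= 0))
  expect_true(all(w$L_ex <= basal$L_max))
  # direct evaluation of the difference-of-Gaussians at 1 and 10 degrees
  net1 <- w$L_ex[1, 2] - w$L_in[1, 2]
  net10 <- w$L_ex[1, 11] - w$L_in[1, 11]
  expect_equal(net1, 2.4 * exp(-1 / 8) - 1.4 * exp(-1 / 1152),
               tolerance = 1e-12)
  expect_equal(net1, 0.719, tolerance = 1e-3)
  expect_equal(net10, -1.284, tolerance = 1e-3)
  # symmetric and translation-invariant on the ring
  expect_equal(w$L_ex, t(w$L_ex))
  expect_equal(w$L_ex[5, 15], w$L_ex[105, 115])
  # leaving the Mexican-hat regime only warns
  expect_warning(av_params(sigma_ex = 30), "Mexican hat")
})

test_that("activation is the expected sigmoid", {
  expect_equal(activation(basal$theta, basal), 0.5)
  expect_equal(activation(15, basal), 1 / (1 + exp(-1.8)))
  expect_equal(activation(1e6, basal), 1)
  expect_lt(activation(0, basal), 1e-3)  # silence at rest
  u <- seq(-10, 40, by = 0.5)
  expect_true(all(diff(activation(u, basal)) > 0))
})

test_that("net input sums external, lateral and cross-modal contributions", {
  n <- basal$n_units
  zero <- numeric(n)
  E_a <- bump(100) * 15
  u <- net_input(basal_net, zero, zero, E_a, zero)
  expect_equal(u$u_a, E_a)   # rest: input is external only
  expect_equal(u$u_v, zero)
  # single active pre-synaptic unit contributes exactly one weight column
  y_a <- zero; y_a[51] <- 1
  u2 <- net_input(basal_net, y_a, zero, zero, zero)
  expect_equal(u2$u_a, basal_net$auditory$L_ex[, 51] -
                 basal_net$auditory$L_in[, 51])
  expect_equal(u2$u_v, basal$W * y_a)
  expect_error(net_input(basal_net, 1, zero, zero, zero), "length")
})

test_that("rest is a fixed point and activities stay in [0,1]", {
  st <- simulate_network(basal_net, list())
  expect_true(st$converged)
  expect_lt(max(st$y_a, st$y_v), 1e-3)
  st2 <- steady(basal_net, av_stimulus("auditory", 120, 15))
  expect_true(all(st2$y_a >= 0 & st2$y_a <= 1))
  expect_true(all(st2$y_v >= 0 & st2$y_v <= 1))
})

test_that("unimodal steady states peak at the stimulus with no phantom", {
  ctl <- run_unimodal_controls(basal, position = 120)
  expect_true(ctl$phantom_free)
  expect_equal(which.max(ctl$auditory_run$y_a) - 1L, 120L)
  expect_equal(which.max(ctl$visual_run$y_v) - 1L, 120L)
  # auditory activation broader and lower than visual activation
  act_a <- ctl$auditory_run$y_a
  act_v <- ctl$visual_run$y_v
  expect_lt(max(act_a), max(act_v))
  expect_gt(sum(act_a > 0.5 * max(act_a)), sum(act_v > 0.5 * max(act_v)))
})

test_that("with W = 0 the layers are decoupled", {
  p0 <- modify_params(basal, list(W = 0))
  net0 <- av_network(p0)
  st_a <- steady(net0, av_stimulus("auditory", 100, 15))
  st_both <- steady(net0, list(av_stimulus("auditory", 100, 15),
                               av_stimulus("visual", 120, 15)))
  expect_equal(st_a$y_a, st_both$y_a, tolerance = 1e-12)
  expect_lt(max(st_a$y_v), 1e-3)
})

test_that("dynamics are translation- and mirror-equivariant", {
  stims <- list(av_stimulus("auditory", 100, 15),
                av_stimulus("visual", 120, 15))
  st <- steady(basal_net, stims)
  # translation by 30 degrees shifts the profiles by 30 units
  st_sh <- steady(basal_net, list(av_stimulus("auditory", 130, 15),
                                  av_stimulus("visual", 150, 15)))
  shift_idx <- function(y, k) y[(seq_along(y) - 1 - k) %% length(y) + 1]
  expect_equal(st_sh$y_a, shift_idx(st$y_a, 30), tolerance = 1e-9)
  expect_equal(st_sh$y_v, shift_idx(st$y_v, 30), tolerance = 1e-9)
  # mirror about 0: positions p -> -p mod 180 reflects the profiles
  st_mir <- steady(basal_net, list(av_stimulus("auditory", 80, 15),
                                   av_stimulus("visual", 60, 15)))
  reflect <- function(y) y[c(1, rev(seq_along(y))[-length(y)])]
  expect_equal(st_mir$y_a, reflect(st$y_a), tolerance = 1e-9)
  expect_equal(st_mir$y_v, reflect(st$y_v), tolerance = 1e-9)
})

test_that("halving the integration step leaves the steady state unchanged", {
  stims <- list(av_stimulus("auditory", 100, 15),
                av_stimulus("visual", 120, 15))
  st1 <- steady(basal_net, stims)
  st2 <- steady(av_network(modify_params(basal, list(dt = 0.05))), stims)
  expect_lt(max(abs(st1$y_a - st2$y_a)), 1e-3)
  expect_lt(max(abs(st1$y_v - st2$y_v)), 1e-3)
})

test_that("snapshots record the trajectory at requested times", {
  stims <- list(av_stimulus("auditory", 100, 15),
                av_stimulus("visual", 120, 15))
  st_snap <- suppressWarnings(
    simulate_network(basal_net, stims, snapshot_times = c(2, 50)))
  expect_equal(sort(unique(st_snap$snapshots$time_ms)), c(2, 50))
  early <- subset(st_snap$snapshots, time_ms == 2 & modality == "visual")
  late <- subset(st_snap$snapshots, time_ms == 50 & modality == "visual")
  expect_lt(max(early$activity), max(late$activity))  # rising transient
  # right after onset the auditory activity peaks at the true sound
  # position; later it has migrated to the visual position
  aud2 <- subset(st_snap$snapshots, time_ms == 2 & modality == "auditory")
  aud50 <- subset(st_snap$snapshots, time_ms == 50 & modality == "auditory")
  expect_equal(aud2$unit_deg[which.max(aud2$activity)], 100)
  expect_equal(aud50$unit_deg[which.max(aud50$activity)], 120)
})
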