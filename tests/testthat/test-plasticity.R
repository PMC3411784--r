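# a paradigm-1a-trained network, shared by several tests below
trained_1a <- train_network(basal_net, make_schedule("1a"))

test_that("learning factors respect the saturation endpoints", {
  expect_equal(learning_rate_ex(0, basal), 0.015)
  expect_equal(learning_rate_ex(basal$L_max, basal), 0)
  expect_equal(learning_rate_ex(basal$L_max / 2, basal), 0.015 / 2)
  expect_equal(learning_rate_in(0, basal), 0)
  expect_equal(learning_rate_in(basal$L_in0, basal), 0.025)
  expect_equal(learning_rate_in(0.7, basal), 0.0125)
  # capped above the pre-training peak
  expect_equal(learning_rate_in(2 * basal$L_in0, basal), 0.025)
})

test_that("Hebbian deltas are threshold-gated and asymmetric", {
  w <- lateral_weights(basal)
  n <- basal$n_units
  # post-synaptic activity exactly at threshold: nothing changes
  y <- rep(basal$theta_post, n)
  d0 <- hebbian_deltas(y, y, w$L_ex, w$L_in, basal)
  expect_equal(max(abs(d0$dL_ex)), 0)
  expect_equal(max(abs(d0$dL_in)), 0)
  # silent pre-synaptic unit contributes nothing
  y_pre <- rep(0.8, n); y_pre[10] <- 0
  y_post <- rep(0.8, n)
  d1 <- hebbian_deltas(y_pre, y_post, w$L_ex, w$L_in, basal)
  expect_equal(d1$dL_ex[, 10], rep(0, n))
  expect_true(all(d1$dL_ex >= 0) && all(d1$dL_in <= 0))
  expect_equal(diag(d1$dL_ex), rep(0, n))
  # asymmetry: only the synapse onto the supra-threshold neuron potentiates
  y2 <- numeric(n); y2[5] <- 0.9; y2[50] <- 0.4
  d2 <- hebbian_deltas(y2, y2, w$L_ex, w$L_in, basal)
  expect_gt(d2$dL_ex[5, 50], 0)   # 50 -> 5 potentiates
  expect_equal(d2$dL_ex[50, 5], 0)  # 5 -> 50 gated off
})

test_that("normalization conserves row sums and redistributes weight", {
  w <- lateral_weights(basal)
  t_ex <- rowSums(w$L_ex); t_in <- rowSums(w$L_in)
  # identity when nothing changed
  out <- normalize_incoming(w$L_ex, w$L_in, t_ex, t_in, basal)
  expect_identical(out$L_ex, w$L_ex)
  expect_identical(out$L_in, w$L_in)
  # one synapse grows: the rest of its row shrinks, sum conserved
  L2 <- w$L_ex; L2[7, 20] <- L2[7, 20] + 0.5
  out2 <- normalize_incoming(L2, w$L_in, t_ex, t_in, basal)
  expect_equal(rowSums(out2$L_ex), t_ex, tolerance = 1e-12)
  others <- setdiff(which(w$L_ex[7, ] > 1e-12), 20)
  expect_true(all(out2$L_ex[7, others] < w$L_ex[7, others]))
  # one inhibitory synapse depressed: the others in the row grow
  L3 <- w$L_in; L3[7, 20] <- L3[7, 20] - 0.5
  out3 <- normalize_incoming(w$L_ex, L3, t_ex, t_in, basal)
  expect_equal(rowSums(out3$L_in), t_in, tolerance = 1e-12)
  expect_true(all(out3$L_in[7, -c(7, 20)] > w$L_in[7, -c(7, 20)]))
  expect_error(normalize_incoming(w$L_ex * 0, w$L_in, t_ex, t_in, basal),
               "degenerate")
})

test_that("sub-threshold training leaves synapses bit-identical", {
  stim <- list(av_stimulus("auditory", 100, 5), av_stimulus("visual", 120, 5))
  net2 <- run_training_trial(basal_net, stim, duration = 50)
  expect_identical(net2$auditory$L_ex, basal_net$auditory$L_ex)
  expect_identical(net2$auditory$L_in, basal_net$auditory$L_in)
  expect_identical(net2$visual$L_ex, basal_net$visual$L_ex)
})

test_that("training conserves incoming sums and respects bounds", {
  for (layer in c("auditory", "visual")) {
    L_ex <- trained_1a[[layer]]$L_ex
    L_in <- trained_1a[[layer]]$L_in
    expect_lt(max(abs(rowSums(L_ex) - trained_1a$target_ex) /
                    trained_1a$target_ex), 1e-6)
    expect_lt(max(abs(rowSums(L_in) - trained_1a$target_in) /
                    trained_1a$target_in), 1e-6)
    expect_true(all(L_ex >= 0 & L_ex <= basal$L_max + 1e-12))
    expect_true(all(L_in >= 0))
    expect_equal(diag(L_ex), rep(0, 180))
    expect_equal(diag(L_in), rep(0, 180))
  }
  # synapses did change
  expect_gt(max(abs(trained_1a$auditory$L_ex - basal_net$auditory$L_ex)),
            0.01)
})

test_that("disparate fixed-position training reshapes lateral input asymmetrically", {
  prof_pre <- synapse_profile(basal_net, "auditory", 120)
  prof_post <- synapse_profile(trained_1a, "auditory", 120)
  # the neuron at the trained visual position now receives net excitation
  # from distal neurons about 30 deg to its left (inhibitory before)...
  left <- prof_post$offset_deg >= -35 & prof_post$offset_deg <= -25
  expect_true(all(prof_pre$net[left] < 0))
  expect_gt(mean(prof_post$net[left]), 0)
  # ...and stronger inhibition from its right
  right <- prof_post$offset_deg >= 5 & prof_post$offset_deg <= 30
  expect_lt(mean(prof_post$net[right]), mean(prof_pre$net[right]))
})

test_that("schedules have the prescribed structure and are seed-reproducible", {
  s1a <- make_schedule("1a")
  expect_equal(nrow(s1a), 10)
  expect_true(all(s1a$p_a == 100 & s1a$p_v == 120 & s1a$duration_ms == 200))
  s1b <- make_schedule("1b")
  expect_true(all(s1b$p_a == s1b$p_v))
  s2a <- make_schedule("2a", seed = 3)
  expect_equal(nrow(s2a), 90)
  expect_equal(as.vector(table(s2a$p_a)), rep(10L, 9))
  expect_true(all(perceived_shift(s2a$p_v, s2a$p_a) == 20))
  # per-block permutations of the nine positions
  blocks <- split(s2a$p_a, rep(1:10, each = 9))
  for (b in blocks) expect_equal(sort(b), sort(seq(20, 180, 20) %% 180))
  expect_identical(make_schedule("2a", seed = 3)$p_a, s2a$p_a)
  expect_false(identical(make_schedule("2a", seed = 4)$p_a, s2a$p_a))
  # schedule generation does not disturb the global RNG stream
  set.seed(11); x1 <- runif(1)
  set.seed(11); invisible(make_schedule("2a", seed = 5)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("unimodal training produces no aftereffect", {
  sch <- data.frame(trial = 1:10, p_a = 100, p_v = NA_real_,
                    duration_ms = 200)
  net_uni <- train_network(basal_net, sch)
  for (pos in c(80, 100, 130)) {
    st <- steady(net_uni, av_stimulus("auditory", pos, 15))
    z <- decode_position(st$y_a, "vector", basal)
    expect_lt(abs(perceived_shift(z, pos)), 0.5)
  }
})

test_that("cross-modal training leaves no visual aftereffect", {
  for (pos in c(100, 120)) {
    st <- steady(trained_1a, av_stimulus("visual", pos, 15))
    z <- decode_position(st$y_v, "vector", basal)
    expect_lt(abs(perceived_shift(z, pos)), 0.5)
  }
})
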