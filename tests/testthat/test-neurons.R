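lif_group <- function(N = 1, refractory = NULL, reset = "v = v0",
                      threshold = "v > v_th") {
  g <- neuron_group(N, LIF_MODEL, threshold = threshold, reset = reset,
                    refractory = refractory,
                    namespace = list(v_th = quantity(-50, "mV")))
  assign_state(g, "v0", quantity(-70, "mV"))
  assign_state(g, "tau_m", quantity(20, "ms"))
  assign_state(g, "v", "v0")
  g
}

test_that("group creation validates the four components", {
  g <- lif_group(10)
  expect_equal(g$N, 10L)
  expect_null(g$refractory)
  expect_true(all(g$active))
  expect_true(all(g$lastspike == -Inf))

  # threshold-only group (spike recording without reset)
  rec <- neuron_group(3, LIF_MODEL, threshold = "v > v_th",
                      namespace = list(v_th = quantity(-50, "mV")))
  expect_null(rec$reset)

  # degenerate empty group: every operation is a no-op
  z <- lif_group(0)
  integration_step(z, 0, 1e-4)
  expect_length(detect_spikes(z, 0), 0)
  apply_reset(z, integer(0), 0)

  expect_error(neuron_group(1, "dv/dt = -v : volt"), "inconsistent")
  expect_error(neuron_group(1, LIF_MODEL, threshold = "v"),
               "dimensionless")
  expect_error(neuron_group(1, LIF_MODEL, reset = "v = 1*second"),
               "dimension mismatch")
  expect_error(neuron_group(1, "dA/dt = -A/tau : 1 (event-driven)
                                tau : second"), "not valid in a neuron")
})

test_that("state assignment supports quantities, expressions and indices", {
  g <- lif_group(5)
  expect_equal(g$state$v, rep(-0.07, 5))

  # i-based expression against a direct loop oracle
  pos <- neuron_group(4, "x : metre")
  assign_state(pos, "x", "i * 10*umetre")
  expect_equal(pos$state$x, (0:3) * 10e-6)

  expect_error(assign_state(g, "v", quantity(1, "second")),
               "dimension mismatch")
  expect_error(assign_state(g, "nope", 1), "unknown state")
})

test_that("random initialisation has the advertised moments", {
  g <- neuron_group(1e5, LIF_MODEL)
  assign_state(g, "v0", quantity(-70, "mV"))
  set.seed(123)
  assign_state(g, "v", "v0 + randn()*3*mV")
  se_mean <- 3e-3 / sqrt(1e5)
  expect_lt(abs(mean(g$state$v) - (-0.07)), 3 * se_mean)
  expect_lt(abs(stats::sd(g$state$v) - 3e-3), 3 * se_mean)
})

test_that("unless-refractory variables are clamped while refractory", {
  g <- neuron_group(2, "
      dv/dt = (v0 - v)/tau_m : volt
      dx/dt = -x/tau_x : 1 (unless refractory)
      v0 : volt
      tau_m : second
      tau_x : second
    ", threshold = "v > v_th", reset = "v = v0",
    refractory = "(t - lastspike) <= 2*ms",
    namespace = list(v_th = quantity(-50, "mV")))
  assign_state(g, "tau_m", quantity(20, "ms"))
  assign_state(g, "tau_x", quantity(5, "ms"))
  assign_state(g, "v0", quantity(-70, "mV"))
  assign_state(g, "v", quantity(-60, "mV"))   # away from rest so v moves
  assign_state(g, "x", 1)
  g$active[1] <- FALSE            # neuron 1 refractory, neuron 2 active
  x_before <- g$state$x
  v_before <- g$state$v
  for (k in 1:5) integration_step(g, k * 1e-4, 1e-4)
  expect_identical(g$state$x[1], x_before[1])   # bit-identical clamp
  expect_lt(g$state$x[2], x_before[2])
  expect_false(identical(g$state$v[1], v_before[1]))  # v keeps evolving
})

test_that("refractory conditions gate spiking and exit correctly", {
  g <- lif_group(1, refractory = "(t - lastspike) <= 2*ms")
  g$state$v <- -0.04                       # above threshold
  sp <- detect_spikes(g, 0)
  expect_identical(sp, 1L)
  apply_reset(g, sp, t = 0.010)            # spike at 10 ms
  expect_false(g$active[1])
  g$state$v <- -0.04                       # drive back above threshold
  # through 12.0 ms the condition (t - lastspike) <= 2 ms holds
  for (t in c(0.0105, 0.011, 0.012)) {
    refractory_exit(g, t)
    expect_length(detect_spikes(g, t), 0)
  }
  refractory_exit(g, 0.0121)
  expect_identical(detect_spikes(g, 0.0121), 1L)
})

test_that("per-neuron refractoriness and voltage-based exit work", {
  g <- neuron_group(2, "
      dv/dt = (v0 - v)/tau_m : volt
      refractoriness : second
      v0 : volt
      tau_m : second
    ", threshold = "v > v_th", reset = "v = v0",
    refractory = "(t - lastspike) <= refractoriness",
    namespace = list(v_th = quantity(-50, "mV")))
  assign_state(g, "refractoriness", c(1e-3, 5e-3))
  g$lastspike <- c(0, 0); g$active <- c(FALSE, FALSE)
  refractory_exit(g, 2e-3)
  expect_identical(g$active, c(TRUE, FALSE))
  refractory_exit(g, 6e-3)
  expect_identical(g$active, c(TRUE, TRUE))

  # HH style: refractory while still depolarized, no lastspike reference
  h <- neuron_group(1, LIF_MODEL, threshold = "v > v_th",
                    refractory = "v >= v_th",
                    namespace = list(v_th = quantity(-50, "mV")))
  h$state$v <- -0.04
  apply_reset(h, detect_spikes(h, 0), 0)
  expect_false(h$active[1])
  refractory_exit(h, 1e-4)          # still above threshold: stays refractory
  expect_false(h$active[1])
  h$state$v <- -0.06                # repolarized
  refractory_exit(h, 2e-4)
  expect_true(h$active[1])
})

test_that("adaptive thresholds compare per neuron and resets hit spikers only", {
  g <- neuron_group(3, "
      dv/dt = (v0 - v)/tau_m : volt
      dvth/dt = -(vth - vth0)/tau_th : volt
      dw/dt = -w/tau_w : amp
      v0 : volt
      vth0 : volt
      tau_m : second
      tau_th : second
      tau_w : second
    ", threshold = "v > vth", reset = "v = v0; vth += 3*mV; w += b",
    namespace = list(b = quantity(5, "pA")))
  assign_state(g, "v0", quantity(-70, "mV"))
  assign_state(g, "vth", c(-0.05, -0.05, -0.03))
  assign_state(g, "v", c(-0.04, -0.06, -0.04))
  sp <- detect_spikes(g, 0)
  expect_identical(sp, 1L)          # only neuron 1 is above ITS threshold

  vth_before <- g$state$vth; w_before <- g$state$w
  apply_reset(g, sp, 0)
  expect_equal(g$state$vth[1] - vth_before[1], 3e-3)   # exactly 3 mV
  expect_equal(g$state$vth[2:3], vth_before[2:3])
  expect_equal(g$state$w[1] - w_before[1], 5e-12)
  expect_equal(g$state$w[2:3], w_before[2:3])

  # after a standard LIF reset the spiker is below threshold again
  expect_length(detect_spikes(g, 0), 0)
  # empty spike list: no change
  st <- g$state
  apply_reset(g, integer(0), 0)
  expect_identical(g$state, st)
})

test_that("inter-spike intervals respect the refractory floor", {
  g <- neuron_group(1, "
      dv/dt = (v0 - v)/tau_m + a : volt
      v0 : volt
      tau_m : second
      a : volt/second
    ", threshold = "v > v_th", reset = "v = v0",
    refractory = "(t - lastspike) <= 2*ms",
    namespace = list(v_th = quantity(-50, "mV")))
  assign_state(g, "v0", quantity(-70, "mV"))
  assign_state(g, "tau_m", quantity(10, "ms"))
  assign_state(g, "a", quantity(100, "volt/second"))
  assign_state(g, "v", "v0")
  m <- spike_monitor(g)
  net <- network(g, m, dt = quantity(0.1, "ms"))
  run(net, quantity(0.3, "s"))
  isi <- diff(spike_records(m)$t)
  expect_gt(length(isi), 10)
  expect_true(all(isi >= 2e-3))
})

test_that("seeded runs are bit-identical", {
  run_once <- function() {
    set.seed(7)                    # covers the random initialisation too
    g <- lif_group(20)
    assign_state(g, "v", "v0 + rand()*25*mV")
    m <- spike_monitor(g)
    net <- network(g, m, dt = quantity(0.1, "ms"))
    run(net, quantity(0.05, "s"))
    spike_records(m)
  }
  expect_identical(run_once(), run_once())
})
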