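simple_pair <- function(Ns = 1, Nt = 1, pre = "g_post += w") {
  src <- neuron_group(Ns, "x : 1", name = "src")
  tgt <- holder_group(Nt, name = "tgt")
  syn <- synapses(src, tgt, eqs = "w : siemens", pre = pre)
  list(src = src, tgt = tgt, syn = syn)
}

test_that("connect realises the printed connectivity patterns", {
  # one-to-one on 5x5 groups
  p <- simple_pair(5, 5)
  expect_equal(connect(p$syn, "i == j"), 5)
  expect_equal(p$syn$i_idx, p$syn$j_idx)

  # ring of N = 6: each neuron connects to both neighbours
  r <- simple_pair(6, 6)
  expect_equal(connect(r$syn, "abs((i - j + N/2) % N - N/2) == 1"), 12)
  out_degree <- table(r$syn$i_idx)
  expect_true(all(out_degree == 2))

  # convergent pattern floor(i/N_post) == j  (4 sources per target)
  cv <- simple_pair(8, 2)
  expect_equal(connect(cv$syn, "floor(i/4) == j"), 8)
  expect_equal(as.integer(table(cv$syn$j_idx)), c(4L, 4L))

  # distance-based: only pairs within a 250 um radius
  src <- neuron_group(10, "x : metre\n y : metre", name = "src")
  tgt <- neuron_group(10, "x : metre\n y : metre\n g : siemens",
                      name = "tgt")
  set.seed(5)
  for (g in list(src, tgt)) {
    assign_state(g, "x", "rand()*1000*umetre")
    assign_state(g, "y", "rand()*1000*umetre")
  }
  syn <- synapses(src, tgt, eqs = "w : siemens", pre = "g_post += w")
  connect(syn, "sqrt((x_pre - x_post)**2 + (y_pre - y_post)**2) < 250*umetre")
  d <- sqrt((src$state$x[syn$i_idx] - tgt$state$x[syn$j_idx])^2 +
            (src$state$y[syn$i_idx] - tgt$state$y[syn$j_idx])^2)
  expect_true(all(d < 250e-6))
  # and no admissible pair is missing
  all_d <- outer(src$state$x, tgt$state$x, "-")^2 +
    outer(src$state$y, tgt$state$y, "-")^2
  expect_equal(syn$M, sum(sqrt(all_d) < 250e-6))
})

test_that("connect equals the brute-force double-loop oracle", {
  cases <- list(
    list(cond = "i == j", p = NULL, n = NULL),
    list(cond = "abs((i - j + N/2) % N - N/2) == 1", p = NULL, n = NULL),
    list(cond = "floor(i/5) == j", p = NULL, n = NULL),
    list(cond = "i != j", p = "0.3", n = NULL),
    list(cond = NULL, p = "exp(-(i - j)**2/50)", n = NULL),
    list(cond = "i != j", p = NULL, n = "1 + (i + j) % 3"),
    list(cond = "(i + j) % 2 == 0", p = "0.7", n = "2")
  )
  for (cs in cases) {
    p <- simple_pair(20, 20)
    seed <- 1000 + nchar(paste(cs$cond, cs$p, cs$n))
    set.seed(seed)
    connect(p$syn, condition = cs$cond, p = cs$p, n = cs$n)
    set.seed(seed)
    oracle <- connect_oracle(p$src, p$tgt, condition = cs$cond, p = cs$p,
                             n = cs$n)
    expect_identical(p$syn$i_idx, oracle$i,
                     label = paste("i for", cs$cond %||% "all"))
    expect_identical(p$syn$j_idx, oracle$j,
                     label = paste("j for", cs$cond %||% "all"))
  }
})

test_that("gaussian-probability connectivity with spatial variables matches the oracle", {
  src <- neuron_group(15, "x : metre\n y : metre", name = "src")
  tgt <- neuron_group(15, "x : metre\n y : metre\n g : siemens",
                      name = "tgt")
  set.seed(11)
  for (g in list(src, tgt)) {
    assign_state(g, "x", "rand()*500*umetre")
    assign_state(g, "y", "rand()*500*umetre")
  }
  syn <- synapses(src, tgt, eqs = "w : siemens", pre = "g_post += w",
                  namespace = list(p_max = 0.9))
  pexpr <- paste0("p_max*exp(-((x_pre - x_post)**2 + (y_pre - y_post)**2)",
                  "/(2*(125*umetre)**2))")
  set.seed(21)
  connect(syn, condition = "i != j", p = pexpr)
  set.seed(21)
  oracle <- connect_oracle(src, tgt, condition = "i != j", p = pexpr,
                           namespace = list(p_max = 0.9))
  expect_identical(syn$i_idx, oracle$i)
  expect_identical(syn$j_idx, oracle$j)
  expect_gt(syn$M, 0)
})

test_that("multiplicity n creates duplicate synapses with additive effect", {
  p3 <- simple_pair(3, 3)
  expect_equal(connect(p3$syn, "i == j", n = "3"), 9)
  assign_synaptic_state(p3$syn, "w", quantity(1, "nS"))
  process_pathway(p3$syn, "pre", 2L, t = 0, dt = 1e-4)
  expect_equal(p3$tgt$state$g, c(0, 3e-9, 0))   # three synapses fired

  p1 <- simple_pair(3, 3)
  connect(p1$syn, "i == j")
  assign_synaptic_state(p1$syn, "w", quantity(1, "nS"))
  process_pathway(p1$syn, "pre", 2L, t = 0, dt = 1e-4)
  expect_equal(p3$tgt$state$g[2], 3 * p1$tgt$state$g[2])
})

test_that("synaptic state assignment supports expressions over both sides", {
  src <- neuron_group(4, "x : metre", name = "src")
  tgt <- neuron_group(4, "x : metre\n g : siemens", name = "tgt")
  assign_state(src, "x", "i * 100*umetre")
  assign_state(tgt, "x", "i * 150*umetre")
  syn <- synapses(src, tgt, eqs = "w : siemens", pre = "g_post += w",
                  namespace = list(speed = "1*metre/second"))
  connect(syn)
  assign_synaptic_state(syn, "delay", "abs(x_pre - x_post)/speed")
  d_expect <- abs(src$state$x[syn$i_idx] - tgt$state$x[syn$j_idx]) / 1
  expect_equal(syn$pathways$pre$delay, d_expect)

  assign_synaptic_state(syn, "w", quantity(2, "nS"))
  expect_equal(syn$state$w, rep(2e-9, 16))
  expect_error(assign_synaptic_state(syn, "w", quantity(1, "volt")),
               "dimension mismatch")
  expect_error(assign_synaptic_state(syn, "delay", "x_pre"),
               "dimension mismatch")
  expect_error(assign_synaptic_state(syn, "w", "rand()"),
               "dimension mismatch")
})

test_that("rand() weight initialisation has mean w_max/2", {
  p <- simple_pair(100, 1000)
  connect(p$syn)
  p$syn$namespace <- eqspike:::normalize_namespace(
    list(w_max = quantity(1, "nS")))
  set.seed(41)
  assign_synaptic_state(p$syn, "w", "rand()*w_max")
  m <- mean(p$syn$state$w)
  se <- 1e-9 / sqrt(12) / sqrt(1e5)
  expect_lt(abs(m - 0.5e-9), 4 * se)
})

test_that("delays shift effects by exactly round(delay/dt) steps", {
  dt <- 1e-4
  for (delay_ms in c(0, 0.7, 1.0, 3.14)) {
    p <- simple_pair(1, 1)
    connect(p$syn)
    assign_synaptic_state(p$syn, "w", quantity(1, "nS"))
    assign_synaptic_state(p$syn, "delay", quantity(delay_ms, "ms"))
    spike_step <- 5L
    expected_step <- spike_step + round(delay_ms * 1e-3 / dt)
    hit_step <- NA
    for (step in 0:60) {
      t <- step * dt
      process_pathway(p$syn, "pre",
                      if (step == spike_step) 1L else integer(0), t, dt)
      if (is.na(hit_step) && p$tgt$state$g[1] > 0) hit_step <- step
    }
    expect_identical(hit_step, as.integer(expected_step),
                     label = paste("delay", delay_ms, "ms"))
  }
})

test_that("pre statements accumulate across due synapses and support rand()", {
  # two sources converging on one target
  src <- neuron_group(2, "x : 1", name = "src")
  tgt <- holder_group(1, name = "tgt")
  syn <- synapses(src, tgt, eqs = "w : siemens", pre = "g_post += w")
  connect(syn)
  assign_synaptic_state(syn, "w", c(1e-9, 2e-9))
  process_pathway(syn, "pre", c(1L, 2L), t = 0, dt = 1e-4)
  expect_equal(tgt$state$g, 3e-9)
})

test_that("the two-spike STDP sequence matches hand-computed traces", {
  src <- neuron_group(1, "x : 1", name = "src")
  tgt <- holder_group(1, name = "tgt")
  ns <- stdp_namespace()
  syn <- synapses(src, tgt, eqs = STDP_EQS, pre = STDP_PRE,
                  post = STDP_POST, namespace = ns)
  connect(syn)
  w0 <- 0.5e-9
  assign_synaptic_state(syn, "w", quantity(0.5, "nS"))
  dt <- 1e-4
  process_pathway(syn, "pre", 1L, t = 0.010, dt = dt)
  process_pathway(syn, "post", 1L, t = 0.020, dt = dt)
  process_pathway(syn, "pre", 1L, t = 0.030, dt = dt)

  # independent closed-form computation of the same sequence
  dApre <- 10e-12; dApost <- -10.5e-12; tau <- 20e-3
  Apre <- dApre                                   # after pre @ 10 ms
  w1 <- w0                                        # Apost still 0
  Apost <- dApost                                 # after post @ 20 ms
  w2 <- min(max(w1 + Apre * exp(-0.010/tau), 0), 1e-9)
  Apre2 <- Apre * exp(-0.020/tau) + dApre         # after pre @ 30 ms
  w3 <- min(max(w2 + Apost * exp(-0.010/tau), 0), 1e-9)
  g_expected <- w1 + w2                           # g incremented at each pre

  expect_equal(syn$state$w, w3, tolerance = 1e-12)
  expect_equal(syn$state$Apre, Apre2, tolerance = 1e-12)
  expect_equal(tgt$state$g, g_expected, tolerance = 1e-12)
})

test_that("event-driven laziness matches clock-driven trace integration", {
  make <- function(event_driven) {
    src <- neuron_group(5, "x : 1", name = "src")
    tgt <- holder_group(5, name = "tgt")
    syn <- synapses(src, tgt, eqs = STDP_EQS, pre = STDP_PRE,
                    post = STDP_POST, namespace = stdp_namespace(),
                    event_driven = event_driven)
    connect(syn)                                 # all-to-all, 25 synapses
    assign_synaptic_state(syn, "w", quantity(0.5, "nS"))
    syn
  }
  dt <- 1e-4; steps <- 20000                      # 2 s
  set.seed(17)
  pre_spikes <- lapply(seq_len(steps), function(s)
    which(stats::runif(5) < 50 * dt))             # 50 Hz Poisson per neuron
  post_spikes <- lapply(seq_len(steps), function(s)
    which(stats::runif(5) < 50 * dt))
  lazy <- make(TRUE); clock <- make(FALSE)
  for (s in seq_len(steps)) {
    t <- (s - 1) * dt
    synapse_step(clock, t, dt)
    for (syn in list(lazy, clock)) {
      process_pathway(syn, "pre", pre_spikes[[s]], t, dt)
      process_pathway(syn, "post", post_spikes[[s]], t, dt)
    }
  }
  expect_gt(sum(lengths(pre_spikes)), 100)
  expect_equal(lazy$state$w, clock$state$w, tolerance = 1e-9)
  expect_gt(stats::sd(lazy$state$w), 0)           # weights actually moved
})

test_that("summed variables overwrite the target with per-neuron sums", {
  # NMDA-style total conductance
  src <- neuron_group(4, "x : 1", name = "src")
  tgt <- neuron_group(3, "g_total : siemens", name = "tgt")
  syn <- synapses(src, tgt, eqs = "
      g_total_post = w*s : siemens (summed)
      w : siemens
      ds/dt = -s/tau_s : 1
      tau_s : second
    ", pre = "s += 1", namespace = list())
  connect(syn, "j == i % 3")
  assign_synaptic_state(syn, "tau_s", quantity(100, "ms"))
  assign_synaptic_state(syn, "w", "(1 + i)*1*nS")
  assign_synaptic_state(syn, "s", c(1, 0.5, 0.25, 0.125))
  summed_update(syn, 0)
  manual <- numeric(3)
  for (k in seq_len(syn$M)) {
    manual[syn$j_idx[k]] <- manual[syn$j_idx[k]] +
      syn$state$w[k] * syn$state$s[k]
  }
  expect_equal(tgt$state$g_total, manual)
  # conservation: neuron total equals synapse total
  expect_equal(sum(tgt$state$g_total), sum(syn$state$w * syn$state$s))

  # zero synapses: totals are zero
  empty <- synapses(src, tgt, eqs = "g_total_post = w*s : siemens (summed)
                                     w : siemens
                                     s : 1")
  summed_update(empty, 0)
  expect_equal(tgt$state$g_total, numeric(3))

  expect_error(synapses(src, tgt,
                        eqs = "q_post = w : siemens (summed)\n w : siemens"),
               "not a target-group variable")
})

test_that("gap-junction currents sum expressions over v_pre and v_post", {
  src <- neuron_group(3, "dv/dt = 0*volt/second : volt", name = "src")
  tgt <- neuron_group(2, "dv/dt = I_gap/Cm : volt
                          I_gap : amp
                          Cm : farad", name = "tgt")
  syn <- synapses(src, tgt, eqs = "
      I_gap_post = gc*(v_pre - v_post) : amp (summed)
    ", namespace = list(gc = quantity(10, "nS")))
  connect(syn)
  assign_state(src, "v", c(-0.07, -0.06, -0.05))
  assign_state(tgt, "v", c(-0.065, -0.055))
  summed_update(syn, 0)
  gc <- 10e-9
  for (jj in 1:2) {
    expect_equal(tgt$state$I_gap[jj],
                 sum(gc * (src$state$v - tgt$state$v[jj])))
  }
})

test_that("probabilistic transmission gates roughly half the spikes", {
  src <- neuron_group(1, "x : 1", name = "src")
  tgt <- holder_group(1, name = "tgt")
  syn <- synapses(src, tgt, eqs = "w : siemens",
                  pre = "g_post += int(rand() < 0.5)*w")
  connect(syn)
  assign_synaptic_state(syn, "w", quantity(1, "nS"))
  set.seed(13)
  n_spikes <- 2000L; transmitted <- 0L
  for (k in seq_len(n_spikes)) {
    before <- tgt$state$g
    process_pathway(syn, "pre", 1L, t = (k - 1) * 1e-4, dt = 1e-4)
    if (tgt$state$g != before) transmitted <- transmitted + 1L
  }
  frac <- transmitted / n_spikes
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_spikes))
})
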