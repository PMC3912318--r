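# Fixture model texts (built in code, no data files) and small oracles used
# across the test files.

# Leaky integrate-and-fire with explicit parameters (Fig-1-style).
LIF_MODEL <- "
  dv/dt = -(v - v0)/tau_m : volt
  v0 : volt
  tau_m : second
"

# Additive-noise membrane equation.
NOISY_MODEL <- "
  dv/dt = -v/tau + tau**-0.5*sigma*xi : volt
  tau : second
  sigma : volt
"

# Conductance-based model with named subexpressions (Hodgkin-Huxley-like
# current decomposition, gating dynamics omitted).
HH_CURRENTS_MODEL <- "
  dv/dt = (Il + IK + INa)/Cm : volt
  Il = gl*(El - v) : amp
  INa = gNa*(ENa - v) : amp
  IK = gK*(EK - v) : amp
  gl : siemens
  gNa : siemens
  gK : siemens
  El : volt
  ENa : volt
  EK : volt
  Cm : farad
"

# Adaptation-current model used for the scheme-application worked example.
ADAPTIVE_CURRENT_MODEL <- "
  dv/dt = (-v - w)/tau_v : volt
  dw/dt = -w/tau_w : volt
  tau_v : second
  tau_w : second
"

# Pair-based STDP in differential (event-driven) form; w_max, the trace
# increments and time constants live in the namespace.
STDP_EQS <- "
  w : siemens
  dApre/dt = -Apre/tau_pre : siemens (event-driven)
  dApost/dt = -Apost/tau_post : siemens (event-driven)
"
STDP_PRE <- "g_post += w
Apre += dApre
w = clip(w + Apost, 0*siemens, w_max)"
STDP_POST <- "Apost += dApost
w = clip(w + Apre, 0*siemens, w_max)"

stdp_namespace <- function() {
  list(tau_pre = quantity(20, "ms"), tau_post = quantity(20, "ms"),
       dApre = quantity(10, "pS"), dApost = quantity(-10.5, "pS"),
       w_max = quantity(1, "nS"))
}

# Plain state-holder groups for synapse tests.
holder_group <- function(N, eqs = "g : siemens", ...) {
  neuron_group(N, eqs, ...)
}

# Brute-force double-loop connection oracle (the independent reference for
# connect()): visits pairs in row-major order, draws one uniform per
# condition-true pair, exactly as the vectorized builder must.
connect_oracle <- function(source, target, condition = NULL, p = NULL,
                           n = NULL, namespace = list()) {
  env_base <- new.env(parent = eqspike:::runtime_base_env())
  mags <- eqspike:::namespace_magnitudes(namespace)
  for (nm in names(mags)) assign(nm, mags[[nm]], envir = env_base)
  cond_e <- if (is.null(condition)) NULL else parse_expression(condition)
  p_e <- if (is.null(p)) NULL else parse_expression(p)
  n_e <- if (is.null(n)) NULL else parse_expression(n)
  is <- integer(0); js <- integer(0)
  for (i0 in seq_len(source$N) - 1L) {
    for (j0 in seq_len(target$N) - 1L) {
      env <- new.env(parent = env_base)
      assign("i", i0, envir = env); assign("j", j0, envir = env)
      assign("N_pre", source$N, envir = env)
      assign("N_post", target$N, envir = env)
      if (source$N == target$N) assign("N", source$N, envir = env)
      for (v in names(source$state))
        assign(paste0(v, "_pre"), source$state[[v]][[i0 + 1L]], envir = env)
      for (v in names(target$state))
        assign(paste0(v, "_post"), target$state[[v]][[j0 + 1L]], envir = env)
      ok <- if (is.null(cond_e)) TRUE else isTRUE(as.logical(eval(cond_e,
                                                                  env)))
      if (!ok) next
      if (!is.null(p_e)) {
        if (!(stats::runif(1) < eval(p_e, env))) next
      }
      count <- if (is.null(n_e)) 1L else as.integer(eval(n_e, env))
      is <- c(is, rep.int(i0 + 1L, count))
      js <- c(js, rep.int(j0 + 1L, count))
    }
  }
  list(i = is, j = js)
}

# Structural + numeric comparison of two abstract code blocks: same targets
# and ops in order, right-hand sides numerically equal at random points.
expect_code_equal <- function(actual, expected_statements) {
  expect_equal(length(actual$statements), length(expected_statements))
  for (k in seq_along(expected_statements)) {
    exp_st <- expected_statements[[k]]
    act_st <- actual$statements[[k]]
    expect_identical(act_st$target, exp_st$target)
    expect_identical(act_st$op, exp_st$op)
    expect_true(expr_equal(act_st$rhs, exp_st$rhs),
                label = paste0("statement ", k, ": ",
                               render_expression(act_st$rhs), " == ",
                               render_expression(exp_st$rhs)))
  }
}
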