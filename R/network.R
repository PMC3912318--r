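## Network: the integer-step clock, the fixed per-step schedule, the run
## loop, and passive monitors. The step counter is authoritative
## (t = step*dt exactly, no drift); all randomness flows through R's global
## RNG, seeded once per run, so a fixed seed gives bit-identical results.
##
## Schedule per step, in order:
##   1. summed_update for all synapse stores
##   2. integration_step for all neuron groups, then synapse_step for all
##      stores (synaptic ODEs see this step's neuron values)
##   3. refractory_exit
##   4. detect_spikes
##   5. process_pathway for all pathways (pre before post per store;
##      zero-delay effects execute this same step)
##   6. apply_reset
##   7. record monitors
##   8. advance the clock

#' Create a network
#'
#' @param ... `eq_neurons` groups, `eq_synapses` stores and monitors (from
#'   [spike_monitor()] / [state_monitor()]), in any order.
#' @param dt Time step as an `eq_quantity` or seconds (default 0.1 ms).
#' @return An environment of class `eq_network`.
#' @export
network <- function(..., dt = quantity(0.1, "ms")) {
  parts <- list(...)
  net <- new.env(parent = emptyenv())
  class(net) <- "eq_network"
  net$groups <- Filter(function(x) inherits(x, "eq_neurons"), parts)
  net$stores <- Filter(function(x) inherits(x, "eq_synapses"), parts)
  net$monitors <- Filter(function(x) inherits(x, "eq_monitor"), parts)
  net$dt <- if (is_quantity(dt)) dt$magnitude else dt
  net$step <- 0L
  net$check_finite <- TRUE
  net
}

#' @export
print.eq_network <- function(x, ...) {
  cat("<network: ", length(x$groups), " groups, ", length(x$stores),
      " synapse stores, t = ", x$step * x$dt, " s>\n", sep = "")
  invisible(x)
}

#' Current network time in seconds
#' @param net An `eq_network`.
#' @export
network_time <- function(net) net$step * net$dt

#' Run a network
#'
#' Executes `round(duration/dt)` steps of the fixed schedule. A NaN or Inf
#' appearing in any state array aborts with a diagnostic naming the variable
#' and step (disable via `net$check_finite <- FALSE`).
#'
#' @param net An `eq_network`.
#' @param duration `eq_quantity` or seconds.
#' @param seed Optional integer; seeds R's global RNG for the run.
#' @return The network, invisibly; monitors hold the recordings.
#' @export
run <- function(net, duration, seed = NULL) {
  stopifnot(inherits(net, "eq_network"))
  if (!is.null(seed)) set.seed(seed)
  dur <- if (is_quantity(duration)) duration$magnitude else duration
  n_steps <- as.integer(round(dur / net$dt))
  dt <- net$dt
  for (k in seq_len(n_steps)) {
    t <- net$step * dt
    for (s in net$stores) summed_update(s, t)
    for (g in net$groups) integration_step(g, t, dt)
    for (s in net$stores) synapse_step(s, t, dt)
    for (g in net$groups) refractory_exit(g, t)
    spikes <- lapply(net$groups, detect_spikes, t = t)
    for (s in net$stores) {
      src_spikes <- spikes_of(net, spikes, s$source)
      tgt_spikes <- spikes_of(net, spikes, s$target)
      process_pathway(s, "pre", src_spikes, t, dt)
      process_pathway(s, "post", tgt_spikes, t, dt)
    }
    for (gi in seq_along(net$groups))
      apply_reset(net$groups[[gi]], spikes[[gi]], t)
    for (m in net$monitors) monitor_record(m, t, spikes, net)
    if (net$check_finite) {
      for (g in net$groups) {
        for (v in names(g$state)) {
          if (anyNA(g$state[[v]]) || any(is.infinite(g$state[[v]])))
            stop("non-finite value in '", v, "' of group '", g$name,
                 "' at step ", net$step, call. = FALSE)
        }
      }
    }
    net$step <- net$step + 1L
  }
  invisible(net)
}

spikes_of <- function(net, spikes, group) {
  for (gi in seq_along(net$groups)) {
    if (identical(net$groups[[gi]], group)) return(spikes[[gi]])
  }
  integer(0)
}

## ---------------------------------------------------------------------------
## Monitors (passive: they never change dynamics)

#' Record spike times and neuron indices
#' @param group An `eq_neurons`.
#' @return An `eq_monitor`; after a run, [spike_records()] returns the data.
#' @export
spike_monitor <- function(group) {
  m <- new.env(parent = emptyenv())
  class(m) <- c("eq_spike_monitor", "eq_monitor")
  m$group <- group
  m$times <- list(); m$indices <- list()
  m
}

#' Snapshot state variables every k-th step
#' @param group An `eq_neurons`.
#' @param vars Character vector of variable names.
#' @param record Neuron indices (1-based) to record, or `TRUE` for all.
#' @param every Record every `every`-th step.
#' @return An `eq_monitor`; after a run, [state_records()] returns the data.
#' @export
state_monitor <- function(group, vars, record = TRUE, every = 1L) {
  stopifnot(all(vars %in% names(group$state)))
  m <- new.env(parent = emptyenv())
  class(m) <- c("eq_state_monitor", "eq_monitor")
  m$group <- group
  m$vars <- vars
  m$record <- if (isTRUE(record)) seq_len(group$N) else as.integer(record)
  m$every <- as.integer(every)
  m$count <- 0L
  m$times <- list()
  m$values <- stats::setNames(lapply(vars, function(v) list()), vars)
  m
}

monitor_record <- function(m, t, spikes, net) {
  if (inherits(m, "eq_spike_monitor")) {
    sp <- spikes_of(net, spikes, m$group)
    if (length(sp)) {
      m$times[[length(m$times) + 1L]] <- rep(t, length(sp))
      m$indices[[length(m$indices) + 1L]] <- sp - 1L   # 0-based outside
    }
  } else if (inherits(m, "eq_state_monitor")) {
    if (m$count %% m$every == 0L) {
      m$times[[length(m$times) + 1L]] <- t
      for (v in m$vars)
        m$values[[v]][[length(m$values[[v]]) + 1L]] <-
          m$group$state[[v]][m$record]
    }
    m$count <- m$count + 1L
  }
  invisible(m)
}

#' Spike recordings as a data frame
#' @param m An `eq_spike_monitor`.
#' @return `data.frame(t, neuron)` with times in seconds (nondecreasing) and
#'   0-based neuron indices.
#' @export
spike_records <- function(m) {
  stopifnot(inherits(m, "eq_spike_monitor"))
  data.frame(t = unlist(m$times) %||% numeric(0),
             neuron = unlist(m$indices) %||% integer(0))
}

#' State recordings as a list of matrices
#' @param m An `eq_state_monitor`.
#' @return List with `t` (vector of times) and one `times x neurons` matrix
#'   per recorded variable (base SI).
#' @export
state_records <- function(m) {
  stopifnot(inherits(m, "eq_state_monitor"))
  out <- list(t = unlist(m$times) %||% numeric(0))
  for (v in m$vars) {
    vals <- m$values[[v]]
    out[[v]] <- if (length(vals))
      do.call(rbind, vals) else
      matrix(numeric(0), nrow = 0, ncol = length(m$record))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
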