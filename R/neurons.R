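## Neuron populations: per-variable state arrays plus the four-component
## model -- equations, threshold condition, reset statements, refractoriness
## condition. Objects are environment-backed (reference semantics) because a
## simulation mutates state in place.

#' Create a neuron group
#'
#' @param N Number of neurons (0 allowed; all operations become no-ops).
#' @param eqs Model description string or `eq_model`.
#' @param threshold Boolean expression string triggering spikes, or `NULL`.
#' @param reset Abstract code string executed on spiking neurons, or `NULL`.
#' @param refractory Boolean expression string; while it evaluates true for a
#'   neuron that has spiked, the neuron is refractory (it cannot spike and its
#'   `unless refractory` variables are clamped). `NULL` disables
#'   refractoriness.
#' @param method Integration scheme name or description (see [get_scheme()]).
#' @param namespace Named list of external constants (`eq_quantity`, numeric,
#'   or strings like `"20*ms"`).
#' @param name Group name used in reports.
#' @return An environment of class `eq_neurons`. State arrays are allocated
#'   at 0 (base SI); `lastspike` starts at `-Inf` so time-based refractory
#'   conditions are false before the first spike.
#' @examples
#' g <- neuron_group(10, "
#'     dv/dt = -(v - v0)/tau_m : volt
#'     v0 : volt
#'     tau_m : second
#'   ", threshold = "v > v_th",
#'   reset = "v = v0",
#'   namespace = list(v_th = quantity(-50, "mV")))
#' @export
neuron_group <- function(N, eqs, threshold = NULL, reset = NULL,
                         refractory = NULL, method = "euler",
                         namespace = list(), name = "neurons") {
  stopifnot(is.numeric(N), N >= 0)
  if (is.character(eqs)) eqs <- parse_model(eqs)
  stopifnot(inherits(eqs, "eq_model"))
  namespace <- normalize_namespace(namespace)
  for (entry in eqs$entries) {
    if (!is.na(entry$flag) && entry$flag != "unless_refractory")
      stop("flag '", entry$flag, "' is not valid in a neuron model",
           call. = FALSE)
  }
  violations <- check_equation_dimensions(eqs, namespace)
  if (length(violations))
    stop("dimensionally inconsistent model:\n  ",
         paste(vapply(violations, `[[`, character(1), "message"),
               collapse = "\n  "), call. = FALSE)

  g <- new.env(parent = emptyenv())
  class(g) <- "eq_neurons"
  g$name <- name
  g$N <- as.integer(N)
  g$eqs <- eqs
  g$namespace <- namespace
  g$state <- stats::setNames(
    lapply(state_vars(eqs), function(v) numeric(g$N)), state_vars(eqs))
  g$lastspike <- rep(-Inf, g$N)
  g$active <- rep(TRUE, g$N)
  g$assignments <- list()   # docgen: latest textual assignment per variable

  symbol_dims <- model_symbol_dims(eqs, namespace)
  resolved <- resolve_subexpressions(eqs)
  sub_map <- sub_expansion_map(resolved)

  compile_condition <- function(text, what) {
    if (is.null(text)) return(NULL)
    e <- substitute_symbols(parse_expression(text), sub_map)
    d <- dims_of_expression(e, symbol_dims)
    if (!is_dimensionless(d))
      stop(what, " condition must be dimensionless (boolean), got ",
           unit_name(d), call. = FALSE)
    e
  }
  g$threshold <- compile_condition(threshold, "threshold")
  g$refractory <- compile_condition(refractory, "refractory")
  g$reset <- if (is.null(reset)) NULL else {
    blk <- parse_statements(reset)
    blk$statements <- lapply(blk$statements, function(st) {
      st$rhs <- substitute_symbols(st$rhs, sub_map); st })
    blk <- new_code_block(blk$statements)
    check_block_dims(blk, symbol_dims, "reset")
    blk
  }
  g$scheme <- get_scheme(method)
  g$integrator <- apply_scheme(g$scheme, eqs)
  g$clamped_vars <- model_vars(eqs, kind = "differential",
                               flag = "unless_refractory")
  g
}

#' @export
print.eq_neurons <- function(x, ...) {
  cat("<neuron group '", x$name, "': ", x$N, " neurons, ",
      length(x$state), " state variables>\n", sep = "")
  invisible(x)
}

# Map subexpression name -> parenthesized resolved rhs, for inlining into
# thresholds, resets and assignments.
sub_expansion_map <- function(resolved_eqs) {
  subs <- model_vars(resolved_eqs, kind = "subexpression",
                     exclude_flag = "summed")
  out <- list()
  for (nm in subs) out[[nm]] <- call("(", resolved_eqs$entries[[nm]]$rhs)
  out
}

# Dimension-check every statement of an abstract code block against declared
# variable dimensions; temporaries take the dimension of their first rhs.
check_block_dims <- function(block, symbol_dims, what) {
  local_dims <- symbol_dims
  for (st in block$statements) {
    d <- dims_of_expression(st$rhs, local_dims)
    if (st$target %in% names(local_dims)) {
      if (!dim_eq(d, local_dims[[st$target]]))
        stop("dimension mismatch in ", what, " statement for '", st$target,
             "': ", unit_name(d), " vs ", unit_name(local_dims[[st$target]]),
             call. = FALSE)
    } else {
      local_dims[[st$target]] <- d
    }
  }
  invisible(TRUE)
}

normalize_namespace <- function(namespace) {
  lapply(namespace, function(v) {
    if (is.character(v)) {
      e <- parse_expression(v)
      d <- dims_of_expression(e, list())
      mag <- eval(e, runtime_base_env())
      quantity(mag, d)
    } else v
  })
}

#' Assign a state variable from a value or expression
#'
#' @param group An `eq_neurons`.
#' @param var Variable name.
#' @param value An `eq_quantity`, a bare numeric vector (interpreted in base
#'   SI, flagged non-symbolic in reports), or an expression string which may
#'   reference other state variables, `i` (own index, 0-based), `N`, `t`,
#'   `rand()`, `randn()` and constants.
#' @param t Current time in seconds (default 0).
#' @return The group, invisibly.
#' @examples
#' # v <- v0 + 3 mV of Gaussian spread:
#' # assign_state(g, "v", "v0 + randn()*3*mV")
#' @export
assign_state <- function(group, var, value, t = 0) {
  stopifnot(inherits(group, "eq_neurons"))
  if (!var %in% names(group$state))
    stop("unknown state variable '", var, "'", call. = FALSE)
  symbol_dims <- model_symbol_dims(group$eqs, group$namespace)
  target_dim <- group$eqs$entries[[var]]$unit
  if (is_quantity(value)) {
    if (!dim_eq(value$dim, target_dim))
      stop("dimension mismatch assigning '", var, "': ",
           unit_name(value$dim), " vs ", unit_name(target_dim),
           call. = FALSE)
    group$state[[var]] <- rep_len(value$magnitude, group$N)
    group$assignments[[var]] <- list(kind = "quantity", value = value)
  } else if (is.character(value)) {
    resolved <- resolve_subexpressions(group$eqs)
    e <- substitute_symbols(parse_expression(value),
                            sub_expansion_map(resolved))
    d <- dims_of_expression(e, symbol_dims)
    if (!dim_eq(d, target_dim))
      stop("dimension mismatch assigning '", var, "': ", unit_name(d),
           " vs ", unit_name(target_dim), call. = FALSE)
    blk <- new_code_block(list(new_statement(var, "=", e)))
    group$state <- execute_block(blk, group$state, seq_len(group$N),
                                 group$N, group$namespace,
                                 scalars = list(t = t, N = group$N,
                                                i = seq_len(group$N) - 1,
                                                lastspike = group$lastspike))
    group$assignments[[var]] <- list(kind = "expression", text = value)
  } else if (is.numeric(value)) {
    group$state[[var]] <- rep_len(value, group$N)
    group$assignments[[var]] <- list(kind = "array",
                                     value = rep_len(value, group$N))
  } else stop("unsupported value type for assign_state", call. = FALSE)
  invisible(group)
}

#' Read a state variable as a quantity
#' @param group An `eq_neurons`.
#' @param var Variable name.
#' @return An `eq_quantity` holding the array (base SI).
#' @export
get_state <- function(group, var) {
  if (!var %in% names(group$state))
    stop("unknown state variable '", var, "'", call. = FALSE)
  quantity(group$state[[var]], group$eqs$entries[[var]]$unit)
}

#' Advance the continuous dynamics by one time step
#'
#' Executes the precompiled integrator code over all neurons; variables
#' flagged `unless refractory` keep their previous value in refractory
#' neurons (the dx/dt = 0 clamp).
#'
#' @param group An `eq_neurons`.
#' @param t Current time (seconds).
#' @param dt Time step (seconds).
#' @export
integration_step <- function(group, t, dt) {
  if (group$N == 0L || !length(group$integrator$statements))
    return(invisible(group))
  clamped <- NULL
  inactive <- which(!group$active)
  if (length(group$clamped_vars) && length(inactive)) {
    clamped <- lapply(group$state[group$clamped_vars], `[`, inactive)
  }
  group$state <- execute_block(group$integrator, group$state,
                               seq_len(group$N), group$N, group$namespace,
                               scalars = list(t = t, dt = dt, N = group$N,
                                              i = seq_len(group$N) - 1,
                                              lastspike = group$lastspike))
  if (!is.null(clamped)) {
    for (v in group$clamped_vars)
      group$state[[v]][inactive] <- clamped[[v]]
  }
  invisible(group)
}

# Evaluate a boolean condition over a subset of neurons.
eval_condition <- function(group, expr, subset, t) {
  n <- length(subset)
  if (n == 0L) return(logical(0))
  env <- new.env(parent = runtime_base_env())
  mags <- namespace_magnitudes(group$namespace)
  for (nm in names(mags)) assign(nm, mags[[nm]], envir = env)
  for (nm in names(group$state))
    assign(nm, group$state[[nm]][subset], envir = env)
  assign("t", t, envir = env)
  assign("lastspike", group$lastspike[subset], envir = env)
  assign("i", subset - 1, envir = env)
  assign("N", group$N, envir = env)
  assign("rand", function() stats::runif(n), envir = env)
  assign("randn", function() stats::rnorm(n), envir = env)
  val <- eval(expr, env)
  as.logical(rep_len(val, n))
}

#' Move refractory neurons back to the active state
#'
#' Re-evaluates the refractoriness condition for every inactive neuron; a
#' false condition releases the neuron.
#'
#' @param group An `eq_neurons`.
#' @param t Current time (seconds).
#' @export
refractory_exit <- function(group, t) {
  if (is.null(group$refractory)) return(invisible(group))
  inactive <- which(!group$active)
  if (!length(inactive)) return(invisible(group))
  still <- eval_condition(group, group$refractory, inactive, t)
  group$active[inactive[!still]] <- TRUE
  invisible(group)
}

#' Detect spiking neurons
#'
#' @param group An `eq_neurons`.
#' @param t Current time (seconds).
#' @return Integer vector of 1-based indices of active neurons whose
#'   threshold condition is true. Refractory neurons never spike.
#' @export
detect_spikes <- function(group, t) {
  if (is.null(group$threshold) || group$N == 0L) return(integer(0))
  active <- which(group$active)
  if (!length(active)) return(integer(0))
  hit <- eval_condition(group, group$threshold, active, t)
  active[hit]
}

#' Apply reset statements to spiking neurons
#'
#' Executes the reset block on the spiking subset, records `lastspike`, and
#' (when a refractoriness condition exists) moves the spikers to the
#' refractory state.
#'
#' @param group An `eq_neurons`.
#' @param spikes Integer vector from [detect_spikes()].
#' @param t Current time (seconds).
#' @export
apply_reset <- function(group, spikes, t) {
  if (!length(spikes)) return(invisible(group))
  if (!is.null(group$reset)) {
    group$state <- execute_block(group$reset, group$state,
                                 as.integer(spikes), length(spikes),
                                 group$namespace,
                                 scalars = list(t = t, N = group$N,
                                                i = as.integer(spikes) - 1,
                                                lastspike =
                                                  group$lastspike[spikes]))
  }
  group$lastspike[spikes] <- t
  if (!is.null(group$refractory)) group$active[spikes] <- FALSE
  invisible(group)
}
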