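## Synapse populations: expression-driven construction, per-synapse state
## with pre/post pathways and transmission delays (discretized to the time
## grid), event-driven linear variables with lazy closed-form updates,
## summed variables copied into post-synaptic state each step, and
## probabilistic transmission via rand() in pathway statements.

new_spike_queue <- function() {
  q <- new.env(parent = emptyenv())
  q$pending <- list()
  q
}

queue_push <- function(q, step, ids) {
  if (!length(ids)) return(invisible(q))
  key <- as.character(step)
  q$pending[[key]] <- c(q$pending[[key]], ids)
  invisible(q)
}

queue_pop <- function(q, step) {
  key <- as.character(step)
  ids <- q$pending[[key]]
  if (!is.null(ids)) q$pending[[key]] <- NULL
  if (is.null(ids)) integer(0) else sort(as.integer(ids))
}

#' Create a synapse store
#'
#' @param source,target `eq_neurons` groups (may be the same group).
#' @param eqs Synaptic model description string or `eq_model` (may be empty).
#'   Differential entries flagged `(event-driven)` must be independent linear
#'   equations; subexpressions flagged `(summed)` must be named `VAR_post`
#'   with `VAR` a target-group variable.
#' @param pre,post Abstract code strings executed on pre-/post-synaptic
#'   spikes. Suffixes `_pre`/`_post` address neuron variables of the source
#'   and target group.
#' @param namespace Named list of external constants.
#' @param method Scheme for non-event-driven synaptic differential equations.
#' @param event_driven If `FALSE`, variables flagged `(event-driven)` are
#'   instead updated every timestep with the same closed-form solution
#'   (clock-driven mode; used to validate the lazy updates).
#' @param name Store name.
#' @return An environment of class `eq_synapses` with zero synapses; call
#'   [connect()] to create them.
#' @export
synapses <- function(source, target, eqs = "", pre = NULL, post = NULL,
                     namespace = list(), method = "euler",
                     event_driven = TRUE, name = "synapses") {
  stopifnot(inherits(source, "eq_neurons"), inherits(target, "eq_neurons"))
  if (is.character(eqs)) {
    eqs <- if (nzchar(trimws(eqs))) parse_model(eqs) else
      structure(list(entries = list()), class = "eq_model")
  }
  namespace <- normalize_namespace(namespace)

  syn <- new.env(parent = emptyenv())
  class(syn) <- "eq_synapses"
  syn$name <- name
  syn$source <- source
  syn$target <- target
  syn$eqs <- eqs
  syn$namespace <- namespace
  syn$M <- 0L
  syn$i_idx <- integer(0)     # 1-based source indices
  syn$j_idx <- integer(0)     # 1-based target indices
  syn$state <- stats::setNames(
    lapply(state_vars(eqs), function(v) numeric(0)), state_vars(eqs))
  syn$lastupdate <- numeric(0)
  syn$event_driven_mode <- isTRUE(event_driven)
  syn$assignments <- list()

  # dimension context: synaptic entries + suffixed neuron variables
  extra_dims <- suffixed_dims(source, target)
  violations <- check_equation_dimensions(eqs, namespace, extra_dims)
  if (length(violations))
    stop("dimensionally inconsistent synaptic model:\n  ",
         paste(vapply(violations, `[[`, character(1), "message"),
               collapse = "\n  "), call. = FALSE)
  symbol_dims <- c(model_symbol_dims(eqs, namespace), extra_dims)

  # summed entries: VAR_post must name a target variable of equal dimension
  syn$summed <- list()
  for (nm in model_vars(eqs, kind = "subexpression", flag = "summed")) {
    tgt_var <- sub("_post$", "", nm)
    if (!tgt_var %in% names(target$state))
      stop("summed variable '", nm, "': '", tgt_var,
           "' is not a target-group variable", call. = FALSE)
    if (!dim_eq(eqs$entries[[nm]]$unit, target$eqs$entries[[tgt_var]]$unit))
      stop("summed variable '", nm, "' has dimension ",
           unit_name(eqs$entries[[nm]]$unit), " but target '", tgt_var,
           "' has ", unit_name(target$eqs$entries[[tgt_var]]$unit),
           call. = FALSE)
    syn$summed[[tgt_var]] <- eqs$entries[[nm]]$rhs
  }

  ed_updates <- event_driven_updates(eqs)
  ed_block_statements <- list()
  for (v in names(ed_updates)) {
    if (is.symbol(ed_updates[[v]]) &&
        identical(as.character(ed_updates[[v]]), v)) next  # no-op
    ed_block_statements[[length(ed_block_statements) + 1L]] <-
      new_statement(v, "=", ed_updates[[v]])
  }
  syn$ed_updates <- ed_updates
  maintain_lastupdate <- length(ed_updates) > 0L

  compile_pathway <- function(code_text) {
    if (is.null(code_text)) return(NULL)
    user <- parse_statements(code_text)
    check_block_dims(user, c(symbol_dims,
                             list(lastupdate = dimension(s = 1))),
                     "pathway")
    stmts <- user$statements
    if (syn$event_driven_mode) stmts <- c(ed_block_statements, stmts)
    if (maintain_lastupdate)
      stmts <- c(stmts, list(new_statement("lastupdate", "=",
                                           as.name("t"))))
    new_code_block(stmts)
  }
  syn$pathways <- list()
  if (!is.null(pre))
    syn$pathways$pre <- list(direction = "pre",
                             statements = compile_pathway(pre),
                             source_text = pre,
                             delay = numeric(0), queue = new_spike_queue())
  if (!is.null(post))
    syn$pathways$post <- list(direction = "post",
                              statements = compile_pathway(post),
                              source_text = post,
                              delay = numeric(0), queue = new_spike_queue())

  # per-step machinery: integrator for plain differential entries, and the
  # closed-form block for clock-driven mode
  syn$integrator <- apply_scheme(get_scheme(method), eqs)
  syn$clock_block <- if (!syn$event_driven_mode && length(ed_updates)) {
    new_code_block(c(ed_block_statements,
                     list(new_statement("lastupdate", "=", as.name("t")))))
  } else NULL
  syn
}

#' @export
print.eq_synapses <- function(x, ...) {
  cat("<synapses '", x$name, "': ", x$M, " synapses, ",
      x$source$name, " -> ", x$target$name, ">\n", sep = "")
  invisible(x)
}

suffixed_dims <- function(source, target) {
  out <- list()
  for (v in names(source$state))
    out[[paste0(v, "_pre")]] <- source$eqs$entries[[v]]$unit
  for (v in names(target$state))
    out[[paste0(v, "_post")]] <- target$eqs$entries[[v]]$unit
  out
}

## ---------------------------------------------------------------------------
## Connection building

# Environment for connectivity/assignment expressions at fixed pre index i
# (0-based scalar) over all candidate targets j (0-based vector).
connect_env <- function(syn, i0, n_j) {
  env <- new.env(parent = runtime_base_env())
  mags <- namespace_magnitudes(syn$namespace)
  for (nm in names(mags)) assign(nm, mags[[nm]], envir = env)
  src <- syn$source; tgt <- syn$target
  for (v in names(src$state))
    assign(paste0(v, "_pre"), src$state[[v]][[i0 + 1L]], envir = env)
  for (v in names(tgt$state))
    assign(paste0(v, "_post"), tgt$state[[v]], envir = env)
  assign("i", i0, envir = env)
  assign("j", seq_len(n_j) - 1, envir = env)
  assign("N_pre", src$N, envir = env)
  assign("N_post", tgt$N, envir = env)
  if (src$N == tgt$N) assign("N", src$N, envir = env)
  assign("rand", function() stats::runif(n_j), envir = env)
  assign("randn", function() stats::rnorm(n_j), envir = env)
  env
}

#' Create synapses from condition / probability / multiplicity expressions
#'
#' Visits all (i, j) pairs in row-major order (i outer, j inner). A pair is
#' admitted when `condition` is true (or always, if `NULL`); if `p` is given
#' a uniform draw decides creation (`u < p`, one draw per condition-true
#' pair, in visit order); `n` synapses are created per admitted pair
#' (default 1). New synapses start with state 0, `lastupdate = t`, delay 0.
#'
#' @param syn An `eq_synapses`.
#' @param condition Boolean expression string over `i`, `j`, `N_pre`,
#'   `N_post`, `N` (when the groups have equal size), `_pre`/`_post`
#'   variables and constants; `NULL` admits all pairs.
#' @param p Probability expression (dimensionless, in `[0, 1]`), or `NULL`.
#' @param n Synapse-count expression (positive integer-valued), or `NULL`.
#' @param t Creation time in seconds.
#' @return The number of synapses created, invisibly the store is updated.
#' @examples
#' # one-to-one:    connect(syn, "i == j")
#' # ring of N:     connect(syn, "abs((i - j + N/2) % N - N/2) == 1")
#' @export
connect <- function(syn, condition = NULL, p = NULL, n = NULL, t = 0) {
  stopifnot(inherits(syn, "eq_synapses"))
  cond_e <- if (is.null(condition)) NULL else parse_expression(condition)
  p_e <- if (is.null(p)) NULL else
    (if (is.numeric(p)) p else parse_expression(p))
  n_e <- if (is.null(n)) NULL else
    (if (is.numeric(n)) n else parse_expression(n))
  Np <- syn$source$N; Nq <- syn$target$N
  new_i <- integer(0); new_j <- integer(0)
  for (i0 in seq_len(Np) - 1L) {
    env <- connect_env(syn, i0, Nq)
    keep <- if (is.null(cond_e)) rep(TRUE, Nq) else
      as.logical(rep_len(eval(cond_e, env), Nq))
    js <- which(keep)          # 1-based candidate targets, ascending
    if (!length(js)) next
    if (!is.null(p_e)) {
      pv <- if (is.numeric(p_e)) rep(p_e, Nq) else
        rep_len(eval(p_e, env), Nq)
      pv <- pv[js]
      if (any(pv < 0 | pv > 1))
        stop("connection probability outside [0, 1]", call. = FALSE)
      u <- stats::runif(length(js))
      js <- js[u < pv]
      if (!length(js)) next
    }
    counts <- if (is.null(n_e)) rep(1L, length(js)) else {
      nv <- if (is.numeric(n_e)) rep(n_e, Nq) else rep_len(eval(n_e, env), Nq)
      nv <- nv[js]
      if (any(nv != round(nv)) || any(nv < 1))
        stop("synapse multiplicity n must be a positive integer",
             call. = FALSE)
      as.integer(nv)
    }
    new_i <- c(new_i, rep.int(i0 + 1L, sum(counts)))
    new_j <- c(new_j, rep.int(js, counts))
  }
  created <- length(new_i)
  if (created) {
    syn$i_idx <- c(syn$i_idx, new_i)
    syn$j_idx <- c(syn$j_idx, new_j)
    syn$M <- length(syn$i_idx)
    for (v in names(syn$state))
      syn$state[[v]] <- c(syn$state[[v]], numeric(created))
    syn$lastupdate <- c(syn$lastupdate, rep(t, created))
    for (pw in names(syn$pathways))
      syn$pathways[[pw]]$delay <- c(syn$pathways[[pw]]$delay,
                                    numeric(created))
  }
  created
}

## ---------------------------------------------------------------------------
## State assignment

# arrays + per-variable index maps for executing a block over synapses `ids`.
syn_execution_context <- function(syn, block, ids) {
  arrays <- list(); index <- list()
  used <- union(block$read_set, block$write_set)
  for (v in names(syn$state)) {
    arrays[[v]] <- syn$state[[v]]; index[[v]] <- ids
  }
  arrays$lastupdate <- syn$lastupdate; index$lastupdate <- ids
  src <- syn$source; tgt <- syn$target
  for (nm in used) {
    if (grepl("_pre$", nm)) {
      base <- sub("_pre$", "", nm)
      if (base %in% names(src$state)) {
        arrays[[nm]] <- src$state[[base]]
        index[[nm]] <- syn$i_idx[ids]
      }
    } else if (grepl("_post$", nm)) {
      base <- sub("_post$", "", nm)
      if (base %in% names(tgt$state)) {
        arrays[[nm]] <- tgt$state[[base]]
        index[[nm]] <- syn$j_idx[ids]
      }
    }
  }
  list(arrays = arrays, index = index)
}

syn_execute <- function(syn, block, ids, t, dt) {
  if (!length(ids) || !length(block$statements)) return(invisible(syn))
  ctx <- syn_execution_context(syn, block, ids)
  out <- execute_block(block, ctx$arrays, ctx$index, length(ids),
                       syn$namespace,
                       scalars = list(t = t, dt = dt,
                                      i = syn$i_idx[ids] - 1,
                                      j = syn$j_idx[ids] - 1,
                                      N_pre = syn$source$N,
                                      N_post = syn$target$N))
  for (nm in names(out)) {
    if (nm %in% names(syn$state)) syn$state[[nm]] <- out[[nm]]
    else if (nm == "lastupdate") syn$lastupdate <- out[[nm]]
    else if (grepl("_pre$", nm))
      syn$source$state[[sub("_pre$", "", nm)]] <- out[[nm]]
    else if (grepl("_post$", nm))
      syn$target$state[[sub("_post$", "", nm)]] <- out[[nm]]
  }
  invisible(syn)
}

#' Assign a synaptic state variable or delay
#'
#' @param syn An `eq_synapses`.
#' @param var A synaptic variable name, `"delay"` (pre-pathway delay) or
#'   `"delay_post"` (post-pathway delay).
#' @param value `eq_quantity`, numeric vector (base SI), or expression string
#'   over synaptic variables, `i`, `j`, `_pre`/`_post` variables and
#'   constants.
#' @param t Current time (seconds).
#' @export
assign_synaptic_state <- function(syn, var, value, t = 0) {
  stopifnot(inherits(syn, "eq_synapses"))
  is_delay <- var %in% c("delay", "delay_post")
  pathway <- if (identical(var, "delay")) "pre" else
    if (identical(var, "delay_post")) "post" else NULL
  if (is_delay && is.null(syn$pathways[[pathway]]))
    stop("no ", pathway, " pathway to set delays on", call. = FALSE)
  if (!is_delay && !var %in% names(syn$state))
    stop("unknown synaptic variable '", var, "'", call. = FALSE)
  target_dim <- if (is_delay) dimension(s = 1) else
    syn$eqs$entries[[var]]$unit
  record <- NULL
  if (is_quantity(value)) {
    if (!dim_eq(value$dim, target_dim))
      stop("dimension mismatch assigning '", var, "'", call. = FALSE)
    vals <- rep_len(value$magnitude, syn$M)
    record <- list(kind = "quantity", value = value)
  } else if (is.numeric(value)) {
    vals <- rep_len(value, syn$M)
    record <- list(kind = "array", value = vals)
  } else if (is.character(value)) {
    e <- parse_expression(value)
    d <- dims_of_expression(e, c(model_symbol_dims(syn$eqs, syn$namespace),
                                 suffixed_dims(syn$source, syn$target)))
    if (!dim_eq(d, target_dim))
      stop("dimension mismatch assigning '", var, "': ", unit_name(d),
           " vs ", unit_name(target_dim), call. = FALSE)
    tmp_target <- if (is_delay) "_delay_tmp" else var
    blk <- new_code_block(list(new_statement(tmp_target, "=", e)))
    if (is_delay) {
      ctx <- syn_execution_context(syn, blk, seq_len(syn$M))
      ctx$arrays[["_delay_tmp"]] <- numeric(syn$M)
      ctx$index[["_delay_tmp"]] <- seq_len(syn$M)
      out <- execute_block(blk, ctx$arrays, ctx$index, syn$M, syn$namespace,
                           scalars = list(t = t, i = syn$i_idx - 1,
                                          j = syn$j_idx - 1,
                                          N_pre = syn$source$N,
                                          N_post = syn$target$N))
      vals <- out[["_delay_tmp"]]
    } else {
      syn_execute(syn, blk, seq_len(syn$M), t, dt = NA_real_)
      vals <- NULL
    }
    record <- list(kind = "expression", text = value)
  } else stop("unsupported value type", call. = FALSE)
  if (!is.null(vals)) {
    if (is_delay) {
      if (any(vals < 0)) stop("delays must be non-negative", call. = FALSE)
      syn$pathways[[pathway]]$delay <- vals
    } else {
      syn$state[[var]] <- vals
    }
  }
  syn$assignments[[var]] <- record
  invisible(syn)
}

## ---------------------------------------------------------------------------
## Event processing

#' Process one pathway for one time step
#'
#' Enqueues this step's spikes of the trigger group (source for `pre`,
#' target for `post`) at `due step = step + round(delay/dt)` and executes all
#' effects due this step: event-driven variable updates first, then the
#' pathway statements, then `lastupdate = t`. Must be called every step to
#' flush delayed effects.
#'
#' @param syn An `eq_synapses`.
#' @param direction `"pre"` or `"post"`.
#' @param spikes Integer vector of 1-based trigger-group indices that spiked
#'   this step.
#' @param t Current time (seconds).
#' @param dt Time step (seconds).
#' @export
process_pathway <- function(syn, direction, spikes, t, dt) {
  pw <- syn$pathways[[direction]]
  if (is.null(pw)) return(invisible(syn))
  step <- as.integer(round(t / dt))
  if (length(spikes) && syn$M) {
    trigger_idx <- if (direction == "pre") syn$i_idx else syn$j_idx
    ids <- which(trigger_idx %in% spikes)
    if (length(ids)) {
      due <- step + as.integer(round(pw$delay[ids] / dt))
      for (d in unique(due))
        queue_push(pw$queue, d, ids[due == d])
    }
  }
  due_ids <- queue_pop(pw$queue, step)
  if (length(due_ids))
    syn_execute(syn, pw$statements, due_ids, t, dt)
  invisible(syn)
}

#' Per-step continuous update of synaptic state
#'
#' Integrates non-event-driven synaptic differential equations with the
#' store's scheme; in clock-driven mode additionally applies the closed-form
#' update of the event-driven variables every step.
#'
#' @param syn An `eq_synapses`.
#' @param t Current time (seconds).
#' @param dt Time step (seconds).
#' @export
synapse_step <- function(syn, t, dt) {
  if (!syn$M) return(invisible(syn))
  if (!is.null(syn$clock_block))
    syn_execute(syn, syn$clock_block, seq_len(syn$M), t, dt)
  if (length(syn$integrator$statements))
    syn_execute(syn, syn$integrator, seq_len(syn$M), t, dt)
  invisible(syn)
}

#' Copy summed synaptic expressions into post-synaptic variables
#'
#' For every synaptic subexpression `VAR_post = expr : U (summed)`, the
#' target variable `VAR` is overwritten with the per-target-neuron sum of
#' `expr` over the converging synapses; neurons without synapses get 0.
#'
#' @param syn An `eq_synapses`.
#' @param t Current time (seconds).
#' @export
summed_update <- function(syn, t) {
  if (!length(syn$summed)) return(invisible(syn))
  tgt <- syn$target
  for (tgt_var in names(syn$summed)) {
    total <- numeric(tgt$N)
    if (syn$M) {
      expr <- syn$summed[[tgt_var]]
      env <- new.env(parent = runtime_base_env())
      mags <- namespace_magnitudes(syn$namespace)
      for (nm in names(mags)) assign(nm, mags[[nm]], envir = env)
      for (v in names(syn$state)) assign(v, syn$state[[v]], envir = env)
      src <- syn$source
      for (v in names(src$state))
        assign(paste0(v, "_pre"), src$state[[v]][syn$i_idx], envir = env)
      for (v in names(tgt$state))
        assign(paste0(v, "_post"), tgt$state[[v]][syn$j_idx], envir = env)
      assign("i", syn$i_idx - 1, envir = env)
      assign("j", syn$j_idx - 1, envir = env)
      assign("t", t, envir = env)
      vals <- rep_len(eval(expr, env), syn$M)
      agg <- rowsum(vals, group = syn$j_idx)
      total[as.integer(rownames(agg))] <- agg[, 1L]
    }
    tgt$state[[tgt_var]] <- total
  }
  invisible(syn)
}
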