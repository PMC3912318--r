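## Model files and the command-line entry point. A model file is UTF-8 text
## with sections:
##
##   [neurons NAME]            one neuron group
##   [synapses NAME SRC TGT]   one synapse store between named groups
##   [run]                     simulation settings
##
## Keys inside a section are `key = value` lines (value is the rest of the
## line; statements may contain further `=`). `equations:` opens an indented
## block holding the model description. `const NAME = EXPR` declares a
## namespace constant (units allowed); `set NAME = EXPR` assigns a state
## variable. Neuron keys: N, threshold, reset, refractory, method. Synapse
## keys: pre, post, connect (condition), p, n, method, clock_driven.
## Run keys: duration, dt, seed.

#' Parse a model file
#' @param path File path.
#' @return A nested list of sections (internal format consumed by
#'   [build_network_from_file()]).
#' @export
parse_model_file <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sections <- list()
  current <- NULL
  block_key <- NULL
  k <- 0L
  flush <- function() {
    if (!is.null(current)) sections[[length(sections) + 1L]] <<- current
  }
  for (raw in lines) {
    k <- k + 1L
    line <- sub("#.*$", "", raw)
    if (!nzchar(trimws(line))) next
    indented <- grepl("^[ \t]", line)
    if (!is.null(block_key) && indented) {
      current[[block_key]] <- paste0(current[[block_key]], trimws(line), "\n")
      next
    }
    block_key <- NULL
    line <- trimws(line)
    m <- regmatches(line, regexec(
      "^\\[\\s*(neurons|synapses|run)\\s*([^]]*)\\]$", line))[[1L]]
    if (length(m)) {
      flush()
      words <- strsplit(trimws(m[[3L]]), "\\s+")[[1L]]
      current <- list(type = m[[2L]],
                      name = if (length(words)) words[[1L]] else m[[2L]],
                      args = if (length(words) > 1L) words[-1L]
                             else character(0),
                      const = list(), set = list())
      next
    }
    if (is.null(current))
      stop("line ", k, ": content before first section header", call. = FALSE)
    if (grepl("^(equations|reset|pre|post):\\s*$", line)) {
      block_key <- sub(":\\s*$", "", line)
      current[[block_key]] <- ""
      next
    }
    m <- regmatches(line, regexec(
      "^const\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", line))[[1L]]
    if (length(m)) { current$const[[m[[2L]]]] <- m[[3L]]; next }
    m <- regmatches(line, regexec(
      "^set\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", line))[[1L]]
    if (length(m)) {
      current$set[[length(current$set) + 1L]] <-
        list(var = m[[2L]], value = m[[3L]])
      next
    }
    m <- regmatches(line, regexec(
      "^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", line))[[1L]]
    if (length(m)) { current[[m[[2L]]]] <- m[[3L]]; next }
    stop("line ", k, ": cannot parse '", line, "'", call. = FALSE)
  }
  flush()
  sections
}

eval_scalar_setting <- function(text) {
  e <- parse_expression(text)
  d <- dims_of_expression(e, list())
  quantity(eval(e, runtime_base_env()), d)
}

#' Build a network from a parsed model file
#' @param sections Output of [parse_model_file()].
#' @return List with `net` (an `eq_network`), `groups`, `stores`,
#'   `spike_monitors`, `state_monitors` and `settings` (duration, dt, seed).
#' @export
build_network_from_file <- function(sections) {
  groups <- list(); stores <- list()
  settings <- list(duration = quantity(1, "s"), dt = quantity(0.1, "ms"),
                   seed = NULL)
  for (sec in sections) {
    if (sec$type == "neurons") {
      ns <- lapply(sec$const, function(txt) eval_scalar_setting(txt))
      g <- neuron_group(
        N = as.integer(sec[["N"]] %||% 1L),
        eqs = sec[["equations"]] %||% stop("section [neurons ", sec$name,
                                      "]: missing equations",
                                      call. = FALSE),
        threshold = sec[["threshold"]], reset = sec[["reset"]],
        refractory = sec[["refractory"]],
        method = sec[["method"]] %||% "euler",
        namespace = ns, name = sec$name)
      for (s in sec$set) assign_state(g, s$var, s$value)
      groups[[sec$name]] <- g
    } else if (sec$type == "synapses") {
      if (length(sec$args) != 2L)
        stop("[synapses ", sec$name, "] needs source and target names",
             call. = FALSE)
      src <- groups[[sec$args[[1L]]]]; tgt <- groups[[sec$args[[2L]]]]
      if (is.null(src) || is.null(tgt))
        stop("[synapses ", sec$name, "]: unknown group", call. = FALSE)
      ns <- lapply(sec$const, function(txt) eval_scalar_setting(txt))
      s <- synapses(src, tgt, eqs = sec[["equations"]] %||% "",
                    pre = sec[["pre"]], post = sec[["post"]], namespace = ns,
                    method = sec[["method"]] %||% "euler",
                    event_driven = !isTRUE(as.logical(sec[["clock_driven"]]
                                                      %||% "FALSE")),
                    name = sec$name)
      connect(s, condition = sec[["connect"]], p = sec[["p"]], n = sec[["n"]])
      for (st in sec$set) assign_synaptic_state(s, st$var, st$value)
      stores[[sec$name]] <- s
    } else if (sec$type == "run") {
      if (!is.null(sec[["duration"]]))
        settings$duration <- eval_scalar_setting(sec[["duration"]])
      if (!is.null(sec[["dt"]])) settings$dt <- eval_scalar_setting(sec[["dt"]])
      if (!is.null(sec[["seed"]])) settings$seed <- as.integer(sec[["seed"]])
    }
  }
  spike_mons <- lapply(groups, spike_monitor)
  net <- do.call(network, c(unname(groups), unname(stores),
                            unname(spike_mons),
                            list(dt = settings$dt)))
  list(net = net, groups = groups, stores = stores,
       spike_monitors = spike_mons, settings = settings)
}

#' Run a model file and collect spikes
#'
#' @param path Model file path.
#' @param duration,dt,seed Optional overrides of the file's `[run]` section
#'   (`eq_quantity`, seconds, or setting strings like `"0.5*second"`).
#' @return List with `spikes` (data frame `t`, `group`, `neuron`), `groups`
#'   and `stores`.
#' @export
run_model_file <- function(path, duration = NULL, dt = NULL, seed = NULL) {
  sections <- parse_model_file(path)
  if (!is.null(dt)) {
    for (k in seq_along(sections)) {
      if (sections[[k]]$type == "run")
        sections[[k]]$dt <- NULL
    }
  }
  built <- build_network_from_file(sections)
  if (!is.null(dt)) {
    built$net$dt <- if (is.character(dt)) eval_scalar_setting(dt)$magnitude
      else if (is_quantity(dt)) dt$magnitude else dt
  }
  dur <- if (is.null(duration)) built$settings$duration
    else if (is.character(duration)) eval_scalar_setting(duration)
    else duration
  seed <- if (is.null(seed)) built$settings$seed else as.integer(seed)
  run(built$net, dur, seed = seed)
  sp <- do.call(rbind, lapply(names(built$spike_monitors), function(nm) {
    df <- spike_records(built$spike_monitors[[nm]])
    if (nrow(df)) cbind(df, group = nm) else
      data.frame(t = numeric(0), neuron = integer(0), group = character(0))
  }))
  list(spikes = sp[, c("t", "group", "neuron")], groups = built$groups,
       stores = built$stores)
}

#' Command-line interface
#'
#' `eqspike_cli(c("run", FILE, "--duration", "1*second", "--dt", "0.1*ms",
#' "--seed", "42", "--spikes", "out.csv", "--dump-code", "DIR"))` simulates a
#' model file; `eqspike_cli(c("document", FILE, "--format", "latex", "-o",
#' "report.tex"))` writes the automatic model documentation.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the result of the underlying operation.
#' @export
eqspike_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: eqspike run|document MODELFILE [options]",
                          call. = FALSE)
  cmd <- args[[1L]]; rest <- args[-1L]
  opt <- list(positional = character(0))
  k <- 1L
  while (k <= length(rest)) {
    a <- rest[[k]]
    if (grepl("^--", a) || a == "-o") {
      key <- sub("^--?", "", a)
      opt[[key]] <- rest[[k + 1L]]; k <- k + 2L
    } else {
      opt$positional <- c(opt$positional, a); k <- k + 1L
    }
  }
  if (!length(opt$positional)) stop("missing MODELFILE", call. = FALSE)
  path <- opt$positional[[1L]]
  if (cmd == "run") {
    res <- run_model_file(path, duration = opt$duration, dt = opt$dt,
                          seed = if (!is.null(opt$seed))
                            as.integer(opt$seed))
    if (!is.null(opt$spikes))
      utils::write.csv(res$spikes, opt$spikes, row.names = FALSE)
    if (!is.null(opt$states)) {
      states <- do.call(rbind, lapply(res$groups, function(g) {
        do.call(rbind, lapply(names(g$state), function(v)
          data.frame(group = g$name, variable = v,
                     neuron = seq_len(g$N) - 1L, value = g$state[[v]])))
      }))
      utils::write.csv(states, opt$states, row.names = FALSE)
    }
    if (!is.null(opt[["dump-code"]])) {
      dir.create(opt[["dump-code"]], showWarnings = FALSE, recursive = TRUE)
      for (g in res$groups) {
        for (dialect in c("vectorized", "loop")) {
          writeLines(render_loop_source(g$integrator, dialect,
                                        state_vars = names(g$state)),
                     file.path(opt[["dump-code"]],
                               paste0(g$name, "_update_", dialect, ".txt")))
        }
      }
    }
    return(invisible(res))
  }
  if (cmd == "document") {
    sections <- parse_model_file(path)
    built <- build_network_from_file(sections)
    fmt <- opt$format %||% "text"
    out_lines <- character(0)
    for (obj in c(built$groups, built$stores)) {
      rep_ <- model_report(obj)
      out_lines <- c(out_lines, paste0("% ", rep_$name))
      out_lines <- c(out_lines,
        if (fmt == "latex") paste0("$", rep_$latex, "$") else rep_$text,
        unlist(rep_$assignments), "")
    }
    if (!is.null(opt$o)) writeLines(out_lines, opt$o)
    else cat(out_lines, sep = "\n")
    return(invisible(out_lines))
  }
  stop("unknown command '", cmd, "'", call. = FALSE)
}
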