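## Integration schemes: textual descriptions of explicit integrators over a
## generic state vector x, combined symbolically with model equations into
## abstract code. Each scheme statement is expanded componentwise over the
## state variables: x maps to the variable, temporaries map to per-variable
## fresh names (`_k_v`), x_new maps to `_y_v`, and f(A, B) expands to the
## drift of the variable with every state symbol u replaced by the
## u-component of A and t replaced by B. For stochastic schemes g(A, B)*dW
## expands additively over the noise processes, with one fresh normal draw of
## standard deviation sqrt(dt) per process per step, shared across variables
## that reference the same process.

#' Parse an integration-scheme description
#'
#' Each line reads `NAME = EXPR`; expressions may use `x`, `t`, `dt`,
#' `f(EXPR, EXPR)`, `g(EXPR, EXPR)`, `dW` and previously defined temporary
#' names. Exactly one statement must assign `x_new`, and it must be last.
#'
#' @param text Scheme description string.
#' @return An object of class `eq_scheme` with `statements` (list of
#'   `list(target, rhs)`) and `is_stochastic`.
#' @examples
#' parse_scheme("x_new = x + dt*f(x,t)")
#' @export
parse_scheme <- function(text) {
  lines <- trimws(sub("#.*$", "", strsplit(text, "\n", fixed = TRUE)[[1L]]))
  lines <- lines[nzchar(lines)]
  re <- "^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$"
  statements <- list()
  temps <- character(0)
  stochastic <- FALSE
  for (line in lines) {
    m <- regmatches(line, regexec(re, line))[[1L]]
    if (!length(m))
      stop("cannot parse scheme line '", line, "'", call. = FALSE)
    target <- m[[2L]]
    rhs <- parse_expression(m[[3L]])
    ids <- setdiff(expr_identifiers(rhs), c("f", "g"))
    unknown <- setdiff(ids, c("x", "t", "dt", "dW", temps))
    if ("x_new" %in% unknown || "x_prev" %in% unknown)
      stop("schemes may not reference '", intersect(unknown,
           c("x_new", "x_prev"))[[1L]],
           "' on a right-hand side (implicit/multistep methods are not ",
           "supported)", call. = FALSE)
    if (length(unknown))
      stop("unknown symbol '", unknown[[1L]], "' in scheme line '", line, "'",
           call. = FALSE)
    if ("dW" %in% ids || "g" %in% expr_called_functions(rhs))
      stochastic <- TRUE
    statements[[length(statements) + 1L]] <- list(target = target, rhs = rhs)
    if (target != "x_new") temps <- c(temps, target)
  }
  targets <- vapply(statements, `[[`, character(1), "target")
  if (sum(targets == "x_new") != 1L || targets[[length(targets)]] != "x_new")
    stop("a scheme must assign x_new exactly once, as its last statement",
         call. = FALSE)
  structure(list(statements = statements, is_stochastic = stochastic),
            class = "eq_scheme")
}

# Built-in schemes, selectable by name.
BUILTIN_SCHEME_TEXT <- c(
  euler = "x_new = x + dt*f(x,t)",
  midpoint = "k = dt*f(x,t)\nx_new = x + dt*f(x + k/2, t + dt/2)",
  euler_maruyama = "x_new = x + dt*f(x,t) + g(x,t)*dW"
)

#' Retrieve a scheme by name or parse a description
#' @param method A scheme name (`"euler"`, `"midpoint"`, `"euler_maruyama"`),
#'   a scheme description string, or an `eq_scheme`.
#' @return An `eq_scheme`.
#' @export
get_scheme <- function(method) {
  if (inherits(method, "eq_scheme")) return(method)
  stopifnot(is.character(method), length(method) == 1L)
  if (method %in% names(BUILTIN_SCHEME_TEXT))
    return(parse_scheme(BUILTIN_SCHEME_TEXT[[method]]))
  parse_scheme(method)
}

#' Combine a scheme with model equations into abstract code
#'
#' Implements the componentwise scheme-application algorithm: every scheme
#' statement is expanded once per state variable with fresh per-variable
#' temporaries (`_k_<var>`, `_y_<var>` for `x_new`), followed by copy-back
#' statements `var = _y_<var>`. For stochastic models the drift/diffusion
#' split must succeed and every diffusion factor must be state-independent
#' (additive noise); each noise process contributes one draw
#' `_dW_<xi> = randn()*sqrt(dt)` per step, shared across variables.
#'
#' @param scheme An `eq_scheme`, or a name accepted by [get_scheme()].
#' @param eqs An `eq_model`.
#' @return An `eq_code` block.
#' @examples
#' eqs <- parse_model("
#'   dv/dt = -(v - v0)/tau : volt
#'   v0 : volt
#'   tau : second
#' ")
#' apply_scheme("euler", eqs)
#' @export
apply_scheme <- function(scheme, eqs) {
  scheme <- get_scheme(scheme)
  eqs <- resolve_subexpressions(eqs)
  vars <- model_vars(eqs, kind = "differential",
                     exclude_flag = "event_driven")
  if (!length(vars)) return(new_code_block(list()))

  dd <- split_drift_diffusion(eqs)
  f <- dd$f[vars]
  g <- dd$g[vars]
  xi_names <- sort(unique(unlist(lapply(g, names))))
  if (length(xi_names) && !scheme$is_stochastic)
    stop("model is stochastic but scheme '", "'",
         " has no diffusion term; use euler_maruyama", call. = FALSE)
  # additive-noise restriction: diffusion factors must be state-independent
  for (v in vars) {
    for (xi in names(g[[v]])) {
      bad <- intersect(expr_identifiers(g[[v]][[xi]]), vars)
      if (length(bad))
        stop("state-dependent diffusion factor for '", v,
             "' (depends on '", bad[[1L]],
             "'); only additive noise is supported", call. = FALSE)
    }
  }

  temp_names <- setdiff(vapply(scheme$statements, `[[`, character(1),
                               "target"), "x_new")
  fresh <- function(base, v) paste0("_", base, "_", v)

  # component v of expression A over {x, temps, t, dt}
  component <- function(e, v) {
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (nm == "x") return(as.name(v))
      if (nm %in% temp_names) return(as.name(fresh(nm, v)))
      return(e)
    }
    if (!is.call(e)) return(e)
    head <- if (is.symbol(e[[1L]])) as.character(e[[1L]]) else ""
    if (head == "f") {
      A <- e[[2L]]; B <- e[[3L]]
      map <- lapply(stats::setNames(vars, vars),
                    function(u) call("(", component(A, u)))
      map[["t"]] <- call("(", component(B, v))
      return(call("(", substitute_symbols(f[[v]], map)))
    }
    if (head == "g")
      stop("g() may only appear multiplied by dW", call. = FALSE)
    # g(A,B)*dW or dW*g(A,B): expand additively over noise processes
    if (head == "*" && length(e) == 3L) {
      parts <- list(e[[2L]], e[[3L]])
      is_g <- vapply(parts, function(p) is.call(p) && is.symbol(p[[1L]]) &&
                       as.character(p[[1L]]) == "g", logical(1))
      is_dW <- vapply(parts, function(p) is.symbol(p) &&
                        as.character(p) == "dW", logical(1))
      if (any(is_g) && any(is_dW)) {
        gcall <- parts[[which(is_g)]]
        A <- gcall[[2L]]; B <- gcall[[3L]]
        total <- NULL
        for (xi in xi_names) {
          gexpr <- g[[v]][[xi]]
          if (is.null(gexpr)) next
          map <- lapply(stats::setNames(vars, vars),
                        function(u) call("(", component(A, u)))
          map[["t"]] <- call("(", component(B, v))
          term <- call("*", call("(", substitute_symbols(gexpr, map)),
                       as.name(paste0("_dW_", xi)))
          total <- if (is.null(total)) term else call("+", total, term)
        }
        return(if (is.null(total)) 0 else total)
      }
    }
    for (k in seq_along(e)) if (k > 1L) e[[k]] <- component(e[[k]], v)
    e
  }

  statements <- list()
  if (scheme$is_stochastic) {
    for (xi in xi_names) {
      statements[[length(statements) + 1L]] <-
        new_statement(paste0("_dW_", xi), "=",
                      parse_expression("randn()*sqrt(dt)"))
    }
  }
  for (sigma in scheme$statements) {
    for (v in vars) {
      target <- if (sigma$target == "x_new") fresh("y", v)
        else fresh(sigma$target, v)
      statements[[length(statements) + 1L]] <-
        new_statement(target, "=", simplify_expr(component(sigma$rhs, v)))
    }
  }
  for (v in vars) {
    statements[[length(statements) + 1L]] <-
      new_statement(v, "=", as.name(fresh("y", v)))
  }
  new_code_block(statements)
}

#' Closed-form event-driven updates for linear synaptic equations
#'
#' For every differential entry flagged `(event-driven)` with right-hand side
#' `a * x` (a state-independent), returns the exact update
#' `x <- x * exp(a * (t - lastupdate))` to be applied lazily at spike times.
#'
#' @param eqs An `eq_model`.
#' @return Named list variable -> update expression (language object).
#' @examples
#' eqs <- parse_model(
#'   "dA/dt = -A/tau_pre : 1 (event-driven)\n tau_pre : second")
#' event_driven_updates(eqs)
#' @export
event_driven_updates <- function(eqs) {
  updates <- list()
  ed_vars <- model_vars(eqs, kind = "differential", flag = "event_driven")
  diff_vars <- model_vars(eqs, kind = "differential")
  for (v in ed_vars) {
    rhs <- eqs$entries[[v]]$rhs
    a <- tryCatch(linear_coeff(rhs, v), error = function(e)
      stop("event-driven equation for '", v, "' is not linear: ",
           conditionMessage(e), call. = FALSE))
    # rhs must be exactly a*v: substituting v -> 0 must leave nothing
    residual <- simplify_expr(substitute_symbols(rhs,
                                                 stats::setNames(list(0), v)))
    if (!identical(num_value(residual), 0))
      stop("event-driven equation for '", v,
           "' must have the form a*", v, call. = FALSE)
    bad <- intersect(expr_identifiers(a), diff_vars)
    if (length(bad))
      stop("event-driven equations must be independent; coefficient of '",
           v, "' depends on '", bad[[1L]], "'", call. = FALSE)
    if (identical(num_value(a), 0)) {
      updates[[v]] <- as.name(v)        # da/dt = 0: no-op
    } else {
      updates[[v]] <- call("*", as.name(v),
                           call("exp", call("*", call("(", a),
                                call("(", call("-", as.name("t"),
                                               as.name("lastupdate"))))))
    }
  }
  updates
}
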