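## Model equations: parsing multi-line model description strings into an
## ordered, validated set of entries (differential equations, named
## subexpressions, parameters), each with a unit annotation and optional flag.
##
## Line grammar (one entry per logical line; `#` starts a comment; a line
## ending inside unbalanced parentheses continues on the next):
##   dNAME/dt = EXPR : UNIT [(FLAG)]
##   NAME = EXPR : UNIT [(FLAG)]
##   NAME : UNIT [(FLAG)]
## Flags: `unless refractory` (differential, neuronal), `event-driven`
## (differential, synaptic), `summed` (subexpression, synaptic).

RESERVED_NAMES <- c("t", "dt", "i", "j", "N", "N_pre", "N_post",
                    "lastspike", "lastupdate", "dW", "x_new",
                    EXPR_FUNCTIONS)

FLAG_CANON <- c("unless refractory" = "unless_refractory",
                "unless-refractory" = "unless_refractory",
                "unless_refractory" = "unless_refractory",
                "event-driven" = "event_driven",
                "event_driven" = "event_driven",
                "summed" = "summed")

#' Parse a multi-line model description
#'
#' @param text Model description string; see the package vignette for the
#'   grammar.
#' @return An object of class `eq_model` with an ordered named list `entries`;
#'   each entry has `name`, `kind` (`"differential"`, `"subexpression"` or
#'   `"parameter"`), `rhs` (language object or `NULL`), `unit`
#'   (`eq_dimension`), `unit_text`, `flag` (canonical flag name or `NA`), and
#'   `stochastic` (character vector of xi identifiers in the rhs).
#' @examples
#' eqs <- parse_model("
#'   dv/dt = -(v - v0)/tau_m : volt
#'   v0 : volt
#'   tau_m : second
#' ")
#' names(eqs$entries)
#' @export
parse_model <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  # strip comments, join continuation lines (unbalanced parentheses)
  logical_lines <- character(0); line_nos <- integer(0)
  buffer <- ""; buffer_start <- 0L
  paren_balance <- function(s) {
    chars <- strsplit(s, "")[[1L]]
    sum(chars == "(") - sum(chars == ")")
  }
  for (ln in seq_along(raw)) {
    s <- sub("#.*$", "", raw[[ln]])
    if (!nzchar(trimws(s)) && !nzchar(buffer)) next
    if (!nzchar(buffer)) buffer_start <- ln
    buffer <- if (nzchar(buffer)) paste(buffer, trimws(s)) else trimws(s)
    if (paren_balance(buffer) > 0L) next
    if (nzchar(trimws(buffer))) {
      logical_lines <- c(logical_lines, buffer)
      line_nos <- c(line_nos, buffer_start)
    }
    buffer <- ""
  }
  if (nzchar(trimws(buffer)))
    stop("unbalanced parentheses at end of model description", call. = FALSE)

  entries <- list()
  ident <- "[A-Za-z][A-Za-z0-9_]*"
  re_diff  <- paste0("^d(", ident, ")\\s*/\\s*dt\\s*=\\s*(.*?)\\s*:\\s*(.+)$")
  re_sub   <- paste0("^(", ident, ")\\s*=\\s*(.*?)\\s*:\\s*(.+)$")
  re_param <- paste0("^(", ident, ")\\s*:\\s*(.+)$")

  split_unit_flag <- function(tail, lineno) {
    m <- regmatches(tail, regexec("^(.*?)\\s*\\(([^()]+)\\)\\s*$", tail))[[1L]]
    if (length(m)) {
      flag_raw <- trimws(m[[3L]])
      if (!flag_raw %in% names(FLAG_CANON))
        stop("line ", lineno, ": unknown flag '", flag_raw, "'", call. = FALSE)
      list(unit = trimws(m[[2L]]), flag = FLAG_CANON[[flag_raw]])
    } else {
      list(unit = trimws(tail), flag = NA_character_)
    }
  }

  for (k in seq_along(logical_lines)) {
    line <- logical_lines[[k]]; lineno <- line_nos[[k]]
    entry <- NULL
    m <- regmatches(line, regexec(re_diff, line))[[1L]]
    if (length(m)) {
      uf <- split_unit_flag(m[[4L]], lineno)
      entry <- list(name = m[[2L]], kind = "differential",
                    rhs = parse_expression(m[[3L]]),
                    unit_text = uf$unit, flag = uf$flag)
    } else {
      m <- regmatches(line, regexec(re_sub, line))[[1L]]
      if (length(m)) {
        uf <- split_unit_flag(m[[4L]], lineno)
        entry <- list(name = m[[2L]], kind = "subexpression",
                      rhs = parse_expression(m[[3L]]),
                      unit_text = uf$unit, flag = uf$flag)
      } else {
        m <- regmatches(line, regexec(re_param, line))[[1L]]
        if (length(m)) {
          uf <- split_unit_flag(m[[3L]], lineno)
          if (!is.na(uf$flag))
            stop("line ", lineno, ": flags are not allowed on parameters",
                 call. = FALSE)
          entry <- list(name = m[[2L]], kind = "parameter", rhs = NULL,
                        unit_text = uf$unit, flag = NA_character_)
        }
      }
    }
    if (is.null(entry))
      stop("line ", lineno, ": cannot parse '", line, "'", call. = FALSE)
    if (entry$name %in% RESERVED_NAMES || is_xi_name(entry$name))
      stop("line ", lineno, ": '", entry$name, "' is a reserved name",
           call. = FALSE)
    if (entry$name %in% names(entries))
      stop("line ", lineno, ": duplicate definition of '", entry$name, "'",
           call. = FALSE)
    entry$unit <- parse_unit(entry$unit_text)$dim
    entry$stochastic <- if (is.null(entry$rhs)) character(0) else
      Filter(is_xi_name, expr_identifiers(entry$rhs))
    # flag / kind compatibility
    if (!is.na(entry$flag)) {
      if (entry$flag %in% c("unless_refractory", "event_driven") &&
          entry$kind != "differential")
        stop("line ", lineno, ": flag only valid on differential equations",
             call. = FALSE)
      if (entry$flag == "summed") {
        if (entry$kind != "subexpression")
          stop("line ", lineno, ": (summed) only valid on subexpressions",
               call. = FALSE)
        if (!grepl("_post$", entry$name))
          stop("line ", lineno,
               ": (summed) targets must be named 'VAR_post'", call. = FALSE)
      }
    }
    if (length(entry$stochastic) && entry$kind != "differential")
      stop("line ", lineno, ": xi only allowed in differential equations",
           call. = FALSE)
    entries[[entry$name]] <- entry
  }
  structure(list(entries = entries), class = "eq_model")
}

#' @export
print.eq_model <- function(x, ...) {
  cat(render_model(x))
  invisible(x)
}

#' Render a model back to its textual form
#' @param eqs An `eq_model`.
#' @return A single string reparsable by [parse_model()].
#' @export
render_model <- function(eqs) {
  lines <- vapply(eqs$entries, function(entry) {
    flag_txt <- if (!is.na(entry$flag)) {
      canon <- c(unless_refractory = "unless refractory",
                 event_driven = "event-driven", summed = "summed")
      paste0(" (", canon[[entry$flag]], ")")
    } else ""
    switch(entry$kind,
      differential = paste0("d", entry$name, "/dt = ",
                            render_expression(entry$rhs), " : ",
                            entry$unit_text, flag_txt),
      subexpression = paste0(entry$name, " = ", render_expression(entry$rhs),
                             " : ", entry$unit_text, flag_txt),
      parameter = paste0(entry$name, " : ", entry$unit_text))
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

# Entry names by kind helpers
model_vars <- function(eqs, kind = NULL, flag = NULL, exclude_flag = NULL) {
  keep <- vapply(eqs$entries, function(entry) {
    ok <- TRUE
    if (!is.null(kind)) ok <- ok && entry$kind %in% kind
    if (!is.null(flag)) ok <- ok && identical(entry$flag, flag)
    if (!is.null(exclude_flag))
      ok <- ok && !identical(entry$flag, exclude_flag)
    ok
  }, logical(1))
  names(eqs$entries)[keep]
}

# State variables: everything that gets a per-instance array.
state_vars <- function(eqs) model_vars(eqs, kind = c("differential",
                                                     "parameter"))

#' Substitute named subexpressions into the differential equations
#'
#' Every non-summed subexpression is inlined into all right-hand sides that
#' reference it (including other subexpressions). The inlined subexpression
#' entries are kept in the model so that thresholds and resets can still
#' refer to them.
#'
#' @param eqs An `eq_model`.
#' @return An `eq_model` whose differential right-hand sides contain no
#'   non-summed subexpression names.
#' @export
resolve_subexpressions <- function(eqs) {
  subs <- model_vars(eqs, kind = "subexpression", exclude_flag = "summed")
  if (!length(subs)) return(eqs)
  # topological order via repeated substitution; detect cycles first
  deps <- lapply(subs, function(nm)
    intersect(expr_identifiers(eqs$entries[[nm]]$rhs), subs))
  names(deps) <- subs
  order <- character(0); pending <- subs
  while (length(pending)) {
    ready <- pending[vapply(pending, function(nm)
      all(deps[[nm]] %in% order), logical(1))]
    if (!length(ready)) {
      stop("cyclic subexpressions: ", paste(pending, collapse = " -> "),
           call. = FALSE)
    }
    order <- c(order, ready)
    pending <- setdiff(pending, ready)
  }
  resolved <- list()
  for (nm in order) {
    rhs <- eqs$entries[[nm]]$rhs
    rhs <- substitute_symbols(rhs, resolved)
    # parenthesize to preserve precedence when inlined
    resolved[[nm]] <- call("(", rhs)
  }
  for (nm in names(eqs$entries)) {
    entry <- eqs$entries[[nm]]
    if (is.null(entry$rhs)) next
    if (entry$kind == "subexpression" && nm %in% order) {
      eqs$entries[[nm]]$rhs <- resolved[[nm]][[2L]]
    } else {
      eqs$entries[[nm]]$rhs <- substitute_symbols(entry$rhs, resolved)
    }
  }
  eqs
}

#' Split stochastic equations into drift and diffusion parts
#'
#' Each differential right-hand side must be affine in every noise symbol
#' `xi`, `xi_1`, ...: `rhs = f + sum_k g_k * xi_k`. Returns the deterministic
#' drift `f` per variable and the diffusion factor `g` per (variable, noise
#' process) pair.
#'
#' @param eqs An `eq_model` (subexpressions need not be resolved; they are
#'   resolved internally).
#' @return A list with `f` (named list variable -> expression) and `g`
#'   (named list variable -> named list xi-name -> expression).
#' @examples
#' eqs <- parse_model("
#'   dv/dt = -v/tau + tau**-0.5*sigma*xi : volt
#'   tau : second
#'   sigma : volt
#' ")
#' split_drift_diffusion(eqs)$g$v$xi
#' @export
split_drift_diffusion <- function(eqs) {
  eqs <- resolve_subexpressions(eqs)
  f <- list(); g <- list()
  for (entry in eqs$entries) {
    if (entry$kind != "differential") next
    rhs <- entry$rhs
    xis <- sort(Filter(is_xi_name, expr_identifiers(rhs)))
    gs <- list()
    for (xi in xis) {
      coef <- tryCatch(linear_coeff(rhs, xi), error = function(e)
        stop("unsupported noise term in equation for '", entry$name, "': ",
             conditionMessage(e), call. = FALSE))
      if (any(vapply(c(coef), function(x)
            any(is_xi_name(expr_identifiers(x))), logical(1))))
        stop("unsupported noise term in equation for '", entry$name,
             "': diffusion factor depends on xi", call. = FALSE)
      gs[[xi]] <- coef
    }
    drift <- rhs
    if (length(xis)) {
      zero_map <- stats::setNames(rep(list(0), length(xis)), xis)
      drift <- simplify_expr(substitute_symbols(rhs, zero_map))
    }
    f[[entry$name]] <- drift
    g[[entry$name]] <- gs
  }
  list(f = f, g = g)
}
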