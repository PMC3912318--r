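## Automatic model documentation: LaTeX and plain-text renderings of model
## equations, event strings and state-variable assignments, regenerated from
## the model objects themselves so the report can never drift out of sync.

GREEK_NAMES <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
                 "theta", "iota", "kappa", "lambda", "mu", "nu", "xi", "pi",
                 "rho", "sigma", "tau", "upsilon", "phi", "chi", "psi",
                 "omega")

# tau_m -> \tau_{m}; v0 -> v_{0}; sigma -> \sigma; plain names unchanged.
latex_identifier <- function(nm) {
  main <- nm; sub <- NULL
  if (grepl("_", nm)) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1L]]
    main <- parts[[1L]]
    sub <- paste(parts[-1L], collapse = "\\_")
  } else if (grepl("^[A-Za-z]+[0-9]+$", nm)) {
    main <- sub("[0-9]+$", "", nm)
    sub <- sub("^[A-Za-z]+", "", nm)
  }
  if (main %in% GREEK_NAMES) main <- paste0("\\", main)
  if (is.null(sub)) main else paste0(main, "_{", sub, "}")
}

latex_precedence <- c("|" = 1, "&" = 2, "==" = 3, "!=" = 3, "<" = 3,
                      ">" = 3, "<=" = 3, ">=" = 3, "+" = 4, "-" = 4,
                      "*" = 5, "/" = 5, "%%" = 5, "^" = 6)

expr_to_latex <- function(e, parent_prec = 0) {
  wrap <- function(txt, prec) {
    if (prec < parent_prec) paste0("\\left(", txt, "\\right)") else txt
  }
  if (is_number(e)) return(format(as.numeric(e)))
  if (is.symbol(e)) return(latex_identifier(as.character(e)))
  if (!is.call(e)) return(deparse(e))
  op <- if (is.symbol(e[[1L]])) as.character(e[[1L]]) else ""
  args <- as.list(e)[-1L]
  if (op == "(") return(expr_to_latex(args[[1L]], parent_prec))
  if (op == "/" && length(args) == 2L)
    return(paste0("\\frac{", expr_to_latex(args[[1L]]), "}{",
                  expr_to_latex(args[[2L]]), "}"))
  if (op == "^") {
    base <- expr_to_latex(args[[1L]], 7)
    return(paste0("{", base, "}^{", expr_to_latex(args[[2L]]), "}"))
  }
  if (op %in% c("+", "-") && length(args) == 1L)
    return(wrap(paste0(op, expr_to_latex(args[[1L]], 5)), 4))
  if (op %in% c("+", "-"))
    return(wrap(paste0(expr_to_latex(args[[1L]], 4), " ", op, " ",
                       expr_to_latex(args[[2L]], 4.5)), 4))
  if (op == "*")
    return(wrap(paste0(expr_to_latex(args[[1L]], 5), " \\cdot ",
                       expr_to_latex(args[[2L]], 5)), 5))
  if (op == "%%")
    return(wrap(paste0(expr_to_latex(args[[1L]], 5), " \\bmod ",
                       expr_to_latex(args[[2L]], 5)), 5))
  if (op %in% c("<", ">", "==", "!=", "<=", ">=")) {
    sym <- c("<" = "<", ">" = ">", "==" = "=", "!=" = "\\neq",
             "<=" = "\\leq", ">=" = "\\geq")[[op]]
    return(wrap(paste0(expr_to_latex(args[[1L]], 3), " ", sym, " ",
                       expr_to_latex(args[[2L]], 3)), 3))
  }
  if (op == "&")
    return(wrap(paste0(expr_to_latex(args[[1L]], 2), " \\wedge ",
                       expr_to_latex(args[[2L]], 2)), 2))
  if (op == "|")
    return(wrap(paste0(expr_to_latex(args[[1L]], 1), " \\vee ",
                       expr_to_latex(args[[2L]], 1)), 1))
  if (op == "!")
    return(paste0("\\neg ", expr_to_latex(args[[1L]], 6)))
  if (op == "sqrt")
    return(paste0("\\sqrt{", expr_to_latex(args[[1L]]), "}"))
  if (op == "abs")
    return(paste0("\\left|", expr_to_latex(args[[1L]]), "\\right|"))
  if (op == "exp" && length(args) == 1L)
    return(paste0("e^{", expr_to_latex(args[[1L]]), "}"))
  if (op == "rand") return("\\mathcal{U}(0, 1)")
  if (op == "randn") return("\\mathcal{N}(0, 1)")
  # generic function call
  paste0("\\operatorname{", op, "}\\left(",
         paste(vapply(args, expr_to_latex, character(1)), collapse = ", "),
         "\\right)")
}

#' Render model equations as LaTeX lines
#'
#' Differential entries render as `\frac{dVAR}{dt} = RHS` with a
#' `\text{(unit: U)}` annotation; subexpressions and parameters render
#' analogously. Greek-letter identifiers map to Greek glyphs.
#'
#' @param eqs An `eq_model`.
#' @return Character vector, one LaTeX line (math-mode content) per entry.
#' @examples
#' eqs <- parse_model("dgs/dt = -gs/tau_s : siemens\n tau_s : second")
#' equations_to_latex(eqs)[1]
#' @export
equations_to_latex <- function(eqs) {
  stopifnot(inherits(eqs, "eq_model"))
  vapply(eqs$entries, function(entry) {
    u <- unit_name(entry$unit)
    ann <- paste0("\\quad\\text{(unit: ", u, ")}")
    switch(entry$kind,
      differential = paste0("\\frac{d", latex_identifier(entry$name),
                            "}{dt} = ", expr_to_latex(entry$rhs), ann),
      subexpression = paste0(latex_identifier(entry$name), " = ",
                             expr_to_latex(entry$rhs), ann),
      parameter = paste0(latex_identifier(entry$name), ann))
  }, character(1), USE.NAMES = FALSE)
}

# Render an assignment expression for humans: randn() -> N(0, 1),
# rand() -> U(0, 1), literal*unit products as "20 ms".
describe_expr <- function(e) {
  if (is_number(e)) return(format(as.numeric(e)))
  if (is.symbol(e)) return(as.character(e))
  if (!is.call(e)) return(deparse(e))
  op <- if (is.symbol(e[[1L]])) as.character(e[[1L]]) else ""
  args <- as.list(e)[-1L]
  if (op == "(") return(paste0("(", describe_expr(args[[1L]]), ")"))
  if (op == "rand") return("U(0, 1)")
  if (op == "randn") return("N(0, 1)")
  if (op == "*" && length(args) == 2L) {
    lhs <- args[[1L]]; rhs <- args[[2L]]
    if (is.symbol(rhs) && is_unit_name(as.character(rhs)))
      return(paste(describe_expr(lhs), as.character(rhs)))
    # "5 ms N(0, 1)", not "5 ms * N(0, 1)"
    if (is.call(rhs) && is.symbol(rhs[[1L]]) &&
        as.character(rhs[[1L]]) %in% c("rand", "randn"))
      return(paste(describe_expr(lhs), describe_expr(rhs)))
    return(paste(describe_expr(lhs), "*", describe_expr(rhs)))
  }
  if (op %in% c("+", "-", "/", "^", "%%", "<", ">", "<=", ">=", "==",
                "!=") && length(args) == 2L) {
    opt <- if (op == "^") "**" else if (op == "%%") "%" else op
    return(paste(describe_expr(args[[1L]]), opt, describe_expr(args[[2L]])))
  }
  if (op %in% c("+", "-") && length(args) == 1L)
    return(paste0(op, describe_expr(args[[1L]])))
  paste0(op, "(", paste(vapply(args, describe_expr, character(1)),
                        collapse = ", "), ")")
}

#' Human-readable description of a state assignment
#'
#' @param var Variable name.
#' @param source The recorded assignment: an `eq_quantity`, an expression
#'   string, or a numeric array (which yields summary statistics, flagged
#'   non-symbolic).
#' @return A single character string such as `"tau_m = 20 ms + 5 ms N(0, 1)"`.
#' @export
describe_assignment <- function(var, source) {
  if (is_quantity(source))
    return(paste(var, "=", format_quantity(source)))
  if (is.character(source))
    return(paste(var, "=", describe_expr(parse_expression(source))))
  if (is.numeric(source)) {
    return(sprintf(
      "%s = <array of %d values: min %.6g, max %.6g, mean %.6g, sd %.6g> (non-symbolic)",
      var, length(source), min(source), max(source), mean(source),
      stats::sd(source)))
  }
  stop("unsupported assignment source", call. = FALSE)
}

#' Generate a model report for a group or synapse store
#'
#' @param obj An `eq_neurons` or `eq_synapses`.
#' @return An object of class `eq_report`: list with `latex` (character
#'   vector of equation lines), `text` (plain-text equation lines), `events`
#'   (threshold/reset/refractory or pre/post strings), `assignments`
#'   (descriptions via [describe_assignment()]) and `parameters` (data frame
#'   of namespace constants).
#' @export
model_report <- function(obj) {
  stopifnot(inherits(obj, "eq_neurons") || inherits(obj, "eq_synapses"))
  eqs <- obj$eqs
  text_lines <- if (length(eqs$entries))
    strsplit(render_model(eqs), "\n")[[1L]] else character(0)
  events <- list()
  if (inherits(obj, "eq_neurons")) {
    if (!is.null(obj$threshold))
      events$threshold <- render_expression(obj$threshold)
    if (!is.null(obj$reset)) events$reset <- render_statements(obj$reset)
    if (!is.null(obj$refractory))
      events$refractory <- render_expression(obj$refractory)
  } else {
    for (pw in names(obj$pathways))
      events[[pw]] <- obj$pathways[[pw]]$source_text
  }
  assignments <- character(0)
  for (v in names(obj$assignments)) {
    rec <- obj$assignments[[v]]
    src <- switch(rec$kind, quantity = rec$value, expression = rec$text,
                  array = rec$value)
    assignments[[v]] <- describe_assignment(v, src)
  }
  params <- data.frame(name = character(0), value = character(0),
                       stringsAsFactors = FALSE)
  for (nm in names(obj$namespace)) {
    v <- obj$namespace[[nm]]
    params <- rbind(params, data.frame(
      name = nm,
      value = if (is_quantity(v)) format_quantity(v) else format(v),
      stringsAsFactors = FALSE))
  }
  structure(list(name = obj$name,
                 latex = if (length(eqs$entries))
                   equations_to_latex(eqs) else character(0),
                 text = text_lines, events = events,
                 assignments = assignments, parameters = params),
            class = "eq_report")
}

#' @export
print.eq_report <- function(x, ...) {
  cat("Model report:", x$name, "\n")
  if (length(x$text)) {
    cat("Equations:\n")
    for (line in x$text) cat(" ", line, "\n")
  }
  for (nm in names(x$events))
    cat(nm, ": ", x$events[[nm]], "\n", sep = "")
  if (length(x$assignments)) {
    cat("Assignments:\n")
    for (a in x$assignments) cat(" ", a, "\n")
  }
  if (nrow(x$parameters)) {
    cat("Parameters:\n")
    for (k in seq_len(nrow(x$parameters)))
      cat("  ", x$parameters$name[[k]], " = ", x$parameters$value[[k]],
          "\n", sep = "")
  }
  invisible(x)
}

# Minimal math-mode sanity check used by the tests: balanced braces and only
# known backslash commands.
KNOWN_LATEX_COMMANDS <- c(GREEK_NAMES, "frac", "sqrt", "cdot", "left",
                          "right", "text", "quad", "leq", "geq", "neq",
                          "wedge", "vee", "neg", "bmod", "operatorname",
                          "mathcal", "_", "Delta")

latex_well_formed <- function(line) {
  chars <- strsplit(line, "")[[1L]]
  depth <- 0L
  for (ch in chars) {
    if (ch == "{") depth <- depth + 1L
    if (ch == "}") depth <- depth - 1L
    if (depth < 0L) return(FALSE)
  }
  if (depth != 0L) return(FALSE)
  cmds <- regmatches(line, gregexpr("\\\\[A-Za-z]+", line))[[1L]]
  all(sub("^\\\\", "", cmds) %in% KNOWN_LATEX_COMMANDS)
}
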