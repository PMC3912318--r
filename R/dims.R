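## Dimension inference over expression trees. Every leaf identifier must
## resolve to a declared dimension, a unit name, or a reserved symbol.
## Transcendental functions, int(), rand()/randn() require/return
## dimensionless arguments; sqrt halves exponents; clip and min/max require
## equal dimensions; comparisons return dimensionless booleans.

# Reserved symbols and their dimensions, available in every expression.
reserved_symbol_dims <- function() {
  list(t = dimension(s = 1), dt = dimension(s = 1),
       lastspike = dimension(s = 1), lastupdate = dimension(s = 1),
       i = DIMENSIONLESS, j = DIMENSIONLESS,
       N = DIMENSIONLESS, N_pre = DIMENSIONLESS, N_post = DIMENSIONLESS)
}

# Dimension of the white-noise symbols xi, xi_1, xi_2, ...: second^(-1/2),
# the unique choice making additive-noise equations consistent with a Wiener
# increment of variance dt.
XI_DIM <- dimension(s = -0.5)

is_xi_name <- function(nm) grepl("^xi(_[0-9]+)?$", nm)

dim_stop <- function(...) {
  stop(structure(class = c("eq_dim_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Infer the dimension of an expression
#'
#' @param expr A language object (see [parse_expression()]).
#' @param symbol_dims Named list mapping identifier -> `eq_dimension`.
#'   Reserved symbols (`t`, `dt`, `i`, `j`, `N`, `lastspike`, `lastupdate`),
#'   unit names and `xi`/`xi_k` are always available.
#' @return An `eq_dimension`; signals an error of class `eq_dim_error` on a
#'   dimensional inconsistency or an unresolved identifier.
#' @examples
#' d <- dims_of_expression(parse_expression("gl*(El - v)"),
#'   list(gl = parse_unit("siemens")$dim, El = parse_unit("volt")$dim,
#'        v = parse_unit("volt")$dim))
#' unit_name(d)  # "A"
#' @export
dims_of_expression <- function(expr, symbol_dims = list()) {
  reserved <- reserved_symbol_dims()
  rec <- function(e) {
    if (is_number(e)) return(DIMENSIONLESS)
    if (is.logical(e)) return(DIMENSIONLESS)
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (nm %in% names(symbol_dims)) return(symbol_dims[[nm]])
      if (nm %in% names(reserved)) return(reserved[[nm]])
      if (is_xi_name(nm)) return(XI_DIM)
      u <- lookup_unit(nm)
      if (!is.null(u)) return(u$dim)
      dim_stop("unresolved identifier '", nm, "'")
    }
    if (!is.call(e)) dim_stop("unsupported expression node")
    op <- if (is.symbol(e[[1L]])) as.character(e[[1L]]) else
      dim_stop("unsupported call head")
    args <- as.list(e)[-1L]
    same_dims <- function(where) {
      ds <- lapply(args, rec)
      for (k in seq_along(ds)[-1L]) {
        if (!dim_eq(ds[[1L]], ds[[k]]))
          dim_stop("dimension mismatch in ", where, ": ",
                   dim_label(ds[[1L]]), " vs ", dim_label(ds[[k]]))
      }
      ds[[1L]]
    }
    dimensionless_args <- function(fn) {
      for (a in args) {
        if (!is_dimensionless(rec(a)))
          dim_stop("argument of ", fn, "() must be dimensionless")
      }
      DIMENSIONLESS
    }
    switch(op,
      "(" = rec(args[[1L]]),
      "+" = , "-" = {
        if (length(args) == 1L) rec(args[[1L]])
        else same_dims(paste0("'", op, "'"))
      },
      "*" = dim_mul(rec(args[[1L]]), rec(args[[2L]])),
      "/" = dim_div(rec(args[[1L]]), rec(args[[2L]])),
      "%%" = same_dims("'%'"),
      "^" = {
        base_d <- rec(args[[1L]])
        p <- num_value(args[[2L]])
        if (is.na(p)) {
          # non-literal exponent: both sides must be dimensionless
          if (!is_dimensionless(rec(args[[2L]])))
            dim_stop("exponent must be dimensionless")
          if (!is_dimensionless(base_d))
            dim_stop("non-literal exponent requires dimensionless base")
          DIMENSIONLESS
        } else {
          d <- dim_pow(base_d, p)
          if (any(abs(unclass(d) * 4 - round(unclass(d) * 4)) > 1e-9))
            dim_stop("fractional exponent produces non-rational dimension")
          d
        }
      },
      "<" = , ">" = , "<=" = , ">=" = , "==" = , "!=" = {
        same_dims("comparison"); DIMENSIONLESS
      },
      "&" = , "|" = , "!" = dimensionless_args("boolean operator"),
      "exp" = , "log" = , "sin" = , "cos" = dimensionless_args(op),
      "int" = , "floor" = dimensionless_args(op),
      "rand" = , "randn" = DIMENSIONLESS,
      "sqrt" = dim_pow(rec(args[[1L]]), 0.5),
      "abs" = rec(args[[1L]]),
      "clip" = same_dims("clip()"),
      "min" = , "max" = same_dims(paste0(op, "()")),
      dim_stop("unknown function '", op, "'")
    )
  }
  rec(expr)
}

#' Check the unit annotations of a model
#'
#' For a differential entry `dx/dt = rhs : U` the right-hand side must have
#' dimension U/second; for a subexpression `x = rhs : U` it must have
#' dimension U. Violations are returned, not raised.
#'
#' @param eqs An `eq_model` (see [parse_model()]).
#' @param namespace Named list of external constants (`eq_quantity` or bare
#'   numerics).
#' @param extra_dims Named list of additional identifier dimensions, e.g.
#'   `_pre`/`_post` suffixed neuron variables for synaptic models.
#' @return A list of violations, each with elements `name`, `expected`,
#'   `actual` (dimensions or `NA` for unresolved identifiers) and `message`.
#'   An empty list means the model is dimensionally consistent.
#' @export
check_equation_dimensions <- function(eqs, namespace = list(),
                                      extra_dims = list()) {
  stopifnot(inherits(eqs, "eq_model"))
  symbol_dims <- model_symbol_dims(eqs, namespace, extra_dims)
  violations <- list()
  second <- dimension(s = 1)
  for (entry in eqs$entries) {
    if (is.null(entry$rhs)) next
    expected <- if (entry$kind == "differential")
      dim_div(entry$unit, second) else entry$unit
    actual <- tryCatch(dims_of_expression(entry$rhs, symbol_dims),
                       eq_dim_error = function(e) e)
    if (inherits(actual, "eq_dim_error")) {
      if (grepl("unresolved identifier", conditionMessage(actual)))
        stop(conditionMessage(actual), " in equation for '", entry$name, "'",
             call. = FALSE)
      violations[[length(violations) + 1L]] <-
        list(name = entry$name, expected = expected, actual = NA,
             message = conditionMessage(actual))
    } else if (!dim_eq(actual, expected)) {
      violations[[length(violations) + 1L]] <-
        list(name = entry$name, expected = expected, actual = actual,
             message = paste0("equation for '", entry$name, "' has dimension ",
                              unit_name(actual), ", expected ",
                              unit_name(expected)))
    }
  }
  violations
}

# Dimensions of every identifier a model's expressions may reference.
model_symbol_dims <- function(eqs, namespace = list(), extra_dims = list()) {
  dims <- list()
  for (entry in eqs$entries) dims[[entry$name]] <- entry$unit
  for (nm in names(namespace)) {
    v <- namespace[[nm]]
    dims[[nm]] <- if (is_quantity(v)) v$dim else DIMENSIONLESS
  }
  for (nm in names(extra_dims)) dims[[nm]] <- extra_dims[[nm]]
  dims
}
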