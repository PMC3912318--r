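## Expression infrastructure: translation between the user-facing expression
## grammar (Python-flavoured: `**`, `and/or/not`, `%`, int(), clip(), rand(),
## randn()) and base-R language objects, plus the tree manipulations the rest
## of the package builds on (substitution, identifier sets, linear-coefficient
## extraction, zero/one folding, numeric equality testing, rendering).

# The closed function set admissible in model expressions.
EXPR_FUNCTIONS <- c("abs", "floor", "exp", "log", "sin", "cos", "sqrt",
                    "clip", "int", "rand", "randn", "min", "max")

# Operators that may appear inside expression trees.
EXPR_OPERATORS <- c("+", "-", "*", "/", "^", "%%",
                    "<", ">", "<=", ">=", "==", "!=", "&", "|", "!", "(")

#' Parse an expression in the model grammar
#'
#' Translates the package's expression syntax (power `**`, modulo `%`, boolean
#' `and`/`or`/`not`, identifiers that may start with an underscore) into a base
#' R language object.
#'
#' @param text A single character string.
#' @return An R language object (call, symbol or literal).
#' @examples
#' parse_expression("tau**-0.5 * sigma * xi")
#' parse_expression("i != j and rand() < 0.1")
#' @export
parse_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  src <- text
  # `%` -> `%%` (collapse any pre-existing `%%` first so we never emit `%%%%`)
  txt <- gsub("%%", "%", text, fixed = TRUE)
  txt <- gsub("%", "%%", txt, fixed = TRUE)
  # word-boundary boolean keywords
  txt <- gsub("\\bnot\\b", "!", txt)
  txt <- gsub("\\band\\b", "&", txt)
  txt <- gsub("\\bor\\b", "|", txt)
  # leading-underscore identifiers (scheme temporaries like _k_v) need quoting
  txt <- gsub("(^|[^A-Za-z0-9_`])(_[A-Za-z0-9_]+)", "\\1`\\2`", txt)
  e <- tryCatch(str2lang(txt), error = function(err) {
    stop("cannot parse expression '", src, "': ", conditionMessage(err),
         call. = FALSE)
  })
  e
}

#' Render a language object in the model grammar
#'
#' Inverse of [parse_expression()]: `^` prints as `**`, `%%` as `%`, boolean
#' operators as `and`/`or`/`not`.
#'
#' @param e A language object.
#' @return A character string.
#' @export
render_expression <- function(e) {
  txt <- paste(deparse(e, width.cutoff = 500L), collapse = " ")
  txt <- gsub("`", "", txt, fixed = TRUE)
  txt <- gsub("%%", " % ", txt, fixed = TRUE)
  txt <- gsub("^", "**", txt, fixed = TRUE)
  txt <- gsub(" & ", " and ", txt, fixed = TRUE)
  txt <- gsub(" | ", " or ", txt, fixed = TRUE)
  txt <- gsub("!(?!=)", "not ", txt, perl = TRUE)
  gsub("\\s+", " ", trimws(txt))
}

# All symbols occurring in an expression, excluding call heads.
expr_identifiers <- function(e) {
  ids <- character(0)
  walk <- function(x) {
    if (is.symbol(x)) {
      ids[[length(ids) + 1L]] <<- as.character(x)
    } else if (is.call(x)) {
      head <- x[[1L]]
      args <- as.list(x)[-1L]
      if (!is.symbol(head)) walk(head)
      lapply(args, walk)
    }
  }
  walk(e)
  unique(ids)
}

# Function names called anywhere in an expression.
expr_called_functions <- function(e) {
  fns <- character(0)
  walk <- function(x) {
    if (is.call(x)) {
      if (is.symbol(x[[1L]])) fns[[length(fns) + 1L]] <<- as.character(x[[1L]])
      lapply(as.list(x)[-1L], walk)
    }
  }
  walk(e)
  unique(fns)
}

contains_symbol <- function(e, name) {
  name %in% expr_identifiers(e)
}

# Substitute symbols by language objects. `map` is a named list whose values
# are language objects (or numbers).
substitute_symbols <- function(e, map) {
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (nm %in% names(map)) return(map[[nm]])
    return(e)
  }
  if (is.call(e)) {
    for (k in seq_along(e)) {
      if (k == 1L && is.symbol(e[[k]])) next  # keep function heads
      e[[k]] <- substitute_symbols(e[[k]], map)
    }
    return(e)
  }
  e
}

is_number <- function(x) is.numeric(x) || is.integer(x)

num_value <- function(e) {
  # numeric literal possibly wrapped in unary minus / parentheses; NA otherwise
  if (is_number(e)) return(as.numeric(e))
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(" ) return(num_value(e[[2L]]))
    if (op == "-" && length(e) == 2L) {
      v <- num_value(e[[2L]]); return(if (is.na(v)) NA_real_ else -v)
    }
    if (op == "+" && length(e) == 2L) return(num_value(e[[2L]]))
  }
  NA_real_
}

# Fold additive/multiplicative identities introduced by symbolic manipulation
# (0*x, x+0, x^1, 1*x, -(0), double negation). Purely cosmetic plus it keeps
# drift expressions clean after substituting xi -> 0.
simplify_expr <- function(e) {
  if (!is.call(e)) return(e)
  op <- if (is.symbol(e[[1L]])) as.character(e[[1L]]) else ""
  args <- lapply(as.list(e)[-1L], simplify_expr)
  zero <- function(x) identical(num_value(x), 0)
  one  <- function(x) identical(num_value(x), 1)
  if (op == "(") {
    inner <- args[[1L]]
    if (is.symbol(inner) || is_number(inner)) return(inner)
    e[[2L]] <- inner
    return(e)
  }
  if (op == "+" && length(args) == 2L) {
    if (zero(args[[1L]])) return(args[[2L]])
    if (zero(args[[2L]])) return(args[[1L]])
  }
  if (op == "+" && length(args) == 1L) return(args[[1L]])
  if (op == "-" && length(args) == 2L) {
    if (zero(args[[2L]])) return(args[[1L]])
    if (zero(args[[1L]])) return(simplify_expr(call("-", args[[2L]])))
  }
  if (op == "-" && length(args) == 1L) {
    if (zero(args[[1L]])) return(0)
    if (is.call(args[[1L]]) && identical(args[[1L]][[1L]], as.name("-")) &&
        length(args[[1L]]) == 2L)
      return(args[[1L]][[2L]])
  }
  if (op == "*") {
    if (zero(args[[1L]]) || zero(args[[2L]])) return(0)
    if (one(args[[1L]])) return(args[[2L]])
    if (one(args[[2L]])) return(args[[1L]])
  }
  if (op == "/") {
    if (zero(args[[1L]])) return(0)
    if (one(args[[2L]])) return(args[[1L]])
  }
  if (op == "^") {
    if (one(args[[2L]])) return(args[[1L]])
    if (zero(args[[2L]])) return(1)
  }
  for (k in seq_along(args)) e[[k + 1L]] <- args[[k]]
  e
}

#' Linear coefficient of a symbol in an expression
#'
#' Computes `a` such that `e = a*s + rest` with `rest` free of `s`, by
#' structural recursion. Errors when `s` occurs non-linearly (inside a function
#' call, a power, a denominator, or multiplied with itself).
#'
#' @param e language object
#' @param s character, the symbol name
#' @return language object for the coefficient (may be the number 0)
#' @keywords internal
linear_coeff <- function(e, s) {
  if (is.symbol(e)) {
    return(if (identical(as.character(e), s)) 1 else 0)
  }
  if (is_number(e)) return(0)
  if (!is.call(e)) stop("unsupported expression node", call. = FALSE)
  op <- if (is.symbol(e[[1L]])) as.character(e[[1L]]) else ""
  args <- as.list(e)[-1L]
  has <- vapply(args, contains_symbol, logical(1), name = s)
  if (!any(has)) return(0)
  if (op == "(") return(linear_coeff(args[[1L]], s))
  if (op == "+" && length(args) == 2L)
    return(simplify_expr(call("+", linear_coeff(args[[1L]], s),
                              linear_coeff(args[[2L]], s))))
  if (op == "+" && length(args) == 1L) return(linear_coeff(args[[1L]], s))
  if (op == "-" && length(args) == 2L)
    return(simplify_expr(call("-", linear_coeff(args[[1L]], s),
                              linear_coeff(args[[2L]], s))))
  if (op == "-" && length(args) == 1L)
    return(simplify_expr(call("-", linear_coeff(args[[1L]], s))))
  if (op == "*") {
    if (all(has))
      stop("symbol '", s, "' occurs non-linearly (product with itself)",
           call. = FALSE)
    if (has[[1L]])
      return(simplify_expr(call("*", linear_coeff(args[[1L]], s), args[[2L]])))
    return(simplify_expr(call("*", args[[1L]], linear_coeff(args[[2L]], s))))
  }
  if (op == "/") {
    if (has[[2L]])
      stop("symbol '", s, "' occurs non-linearly (in a denominator)",
           call. = FALSE)
    return(simplify_expr(call("/", linear_coeff(args[[1L]], s), args[[2L]])))
  }
  stop("symbol '", s, "' occurs non-linearly (inside '", op, "')",
       call. = FALSE)
}

# Numeric equality of two expressions over named symbols, evaluated at random
# points. Calls to rand()/randn() are replaced by shared auxiliary symbols so
# stochastic update code can be compared deterministically (valid when each
# draw appears at most once per expression, which holds for the generated
# integrator code: one draw per noise process).
expr_equal <- function(e1, e2, vars = NULL, n_points = 12L, tol = 1e-9,
                       range = c(0.2, 2)) {
  strip_rng <- function(e) {
    k <- 0L
    walk <- function(x) {
      if (is.call(x) && is.symbol(x[[1L]]) &&
          as.character(x[[1L]]) %in% c("rand", "randn")) {
        k <<- k + 1L
        return(as.name(paste0(".", as.character(x[[1L]]))))
      }
      if (is.call(x)) for (i in seq_along(x)) if (i > 1L) x[[i]] <- walk(x[[i]])
      x
    }
    walk(e)
  }
  e1 <- strip_rng(e1); e2 <- strip_rng(e2)
  if (is.null(vars)) vars <- union(expr_identifiers(e1), expr_identifiers(e2))
  vars <- union(vars, c(".rand", ".randn"))
  fns <- list(int = function(x) if (is.logical(x)) as.numeric(x) else trunc(x),
              clip = function(x, lo, hi) pmin(pmax(x, lo), hi),
              min = pmin, max = pmax)
  for (rep in seq_len(n_points)) {
    env <- new.env(parent = baseenv())
    for (f in names(fns)) assign(f, fns[[f]], envir = env)
    for (v in vars) assign(v, stats::runif(1, range[1L], range[2L]),
                           envir = env)
    v1 <- eval(e1, env); v2 <- eval(e2, env)
    denom <- max(abs(v1), abs(v2), 1)
    if (!is.finite(v1) || !is.finite(v2)) return(FALSE)
    if (abs(v1 - v2) / denom > tol) return(FALSE)
  }
  TRUE
}
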