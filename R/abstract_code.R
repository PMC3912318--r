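## Abstract code: ordered `variable operator expression` statements, the
## single intermediate representation for integrators, resets, synaptic
## statements and state assignments. Blocks are executed vectorized over
## instances (neurons or synapses) with semantics equal to a per-instance
## loop; they can also be rendered as loop-style source text for inspection.

ASSIGN_OPS <- c("=", "+=", "-=", "*=", "/=")

new_statement <- function(target, op, rhs) {
  stopifnot(op %in% ASSIGN_OPS)
  list(target = target, op = op, rhs = rhs)
}

# Build a block from a list of statements and compute dependency sets.
new_code_block <- function(statements) {
  written <- character(0)
  read_set <- character(0); write_set <- character(0); temp_set <- character(0)
  for (st in statements) {
    ids <- setdiff(expr_identifiers(st$rhs), expr_called_functions(st$rhs))
    read_set <- union(read_set, setdiff(ids, written))
    if (st$op != "=" && !(st$target %in% written))
      read_set <- union(read_set, st$target)
    if (!(st$target %in% written) && st$op == "=")
      temp_set <- union(temp_set, st$target)
    write_set <- union(write_set, st$target)
    written <- union(written, st$target)
  }
  # a name read before its first write is not a temporary
  temp_set <- setdiff(temp_set, read_set)
  structure(list(statements = statements, read_set = read_set,
                 write_set = write_set, temp_set = temp_set),
            class = "eq_code")
}

#' Parse abstract code statements
#'
#' One statement per line or `;`-separated: `target op expression` with `op`
#' one of `=`, `+=`, `-=`, `*=`, `/=`. Control structures are not supported.
#'
#' @param text Character string.
#' @return An object of class `eq_code` with fields `statements`, `read_set`,
#'   `write_set` and `temp_set`.
#' @examples
#' blk <- parse_statements("v = v0; w += 5*pA")
#' blk$write_set
#' @export
parse_statements <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  pieces <- unlist(strsplit(strsplit(text, "\n", fixed = TRUE)[[1L]], ";",
                            fixed = TRUE))
  pieces <- trimws(sub("#.*$", "", pieces))
  pieces <- pieces[nzchar(pieces)]
  if (any(grepl("\\b(if|else|for|while)\\b", pieces)))
    stop("control structures are not supported in abstract code",
         call. = FALSE)
  re <- "^(`?[A-Za-z_][A-Za-z0-9_]*`?)\\s*(\\+=|-=|\\*=|/=|=(?![=]))\\s*(.*)$"
  statements <- lapply(pieces, function(line) {
    m <- regmatches(line, regexec(re, line, perl = TRUE))[[1L]]
    if (!length(m) || !nzchar(trimws(m[[4L]])))
      stop("malformed abstract code statement: '", line, "'", call. = FALSE)
    new_statement(gsub("`", "", m[[2L]]), m[[3L]], parse_expression(m[[4L]]))
  })
  new_code_block(statements)
}

#' @export
print.eq_code <- function(x, ...) {
  for (st in x$statements)
    cat(st$target, st$op, render_expression(st$rhs), "\n")
  invisible(x)
}

#' Render a code block as statement text
#' @param block An `eq_code`.
#' @return Character string, one statement per line.
#' @export
render_statements <- function(block) {
  paste0(vapply(block$statements, function(st)
    paste(st$target, st$op, render_expression(st$rhs)), character(1)),
    collapse = "\n")
}

## ---------------------------------------------------------------------------
## Execution

# Runtime function set available inside abstract code expressions.
runtime_functions <- function() {
  list(int = function(x) if (is.logical(x)) as.numeric(x) else trunc(x),
       clip = function(x, lo, hi) pmin(pmax(x, lo), hi),
       min = function(...) pmin(...),
       max = function(...) pmax(...))
}

# Environment chain: base R -> runtime functions -> unit scale factors.
# Cached; namespaces chain below it per call.
runtime_base_env <- function() {
  if (!is.null(.unit_cache$runtime_env)) return(.unit_cache$runtime_env)
  fn_env <- new.env(parent = baseenv())
  fns <- runtime_functions()
  for (nm in names(fns)) assign(nm, fns[[nm]], envir = fn_env)
  unit_env <- new.env(parent = fn_env)
  reg <- unit_registry()
  for (nm in ls(reg)) assign(nm, get(nm, envir = reg)$scale, envir = unit_env)
  .unit_cache$runtime_env <- unit_env
  unit_env
}

namespace_magnitudes <- function(namespace) {
  lapply(namespace, function(v) if (is_quantity(v)) v$magnitude else v)
}

#' Execute an abstract code block
#'
#' Vectorized execution over instances with per-instance-loop semantics.
#' `arrays` holds the persistent state; `index` maps each persistent variable
#' to the array slot of every instance (a single integer vector applies to
#' all variables). `rand()`/`randn()` draw once per instance per occurrence
#' from R's global RNG, in left-to-right statement order. When several
#' instances address the same slot, `+=`/`-=` accumulate all contributions;
#' for plain `=` the highest-numbered instance wins.
#'
#' @param block An `eq_code`.
#' @param arrays Named list of numeric vectors (persistent state, base SI).
#' @param index Integer vector (slots, applied to every variable) or named
#'   list of integer vectors per variable; all of length `n`.
#' @param n Number of instances.
#' @param namespace Named list of constants (`eq_quantity` or numeric).
#' @param scalars Named list of additional per-call values (`t`, `dt`,
#'   per-instance vectors such as `i`), available as symbols.
#' @return The updated `arrays` list.
#' @export
execute_block <- function(block, arrays, index, n, namespace = list(),
                          scalars = list()) {
  if (n == 0L || !length(block$statements)) return(arrays)
  if (!is.list(index)) {
    idx_map <- stats::setNames(rep(list(as.integer(index)), length(arrays)),
                               names(arrays))
  } else idx_map <- lapply(index, as.integer)

  persistent <- names(arrays)
  # loop fallback when a slot-sharing variable is also read explicitly
  dup_vars <- names(idx_map)[vapply(idx_map, anyDuplicated,
                                    integer(1)) > 0L]
  dup_vars <- intersect(dup_vars, intersect(block$write_set, persistent))
  needs_loop <- FALSE
  if (length(dup_vars)) {
    explicit_reads <- unique(unlist(lapply(block$statements, function(st)
      setdiff(expr_identifiers(st$rhs), expr_called_functions(st$rhs)))))
    bad_ops <- vapply(block$statements, function(st)
      st$target %in% dup_vars && st$op %in% c("*=", "/="), logical(1))
    needs_loop <- length(intersect(dup_vars, explicit_reads)) > 0L ||
      any(bad_ops)
  }
  if (needs_loop)
    return(execute_reference(block, arrays, idx_map, n, namespace, scalars))

  ns_env <- new.env(parent = runtime_base_env())
  mags <- namespace_magnitudes(namespace)
  for (nm in names(mags)) assign(nm, mags[[nm]], envir = ns_env)
  env <- new.env(parent = ns_env)
  for (nm in names(scalars)) assign(nm, scalars[[nm]], envir = env)
  assign("rand", function() stats::runif(n), envir = env)
  assign("randn", function() stats::rnorm(n), envir = env)

  used <- union(block$read_set, block$write_set)
  live <- intersect(used, persistent)
  for (nm in live) assign(nm, arrays[[nm]][idx_map[[nm]]], envir = env)

  for (st in block$statements) {
    val <- eval(st$rhs, env)
    if (is.logical(val)) val <- as.numeric(val)
    val <- rep_len(val, n)
    tgt <- st$target
    if (tgt %in% persistent) {
      idx <- idx_map[[tgt]]
      arr <- arrays[[tgt]]
      if (anyDuplicated(idx)) {
        if (st$op == "=") {
          arr[idx] <- val
        } else {
          delta <- switch(st$op, "+=" = val, "-=" = -val,
                          stop("unreachable"))
          agg <- rowsum(delta, group = idx)
          arr[as.integer(rownames(agg))] <-
            arr[as.integer(rownames(agg))] + agg[, 1L]
        }
      } else {
        arr[idx] <- switch(st$op,
          "=" = val, "+=" = arr[idx] + val, "-=" = arr[idx] - val,
          "*=" = arr[idx] * val, "/=" = arr[idx] / val)
      }
      arrays[[tgt]] <- arr
      assign(tgt, arr[idx], envir = env)
    } else {
      old <- if (st$op != "=") get(tgt, envir = env)
      assign(tgt, switch(st$op,
        "=" = val, "+=" = old + val, "-=" = old - val,
        "*=" = old * val, "/=" = old / val), envir = env)
    }
  }
  arrays
}

# Reference per-instance interpreter: executes every statement for instance 1,
# then instance 2, ... with immediate write-through. The oracle for the
# vectorized path and the fallback for slot-sharing corner cases.
execute_reference <- function(block, arrays, index, n, namespace = list(),
                              scalars = list()) {
  if (!is.list(index))
    index <- stats::setNames(rep(list(as.integer(index)), length(arrays)),
                             names(arrays))
  ns_env <- new.env(parent = runtime_base_env())
  mags <- namespace_magnitudes(namespace)
  for (nm in names(mags)) assign(nm, mags[[nm]], envir = ns_env)
  persistent <- names(arrays)
  for (inst in seq_len(n)) {
    env <- new.env(parent = ns_env)
    for (nm in names(scalars)) {
      v <- scalars[[nm]]
      assign(nm, if (length(v) >= inst && length(v) > 1L) v[[inst]] else v,
             envir = env)
    }
    assign("rand", function() stats::runif(1L), envir = env)
    assign("randn", function() stats::rnorm(1L), envir = env)
    used <- union(block$read_set, block$write_set)
    for (nm in intersect(used, persistent))
      assign(nm, arrays[[nm]][[index[[nm]][[inst]]]], envir = env)
    for (st in block$statements) {
      val <- eval(st$rhs, env)
      if (is.logical(val)) val <- as.numeric(val)
      tgt <- st$target
      old <- if (st$op != "=") get(tgt, envir = env)
      new <- switch(st$op, "=" = val, "+=" = old + val, "-=" = old - val,
                    "*=" = old * val, "/=" = old / val)
      assign(tgt, new, envir = env)
      if (tgt %in% persistent)
        arrays[[tgt]][[index[[tgt]][[inst]]]] <- new
    }
  }
  arrays
}

#' Execute a block over a subset of instances
#'
#' Convenience wrapper around [execute_block()] for the common case where all
#' variables share one index vector (neuron groups).
#'
#' @param block An `eq_code`.
#' @param state Named list of numeric arrays.
#' @param subset Integer vector of 1-based instance indices.
#' @param namespace,scalars See [execute_block()].
#' @return Updated `state`.
#' @export
execute <- function(block, state, subset = seq_along(state[[1L]]),
                    namespace = list(), scalars = list()) {
  execute_block(block, state, as.integer(subset), length(subset),
                namespace, scalars)
}

## ---------------------------------------------------------------------------
## Rendering as loop-style source text (inspection only, never executed)

# Replace `^` by pow() calls, booleans by C forms.
to_c_expr <- function(e) {
  if (!is.call(e)) return(e)
  op <- if (is.symbol(e[[1L]])) as.character(e[[1L]]) else ""
  for (k in seq_along(e)) if (k > 1L) e[[k]] <- to_c_expr(e[[k]])
  if (op == "^") return(as.call(list(as.name("pow"), e[[2L]], e[[3L]])))
  if (op == "%%") return(as.call(list(as.name("fmod"), e[[2L]], e[[3L]])))
  e
}

render_c_expr <- function(e) {
  txt <- paste(deparse(to_c_expr(e), width.cutoff = 500L), collapse = " ")
  txt <- gsub("`", "", txt, fixed = TRUE)
  txt <- gsub(" & ", " && ", txt, fixed = TRUE)
  txt <- gsub(" | ", " || ", txt, fixed = TRUE)
  gsub("\\s+", " ", trimws(txt))
}

#' Render a code block as target-language source text
#'
#' The `vectorized` dialect emits whole-array statements (persistent
#' variables addressed as full arrays, temporaries as plain names). The
#' `loop` dialect emits an explicit indexed loop with scalar reads from the
#' state arrays before the statements and writes back after them; statements
#' gain `;` terminators and the power operator is replaced by `pow()`. The
#' output is text for inspection and golden-file testing only.
#'
#' @param block An `eq_code`.
#' @param dialect `"vectorized"` or `"loop"`.
#' @param state_vars Character vector naming the persistent state variables.
#' @return A single character string.
#' @export
render_loop_source <- function(block, dialect = c("vectorized", "loop"),
                               state_vars = character(0)) {
  dialect <- match.arg(dialect)
  persistent <- intersect(union(block$read_set, block$write_set), state_vars)
  if (dialect == "vectorized") {
    lines <- vapply(block$statements, function(st) {
      tgt <- if (st$target %in% state_vars)
        paste0(st$target, "[:]") else st$target
      paste(tgt, st$op, render_expression(st$rhs))
    }, character(1))
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  reads <- intersect(block$read_set, persistent)
  writes <- intersect(block$write_set, persistent)
  temps <- block$temp_set
  body <- c(
    vapply(reads, function(v)
      sprintf("    double %s = %s_array[_idx];", v, v), character(1)),
    vapply(setdiff(writes, reads), function(v)
      sprintf("    double %s;", v), character(1)),
    vapply(temps, function(v) sprintf("    double %s;", v), character(1)),
    vapply(block$statements, function(st)
      sprintf("    %s %s %s;", st$target, st$op, render_c_expr(st$rhs)),
      character(1)),
    vapply(writes, function(v)
      sprintf("    %s_array[_idx] = %s;", v, v), character(1))
  )
  paste0(paste(c("for(int _idx=0; _idx<_N; _idx++)", "{", body, "}"),
               collapse = "\n"), "\n")
}
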