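## Physical units: Dimension (exponents over the 7 SI base dimensions) and
## Quantity (magnitude in base SI + Dimension). Unit names exist only at the
## parse/render boundary; all stored state is base-SI floats. Exponents are
## stored as doubles, which represent the dyadic rationals needed for sqrt and
## `**-0.5` exactly.

DIM_NAMES <- c("m", "kg", "s", "A", "K", "mol", "cd")

#' Construct a physical dimension
#'
#' @param m,kg,s,A,K,mol,cd Exponents of the SI base dimensions (length, mass,
#'   time, current, temperature, amount, luminous intensity).
#' @return An object of class `eq_dimension` (a named numeric of length 7).
#' @examples
#' dimension(s = -1)            # frequency
#' dimension()                  # dimensionless
#' @export
dimension <- function(m = 0, kg = 0, s = 0, A = 0, K = 0, mol = 0, cd = 0) {
  d <- c(m = m, kg = kg, s = s, A = A, K = K, mol = mol, cd = cd)
  structure(as.numeric(d), names = DIM_NAMES, class = "eq_dimension")
}

DIMENSIONLESS <- dimension()

#' @export
print.eq_dimension <- function(x, ...) {
  cat("<dimension>", dim_label(x), "\n")
  invisible(x)
}

dim_label <- function(d) {
  if (is_dimensionless(d)) return("1")
  nz <- which(unclass(d) != 0)
  paste(sprintf("%s^%g", DIM_NAMES[nz], unclass(d)[nz]), collapse = " ")
}

#' Test for the dimensionless dimension
#' @param d An `eq_dimension`.
#' @export
is_dimensionless <- function(d) all(unclass(d) == 0)

dim_eq <- function(a, b) isTRUE(all.equal(unclass(a), unclass(b),
                                          tolerance = 1e-12,
                                          check.attributes = FALSE))

dim_mul <- function(a, b) structure(unclass(a) + unclass(b),
                                    names = DIM_NAMES, class = "eq_dimension")
dim_div <- function(a, b) structure(unclass(a) - unclass(b),
                                    names = DIM_NAMES, class = "eq_dimension")
dim_pow <- function(a, p) structure(unclass(a) * p,
                                    names = DIM_NAMES, class = "eq_dimension")

## ---------------------------------------------------------------------------
## Quantity

#' Construct a quantity (magnitude + dimension)
#'
#' @param magnitude numeric scalar or vector, in base SI.
#' @param dim an `eq_dimension`, or a unit string parsed by [parse_unit()]
#'   (in which case `magnitude` is interpreted in that unit).
#' @return An `eq_quantity`.
#' @examples
#' quantity(20, "ms")     # 0.02 s
#' quantity(3, "mV")
#' @export
quantity <- function(magnitude, dim = DIMENSIONLESS) {
  if (is.character(dim)) {
    u <- parse_unit(dim)
    magnitude <- magnitude * u$magnitude
    dim <- u$dim
  }
  structure(list(magnitude = magnitude, dim = dim), class = "eq_quantity")
}

is_quantity <- function(x) inherits(x, "eq_quantity")

#' @export
print.eq_quantity <- function(x, ...) {
  cat("<quantity>", format_quantity(x), "\n")
  invisible(x)
}

#' @export
Ops.eq_quantity <- function(e1, e2) {
  as_q <- function(x) if (is_quantity(x)) x else quantity(x)
  if (missing(e2)) {
    q <- as_q(e1)
    if (.Generic == "-") return(quantity(-q$magnitude, q$dim))
    if (.Generic == "+") return(q)
    stop("unary '", .Generic, "' undefined for quantities", call. = FALSE)
  }
  q1 <- as_q(e1); q2 <- as_q(e2)
  switch(.Generic,
    "+" = , "-" = {
      if (!dim_eq(q1$dim, q2$dim))
        stop("dimension mismatch in '", .Generic, "': ",
             dim_label(q1$dim), " vs ", dim_label(q2$dim), call. = FALSE)
      quantity(get(.Generic)(q1$magnitude, q2$magnitude), q1$dim)
    },
    "*" = quantity(q1$magnitude * q2$magnitude, dim_mul(q1$dim, q2$dim)),
    "/" = quantity(q1$magnitude / q2$magnitude, dim_div(q1$dim, q2$dim)),
    "^" = {
      if (is_quantity(e2) && !is_dimensionless(q2$dim))
        stop("exponent must be dimensionless", call. = FALSE)
      p <- q2$magnitude
      quantity(q1$magnitude^p, dim_pow(q1$dim, p))
    },
    "==" = , "!=" = , "<" = , ">" = , "<=" = , ">=" = {
      if (!dim_eq(q1$dim, q2$dim))
        stop("dimension mismatch in comparison: ",
             dim_label(q1$dim), " vs ", dim_label(q2$dim), call. = FALSE)
      get(.Generic)(q1$magnitude, q2$magnitude)
    },
    stop("operator '", .Generic, "' undefined for quantities", call. = FALSE)
  )
}

## ---------------------------------------------------------------------------
## Unit registry

.unit_cache <- new.env(parent = emptyenv())

base_unit_table <- function() {
  V  <- dimension(m = 2, kg = 1, s = -3, A = -1)
  list(
    metre    = list(scale = 1,    dim = dimension(m = 1)),
    meter    = list(scale = 1,    dim = dimension(m = 1)),
    m        = list(scale = 1,    dim = dimension(m = 1)),
    second   = list(scale = 1,    dim = dimension(s = 1)),
    s        = list(scale = 1,    dim = dimension(s = 1)),
    kilogram = list(scale = 1,    dim = dimension(kg = 1)),
    gram     = list(scale = 1e-3, dim = dimension(kg = 1)),
    g        = list(scale = 1e-3, dim = dimension(kg = 1)),
    amp      = list(scale = 1,    dim = dimension(A = 1)),
    ampere   = list(scale = 1,    dim = dimension(A = 1)),
    A        = list(scale = 1,    dim = dimension(A = 1)),
    kelvin   = list(scale = 1,    dim = dimension(K = 1)),
    mole     = list(scale = 1,    dim = dimension(mol = 1)),
    volt     = list(scale = 1,    dim = V),
    V        = list(scale = 1,    dim = V),
    farad    = list(scale = 1,    dim = dimension(m = -2, kg = -1, s = 4, A = 2)),
    F        = list(scale = 1,    dim = dimension(m = -2, kg = -1, s = 4, A = 2)),
    siemens  = list(scale = 1,    dim = dimension(m = -2, kg = -1, s = 3, A = 2)),
    S        = list(scale = 1,    dim = dimension(m = -2, kg = -1, s = 3, A = 2)),
    ohm      = list(scale = 1,    dim = dimension(m = 2, kg = 1, s = -3, A = -2)),
    hertz    = list(scale = 1,    dim = dimension(s = -1)),
    Hz       = list(scale = 1,    dim = dimension(s = -1)),
    coulomb  = list(scale = 1,    dim = dimension(s = 1, A = 1)),
    C        = list(scale = 1,    dim = dimension(s = 1, A = 1))
  )
}

SI_PREFIXES <- c(p = 1e-12, n = 1e-9, u = 1e-6, m = 1e-3,
                 k = 1e3, M = 1e6, G = 1e9)

# Full registry: every base/short unit name plus every prefixed form.
# Prefixed forms are inserted first so that genuine unit names win collisions
# (there are none in this set, but it keeps intent explicit).
unit_registry <- function() {
  if (!is.null(.unit_cache$registry)) return(.unit_cache$registry)
  base <- base_unit_table()
  reg <- new.env(parent = emptyenv())
  for (pre in names(SI_PREFIXES)) {
    for (nm in names(base)) {
      if (nm == "kilogram") next   # kg is already a prefixed name
      entry <- base[[nm]]
      assign(paste0(pre, nm),
             list(scale = entry$scale * SI_PREFIXES[[pre]], dim = entry$dim),
             envir = reg)
    }
  }
  for (nm in names(base)) assign(nm, base[[nm]], envir = reg)
  assign("kg", base$kilogram, envir = reg)
  .unit_cache$registry <- reg
  reg
}

lookup_unit <- function(name) {
  reg <- unit_registry()
  if (exists(name, envir = reg, inherits = FALSE))
    get(name, envir = reg, inherits = FALSE)
  else NULL
}

is_unit_name <- function(name) !is.null(lookup_unit(name))

#' Parse a unit token
#'
#' Accepts a supported unit name with optional SI prefix (`p n u m k M G`,
#' `μ` as alias of `u`), the literal `1` for dimensionless, or a
#' product/quotient/power of such names (e.g. `"amp/metre**2"`).
#'
#' @param token character scalar.
#' @return An `eq_quantity` whose magnitude is the scale factor to base SI.
#' @examples
#' parse_unit("mV")       # 1e-3, volt dimension
#' parse_unit("1")        # dimensionless
#' parse_unit("siemens")
#' @export
parse_unit <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  txt <- gsub("μ", "u", trimws(token))
  if (!nzchar(txt)) stop("empty unit token", call. = FALSE)
  e <- tryCatch(str2lang(txt), error = function(err) {
    stop("cannot parse unit '", token, "'", call. = FALSE)
  })
  eval_unit_expr(e, token)
}

eval_unit_expr <- function(e, src) {
  if (is_number(e)) return(quantity(as.numeric(e)))
  if (is.symbol(e)) {
    entry <- lookup_unit(as.character(e))
    if (is.null(entry))
      stop("unknown unit '", as.character(e), "' in '", src, "'",
           call. = FALSE)
    return(quantity(entry$scale, entry$dim))
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(eval_unit_expr(e[[2L]], src))
    if (op == "*" && length(e) == 3L)
      return(eval_unit_expr(e[[2L]], src) * eval_unit_expr(e[[3L]], src))
    if (op == "/" && length(e) == 3L)
      return(eval_unit_expr(e[[2L]], src) / eval_unit_expr(e[[3L]], src))
    if (op == "^") {
      p <- num_value(e[[3L]])
      if (is.na(p)) stop("unit exponent must be numeric in '", src, "'",
                         call. = FALSE)
      return(eval_unit_expr(e[[2L]], src)^p)
    }
    if (op == "-" && length(e) == 2L)
      return(quantity(-1) * eval_unit_expr(e[[2L]], src))
  }
  stop("unsupported unit syntax in '", src, "'", call. = FALSE)
}

## Canonical display names for common dimensions, used by the documentation
## generator and error messages.
canonical_unit_names <- function() {
  list(V = dimension(m = 2, kg = 1, s = -3, A = -1),
       S = dimension(m = -2, kg = -1, s = 3, A = 2),
       F = dimension(m = -2, kg = -1, s = 4, A = 2),
       ohm = dimension(m = 2, kg = 1, s = -3, A = -2),
       A = dimension(A = 1),
       Hz = dimension(s = -1),
       s = dimension(s = 1),
       m = dimension(m = 1),
       C = dimension(s = 1, A = 1),
       kg = dimension(kg = 1),
       "V/s" = dimension(m = 2, kg = 1, s = -4, A = -1),
       "1" = DIMENSIONLESS)
}

#' Human-readable name of a dimension
#' @param d An `eq_dimension`.
#' @return A character string such as `"V"`, `"S"`, `"1"`, or an exponent
#'   product for dimensions without a canonical symbol.
#' @export
unit_name <- function(d) {
  canon <- canonical_unit_names()
  for (nm in names(canon)) if (dim_eq(d, canon[[nm]])) return(nm)
  dim_label(d)
}

# Render a scalar base-SI quantity with a convenient prefix, e.g. "20 ms".
format_quantity <- function(q, digits = 6) {
  d <- q$dim
  base <- unit_name(d)
  mag <- q$magnitude
  if (identical(base, "1"))
    return(paste(format(mag, digits = digits), collapse = ", "))
  if (length(mag) != 1L)
    return(paste0("[", paste(format(mag, digits = digits), collapse = ", "),
                  "] ", base))
  if (mag == 0 || !is.finite(mag)) return(paste(format(mag), base))
  prefixes <- stats::setNames(c(1e9, 1e6, 1e3, 1, 1e-3, 1e-6, 1e-9, 1e-12),
                              c("G", "M", "k", "", "m", "u", "n", "p"))
  if (base %in% c("V", "S", "F", "ohm", "A", "Hz", "s", "m", "C")) {
    for (i in seq_along(prefixes)) {
      if (abs(mag) >= prefixes[[i]]) {
        return(paste(format(mag / prefixes[[i]], digits = digits),
                     paste0(names(prefixes)[[i]], base)))
      }
    }
    return(paste(format(mag / 1e-12, digits = digits), paste0("p", base)))
  }
  paste(format(mag, digits = digits), base)
}
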