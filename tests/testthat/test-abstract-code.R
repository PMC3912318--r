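test_that("statement parsing computes dependency sets", {
  blk <- parse_statements("v = v0")
  expect_identical(blk$write_set, "v")
  expect_identical(blk$read_set, "v0")

  blk2 <- parse_statements("v = v0; w += 5*pA")
  expect_length(blk2$statements, 2)
  expect_identical(blk2$statements[[2]]$op, "+=")
  expect_true("w" %in% blk2$read_set)   # in-place ops read their target

  empty <- parse_statements("")
  expect_length(empty$statements, 0)
  st <- list(v = 1:3 * 1.0)
  expect_identical(execute(empty, st, 1:3), st)

  tmp <- parse_statements("_k = 2*v\nv = v + _k")
  expect_identical(tmp$temp_set, "_k")
  expect_false("_k" %in% tmp$read_set)

  expect_error(parse_statements("if (x > 1) y = 2"), "control")
  expect_error(parse_statements("v == v0"), "malformed")
  expect_error(parse_statements("v ="), "malformed")
})

test_that("execution matches per-instance loop semantics", {
  # reset on a spiking subset leaves other elements untouched
  state <- list(v = c(1, 2, 3, 4), v0 = rep(-1, 4))
  out <- execute(parse_statements("v = v0"), state, subset = c(2L, 4L))
  expect_equal(out$v, c(1, -1, 3, -1))

  # int() gating: no update after the time window
  st <- list(w = c(1, 1))
  blk <- parse_statements("w += 0.1*w_max*int(t < 1*second)")
  out1 <- execute(blk, st, 1:2, namespace = list(w_max = 10),
                  scalars = list(t = 2))
  expect_equal(out1$w, c(1, 1))
  out2 <- execute(blk, st, 1:2, namespace = list(w_max = 10),
                  scalars = list(t = 0.5))
  expect_equal(out2$w, c(2, 2))
})

test_that("same-target accumulation equals the explicit loop oracle", {
  # two synapses converging on target slot 2
  arrays <- list(g = c(0, 0, 0), w = c(0.5, 0.25, 0.125))
  blk <- parse_statements("g += w")
  idx <- list(g = c(2L, 2L, 3L), w = 1:3)
  out <- execute_block(blk, arrays, idx, 3L)
  expect_equal(out$g, c(0, 0.75, 0.125))
  oracle <- eqspike:::execute_reference(blk, arrays, idx, 3L)
  expect_equal(out, oracle)

  # k same-target += of a constant: target increases by exactly k*c
  k <- 7
  arrays2 <- list(g = 0)
  out2 <- execute_block(parse_statements("g += 0.3"), arrays2,
                        list(g = rep(1L, k)), k)
  expect_equal(out2$g, k * 0.3)

  # slot-sharing with a later read falls back to true loop semantics
  arrays3 <- list(g = c(1, 0), h = c(0, 0, 0))
  blk3 <- parse_statements("g += 1\nh = g")
  idx3 <- list(g = c(1L, 1L, 2L), h = 1:3)
  out3 <- execute_block(blk3, arrays3, idx3, 3L)
  expect_equal(out3, eqspike:::execute_reference(blk3, arrays3, idx3, 3L))
  expect_equal(out3$h, c(2, 3, 1))
})

test_that("vectorized execution equals the reference interpreter on random programs", {
  set.seed(7)
  ops <- c("=", "+=", "-=", "*=")
  exprs <- c("a + b", "a*2 - c", "clip(a, 0, 1)", "int(a > b)",
             "abs(b) + floor(c)", "a % 3", "min(a, b)", "b**2",
             "exp(-abs(a))", "(a + b)/(1 + abs(c))")
  for (rep in 1:200) {
    n_stmt <- sample(1:4, 1)
    text <- paste(vapply(seq_len(n_stmt), function(k) {
      paste(sample(c("a", "b", "c"), 1), sample(ops, 1),
            sample(exprs, 1))
    }, character(1)), collapse = "\n")
    blk <- parse_statements(text)
    n <- sample(1:6, 1)
    arrays <- list(a = stats::rnorm(n), b = stats::rnorm(n),
                   c = stats::rnorm(n))
    out_vec <- execute_block(blk, arrays, seq_len(n), n)
    out_ref <- eqspike:::execute_reference(
      blk, arrays, stats::setNames(rep(list(seq_len(n)), 3), c("a", "b", "c")),
      n)
    expect_equal(out_vec, out_ref, tolerance = 1e-12)
  }
})

test_that("rand()/randn() draw once per instance per occurrence, reproducibly", {
  blk <- parse_statements("a = rand()\nb = rand() + randn()")
  arrays <- list(a = numeric(5), b = numeric(5))
  set.seed(99)
  out1 <- execute_block(blk, arrays, 1:5, 5L)
  set.seed(99)
  draws <- list(stats::runif(5), stats::runif(5), stats::rnorm(5))
  expect_equal(out1$a, draws[[1]])
  expect_equal(out1$b, draws[[2]] + draws[[3]])
  set.seed(99)
  expect_identical(execute_block(blk, arrays, 1:5, 5L), out1)
})

test_that("temporaries never leak and disjoint subsets commute", {
  blk <- parse_statements("_tmp = v*2\nv = _tmp + 1")
  state <- list(v = c(1, 2, 3, 4))
  out <- execute(blk, state, 1:4)
  expect_named(out, "v")
  expect_equal(out$v, c(3, 5, 7, 9))

  a_then_b <- execute(blk, execute(blk, state, c(1L, 2L)), c(3L, 4L))
  b_then_a <- execute(blk, execute(blk, state, c(3L, 4L)), c(1L, 2L))
  expect_identical(a_then_b, b_then_a)
})

test_that("modulo is mathematical (non-negative for positive modulus)", {
  st <- list(x = c(-5, -1, 0, 7))
  out <- execute(parse_statements("x = x % 4"), st, 1:4)
  expect_equal(out$x, c(3, 3, 0, 3))
})

test_that("loop-dialect rendering frames statements with reads and writes", {
  blk <- parse_statements("_k = dt*(-v/tau)\nv = v + _k*tau**-0.5")
  src <- render_loop_source(blk, "loop", state_vars = c("v", "tau"))
  expect_match(src, "for\\(int _idx=0; _idx<_N; _idx\\+\\+\\)")
  expect_match(src, "double v = v_array\\[_idx\\];", all = FALSE)
  expect_match(src, "pow\\(tau, -0.5\\)")
  expect_match(src, "v_array\\[_idx\\] = v;")
  expect_false(grepl("\\*\\*", src))
  # every statement line ends with a terminator
  stmts <- grep("^    .* = ", strsplit(src, "\n")[[1]], value = TRUE)
  expect_true(all(grepl(";$", stmts)))

  # golden frame for the euler LIF update, written once by hand
  lif <- apply_scheme("euler", parse_model(LIF_MODEL))
  golden <- c(
    "for(int _idx=0; _idx<_N; _idx++)",
    "{",
    "    double v = v_array[_idx];",
    "    double v0 = v0_array[_idx];",
    "    double tau_m = tau_m_array[_idx];",
    "    double _y_v;",
    "    _y_v = v + dt * (-(v - v0)/tau_m);",
    "    v = _y_v;",
    "    v_array[_idx] = v;",
    "}")
  expect_identical(strsplit(render_loop_source(lif, "loop",
                                               state_vars = c("v", "v0",
                                                              "tau_m")),
                            "\n")[[1]], golden)

  empty <- render_loop_source(parse_statements(""), "loop")
  expect_match(empty, "for\\(int _idx")
})

test_that("vectorized dialect emits whole-array statements", {
  blk <- parse_statements("_y_v = v + dt*(-v/tau)\nv = _y_v")
  src <- render_loop_source(blk, "vectorized", state_vars = "v")
  lines <- strsplit(src, "\n")[[1]]
  expect_identical(lines[1], "_y_v = v + dt * (-v/tau)")
  expect_identical(lines[2], "v[:] = _y_v")
})
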