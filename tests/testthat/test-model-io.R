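test_that("parse_bnet reads the bnet dialect", {
  m <- parse_bnet("targets, factors\nA, A\nB, !A")
  expect_equal(m$nodes, c("A", "B"))
  expect_equal(eval_expression(m$rules$B, c(A = 0)), 1L)

  m2 <- parse_bnet("A, A\nB, A & (C | !A)\nC, B")
  expect_equal(m2$nodes, c("A", "B", "C"))
  expect_equal(regulators(m2, "B"), c("A", "C"))

  # comments, blank lines, header optional
  m3 <- parse_bnet("# comment\n\ntargets, factors\nA, 1\n# more\nB, A\n")
  expect_equal(m3$nodes, c("A", "B"))
})

test_that("parse_bnet rejects malformed input with informative errors", {
  expect_error(parse_bnet("A, A\nB !A"), "line 2")
  expect_error(parse_bnet("A, B"), "B")
  expect_error(parse_bnet("A, A\nA, !A"), "duplicate")
  expect_error(parse_bnet("A, A\nB, A &"), "line 2")
  expect_error(parse_bnet("A, A @ B"), "invalid character")
})

test_that("write_bnet emits the canonical text and round-trips", {
  m <- parse_bnet("A, A\nB, !A")
  expect_equal(write_bnet(m), "targets, factors\nA, A\nB, !A")
  m2 <- parse_bnet(write_bnet(m))
  expect_equal(m2$nodes, m$nodes)
})

test_that("parse/write round-trip preserves semantics on random models", {
  set.seed(401)
  for (rep in 1:100) {
    n <- sample(4:10, 1)
    text <- random_model_text(n, k_max = 3, n_inputs = 2)
    m <- parse_bnet(text)
    out <- write_bnet(m)
    m2 <- parse_bnet(out)
    expect_identical(write_bnet(m2), out) # idempotent
    expect_identical(m2$nodes, m$nodes)
    for (nd in m$nodes) {
      vars <- regulators(m, nd)
      g <- all_assignments(vars)
      v1 <- vapply(seq_len(nrow(g)), function(i) {
        a <- as.integer(unlist(g[i, , drop = FALSE]))
        names(a) <- vars
        eval_expression(m$rules[[nd]], a)
      }, integer(1))
      v2 <- vapply(seq_len(nrow(g)), function(i) {
        a <- as.integer(unlist(g[i, , drop = FALSE]))
        names(a) <- vars
        eval_expression(m2$rules[[nd]], a)
      }, integer(1))
      expect_identical(v1, v2)
    }
  }
})

test_that("input_nodes identifies self-identity and constant rules", {
  expect_equal(input_nodes(mx_model()), c("I1", "I2"))
  expect_equal(input_nodes(parse_bnet("A, B\nB, A")), character(0))
  expect_equal(input_nodes(parse_bnet("A, 1\nB, A")), "A")
  # disjoint from nodes whose rules mention any other variable
  m <- mx_model()
  regulated <- Filter(
    function(n) length(setdiff(regulators(m, n), n)) > 0,
    m$nodes
  )
  expect_length(intersect(input_nodes(m), regulated), 0)
})

test_that("perturbed models re-export and re-parse losslessly", {
  m <- mx_model()
  modes <- c(
    "non_additive_activation", "additive_activation",
    "non_additive_inhibition", "additive_inhibition"
  )
  for (mode in modes) {
    pm <- apply_perturbation(m, "C", mode)
    back <- parse_bnet(write_bnet(pm))
    expect_identical(back$nodes, pm$nodes)
    expect_identical(write_bnet(back), write_bnet(pm))
    expect_identical(fixed_points(back), fixed_points(pm))
  }
})
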