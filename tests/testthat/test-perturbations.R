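test_that("the four perturbation modes rewrite the target rule correctly", {
  m <- mx_model()
  p1 <- apply_perturbation(m, "C", "additive_inhibition")
  expect_equal(expr_string_of(p1, "C"), "(A | B) & !C_INH")
  expect_equal(expr_string_of(p1, "C_INH"), "C_INH")
  expect_true("C_INH" %in% input_nodes(p1))

  p2 <- apply_perturbation(m, "C", "non_additive_activation")
  expect_equal(expr_string_of(p2, "C"), "C_ACT")

  p3 <- apply_perturbation(m, "C", "additive_activation")
  expect_equal(expr_string_of(p3, "C"), "A | B | C_ACT")

  p4 <- apply_perturbation(m, "C", "non_additive_inhibition")
  expect_equal(expr_string_of(p4, "C"), "!C_INH")

  # name collision resolved by numeric suffix
  mm <- parse_bnet("I, I\nC, I\nC_ACT, C")
  p5 <- apply_perturbation(mm, "C", "additive_activation")
  expect_equal(attr(p5, "pert_node"), "C_ACT_2")

  expect_error(apply_perturbation(m, "nope", "additive_activation"), "unknown")
  expect_error(
    apply_perturbation(m, "C", "additive_activation", pert_node = "D"),
    "collides"
  )
  expect_warning(apply_perturbation(m, "I1", "additive_activation"), "input")
})

test_that("additive perturbations with an inactive node are the identity", {
  m <- mx_model()
  fp0 <- fixed_points(m)
  for (mode in c("additive_activation", "additive_inhibition")) {
    pm <- apply_perturbation(m, "C", mode)
    pn <- attr(pm, "pert_node")
    fp <- fixed_points(pm)
    off <- filter_states_by_pert(fp, pn, 0L)
    expect_equal(off[, m$nodes, drop = FALSE], fp0)
  }
})

test_that("non-additive perturbations force exactly one path through the node", {
  m <- mx_model()
  for (target in c("A", "B", "C")) {
    pa <- apply_perturbation(m, target, "non_additive_activation")
    pn <- attr(pa, "pert_node")
    on <- filter_states_by_pert(fixed_points(pa), pn, 1L)
    for (i in seq_len(nrow(on))) {
      expect_equal(on[i, target], c(1L), ignore_attr = TRUE)
      sm <- simplify_drivers(extract_drivers(pa, on[i, ]))
      expect_equal(sm$drivers[[target]], list(pn))
      expect_equal(count_paths(pa, on[i, ], target)[[target]], 1)
    }
    pi_ <- apply_perturbation(m, target, "non_additive_inhibition")
    pn2 <- attr(pi_, "pert_node")
    on2 <- filter_states_by_pert(fixed_points(pi_), pn2, 1L)
    for (i in seq_len(nrow(on2))) {
      expect_equal(on2[i, target], c(0L), ignore_attr = TRUE)
      expect_equal(count_paths(pi_, on2[i, ], target)[[target]], -1)
    }
  }
})

test_that("batch perturbation enumerates node x mode deterministically", {
  m <- mx_model()
  batch <- batch_perturbations(m, exclude = c("I1", "I2", "D"))
  expect_length(batch, 6) # 3 nodes x 2 additive modes
  expect_equal(
    vapply(batch, `[[`, character(1), "target"),
    rep(c("A", "B", "C"), each = 2)
  )
  all4 <- batch_perturbations(m,
    exclude = c("I1", "I2", "D"),
    modes = c(
      "non_additive_activation", "additive_activation",
      "non_additive_inhibition", "additive_inhibition"
    )
  )
  expect_length(all4, 12)
  expect_warning(b0 <- batch_perturbations(m, exclude = m$nodes), "eligible")
  expect_length(b0, 0)
})

test_that("state filtering by perturbation value preserves order", {
  states <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2,
    dimnames = list(NULL, c("X", "P"))
  )
  kept <- filter_states_by_pert(states, "P", 1L)
  expect_equal(kept[, "X"], c(0, 1))
  expect_error(filter_states_by_pert(states, "Q"), "unknown")
  empty <- states[integer(0), , drop = FALSE]
  expect_equal(nrow(filter_states_by_pert(empty, "P")), 0)
})
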