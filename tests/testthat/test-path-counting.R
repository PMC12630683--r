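mx_s10 <- c(I1 = 1, I2 = 0, A = 1, B = 1, C = 1, D = 0)
mx_s00 <- c(I1 = 0, I2 = 0, A = 0, B = 0, C = 0, D = 1)

tree_branch_acyclic <- function(tree, above = character(0)) {
  if (tree$node %in% above) return(FALSE)
  all(vapply(tree$children, tree_branch_acyclic,
    logical(1),
    above = c(above, tree$node)
  ))
}

test_that("enumeration on the convergent toy model matches hand expansion", {
  m <- mx_model()
  trees <- enumerate_paths(m, mx_s10, "C")
  expect_length(trees, 2) # C<-A<-I1 and C<-B<-{I1, !I2}
  expect_setequal(
    vapply(trees, `[[`, logical(1), "simple"),
    c(TRUE, FALSE)
  )
  # an input target is its own single trivial explanation
  expect_length(enumerate_paths(m, mx_s10, "I1"), 1)
})

test_that("a node sustained only by a feedback loop has no acyclic path", {
  loop <- parse_bnet("A, B\nB, A")
  st <- c(A = 1, B = 1)
  expect_length(enumerate_paths(loop, st, "A", loop_policy = "discard"), 0)
  tr <- enumerate_paths(loop, st, "A", loop_policy = "truncate")
  expect_length(tr, 1)
  expect_true(tr[[1]]$truncated)
  expect_equal(count_paths(loop, st, "A")[["A"]], 0)
  expect_equal(
    count_paths(loop, st, "A", loop_policy = "truncate")[["A"]], 1
  )
})

test_that("signed counts on the toy model match the reference expansion", {
  m <- mx_model()
  expect_equal(
    count_paths(m, mx_s10),
    c(I1 = 1, I2 = -1, A = 1, B = 1, C = 2, D = -2),
    ignore_attr = TRUE
  )
  cp <- count_paths(m, mx_s10)
  expect_equal(attr(cp, "simple")[["C"]], 1)
  expect_equal(attr(cp, "complex")[["C"]], 1)
  expect_equal(attr(cp, "complex")[["B"]], 1)
  expect_equal(count_paths(m, mx_s00)[["C"]], -1)
  expect_equal(count_paths(m, mx_s00)[["D"]], 1)
  expect_error(count_paths(m, mx_s10, "nope"), "unknown")
})

test_that("a linear cascade always has exactly one path", {
  for (n in 2:10) {
    m <- chain_model(n)
    st <- setNames(rep(1L, n + 1), m$nodes)
    expect_equal(count_paths(m, st, paste0("X", n))[[1]], 1)
  }
})

test_that("counts add over disjoint OR branches and multiply over AND literals", {
  # d disjoint branches, each a 2-step chain from its own input -> count d
  for (d in 2:4) {
    lines <- character(0)
    for (i in seq_len(d)) {
      lines <- c(lines, paste0("I", i, ", I", i), paste0("B", i, ", I", i))
    }
    lines <- c(lines, paste0("T, ", paste(paste0("B", seq_len(d)), collapse = " | ")))
    m <- parse_bnet(paste(lines, collapse = "\n"))
    st <- setNames(rep(1L, length(m$nodes)), m$nodes)
    expect_equal(count_paths(m, st, "T")[["T"]], d)
  }
  # k-way AND of disjoint diamonds (2 paths each) -> count 2^k
  for (k in 2:4) {
    lines <- character(0)
    for (i in seq_len(k)) {
      lines <- c(
        lines,
        paste0("Ia", i, ", Ia", i), paste0("Ib", i, ", Ib", i),
        paste0("Xa", i, ", Ia", i), paste0("Xb", i, ", Ib", i),
        paste0("C", i, ", Xa", i, " | Xb", i)
      )
    }
    lines <- c(lines, paste0("T, ", paste(paste0("C", seq_len(k)), collapse = " & ")))
    m <- parse_bnet(paste(lines, collapse = "\n"))
    st <- setNames(rep(1L, length(m$nodes)), m$nodes)
    expect_equal(count_paths(m, st, "T")[["T"]], 2^k)
  }
})

test_that("counts are invariant under node declaration order", {
  perm_text <- paste(
    "D, !C",
    "C, A | B",
    "B, I1 & !I2",
    "I2, I2",
    "A, I1",
    "I1, I1",
    sep = "\n"
  )
  m1 <- mx_model()
  m2 <- parse_bnet(perm_text)
  c1 <- count_paths(m1, mx_s10)
  c2 <- count_paths(m2, mx_s10[m2$nodes])
  expect_equal(c1[m1$nodes], c2[m1$nodes])
})

test_that("discard-policy trees are structurally acyclic", {
  set.seed(407)
  for (rep in 1:30) {
    m <- parse_bnet(random_model_text(sample(5:9, 1), k_max = 2, n_inputs = 2))
    fp <- fixed_points(m)
    if (nrow(fp) == 0) next
    for (n in m$nodes) {
      trees <- enumerate_paths(m, fp[1, ], n, loop_policy = "discard")
      for (t in trees) expect_true(tree_branch_acyclic(t))
    }
  }
})

test_that("count_model assembles the per-state table with sign convention", {
  m <- mx_model()
  tab <- count_model(m)
  expect_s3_class(tab, "path_count_table")
  expect_equal(dim(tab$counts), c(4, 6))
  i <- which(tab$states[, "I1"] == 1 & tab$states[, "I2"] == 0)
  expect_equal(
    tab$counts[i, ],
    c(I1 = 1, I2 = -1, A = 1, B = 1, C = 2, D = -2)
  )
  # sign pattern equals the state pattern wherever counts are nonzero
  nz <- tab$counts != 0
  expect_true(all((tab$counts[nz] > 0) == (tab$states[nz] == 1)))
  # classification totals are consistent
  expect_equal(abs(tab$counts), tab$simple + tab$complex)

  nofp <- parse_bnet("A, !A")
  expect_warning(tab0 <- count_model(nofp), "no stable state")
  expect_equal(nrow(tab0$counts), 0)
})

test_that("explicit counting backends agree on cyclic models", {
  set.seed(408)
  checked <- 0
  for (rep in 1:60) {
    m <- parse_bnet(random_model_text(sample(5:9, 1), k_max = 2, n_inputs = 2))
    fp <- fixed_points(m)
    if (nrow(fp) == 0) next
    for (i in seq_len(nrow(fp))) {
      for (policy in c("discard", "truncate")) {
        cm <- count_paths(m, fp[i, ], loop_policy = policy, method = "memo")
        cn <- count_paths(m, fp[i, ], loop_policy = policy, method = "naive")
        expect_equal(cm, cn)
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 20)
})
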