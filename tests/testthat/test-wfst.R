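demo_t <- demo_transducer()

test_that("linear acceptor is the trivial machine of its string", {
  m <- linear_acceptor("GGC")
  expect_length(m$states, 4L)
  expect_equal(wfst_value(m, "GGC", "GGC"), 1)
  expect_equal(wfst_value(m, "GGC", "GGG"), 0)
  expect_equal(wfst_value(m, "GG", "GGC"), 0)

  # empty string: single state, accepts (empty, empty) with weight 1
  e <- linear_acceptor("")
  expect_length(e$states, 1L)
  expect_equal(path_sum(e), 1)

  expect_error(linear_acceptor("GXC", alphabet = c("G", "C")),
               "X")

  # value 1 on (x, x) and 0 on mutated copies
  set.seed(11)
  x <- rand_seq(8)
  mx <- linear_acceptor(x, c("A", "C", "G", "T"))
  expect_equal(wfst_value(mx, x, x), 1)
  for (k in 1:5) {
    chars <- strsplit(x, "")[[1]]
    i <- sample.int(8, 1)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    y <- paste(chars, collapse = "")
    expect_equal(wfst_value(mx, x, y), 0)
  }
})

test_that("inverse swaps the tapes and is an involution", {
  expect_equal(wfst_value(wfst_inverse(demo_t), "CCG", "GGC"), 48)

  tinv2 <- wfst_inverse(wfst_inverse(demo_t))
  expect_equal(tinv2$transitions, demo_t$transitions)
  expect_equal(tinv2$initial, demo_t$initial)
  expect_equal(tinv2$final, demo_t$final)

  # value table of the inverse is the transpose of the value table
  set.seed(21)
  t <- rand_wfst()
  ti <- wfst_inverse(t)
  for (x in all_strings(c("G", "C"), 3)) for (y in all_strings(c("G", "C"), 3))
    expect_equal(enum_value(ti, y, x), enum_value(t, x, y))
})

test_that("composition matches brute-force sum over intermediate strings", {
  # identity transducer leaves the value table unchanged
  idt <- as_wfst(wacc(
    data.frame(src = "0", lab = c("G", "C"), weight = 1, dst = "0"),
    initial = c("0" = 1), final = c("0" = 1)))
  set.seed(31)
  t <- rand_wfst()
  tc <- wfst_compose(t, idt)
  for (x in all_strings(c("G", "C"), 2)) for (y in all_strings(c("G", "C"), 2))
    expect_equal(wfst_value(tc, x, y), enum_value(t, x, y))

  # random small machines vs exhaustive enumeration over z (|z| <= 6)
  set.seed(32)
  for (rep in 1:6) {
    t1 <- rand_wfst(); t2 <- rand_wfst()
    comp <- wfst_compose(t1, t2)
    for (x in c("", "G", "GC", "CCG")) for (y in c("", "C", "GG", "GCC")) {
      expect_equal(wfst_value(comp, x, y),
                   enum_compose_value(t1, t2, x, y, max_z = 6),
                   tolerance = 1e-9)
    }
  }

  expect_error(
    wfst_compose(rand_wfst(alphabet = c("G", "C")),
                 rand_wfst(alphabet = c("A", "T"))),
    "alphabet mismatch")
})

test_that("composition is associative on value tables", {
  set.seed(41)
  for (rep in 1:3) {
    t1 <- rand_wfst(); t2 <- rand_wfst(); t3 <- rand_wfst()
    left <- wfst_compose(wfst_compose(t1, t2), t3)
    right <- wfst_compose(t1, wfst_compose(t2, t3))
    for (x in c("G", "GC", "CC")) for (y in c("C", "GG", "GCC")) {
      vl <- wfst_value(left, x, y)
      vr <- wfst_value(right, x, y)
      expect_equal(vl, vr, tolerance = 1e-9)
    }
  }
})

test_that("output projection sums the transducer over its inputs", {
  a <- project_output(demo_t)
  expect_equal(wa_value(a, "CCG"), 48)

  # projection of a linear acceptor accepts exactly its string
  ax <- project_output(linear_acceptor("GCG"))
  expect_equal(wa_value(ax, "GCG"), 1)
  expect_equal(wa_value(ax, "GCC"), 0)

  # A(y) = sum_x T(x, y) over all x, on a random machine
  set.seed(51)
  t <- rand_wfst()
  a <- project_output(t)
  for (y in all_strings(c("G", "C"), 3)) {
    total <- sum(vapply(all_strings(c("G", "C"), 4),
                        function(x) enum_value(t, x, y), numeric(1)))
    expect_equal(wa_value(a, y), total, tolerance = 1e-9)
  }
})

test_that("path_sum is the exact sum over accepting paths", {
  # worked example: two accepting paths, 36 + 12
  mx <- linear_acceptor("GGC", demo_t$input_alphabet)
  my <- linear_acceptor("CCG", demo_t$output_alphabet)
  expect_equal(path_sum(wfst_compose(wfst_compose(mx, demo_t), my)), 48)

  # empty final support -> 0
  t0 <- wfst(demo_t$transitions, demo_t$initial,
             final = c("2" = 0), states = demo_t$states,
             input_alphabet = demo_t$input_alphabet,
             output_alphabet = demo_t$output_alphabet)
  expect_equal(path_sum(t0), 0)

  # random acyclic machines vs DFS path enumeration
  set.seed(61)
  for (rep in 1:10) {
    t <- rand_wfst(n_states = 6L, n_trans = 12L)
    expect_equal(path_sum(t), enum_path_sum(t), tolerance = 1e-9)
  }

  # all-unit weights: path_sum counts accepting paths
  set.seed(62)
  t <- rand_wfst(n_states = 6L, n_trans = 12L)
  t$transitions$weight <- 1
  n_paths <- enum_path_sum(t)
  expect_equal(path_sum(t), n_paths)
  expect_equal(path_sum(t) %% 1, 0)

  # cyclic machines are rejected, naming a state on the cycle
  cyc <- wfst(data.frame(src = c("a", "b"), ilab = c("G", "C"),
                         olab = c("G", "C"), weight = 1,
                         dst = c("b", "a"), stringsAsFactors = FALSE),
              initial = c(a = 1), final = c(a = 1))
  expect_error(path_sum(cyc), "cyclic")
})

test_that("value agrees with brute-force path enumeration on random triples", {
  set.seed(71)
  for (rep in 1:20) {
    t <- rand_wfst(n_states = 5L, n_trans = 10L)
    x <- rand_seq(sample(0:3, 1), c("G", "C"))
    y <- rand_seq(sample(0:3, 1), c("G", "C"))
    expect_equal(wfst_value(t, x, y), enum_value(t, x, y), tolerance = 1e-9)
  }
})

test_that("inverse value identity holds machine-wide", {
  set.seed(81)
  for (rep in 1:5) {
    t <- rand_wfst()
    ti <- wfst_inverse(t)
    x <- rand_seq(sample(1:3, 1), c("G", "C"))
    y <- rand_seq(sample(1:3, 1), c("G", "C"))
    expect_equal(wfst_value(ti, y, x), wfst_value(t, x, y), tolerance = 1e-12)
  }
})

test_that("machine validation catches structural errors", {
  expect_error(
    wfst(data.frame(src = "0", ilab = "G", olab = "C", weight = 1, dst = "9"),
         initial = c("0" = 1), final = c("1" = 1), states = c("0", "1")),
    "9")
  expect_error(
    wfst(data.frame(src = "0", ilab = "X", olab = "C", weight = 1, dst = "1"),
         initial = c("0" = 1), final = c("1" = 1),
         input_alphabet = c("G", "C"), output_alphabet = c("G", "C")),
    "X")
  expect_true(is_acyclic(linear_acceptor("GGC")))
  expect_false(is_acyclic(as_wfst(wacc(
    data.frame(src = "0", lab = "G", weight = 1, dst = "0"),
    initial = c("0" = 1), final = c("0" = 1)))))
})

test_that("composing a linear acceptor with the n-gram machine stays acyclic", {
  t3 <- ngram_transducer(ngram_spec(3))
  expect_false(is_acyclic(t3)) # the counting machine itself has self-loops
  comp <- wfst_compose(linear_acceptor("ACGTACGT", c("A", "C", "G", "T")), t3)
  expect_true(is_acyclic(comp))
})
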