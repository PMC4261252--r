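test_that("ngram_spec validates its fields", {
  expect_error(ngram_spec(0), "positive")
  expect_error(ngram_spec(3, character(0)), "non-empty")
  s <- ngram_spec()
  expect_equal(s$n, 3L)
  expect_equal(s$alphabet, c("A", "C", "G", "T"))
})

test_that("counting transducer value equals occurrence counts", {
  t3 <- ngram_transducer(ngram_spec(3))
  demo <- demo_sequences()
  expect_equal(wfst_value(t3, demo[["x1"]], "TCT"), 2)
  expect_equal(wfst_value(t3, "ACTCTCT", "TCT"), 2)
  # |z| != n gives value 0
  expect_equal(wfst_value(t3, "AAA", "AAAA"), 0)
  expect_equal(wfst_value(t3, "AAAA", "AA"), 0)
})

test_that("window and transducer counting routes agree", {
  demo <- demo_sequences()
  expect_identical(ngram_count(demo[["y2"]], "TCT"), 3L)
  expect_identical(ngram_count(demo[["y1"]], "TCT"), 2L)
  expect_identical(ngram_count("ACGT", "GGG"), 0L)
  expect_error(ngram_count("ACGT", "GG"), "must equal")

  set.seed(101)
  for (rep in 1:50) {
    x <- rand_seq(sample(3:20, 1))
    z <- rand_seq(3)
    expect_identical(ngram_count(x, z), as.integer(naive_count(x, z)))
  }
  # a subset also checked through the counting transducer
  set.seed(102)
  for (rep in 1:8) {
    x <- rand_seq(sample(3:12, 1))
    z <- rand_seq(3)
    expect_equal(ngram_count(x, z, method = "transducer"), naive_count(x, z))
  }
})

test_that("weighted-automaton n-gram counts sum over the language", {
  demo <- demo_sequences()
  a1 <- project_output(linear_acceptor(demo[["x1"]], c("A", "C", "G", "T")))
  expect_equal(automaton_ngram_count(a1, "TCT"), 2)

  # single string TCT with weight 2: one occurrence x weight 2
  a2 <- wacc(data.frame(src = c("0", "1", "2"), lab = c("T", "C", "T"),
                        weight = c(2, 1, 1), dst = c("1", "2", "3"),
                        stringsAsFactors = FALSE),
             initial = c("0" = 1), final = c("3" = 1),
             alphabet = c("A", "C", "G", "T"))
  expect_equal(automaton_ngram_count(a2, "TCT"), 2)

  # two-branch automaton: weight 3 on a 1-occurrence string and weight 5 on
  # a 2-occurrence string -> 3*1 + 5*2 = 13
  mk_branch <- function(s, w, tag) {
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    sts <- paste0(tag, 0:n)
    data.frame(src = sts[1:n], lab = chars,
               weight = c(w, rep(1, n - 1)), dst = sts[2:(n + 1)],
               stringsAsFactors = FALSE)
  }
  tr <- rbind(mk_branch("ATCTA", 3, "p"), mk_branch("TCTCT", 5, "q"))
  tr$src[tr$src %in% c("p0", "q0")] <- "s"
  a3 <- wacc(tr, initial = c(s = 1),
             final = stats::setNames(c(1, 1), c("p5", "q5")),
             alphabet = c("A", "C", "G", "T"))
  expect_equal(automaton_ngram_count(a3, "TCT"), 13)

  cyc <- wacc(data.frame(src = "0", lab = "A", weight = 0.5, dst = "0"),
              initial = c("0" = 1), final = c("0" = 1),
              alphabet = c("A", "C", "G", "T"))
  expect_error(automaton_ngram_count(cyc, "AAA"), "cyclic")
})

test_that("U = T o T^-1 realizes the n-gram kernel and is PSD", {
  # unigram case: value(U, x, y) = sum_sigma c_x(sigma) c_y(sigma)
  u1 <- pds_kernel_from(ngram_transducer(ngram_spec(1, c("A", "C"))))
  expect_equal(wfst_value(u1, "AACA", "ACC"),
               3 * 1 + 1 * 2) # A: 3 and 1, C: 1 and 2
  # symmetry of the construction
  set.seed(111)
  for (rep in 1:5) {
    x <- rand_seq(6); y <- rand_seq(6)
    u3 <- pds_kernel_from(ngram_transducer(ngram_spec(3)))
    expect_equal(wfst_value(u3, x, y), wfst_value(u3, y, x), tolerance = 1e-12)
  }
})

test_that("count-vector kernel equals the transducer kernel value", {
  expect_equal(ngram_kernel("TCTCT", "TCTCT"), 5)
  expect_equal(ngram_kernel("AAAA", "CCCC"), 0) # no shared 3-gram
  set.seed(121)
  for (rep in 1:10) {
    x <- rand_seq(sample(4:14, 1))
    y <- rand_seq(sample(4:14, 1))
    kc <- ngram_kernel(x, y)
    kt <- ngram_kernel(x, y, method = "transducer")
    expect_equal(kt, kc, tolerance = 1e-9)
    expect_equal(ngram_kernel(y, x), kc) # symmetry
    expect_gte(ngram_kernel(x, x), 0)
  }
  # one longer pair through the full transducer route
  set.seed(122)
  x <- rand_seq(30); y <- rand_seq(30)
  expect_equal(ngram_kernel(x, y, method = "transducer"),
               ngram_kernel(x, y), tolerance = 1e-9)
})

test_that("out-of-alphabet symbols are skipped with a warning", {
  expect_warning(k <- ngram_kernel("ACGNACG", "ACGT"), "skipped")
  expect_no_warning(ngram_kernel("ACGACG", "ACGT"))
  # the N windows contribute nothing: ACG appears once cleanly at each end
  expect_equal(suppressWarnings(ngram_kernel("ACGNACG", "ACGXACG")),
               suppressWarnings(ngram_kernel("ACGNACG", "ACGNACG")))
  # lowercase input is uppercased before counting
  expect_equal(ngram_kernel("acgtacg", "ACGTACG"),
               ngram_kernel("ACGTACG", "ACGTACG"))
})

test_that("gram_matrix matches entrywise kernel calls and normalizes", {
  set.seed(131)
  seqs <- stats::setNames(vapply(1:5, function(i) rand_seq(20), character(1)),
                          paste0("g", 1:5))
  g_raw <- gram_matrix(seqs, normalize = FALSE)
  for (i in 1:5) for (j in 1:5)
    expect_equal(g_raw$values[i, j], ngram_kernel(seqs[[i]], seqs[[j]]))

  g <- gram_matrix(seqs)
  expect_true(g$normalized)
  expect_equal(unname(diag(g$values)), rep(1, 5))
  expect_true(all(abs(g$values - t(g$values)) < 1e-12))

  # identical sequences have normalized similarity 1
  g2 <- gram_matrix(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(g2$values["a", "b"], 1)

  expect_error(gram_matrix(character(0)), "empty")
})

test_that("n-gram kernel cost grows about linearly with sequence length", {
  # work proxy: count-vector route touches each window once; assert the
  # trend over doubling lengths rather than wall-clock
  set.seed(141)
  lens <- c(250, 500, 1000, 2000)
  times <- vapply(lens, function(L) {
    x <- rand_seq(L); y <- rand_seq(L)
    st <- system.time(for (i in 1:20) ngram_kernel(x, y))
    st[["elapsed"]]
  }, numeric(1))
  # doubling the length should not much more than double the time;
  # allow generous slack for timer noise
  expect_lt(times[4] / max(times[1], 1e-3), 8 * 4)
})
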