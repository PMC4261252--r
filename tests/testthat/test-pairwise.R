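# a small hand-made base kernel over four genes
hand_base <- function() {
  ids <- c("w", "x", "y", "z")
  m <- matrix(c(1.0, 2.0, 4.0, 5.0,
                2.0, 1.5, 5.0, 3.0,
                4.0, 5.0, 2.0, 0.5,
                5.0, 3.0, 0.5, 2.5), 4, byrow = TRUE,
              dimnames = list(ids, ids))
  base_kernel_gram(new_gram_matrix(m, ids))
}

test_that("the four pairwise formulas are computed exactly as written", {
  u <- hand_base()
  # pairs already in canonical (lexicographic) order: (w,x) vs (y,z)
  # U(w,y)=4, U(x,z)=3, U(w,z)=5, U(x,y)=5
  expect_equal(prk_value("direct_sum", u, c("w", "x"), c("y", "z")),
               4 + 3 + 5 + 5)
  expect_equal(prk_value("tensor", u, c("w", "x"), c("y", "z")),
               4 * 3 + 5 * 5)
  expect_equal(prk_value("metric", u, c("w", "x"), c("y", "z")),
               (4 - 5 - 5 + 3)^2)
  # cartesian on fully distinct ids: all deltas are 0
  expect_equal(prk_value("cartesian", u, c("w", "x"), c("y", "z")), 0)
  # cartesian with a shared first gene: only delta(x1 = x2) survives,
  # leaving U(y1, y2) = U(x, y) = 5
  expect_equal(prk_value("cartesian", u, c("w", "x"), c("w", "y")), 5)
  expect_error(prk_value("tensor", u, c("w", "nope"), c("y", "z")), "nope")
})

test_that("pair order canonicalization makes the kernel orientation-free", {
  u <- hand_base()
  for (type in PRK_TYPES) {
    expect_equal(prk_value(type, u, c("x", "w"), c("z", "y")),
                 prk_value(type, u, c("w", "x"), c("y", "z")))
    expect_equal(prk_value(type, u, c("w", "x"), c("y", "z")),
                 prk_value(type, u, c("y", "z"), c("w", "x")))
  }
})

test_that("pairwise values agree with an independent base-matrix recomputation", {
  set.seed(201)
  seqs <- stats::setNames(vapply(1:8, function(i) rand_seq(25), character(1)),
                          paste0("g", 1:8))
  u <- base_kernel_ngram(seqs)
  # independent route: rebuild the base table entrywise from ngram_kernel
  ids <- names(seqs)
  U <- matrix(0, 8, 8, dimnames = list(ids, ids))
  for (i in ids) for (j in ids) {
    kij <- ngram_kernel(seqs[[i]], seqs[[j]])
    U[i, j] <- kij / sqrt(ngram_kernel(seqs[[i]], seqs[[i]]) *
                          ngram_kernel(seqs[[j]], seqs[[j]]))
  }
  for (rep in 1:20) {
    p1 <- sort(sample(ids, 2)); p2 <- sort(sample(ids, 2))
    x1 <- p1[1]; y1 <- p1[2]; x2 <- p2[1]; y2 <- p2[2]
    type <- sample(PRK_TYPES, 1)
    expected <- switch(type,
      direct_sum = U[x1, x2] + U[y1, y2] + U[y1, x2] + U[x1, y2],
      tensor = U[x1, x2] * U[y1, y2] + U[x1, y2] * U[y1, x2],
      metric = (U[x1, x2] - U[x1, y2] - U[y1, x2] + U[y1, y2])^2,
      cartesian = U[x1, x2] * (y1 == y2) + (x1 == x2) * U[y1, y2] +
        U[x1, y2] * (y1 == x2) + (x1 == y2) * U[y1, x2])
    expect_equal(prk_value(type, u, p1, p2), expected, tolerance = 1e-12)
  }
})

test_that("transducer-backed and precomputed base kernels agree", {
  set.seed(211)
  seqs <- stats::setNames(vapply(1:4, function(i) rand_seq(12), character(1)),
                          paste0("g", 1:4))
  u_fast <- base_kernel_ngram(seqs)                      # count vectors
  u_slow <- base_kernel_ngram(seqs, method = "transducer") # composition
  pairs <- pairwise_points(c("g1", "g2", "g1"), c("g3", "g4", "g4"))
  for (type in c("tensor", "metric")) {
    k_fast <- pairwise_gram(pairs, type, u_fast)
    k_slow <- pairwise_gram(pairs, type, u_slow)
    expect_equal(k_slow$values, k_fast$values, tolerance = 1e-9)
  }
  # and the cache makes repeated evaluation cheap and consistent
  v1 <- base_value(u_slow, "g1", "g2")
  v2 <- base_value(u_slow, "g2", "g1")
  expect_identical(v1, v2)
})

test_that("pairwise Gram matrices are symmetric and PSD over PSD bases", {
  set.seed(221)
  seqs <- stats::setNames(vapply(1:10, function(i) rand_seq(30), character(1)),
                          sprintf("g%02d", 1:10))
  u <- base_kernel_ngram(seqs)
  pairs_mat <- utils::combn(names(seqs), 2)
  sel <- sample(ncol(pairs_mat), 15)
  pairs <- pairwise_points(pairs_mat[1, sel], pairs_mat[2, sel])
  for (type in PRK_TYPES) {
    kp <- pairwise_gram(pairs, type, u)
    expect_lt(max(abs(kp$values - t(kp$values))), 1e-9)
    ev <- eigen(kp$values, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(abs(ev)))
  }
})

test_that("a 3x3 pairwise matrix matches manual formula evaluation", {
  u <- hand_base()
  pairs <- pairwise_points(c("w", "w", "y"), c("x", "y", "z"))
  kp <- pairwise_gram(pairs, "tensor", u)
  # manual: K(p_i, p_j) = U(x_i,x_j) U(y_i,y_j) + U(x_i,y_j) U(y_i,x_j)
  M <- u$gram$values
  man <- matrix(0, 3, 3)
  px <- pairs$x; py <- pairs$y
  for (i in 1:3) for (j in 1:3)
    man[i, j] <- M[px[i], px[j]] * M[py[i], py[j]] +
      M[px[i], py[j]] * M[py[i], px[j]]
  expect_equal(unname(kp$values), man)
  expect_equal(kp$ids, c("w|x", "w|y", "y|z"))
})

test_that("delta-identity base kernel gives the degenerate-case values", {
  ids <- c("a", "b", "c", "d")
  u <- base_kernel_gram(new_gram_matrix(diag(4), ids))
  # fully distinct quadruple: every U(., .) term is 0
  expect_equal(prk_value("direct_sum", u, c("a", "b"), c("c", "d")), 0)
  expect_equal(prk_value("tensor", u, c("a", "b"), c("c", "d")), 0)
  expect_equal(prk_value("metric", u, c("a", "b"), c("c", "d")), 0)
  expect_equal(prk_value("cartesian", u, c("a", "b"), c("c", "d")), 0)
})

test_that("pairwise symmetry holds across many random cases", {
  set.seed(231)
  ids <- sprintf("g%02d", 1:12)
  X <- matrix(rnorm(12 * 5), 12)
  u <- base_kernel_gram(new_gram_matrix(tcrossprod(X), ids))
  for (rep in 1:100) {
    p1 <- sample(ids, 2); p2 <- sample(ids, 2)
    type <- sample(PRK_TYPES, 1)
    expect_equal(prk_value(type, u, p1, p2), prk_value(type, u, p2, p1),
                 tolerance = 1e-12)
  }
})
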