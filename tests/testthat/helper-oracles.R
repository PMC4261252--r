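# Independent brute-force oracles. These deliberately avoid the package's
# composition / path-sum machinery: values are recomputed by explicit
# recursion over transitions and enumeration over intermediate strings.

# T(x, y) by recursive path enumeration over (state, consumed-x, consumed-y).
# Requires a machine without epsilon:epsilon cycles (all machines used in the
# oracle tests are acyclic or consume input on every loop).
enum_value <- function(t, x, y) {
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  tr <- t$transitions
  by_src <- split(seq_len(nrow(tr)), tr$src)
  rec <- function(q, i, j) {
    tot <- 0
    if (i == length(xs) && j == length(ys)) {
      f <- t$final[q]
      if (!is.na(f)) tot <- tot + as.numeric(f)
    }
    for (r in by_src[[q]]) {
      di <- 0L; dj <- 0L; ok <- TRUE
      if (tr$ilab[r] != EPS) {
        if (i < length(xs) && xs[i + 1L] == tr$ilab[r]) di <- 1L else ok <- FALSE
      }
      if (ok && tr$olab[r] != EPS) {
        if (j < length(ys) && ys[j + 1L] == tr$olab[r]) dj <- 1L else ok <- FALSE
      }
      if (ok) tot <- tot + tr$weight[r] * rec(tr$dst[r], i + di, j + dj)
    }
    tot
  }
  tot <- 0
  for (q in names(t$initial))
    tot <- tot + as.numeric(t$initial[q]) * rec(q, 0L, 0L)
  tot
}

# sum over all accepting paths by depth-first enumeration (acyclic machines)
enum_path_sum <- function(m) {
  tr <- if (inherits(m, "wacc")) m$transitions else m$transitions
  src <- tr$src; dst <- tr$dst; w <- tr$weight
  by_src <- split(seq_along(src), src)
  rec <- function(q, acc) {
    tot <- 0
    f <- m$final[q]
    if (!is.na(f)) tot <- tot + acc * as.numeric(f)
    for (r in by_src[[q]]) tot <- tot + rec(dst[r], acc * w[r])
    tot
  }
  tot <- 0
  for (q in names(m$initial))
    tot <- tot + rec(q, as.numeric(m$initial[q]))
  tot
}

# all strings over an alphabet up to a length (including the empty string)
all_strings <- function(alphabet, max_len) {
  strs <- ""
  pool <- ""
  for (l in seq_len(max_len)) {
    pool <- as.vector(outer(pool, alphabet, paste0))
    strs <- c(strs, pool)
  }
  strs
}

# (T1 o T2)(x, y) = sum_z T1(x, z) T2(z, y), brute-forced over all z
enum_compose_value <- function(t1, t2, x, y, max_z) {
  zs <- all_strings(t2$input_alphabet, max_z)
  sum(vapply(zs, function(z) enum_value(t1, x, z) * enum_value(t2, z, y),
             numeric(1)))
}

# random acyclic transducer: transitions only from lower- to higher-numbered
# states, optional epsilon labels
rand_wfst <- function(n_states = 4L, alphabet = c("G", "C"), n_trans = 8L,
                      eps_prob = 0.25) {
  states <- as.character(seq_len(n_states))
  src_i <- sample.int(n_states - 1L, n_trans, replace = TRUE)
  dst_i <- vapply(src_i, function(s) {
    cand <- (s + 1L):n_states
    cand[sample.int(length(cand), 1L)]
  }, integer(1))
  lab <- function() {
    v <- character(n_trans)
    for (i in seq_len(n_trans))
      v[i] <- if (stats::runif(1) < eps_prob) EPS else sample(alphabet, 1L)
    v
  }
  tr <- data.frame(src = states[src_i], ilab = lab(), olab = lab(),
                   weight = sample(1:5, n_trans, replace = TRUE),
                   dst = states[dst_i], stringsAsFactors = FALSE)
  fin <- stats::setNames(1, states[n_states])
  wfst(tr, initial = c("1" = 1), final = fin,
       input_alphabet = alphabet, output_alphabet = alphabet)
}

# random nucleotide string
rand_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# sliding-window n-gram count (independent of the package's counting code)
naive_count <- function(x, z) {
  n <- nchar(z); L <- nchar(x)
  if (L < n) return(0L)
  starts <- seq_len(L - n + 1L)
  sum(substring(x, starts, starts + n - 1L) == z)
}

# SVM dual by pairwise coordinate ascent (textbook SMO updates), independent
# of kernlab
smo_oracle <- function(K, d, C, sweeps = 300L, tol = 1e-12) {
  n <- length(d)
  a <- rep(0, n)
  for (sweep in seq_len(sweeps)) {
    delta <- 0
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      g <- as.vector(K %*% (a * d))
      Ei <- g[i] - d[i]
      Ej <- g[j] - d[j]
      s <- d[i] * d[j]
      eta <- K[i, i] + K[j, j] - 2 * K[i, j]
      if (eta <= 1e-12) next
      aj_new <- a[j] + d[j] * (Ei - Ej) / eta
      if (s == 1) {
        L <- max(0, a[i] + a[j] - C); H <- min(C, a[i] + a[j])
      } else {
        L <- max(0, a[j] - a[i]); H <- min(C, C + a[j] - a[i])
      }
      aj_new <- min(max(aj_new, L), H)
      ai_new <- a[i] + s * (a[j] - aj_new)
      delta <- delta + abs(aj_new - a[j])
      a[i] <- ai_new; a[j] <- aj_new
    }
    if (delta < tol) break
  }
  a
}

svm_dual_objective <- function(K, d, a) {
  sum(a) - 0.5 * as.numeric(t(a * d) %*% K %*% (a * d))
}

# trapezoidal area under the empirical ROC curve
trapezoid_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(c(Inf, thr, -Inf), function(t)
    mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(c(Inf, thr, -Inf), function(t)
    mean(scores[labels == -1] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
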