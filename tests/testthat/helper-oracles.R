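# Independent oracles and small fixtures, built in code at test time.

# Exhaustive DTW oracle: enumerates every monotone warping path from (1,1) to
# (n,m) with steps {(1,0),(0,1),(1,1)} and returns the minimum accumulated
# |a_i - b_j| cost. Branch-and-bound pruning keeps it exact.
dtw_enum <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return(invisible(NULL))
    if (i == n && j == m) {
      best <<- acc
      return(invisible(NULL))
    }
    if (i < n) rec(i + 1L, j, acc)
    if (j < m) rec(i, j + 1L, acc)
    if (i < n && j < m) rec(i + 1L, j + 1L, acc)
    invisible(NULL)
  }
  rec(1L, 1L, 0)
  best
}

# Shortest-path DTW oracle on the alignment graph (igraph), an algorithmically
# independent formulation of the same optimum.
dtw_igraph <- function(a, b) {
  n <- length(a); m <- length(b)
  id <- function(i, j) (i - 1L) * m + j
  from <- to <- integer(0); w <- numeric(0)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    steps <- list(c(i + 1L, j), c(i, j + 1L), c(i + 1L, j + 1L))
    for (s in steps) {
      if (s[1] <= n && s[2] <= m) {
        from <- c(from, id(i, j)); to <- c(to, id(s[1], s[2]))
        w <- c(w, abs(a[s[1]] - b[s[2]]))
      }
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = n * m, directed = TRUE)
  abs(a[1] - b[1]) +
    igraph::distances(g, v = id(1L, 1L), to = id(n, m), mode = "out",
                      weights = w)[1, 1]
}

# Direct-formula autocorrelation oracle (biased, mean-removed, normalised).
acf_brute <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  vapply(seq_len(n - 1), function(k)
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / denom, numeric(1))
}

# Small synthetic cohort shared across tests (cached per session).
tiny_cohort_env <- new.env()
tiny_cohort <- function() {
  if (is.null(tiny_cohort_env$cohort))
    tiny_cohort_env$cohort <-
      generate_cohort(cohort_config(group_sizes = c(30L, 30L, 20L), seed = 101L))
  tiny_cohort_env$cohort
}

# Restrict a feature matrix to a subject subset (by id), keeping structure.
fm_subset <- function(fm, ids) {
  i <- match(ids, fm$subject_ids)
  structure(list(subject_ids = ids, registry = fm$registry,
                 values = fm$values[i, , drop = FALSE],
                 mask = fm$mask[i, , drop = FALSE]),
            class = "feature_matrix")
}
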