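test_that("admissible cell count is n(n-k-1)/2 = C(n,2) - nk/2", {
  expect_equal(nws_admissible_count(7, 2), 14)
  expect_equal(nws_admissible_count(10, 4), 25)
  # independent check: count non-lattice pairs by circular-distance enumeration
  expect_equal(nws_admissible_count(10, 4), nrow(brute_nonlattice_pairs(10, 4)))
  for (n in 4:30) {
    for (k in seq(2, n - 2, by = 2)) {
      expect_equal(nws_admissible_count(n, k), choose(n, 2) - n * k / 2)
    }
  }
  expect_error(nws_admissible_count(10, 3), class = "streamnet_parameter_error")
})

test_that("flat index <-> cell <-> edge mappings match the worked 7-node ring", {
  # full rows flatten row-major; the triangular tail follows
  expect_equal(nws_cell_to_index(4, 0, 7, 2), 13)
  expect_equal(nws_cell_to_index(2, 2, 7, 2), 10)
  expect_equal(nws_cell_to_index(0, 0, 7, 2), 0)
  expect_equal(nws_index_to_edge(13, 7, 2), cbind(4, 6))
  expect_equal(nws_index_to_edge(0, 7, 2), cbind(0, 2))
  expect_error(nws_index_to_edge(14, 7, 2), class = "streamnet_index_error")
  expect_error(nws_index_to_edge(-1, 7, 2), class = "streamnet_index_error")
  expect_error(nws_cell_to_index(5, 0, 7, 2), class = "streamnet_index_error")
})

test_that("index_to_edge is a bijection onto the non-lattice pairs (n <= 12)", {
  for (n in 4:12) {
    for (k in seq(2, n - 2, by = 2)) {
      A <- nws_admissible_count(n, k)
      edges <- nws_index_to_edge(0:(A - 1), n, k)
      got <- sort(paste(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2]), sep = "-"))
      want <- sort(edge_key(brute_nonlattice_pairs(n, k)))
      expect_identical(got, want, info = sprintf("n=%d k=%d", n, k))
    }
  }
})

test_that("cell_to_index inverts index_to_edge's cell decoding everywhere", {
  for (n in c(9, 14, 23)) {
    for (k in seq(2, n - 2, by = 2)) {
      A <- nws_admissible_count(n, k)
      x <- 0:(A - 1)
      e <- nws_index_to_edge(x, n, k)
      r <- e[, 1]
      j <- (e[, 2] - r - k / 2 - 1) %% n   # invert the partner rule
      expect_equal(nws_cell_to_index(r, j, n, k), x,
                   info = sprintf("n=%d k=%d", n, k))
    }
  }
})

test_that("sample_distinct_integers draws uniformly, without replacement", {
  expect_equal(sample_distinct_integers(0, 99, random_source(1)), double(0))
  expect_equal(sort(sample_distinct_integers(10, 9, random_source(1))), 0:9)
  expect_error(sample_distinct_integers(11, 9, random_source(1)),
               class = "streamnet_parameter_error")
  # distinctness at scale, including ranges beyond 2^31
  big <- sample_distinct_integers(1000, 2^40, random_source(2))
  expect_equal(length(unique(big)), 1000)
  expect_true(all(big >= 0 & big <= 2^40))
  # uniformity: inclusion frequency of each of 10 integers at s=2
  reps <- 20000
  rng <- random_source(3)
  counts <- numeric(10)
  for (i in seq_len(reps)) {
    d <- sample_distinct_integers(2, 9, rng)
    counts[d + 1] <- counts[d + 1] + 1
  }
  for (i in 1:10) expect_in_ci99(counts[i] / reps, 0.2, reps)
  # dense fallback path (s > range/2) still uniform and distinct
  d <- sample_distinct_integers(8, 9, random_source(4))
  expect_equal(length(unique(d)), 8)
})

test_that("the efficient NWS sampler keeps the lattice and adds valid shortcuts", {
  expect_equal(edge_set(gen_nws(12, 4, 0, random_source(1))),
               edge_set(gen_ring_lattice(12, 4)))
  # p=1: S = Binomial(nk/2, 1) = nk/2 shortcuts, all distinct non-lattice pairs
  e <- stream_edges(gen_nws(7, 2, 1, random_source(2)))
  expect_equal(nrow(e), 14)
  lat <- edge_set(gen_ring_lattice(7, 2))
  sc <- edge_key(e[8:14, , drop = FALSE])
  expect_length(intersect(sc, lat), 0)
  # shortcuts never coincide with lattice edges, any parameters
  set.seed(102)  # parameter draws
  rng <- random_source(5)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    k <- sample(seq(2, n - 2, by = 2), 1)
    m <- suppressWarnings(stream_edges(gen_nws(n, k, 0.4, rng)))  # clamp possible
    nl <- n * k / 2
    if (nrow(m) > nl) {
      expect_length(intersect(edge_key(m[(nl + 1):nrow(m), , drop = FALSE]),
                              edge_set(gen_ring_lattice(n, k))), 0)
    }
    expect_false(any(duplicated(edge_key(m))))
  }
})

test_that("overfull binomial draws are clamped to the admissible cells", {
  # n=6, k=4: 12 lattice edges but only 3 admissible cells; p=1 forces S=12
  expect_warning(e <- stream_edges(gen_nws(6, 4, 1, random_source(1))),
                 "clamping")
  expect_equal(nrow(e), 12 + 3)
  expect_equal(edge_set(stream_from_matrix_test(6, e)), edge_set(gen_complete(6)))
})

test_that("the naive NWS oracle matches the lattice at p=0 and its mean count", {
  expect_equal(edge_set(gen_nws_naive(10, 2, 0, random_source(1))),
               edge_set(gen_ring_lattice(10, 2)))
  reps <- 2000
  rng <- random_source(6)
  counts <- vapply(seq_len(reps), function(i) {
    edge_count(gen_nws_naive(9, 2, 0.5, rng))
  }, numeric(1))
  # E|E| = nk/2 + (nk/2) p = 9 + 4.5; shortcut count is Binomial(9, 0.5)
  expect_in_ci99(mean(counts - 9) / 9, 0.5, reps * 9)
})

test_that("naive and efficient samplers agree on shortcut-edge frequencies", {
  # n=8, k=2: 20 admissible pairs; by ring symmetry each is equally likely
  # under both samplers, so pooled per-edge counts form one 2 x 20 table
  reps <- 3000
  n <- 8; k <- 2; p <- 0.6
  keys <- edge_key(brute_nonlattice_pairs(n, k))
  count_shortcuts <- function(gen, seed) {
    rng <- random_source(seed)
    tallies <- setNames(numeric(length(keys)), keys)
    for (i in seq_len(reps)) {
      m <- stream_edges(gen(n, k, p, rng))
      if (nrow(m) > n) {
        sc <- edge_key(m[(n + 1):nrow(m), , drop = FALSE])
        tallies[sc] <- tallies[sc] + 1
      }
    }
    tallies
  }
  t_naive <- count_shortcuts(gen_nws_naive, 21)
  t_eff <- count_shortcuts(gen_nws, 22)
  expect_gt(suppressWarnings(
    stats::chisq.test(rbind(t_naive, t_eff))$p.value), 0.01)
})

test_that("small-world graphs are always connected", {
  set.seed(103)  # parameter draws
  rng <- random_source(8)
  for (i in 1:40) {
    n <- sample(6:50, 1)
    k <- sample(seq(2, min(n - 2, 10), by = 2), 1)
    p <- stats::runif(1)
    expect_true(suppressWarnings(is_connected(gen_nws(n, k, p, rng))),
                info = sprintf("n=%d k=%d p=%.2f", n, k, p))
  }
})
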