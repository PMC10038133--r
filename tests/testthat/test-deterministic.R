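test_that("complete graphs emit every unordered pair in lexicographic order", {
  expect_equal(stream_edges(gen_complete(3)), cbind(c(0, 0, 1), c(1, 2, 2)))
  expect_equal(nrow(stream_edges(gen_complete(1))), 0)
  expect_equal(edge_count(gen_complete(5)), 10)
  # order and content match an independent enumeration
  expect_equal(stream_edges(gen_complete(7)), all_pairs(7))
})

test_that("path and cycle graphs are chains, the cycle closing on itself", {
  expect_equal(stream_edges(gen_path(4)), cbind(0:2, 1:3))
  expect_equal(nrow(stream_edges(gen_path(1))), 0)
  expect_equal(stream_edges(gen_path(2)), cbind(0, 1))
  expect_equal(stream_edges(gen_cycle(3)), cbind(c(0, 1, 2), c(1, 2, 0)))
  expect_equal(degree_histogram(gen_cycle(4)), c("2" = 4L))
  expect_error(gen_cycle(2), class = "streamnet_parameter_error")
})

test_that("barbell graphs wire bell A, bell B, then the connecting path", {
  expect_equal(stream_edges(gen_barbell(2, 0)),
               rbind(c(0, 1), c(2, 3), c(1, 2)))
  expect_equal(edge_count(gen_barbell(3, 0)), 7)   # n1(n1-1) + n2 + 1
  expect_equal(edge_count(gen_barbell(2, 1)), 4)
  expect_true(is_connected(gen_barbell(3, 2)))
  expect_true(is_connected(gen_barbell(2, 5)))
  expect_error(gen_barbell(1, 3), class = "streamnet_parameter_error")
  # path nodes sit between the bells: labels cover 0 .. 2*n1+n2-1
  m <- stream_edges(gen_barbell(3, 4))
  expect_equal(sort(unique(as.vector(m))), 0:9)
})

test_that("ring lattices give every node degree k, once per forward offset", {
  expect_equal(edge_count(gen_ring_lattice(7, 4)), 14)  # nk/2
  expect_equal(degree_histogram(gen_ring_lattice(7, 4)), c("4" = 7L))
  expect_error(gen_ring_lattice(5, 3), class = "streamnet_parameter_error")
  expect_error(gen_ring_lattice(5, 3), "even")
  expect_error(gen_ring_lattice(6, 6), class = "streamnet_parameter_error")
  expect_error(gen_ring_lattice(6, 0), class = "streamnet_parameter_error")
})

test_that("RingLattice(n, 2) and Cycle(n) are the same graph", {
  for (n in c(4, 5, 6, 9, 12, 17)) {
    expect_equal(edge_set(gen_ring_lattice(n, 2)), edge_set(gen_cycle(n)),
                 info = paste("n =", n))
  }
})

test_that("edge counts match their closed forms across parameter sweeps", {
  for (n in c(1, 2, 3, 7, 20)) {
    expect_equal(edge_count(gen_complete(n)), n * (n - 1) / 2)
    expect_equal(edge_count(gen_path(n)), max(n - 1, 0))
    expect_equal(edge_count(gen_empty(n)), 0)
  }
  for (n in c(3, 8, 21)) expect_equal(edge_count(gen_cycle(n)), n)
  for (prm in list(c(2, 0), c(2, 3), c(5, 0), c(4, 7))) {
    expect_equal(edge_count(gen_barbell(prm[1], prm[2])),
                 prm[1] * (prm[1] - 1) + prm[2] + 1)
  }
  for (n in c(6, 11, 16)) {
    for (k in seq(2, n - 2, by = 2)) {
      expect_equal(edge_count(gen_ring_lattice(n, k)), n * k / 2)
    }
  }
})

test_that("huge deterministic graphs yield bounded prefixes instantly", {
  # retained state is independent of n: only the requested prefix is built
  expect_equal(stream_take(gen_complete(1e8), 3), cbind(0, 1:3))
  expect_equal(stream_take(gen_path(1e12), 2), cbind(c(0, 1), c(1, 2)))
  expect_equal(stream_take(gen_ring_lattice(1e10, 4), 2),
               cbind(c(0, 0), c(1, 2)))
  expect_equal(stream_take(gen_cycle(1e12), 1), cbind(0, 1))
  expect_equal(stream_take(gen_barbell(1e6, 1e6), 1), cbind(0, 1))
})

test_that("generators honour the optional byte-width cap", {
  expect_error(gen_path(300, width = 1), class = "streamnet_width_error")
  expect_silent(gen_path(255, width = 1))
  expect_error(gen_barbell(40000, 0, width = 2),
               class = "streamnet_width_error")  # 2*n1 > 65535
})
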