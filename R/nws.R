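#' Newman–Watts–Strogatz small-world samplers
#'
#' The Newman–Watts–Strogatz (NWS) model starts from the ring lattice
#' `RingLattice(n, k)` and, for each of its `nk/2` edges, adds a random
#' "shortcut" edge with probability `p`.  Because the lattice is never
#' removed (no rewiring, unlike Watts–Strogatz), every sampled graph is
#' connected.
#'
#' `gen_nws()` is the memory-efficient sampler: it streams the lattice edges
#' without storing them, draws the number of shortcuts in one go as
#' `S ~ Binomial(nk/2, p)` (the `nk/2` Bernoulli trials are exchangeable),
#' samples `S` distinct flat indices uniformly from the
#' `n(n-k-1)/2` admissible shortcut cells, and maps each index to its edge
#' through the exact bijection implemented by [nws_index_to_edge()].  Only
#' the `S` shortcut edges are ever held in memory.
#'
#' `gen_nws_naive()` is the reference implementation used as a
#' distributional oracle in tests: it materializes the lattice adjacency and,
#' per lattice edge `(u, v)`, adds with probability `p` a shortcut `(u, w)`
#' with `w` drawn uniformly from the nodes not already adjacent to `u` (and
#' `!= u`).  It needs O(n^2) memory and is restricted to test-scale `n`.
#'
#' When `k > (n-1)/2` there are more lattice edges than admissible shortcut
#' cells, so `Binomial(nk/2, p)` can exceed the number of cells; the draw is
#' then clamped to the admissible count, with a warning.
#'
#' @param n node count.
#' @param k even ring-lattice degree, `2 <= k <= n - 2`.
#' @param p shortcut probability in `[0, 1]` (one Bernoulli trial per lattice
#'   edge).
#' @param rng a [random_source()].
#' @param width optional byte width cap, as in [gen_complete()].
#' @return an [edge_stream()]: the `nk/2` lattice edges in ring-lattice
#'   order, then the `S` shortcut edges in sampling order.
#' @name newman_watts_strogatz
#' @examples
#' ec <- edge_count(gen_nws(20, 4, 0.1, random_source(1)))
#' ec >= 40  # at least the nk/2 lattice edges
#' is_connected(gen_nws(30, 2, 0.5, random_source(2)))
NULL

#' Number of admissible shortcut cells
#'
#' Each node can gain `n - k - 1` shortcut partners (everyone except itself
#' and its `k` lattice neighbours); halving for undirectedness gives
#' `n(n-k-1)/2` admissible cells, which always equals
#' `choose(n, 2) - nk/2`.  Exact integer arithmetic (the product is even for
#' even `k`).
#'
#' @inheritParams newman_watts_strogatz
#' @return the admissible cell count as a double.
#' @examples
#' nws_admissible_count(7, 2)  # 14
#' @export
nws_admissible_count <- function(n, k) {
  n <- check_n(n)
  k <- check_ring_k(n, k)
  n * (n - k - 1) / 2
}

#' Flatten an admissible shortcut cell to its array index
#'
#' The admissible cells form an `n` by `n-k-1` matrix (row `r` = lower node,
#' column `j` = offset position; the cell holds partner
#' `w = (r + k/2 + 1 + j) mod n`) with the redundant lower-right half
#' disregarded: rows `0 .. k/2` are full (length `n-k-1`), row `k/2 + i`
#' then loses `i` cells, and rows from `n - k/2 - 1` on are empty.
#' Admissible cells are numbered row-major; this function returns that
#' number.  Inverse of [nws_index_to_edge()]'s index-to-cell step.
#'
#' @param r row (lower node), vectorized.
#' @param j column within the row, vectorized.
#' @inheritParams newman_watts_strogatz
#' @return the 0-based flat index, exact integer arithmetic throughout.
#' @examples
#' nws_cell_to_index(4, 0, 7, 2)  # 13, the last admissible cell
#' nws_cell_to_index(2, 2, 7, 2)  # 10
#' @export
nws_cell_to_index <- function(r, j, n, k) {
  n <- check_n(n)
  k <- check_ring_k(n, k)
  if (length(r) != length(j)) param_error("r and j must have equal length")
  L <- n - k - 1
  half <- k / 2
  rowlen <- ifelse(r <= half, L, L - (r - half))
  bad <- !is.finite(r) | !is.finite(j) | r != floor(r) | j != floor(j) |
    r < 0 | j < 0 | j >= rowlen | r > n - half - 2
  if (any(bad)) {
    index_error("cell (%s, %s) is not an admissible shortcut cell for n=%s, k=%s",
                format(r[bad][1]), format(j[bad][1]), format(n), format(k))
  }
  i <- pmax(r - half, 0)                      # tail row number (0 for full rows)
  tail_before <- (i - 1) * L - (i - 1) * i / 2  # cells in tail rows before row r
  ifelse(r <= half, r * L + j, (half + 1) * L + tail_before + j)
}

#' Map a flat shortcut index to its edge
#'
#' Inverts the row-major flattening of the admissible-cell matrix and then
#' applies the cell-to-partner rule `w = (r + k/2 + 1 + j) mod n`.  Indices
#' `x < (k/2 + 1)(n - k - 1)` fall in the full rows and invert by integer
#' division; the rest lie in the triangular tail of row lengths
#' `n-k-2, n-k-3, ..., 1`, inverted by a square-root estimate corrected with
#' exact integer comparisons, so the bijection is exact for all
#' representable node counts.  Over `x = 0 .. n(n-k-1)/2 - 1` this is a
#' bijection onto exactly the unordered node pairs that are not ring-lattice
#' edges.
#'
#' @param x 0-based flat index (vectorized), in `[0, nws_admissible_count(n, k))`.
#' @inheritParams newman_watts_strogatz
#' @return a two-column matrix of edges `(r, w)`, one row per index.
#' @examples
#' nws_index_to_edge(13, 7, 2)  # edge (4, 6)
#' nws_index_to_edge(0, 7, 2)   # edge (0, 2)
#' @export
nws_index_to_edge <- function(x, n, k) {
  n <- check_n(n)
  k <- check_ring_k(n, k)
  total <- n * (n - k - 1) / 2
  if (length(x) && (any(!is.finite(x)) || any(x != floor(x)) ||
                    any(x < 0) || any(x >= total))) {
    index_error("shortcut index out of range [0, %s)",
                format(total, scientific = FALSE))
  }
  L <- n - k - 1
  half <- k / 2
  full <- (half + 1) * L        # cells in the full rows
  r <- x %/% L                  # full-row guess
  j <- x %% L
  in_tail <- x >= full
  if (any(in_tail)) {
    y <- x[in_tail] - full
    # largest a with S(a) = a*L - a(a+1)/2 <= y  (cells in tail rows 1..a)
    S <- function(a) a * L - a * (a + 1) / 2
    a <- floor((L - 0.5) - sqrt(pmax((L - 0.5)^2 - 2 * y, 0)))
    a <- pmax(a, 0)
    for (it in 1:2) {
      a <- a - (S(a) > y)
      a <- a + (S(a + 1) <= y)
    }
    r[in_tail] <- half + a + 1
    j[in_tail] <- y - S(a)
  }
  w <- (r + half + 1 + j) %% n
  cbind(r, w, deparse.level = 0)
}

#' Sample distinct integers uniformly without replacement
#'
#' Draws `s` distinct integers uniformly from `0 .. upper` in O(s) memory,
#' independent of the size of the range: candidates are drawn uniformly and
#' de-duplicated until `s` survive (cheap while `s` is at most half the
#' range), falling back to R's without-replacement sampler when `s` is a
#' large fraction of the range (where the range is itself O(s)).
#'
#' @param s how many integers to draw, `0 <= s <= upper + 1`.
#' @param upper inclusive upper bound of the range (may exceed 2^31).
#' @param rng a [random_source()].
#' @return a numeric vector of `s` distinct integers, in draw order.
#' @examples
#' sort(sample_distinct_integers(3, 9, random_source(1)))
#' @export
sample_distinct_integers <- function(s, upper, rng = random_source()) {
  if (!is_count(s)) param_error("s must be a non-negative integer")
  if (!is_count(upper)) param_error("upper must be a non-negative integer")
  N <- upper + 1
  if (s > N) param_error("cannot draw %s distinct integers from a range of %s",
                         format(s), format(N, scientific = FALSE))
  if (s == 0) return(double(0))
  rs_eval(rng, function() {
    if (s > N / 2) return(sample.int(N, s) - 1)
    acc <- double(0)
    while (length(acc) < s) {
      need <- s - length(acc)
      acc <- unique(c(acc, runif_int(ceiling(1.5 * need) + 8, upper)))
    }
    acc[seq_len(s)]
  })
}

#' @rdname newman_watts_strogatz
#' @export
gen_nws <- function(n, k, p, rng = random_source(), width = NULL) {
  n <- check_n(n)
  k <- check_ring_k(n, k)
  p <- check_prob(p)
  check_width_cap(n, width)
  lattice_edges <- n * k / 2
  admissible <- n * (n - k - 1) / 2
  shortcut_stream <- function() {
    S <- rs_eval(rng, function() stats::rbinom(1, lattice_edges, p))
    if (S > admissible) {
      warning(sprintf(paste0(
        "Binomial(nk/2, p) drew %s shortcuts but only %s admissible cells ",
        "exist (k > (n-1)/2); clamping"),
        format(S), format(admissible, scientific = FALSE)))
      S <- admissible
    }
    idx <- sample_distinct_integers(S, admissible - 1, rng)
    stream_from_matrix(n, nws_index_to_edge(idx, n, k))
  }
  stream_concat(n, list(
    function() gen_ring_lattice(n, k),
    shortcut_stream
  ))
}

#' @rdname newman_watts_strogatz
#' @export
gen_nws_naive <- function(n, k, p, rng = random_source(), width = NULL) {
  n <- check_n(n)
  k <- check_ring_k(n, k)
  p <- check_prob(p)
  check_width_cap(n, width)
  if (n > 2000) param_error("gen_nws_naive is a test-scale oracle (n too large)")
  lat <- stream_edges(gen_ring_lattice(n, k))
  edges <- rs_eval(rng, function() {
    adj <- matrix(FALSE, n, n)                 # adj[u+1, w+1]
    diag(adj) <- TRUE                          # bars self-loops
    adj[cbind(lat[, 1] + 1, lat[, 2] + 1)] <- TRUE
    adj[cbind(lat[, 2] + 1, lat[, 1] + 1)] <- TRUE
    shortcuts <- list()
    coin <- stats::runif(nrow(lat)) < p
    for (i in which(coin)) {
      u <- lat[i, 1]
      candidates <- which(!adj[u + 1, ]) - 1
      if (length(candidates) == 0L) next       # u already adjacent to everyone
      w <- candidates[floor(stats::runif(1) * length(candidates)) + 1]
      adj[u + 1, w + 1] <- TRUE
      adj[w + 1, u + 1] <- TRUE
      shortcuts[[length(shortcuts) + 1L]] <- c(u, w)
    }
    rbind(lat, do.call(rbind, c(shortcuts, list(matrix(numeric(0), 0, 2)))))
  })
  stream_from_matrix(n, edges)
}
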