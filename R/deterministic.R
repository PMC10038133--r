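#' Deterministic contact-network models
#'
#' Constant-memory streaming generators for the non-random models: complete,
#' path, barbell, cycle, ring lattice, and empty graphs.  Each returns a lazy
#' [edge_stream()]; none ever materializes the network.  Emission order is
#' part of this package's contract (it makes seeded binary output
#' byte-reproducible):
#'
#' * complete: unordered pairs `(u, v)`, `u < v`, in lexicographic order;
#' * path / cycle: chain edges `(i, i+1)`, the cycle closing with `(n-1, 0)`;
#' * barbell: bell A, bell B, then the connecting path;
#' * ring lattice: for each node `u` in order, forward offsets `d = 1..k/2`,
#'   emitting `(u, (u+d) mod n)`.
#'
#' @param n node count (`>= 1`; `>= 3` for a cycle, which would otherwise
#'   need self-loops or duplicate edges; `>= 4` for a ring lattice).
#' @param width optional byte width (1, 2, 4 or 8); when given, `n` must not
#'   exceed [max_nodes()] for that width.
#' @return an [edge_stream()].
#' @name deterministic_models
#' @examples
#' stream_edges(gen_complete(3))         # (0,1) (0,2) (1,2)
#' edge_count(gen_barbell(3, 0))         # n1*(n1-1) + n2 + 1 = 7
#' degree_histogram(gen_ring_lattice(8, 4))  # all 8 nodes have degree 4
NULL

# Lexicographic walk over unordered pairs of 0..n-1; shared by the complete
# graph and the naive G(n,p) sampler.  Returns a closure(size) -> matrix|NULL.
make_pair_walker <- function(n) {
  u <- 0
  v <- 1
  function(size) {
    if (u > n - 2) return(NULL)
    us <- list()
    vs <- list()
    rows <- 0
    while (rows < size && u <= n - 2) {
      avail <- (n - 1) - v + 1
      take <- min(avail, size - rows)
      us[[length(us) + 1L]] <- rep(u, take)
      vs[[length(vs) + 1L]] <- v + seq_len(take) - 1
      v <<- v + take
      rows <- rows + take
      if (v > n - 1) {
        u <<- u + 1
        v <<- u + 1
      }
    }
    cbind(unlist(us), unlist(vs))
  }
}

#' @rdname deterministic_models
#' @export
gen_complete <- function(n, width = NULL) {
  n <- check_n(n)
  check_width_cap(n, width)
  walker <- make_pair_walker(n)
  edge_stream(n, walker)
}

#' @rdname deterministic_models
#' @export
gen_path <- function(n, width = NULL) {
  n <- check_n(n)
  check_width_cap(n, width)
  i <- 0
  edge_stream(n, function(size) {
    if (i > n - 2) return(NULL)
    take <- min(size, (n - 1) - i)
    is <- i + seq_len(take) - 1
    i <<- i + take
    cbind(is, is + 1)
  })
}

#' @rdname deterministic_models
#' @export
gen_cycle <- function(n, width = NULL) {
  n <- check_n(n)
  if (n < 3) param_error("cycle requires n >= 3 (got %s)", format(n))
  check_width_cap(n, width)
  stream_concat(n, list(
    function() gen_path(n),
    function() stream_from_matrix(n, cbind(n - 1, 0))
  ))
}

#' @param n1 barbell bell size (each bell is a complete graph on `n1 >= 2`
#'   nodes).
#' @param n2 barbell path length (`n2 >= 0` nodes between the bells; with
#'   `n2 = 0` the bells are bridged by a single edge).
#' @rdname deterministic_models
#' @export
gen_barbell <- function(n1, n2, width = NULL) {
  n1 <- check_n(n1, min = 2, what = "n1")
  n2 <- check_n(n2, min = 0, what = "n2")
  n <- 2 * n1 + n2
  check_width_cap(n, width)
  # Bell A on 0..n1-1, bell B on n1..2n1-1, path on 2n1..2n1+n2-1; the path
  # (or, if n2 = 0, a direct bridge) joins node n1-1 of A to node n1 of B.
  link <- if (n2 == 0) {
    cbind(n1 - 1, n1)
  } else {
    p <- 2 * n1 + seq_len(max(n2 - 1, 0)) - 1
    rbind(cbind(n1 - 1, 2 * n1),
          cbind(p, p + 1),
          cbind(2 * n1 + n2 - 1, n1))
  }
  stream_concat(n, list(
    function() gen_complete(n1),
    function() stream_offset(gen_complete(n1), n1, n),
    function() stream_from_matrix(n, link)
  ))
}

#' @param k ring-lattice degree: each node is joined to its `k/2` nearest
#'   neighbours on each side, so `k` must be even, with `2 <= k <= n - 2`
#'   (larger `k` would force duplicate edges under the mod-`n` offsets).
#' @rdname deterministic_models
#' @export
gen_ring_lattice <- function(n, k, width = NULL) {
  n <- check_n(n)
  k <- check_ring_k(n, k)
  check_width_cap(n, width)
  half <- k / 2
  total <- n * half          # = nk/2 edges
  t0 <- 0                    # linear position: t = u*half + (d-1)
  edge_stream(n, function(size) {
    if (t0 >= total) return(NULL)
    take <- min(size, total - t0)
    ts <- t0 + seq_len(take) - 1
    t0 <<- t0 + take
    u <- ts %/% half
    d <- ts %% half + 1
    cbind(u, (u + d) %% n)
  })
}

check_ring_k <- function(n, k) {
  if (!is_count(k)) param_error("k must be a non-negative integer")
  if (k %% 2 != 0) param_error("k must be even (got %s): each node takes k/2 neighbours per side", format(k))
  if (k < 2 || k > n - 2) {
    param_error("k must satisfy 2 <= k <= n - 2 (got k = %s, n = %s)",
                format(k), format(n))
  }
  as.double(k)
}

#' @rdname deterministic_models
#' @export
gen_empty <- function(n, width = NULL) {
  n <- check_n(n)
  check_width_cap(n, width)
  edge_stream(n, function(size) NULL)
}
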