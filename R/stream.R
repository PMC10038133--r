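#' Lazy edge streams
#'
#' An `edge_stream` is a single-use iterator over the edges of an undirected
#' graph on nodes `0 .. n-1`.  Edges are produced in chunks (two-column
#' numeric matrices, one row per edge) on demand, so consuming a bounded
#' prefix of a stream never requires generating -- or storing -- the whole
#' network.  This is what lets the package write global-scale contact
#' networks in constant memory.
#'
#' Streams are deliberately cheap objects: a declared node count plus a
#' chunk-producing closure.  They are exhausted by consumption; to iterate a
#' network twice, build the stream twice (stochastic generators rebuilt from
#' the same seed yield edge-for-edge identical streams).
#'
#' @param n declared node count (nodes are `0 .. n-1`; isolated nodes are
#'   allowed and carried by `n`, not by edges).
#' @param next_chunk function of one argument `size` returning the next chunk
#'   as a two-column numeric matrix, or `NULL` when the stream is exhausted.
#'   `size` is a hint: chunks may be larger or smaller, but must be bounded.
#' @return an object of class `edge_stream`.
#' @seealso [stream_take()], [stream_edges()], [edge_count()]
#' @export
edge_stream <- function(n, next_chunk) {
  stopifnot(is.function(next_chunk))
  structure(list(n = as.double(n), next_chunk = next_chunk),
            class = "edge_stream")
}

#' @export
print.edge_stream <- function(x, ...) {
  cat(sprintf("<edge_stream: n = %s, lazy>\n", format(x$n, scientific = FALSE)))
  invisible(x)
}

#' Pull the next chunk of edges from a stream
#'
#' @param stream an [edge_stream()].
#' @param size chunk-size hint (rows).
#' @return a two-column matrix of edges, or `NULL` if exhausted.
#' @export
stream_next <- function(stream, size = 65536L) {
  stopifnot(inherits(stream, "edge_stream"))
  stream$next_chunk(size)
}

#' Take the first k edges of a stream
#'
#' Consumes just enough of the stream to return its first `k` edges (fewer if
#' the stream ends first).  Runs in time and memory proportional to `k`, not
#' to the full edge count -- e.g. the first 10 edges of `gen_complete(1e8)`
#' are available in milliseconds.
#'
#' @param stream an [edge_stream()].
#' @param k number of edges wanted.
#' @return a two-column numeric matrix with at most `k` rows.
#' @export
stream_take <- function(stream, k) {
  stopifnot(inherits(stream, "edge_stream"), is_count(k))
  got <- list()
  have <- 0
  while (have < k) {
    ch <- stream$next_chunk(min(k - have, 65536))
    if (is.null(ch)) break
    got[[length(got) + 1L]] <- ch
    have <- have + nrow(ch)
  }
  out <- do.call(rbind, c(got, list(matrix(numeric(0), 0, 2))))
  dimnames(out) <- NULL
  if (nrow(out) > k) out <- out[seq_len(k), , drop = FALSE]
  out
}

#' Materialize a whole stream (test scale)
#'
#' Fully consumes the stream into one matrix.  This defeats the streaming
#' memory contract by design and is intended for inspection and testing.
#'
#' @inheritParams stream_take
#' @return a two-column numeric matrix of all edges, in emission order.
#' @export
stream_edges <- function(stream) {
  stopifnot(inherits(stream, "edge_stream"))
  got <- list()
  repeat {
    ch <- stream$next_chunk(65536L)
    if (is.null(ch)) break
    got[[length(got) + 1L]] <- ch
  }
  out <- do.call(rbind, c(got, list(matrix(numeric(0), 0, 2))))
  dimnames(out) <- NULL
  out
}

#' Count the edges of a stream
#'
#' Fully consumes the stream, keeping only a running total (constant memory).
#'
#' @inheritParams stream_take
#' @return the number of edges produced.
#' @export
edge_count <- function(stream) {
  stopifnot(inherits(stream, "edge_stream"))
  total <- 0
  repeat {
    ch <- stream$next_chunk(65536L)
    if (is.null(ch)) break
    total <- total + nrow(ch)
  }
  total
}

#' Degree histogram of a stream (test scale)
#'
#' Tallies node degrees, including degree-0 nodes implied by the declared
#' node count.  Requires O(n) memory and is therefore a test-scale utility,
#' exempt from the streaming contract.
#'
#' @inheritParams stream_take
#' @return a named integer vector: `names` are degrees, values the number of
#'   nodes with that degree.  `sum(degree * count)` equals twice the edge
#'   count.
#' @export
degree_histogram <- function(stream) {
  stopifnot(inherits(stream, "edge_stream"))
  n <- stream$n
  if (n > 1e8) param_error("degree_histogram is a test-scale utility (n too large)")
  deg <- integer(max(n, 0))
  repeat {
    ch <- stream$next_chunk(65536L)
    if (is.null(ch)) break
    deg <- deg + tabulate(as.integer(c(ch[, 1], ch[, 2])) + 1L, nbins = n)
  }
  tb <- table(deg)
  out <- as.integer(tb)
  names(out) <- names(tb)
  out
}

#' Is the streamed graph connected? (test scale)
#'
#' Union-find over the edges plus the declared node count; O(n) memory, so a
#' test-scale utility exempt from the streaming contract.  A graph with a
#' single node is connected; one with zero nodes is not.
#'
#' @inheritParams stream_take
#' @return `TRUE` if every pair of the `n` nodes is joined by a path.
#' @export
is_connected <- function(stream) {
  stopifnot(inherits(stream, "edge_stream"))
  n <- stream$n
  if (n > 1e8) param_error("is_connected is a test-scale utility (n too large)")
  if (n < 1) return(FALSE)
  if (n == 1) return(TRUE)
  parent <- seq_len(n)  # 1-based
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]  # path halving
      i <- parent[i]
    }
    i
  }
  comps <- n
  repeat {
    ch <- stream$next_chunk(65536L)
    if (is.null(ch)) break
    for (r in seq_len(nrow(ch))) {
      a <- find(as.integer(ch[r, 1]) + 1L)
      b <- find(as.integer(ch[r, 2]) + 1L)
      if (a != b) {
        parent[b] <- a
        comps <- comps - 1L
        if (comps == 1L) break
      }
    }
  }
  comps == 1L
}

# Stream over an in-memory edge matrix (used by readers, NWS shortcuts, tests).
stream_from_matrix <- function(n, mat) {
  mat <- as.matrix(mat)
  dimnames(mat) <- NULL
  pos <- 0L
  edge_stream(n, function(size) {
    if (pos >= nrow(mat)) return(NULL)
    take <- min(size, nrow(mat) - pos)
    out <- mat[pos + seq_len(take), , drop = FALSE]
    pos <<- pos + take
    out
  })
}

# Concatenate sub-streams; makers are zero-argument closures so each
# sub-stream is created only when reached.
stream_concat <- function(n, makers) {
  idx <- 1L
  cur <- NULL
  edge_stream(n, function(size) {
    repeat {
      if (is.null(cur)) {
        if (idx > length(makers)) return(NULL)
        cur <<- makers[[idx]]()
        idx <<- idx + 1L
      }
      ch <- cur$next_chunk(size)
      if (!is.null(ch)) return(ch)
      cur <<- NULL
    }
  })
}

# Relabel a stream's nodes by a constant offset.
stream_offset <- function(stream, delta, n) {
  edge_stream(n, function(size) {
    ch <- stream$next_chunk(size)
    if (is.null(ch)) NULL else ch + delta
  })
}

#' Largest node count representable at a given byte width
#'
#' Node identifiers are stored on disk as fixed-width unsigned integers of
#' `b` bytes, so a width supports labels `0 .. 2^(8b) - 1`: 255 for 1 byte,
#' 65,535 for 2 bytes, about 4.3 billion for 4 bytes, and about 1.8e19 for
#' 8 bytes (in-memory arithmetic additionally caps exact labels at `2^53`,
#' the double-precision integer limit).
#'
#' @param width bytes per node identifier; one of 1, 2, 4, 8.
#' @return `2^(8 * width) - 1` as a double.
#' @examples
#' max_nodes(2)  # 65535
#' @export
max_nodes <- function(width) {
  if (!is_count(width) || !(width %in% c(1, 2, 4, 8))) {
    width_error("unsupported node width %s: must be one of 1, 2, 4, 8",
                paste(format(width), collapse = ","))
  }
  2^(8 * width) - 1
}

# Shared by generators that accept an optional width cap.
check_width_cap <- function(n, width) {
  if (is.null(width)) return(invisible(n))
  if (n > max_nodes(width)) {
    width_error("n = %s exceeds the %d-byte node limit of %s",
                format(n, scientific = FALSE), as.integer(width),
                format(max_nodes(width), scientific = FALSE))
  }
  invisible(n)
}
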