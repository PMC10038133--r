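#' Barabási–Albert preferential-attachment sampler
#'
#' Grows a scale-free network: nodes `0 .. m-1` form the initial target set,
#' and each new node `v = m .. n-1` attaches to `m` distinct existing nodes
#' drawn uniformly from a list of repeated endpoints (each past endpoint
#' appears once per incident edge, which is exactly degree-proportional
#' sampling), redrawing on duplicates.  After each step `v`'s `m` targets and
#' `m` copies of `v` are appended to that list.
#'
#' Every sampled graph is simple, connected, and has exactly `m * (n - m)`
#' edges, so the repeated-endpoints working array can be reserved up-front at
#' its final length `2 m (n - m)`.  This is the one generator whose working
#' set grows with `n` (O(nm)); emission itself is still chunked and lazy.
#'
#' The very first new node (`v = m`) must attach to all of `0 .. m-1` -- the
#' only `m` distinct targets available -- and does so directly, without
#' consuming random draws.
#'
#' @param n node count.
#' @param m edges attached per new node, `1 <= m < n`.
#' @param rng a [random_source()].
#' @param width optional byte width cap, as in [gen_complete()].
#' @return an [edge_stream()]; each edge is emitted as `(new node, target)`.
#' @examples
#' edge_count(gen_ba(10, 3, random_source(1)))  # exactly 3 * (10 - 3) = 21
#' is_connected(gen_ba(50, 1, random_source(2)))
#' @export
gen_ba <- function(n, m, rng = random_source(), width = NULL) {
  n <- check_n(n)
  if (!is_count(m, min = 1) || m >= n) {
    param_error("m must satisfy 1 <= m < n (got m = %s, n = %s)",
                paste(format(m), collapse = ","), format(n))
  }
  m <- as.double(m)
  check_width_cap(n, width)

  repeatv <- NULL   # allocated at first chunk: 2 endpoints per final edge
  rlen <- 0
  v <- m            # next node to wire in

  edge_stream(n, function(size) {
    if (v > n - 1) return(NULL)
    if (is.null(repeatv)) repeatv <<- double(2 * m * (n - m))
    rs_eval(rng, function() {
      out <- list()
      emitted <- 0
      while (emitted < size && v <= n - 1) {
        if (v == m) {
          targets <- seq_len(m) - 1
        } else {
          targets <- double(m)
          cnt <- 0L
          while (cnt < m) {
            t <- repeatv[floor(stats::runif(1) * rlen) + 1]
            if (cnt == 0L || !any(targets[seq_len(cnt)] == t)) {
              cnt <- cnt + 1L
              targets[cnt] <- t
            }
          }
        }
        out[[length(out) + 1L]] <- cbind(rep(v, m), targets)
        repeatv[rlen + seq_len(m)] <<- targets
        repeatv[rlen + m + seq_len(m)] <<- rep(v, m)
        rlen <<- rlen + 2 * m
        emitted <- emitted + m
        v <<- v + 1
      }
      do.call(rbind, out)
    })
  })
}
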