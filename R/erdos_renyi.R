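#' Erdős–Rényi G(n, p) samplers
#'
#' Two streaming samplers for the G(n, p) model, in which each of the
#' `choose(n, 2)` possible edges is included independently with probability
#' `p`.  Both hold O(1) state beyond the chunk being emitted and produce
#' identically distributed graphs:
#'
#' * `gen_er_naive()` walks every unordered pair in lexicographic order and
#'   flips a Bernoulli(p) coin per pair -- O(n^2) time.
#' * `gen_er_fast()` skip-samples: the gap to the next included pair is
#'   geometric, `1 + floor(log(1 - r) / log(1 - p))` with `r ~ Uniform(0,1)`,
#'   so only included pairs are visited and expected time is O(n + |E|),
#'   far faster on the sparse graphs typical of contact networks.  Landed-on
#'   positions are decoded to pairs by exact integer arithmetic.  `p = 0`
#'   (no draws) and `p = 1` (complete walk; `log(1-p)` is undefined) are
#'   special-cased.
#'
#' @param n node count.
#' @param p edge-inclusion probability in `[0, 1]`.
#' @param rng a [random_source()].
#' @param width optional byte width cap, as in [gen_complete()].
#' @return an [edge_stream()] with edges in lexicographic order.
#' @name erdos_renyi
#' @examples
#' edge_count(gen_er_naive(5, 1, random_source(1)))  # 10 = choose(5,2)
#' e <- stream_edges(gen_er_fast(100, 0.05, random_source(7)))
NULL

#' @rdname erdos_renyi
#' @export
gen_er_naive <- function(n, p, rng = random_source(), width = NULL) {
  n <- check_n(n)
  p <- check_prob(p)
  check_width_cap(n, width)
  walker <- make_pair_walker(n)
  edge_stream(n, function(size) {
    repeat {
      block <- walker(max(size, 4096L))
      if (is.null(block)) return(NULL)
      keep <- rs_eval(rng, function() stats::runif(nrow(block)) < p)
      if (any(keep)) return(block[keep, , drop = FALSE])
      # no hits in this block of pairs: keep scanning
    }
  })
}

#' @rdname erdos_renyi
#' @export
gen_er_fast <- function(n, p, rng = random_source(), width = NULL) {
  n <- check_n(n)
  p <- check_prob(p)
  check_width_cap(n, width)
  if (p == 0) return(gen_empty(n))
  if (p == 1) return(gen_complete(n))
  total <- n * (n - 1) / 2
  if (total > MAX_EXACT) {
    param_error("n too large for exact pair indexing (choose(n,2) > 2^53)")
  }
  pos <- -1      # index of the last included pair
  done <- FALSE
  log1mp <- log1p(-p)
  edge_stream(n, function(size) {
    if (done) return(NULL)
    b <- min(max(size, 1L), 65536L)
    cand <- rs_eval(rng, function() {
      gaps <- floor(log1p(-stats::runif(b)) / log1mp)
      pos + cumsum(1 + gaps)
    })
    keep <- cand < total
    if (all(keep)) {
      pos <<- cand[b]
    } else {
      done <<- TRUE
      cand <- cand[keep]
      if (length(cand) == 0L) return(NULL)
    }
    pair_from_index(cand, n)
  })
}

# Decode 0-based lexicographic pair indices to pairs (u, v), u < v.
# f(u) = u*n - u*(u+1)/2 pairs precede row u; invert with a float sqrt
# estimate corrected by exact integer comparisons (all values <= 2^53).
pair_from_index <- function(idx, n) {
  f <- function(u) u * n - u * (u + 1) / 2
  u <- floor(n - 0.5 - sqrt((n - 0.5)^2 - 2 * idx))
  u <- pmax(u, 0)
  for (i in 1:2) {
    u <- u - (f(u) > idx)
    u <- u + (f(u + 1) <= idx)
  }
  v <- u + 1 + (idx - f(u))
  cbind(u, v, deparse.level = 0)
}
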