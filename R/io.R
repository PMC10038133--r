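#' On-disk network formats
#'
#' Two formats, both written streamingly (constant memory in the number of
#' edges) and transparently gzip-compressed when the file name ends in
#' `.gz`:
#'
#' * **Tab-delimited edge list.**  The `"plain"` dialect is one
#'   `u<TAB>v` line per edge.  The `"favites"` dialect is the contact-network
#'   convention of the FAVITES epidemic-simulation framework: one
#'   `NODE<TAB><label><TAB>.` line per node (attributes empty), then one
#'   `EDGE<TAB><u><TAB><v><TAB>.<TAB>u` line per edge, the trailing `u`
#'   marking the edge undirected.  A plain edge list cannot represent
#'   isolated nodes; use the favites dialect when the node count matters
#'   downstream (empty and very sparse graphs).
#'
#' * **Compact binary.**  One header byte holding the node width `b`
#'   (1, 2, 4 or 8), then each edge's two endpoints as `b`-byte little-endian
#'   unsigned integers in emission order: exactly `2 * b * |E| + 1` bytes for
#'   `|E|` edges.  The layout (header semantics, endianness, emission order)
#'   is this package's own dialect; the node count is not recorded.
#'
#' @name graph_io
NULL

is_gz_path <- function(path) grepl("\\.gz$", path)

# Open a sink/source; "-" means standard output (via /dev/stdout for binary).
open_sink <- function(path, binary = FALSE) {
  if (inherits(path, "connection")) return(list(con = path, own = FALSE))
  stopifnot(is.character(path), length(path) == 1L)
  mode <- if (binary) "wb" else "w"
  con <- if (identical(path, "-")) {
    if (binary) file("/dev/stdout", "wb") else stdout()
  } else if (is_gz_path(path)) {
    gzfile(path, mode)
  } else {
    file(path, mode)
  }
  list(con = con, own = !identical(path, "-") || binary)
}

open_source <- function(path, binary = FALSE) {
  if (inherits(path, "connection")) return(list(con = path, own = FALSE))
  stopifnot(is.character(path), length(path) == 1L)
  # gzfile() reads uncompressed files transparently, so use it throughout
  list(con = gzfile(path, if (binary) "rb" else "rt"), own = TRUE)
}

fmt_label <- function(x) sprintf("%.0f", x)

#' Write a stream as a tab-delimited edge list
#'
#' @param stream an [edge_stream()].
#' @param path output file name, `"-"` for standard output, or an open
#'   connection; a `.gz` suffix enables gzip compression.
#' @param dialect `"plain"` (one `u<TAB>v` line per edge) or `"favites"`
#'   (`NODE` records for all `n` nodes, then `EDGE` records).
#' @param chunk_size edges fetched per chunk.
#' @return (invisibly) the number of lines written: `|E|` for plain,
#'   `n + |E|` for favites.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_edge_list(gen_path(3), f)
#' readLines(f)  # "0\t1" "1\t2"
#' @rdname graph_io
#' @export
write_edge_list <- function(stream, path, dialect = c("plain", "favites"),
                            chunk_size = 65536L) {
  stopifnot(inherits(stream, "edge_stream"))
  dialect <- match.arg(dialect)
  sink <- open_sink(path, binary = FALSE)
  if (sink$own) on.exit(close(sink$con))
  lines <- 0
  tryCatch({
    if (dialect == "favites") {
      i <- 0
      while (i < stream$n) {
        take <- min(chunk_size, stream$n - i)
        ids <- i + seq_len(take) - 1
        writeLines(paste0("NODE\t", fmt_label(ids), "\t."), sink$con)
        i <- i + take
        lines <- lines + take
      }
    }
    repeat {
      ch <- stream$next_chunk(chunk_size)
      if (is.null(ch)) break
      u <- fmt_label(ch[, 1])
      v <- fmt_label(ch[, 2])
      out <- if (dialect == "plain") {
        paste0(u, "\t", v)
      } else {
        paste0("EDGE\t", u, "\t", v, "\t.\tu")
      }
      writeLines(out, sink$con)
      lines <- lines + length(out)
    }
  }, error = function(e) {
    io_error("write failed after %s lines (partial file): %s",
             format(lines), conditionMessage(e))
  })
  invisible(lines)
}

#' Read a tab-delimited edge list
#'
#' The reader materializes the file (it is an interoperability and round-trip
#' testing utility, not part of the streaming pipeline) and returns a stream
#' over it.  The plain dialect carries no node count, so `n` is inferred as
#' `1 + max(label)` (0 for an empty file); the favites dialect counts its
#' `NODE` records.
#'
#' @param path input file name or connection (`.gz` handled transparently).
#' @inheritParams write_edge_list
#' @return an [edge_stream()] yielding the file's edges in order.
#' @rdname graph_io
#' @export
read_edge_list <- function(path, dialect = c("plain", "favites"),
                           chunk_size = 65536L) {
  dialect <- match.arg(dialect)
  src <- open_source(path, binary = FALSE)
  if (src$own) on.exit(close(src$con))
  us <- list(); vs <- list()
  n_nodes <- 0
  lineno <- 0
  repeat {
    lines <- readLines(src$con, n = chunk_size)
    if (length(lines) == 0L) break
    if (dialect == "plain") {
      bad <- !grepl("^[0-9]+\t[0-9]+$", lines)
      if (any(bad)) {
        parse_error("malformed plain edge-list line %d: %s",
                    lineno + which(bad)[1], lines[which(bad)[1]])
      }
      us[[length(us) + 1L]] <- as.numeric(sub("\t.*$", "", lines))
      vs[[length(vs) + 1L]] <- as.numeric(sub("^.*\t", "", lines))
    } else {
      is_node <- grepl("^NODE\t[0-9]+\t", lines)
      is_edge <- grepl("^EDGE\t[0-9]+\t[0-9]+\t", lines)
      if (any(!is_node & !is_edge)) {
        bad <- which(!is_node & !is_edge)[1]
        parse_error("malformed favites line %d: %s", lineno + bad, lines[bad])
      }
      n_nodes <- n_nodes + sum(is_node)
      el <- lines[is_edge]
      if (length(el)) {
        parts <- strsplit(el, "\t", fixed = TRUE)
        us[[length(us) + 1L]] <- as.numeric(vapply(parts, `[[`, "", 2L))
        vs[[length(vs) + 1L]] <- as.numeric(vapply(parts, `[[`, "", 3L))
      }
    }
    lineno <- lineno + length(lines)
  }
  u <- unlist(us); v <- unlist(vs)
  mat <- cbind(if (is.null(u)) numeric(0) else u,
               if (is.null(v)) numeric(0) else v)
  n <- if (dialect == "favites") n_nodes
       else if (nrow(mat) == 0L) 0 else 1 + max(mat)
  stream_from_matrix(n, mat)
}

#' Write a stream in the compact binary format
#'
#' @param width bytes per node identifier (1, 2, 4 or 8); every label must be
#'   below `2^(8 * width)`.
#' @inheritParams write_edge_list
#' @return (invisibly) the bytes written: exactly `2 * width * |E| + 1`.
#' @examples
#' f <- tempfile(fileext = ".bin")
#' write_binary(gen_complete(4), f, width = 4)
#' file.size(f)  # 2*4*6 + 1 = 49
#' @rdname graph_io
#' @export
write_binary <- function(stream, path, width = 4, chunk_size = 65536L) {
  stopifnot(inherits(stream, "edge_stream"))
  limit <- max_nodes(width) + 1
  b <- as.integer(width)
  sink <- open_sink(path, binary = TRUE)
  if (sink$own) on.exit(close(sink$con))
  writeBin(as.raw(b), sink$con)
  bytes <- 1
  edges_before <- 0
  repeat {
    ch <- stream$next_chunk(chunk_size)
    if (is.null(ch)) break
    x <- as.vector(t(ch))            # u1 v1 u2 v2 ...
    if (any(x >= limit)) {
      ei <- ceiling(which(x >= limit)[1] / 2)
      io_error("edge %s (%s, %s) has a label exceeding the %d-byte limit %s",
               format(edges_before + ei), fmt_label(ch[ei, 1]),
               fmt_label(ch[ei, 2]), b,
               format(limit - 1, scientific = FALSE))
    }
    bytes_mat <- matrix(0, nrow = b, ncol = length(x))
    for (i in seq_len(b)) {          # little-endian: low byte first
      bytes_mat[i, ] <- x %% 256
      x <- x %/% 256
    }
    writeBin(as.raw(bytes_mat), sink$con)
    bytes <- bytes + b * ncol(bytes_mat)
    edges_before <- edges_before + nrow(ch)
  }
  invisible(bytes)
}

#' Read a compact binary network file
#'
#' Materializes the file and returns a stream over it (see
#' [read_edge_list()] for the rationale).  The format does not record the
#' node count, so `n` is inferred as `1 + max(label)` (0 for a header-only
#' file); the width read from the header is attached as the stream's
#' `width` attribute.  `write -> read -> write` is byte-identical.
#'
#' @rdname graph_io
#' @export
read_binary <- function(path, chunk_size = 65536L) {
  src <- open_source(path, binary = TRUE)
  if (src$own) on.exit(close(src$con))
  hdr <- readBin(src$con, "raw", n = 1L)
  if (length(hdr) == 0L) format_error("empty file: missing width header byte")
  b <- as.integer(hdr)
  if (!b %in% c(1L, 2L, 4L, 8L)) {
    format_error("bad header byte 0x%02x: width must be 1, 2, 4 or 8", b)
  }
  weights <- 256^(seq_len(b) - 1)
  vals <- list()
  leftover <- raw(0)
  repeat {
    chunk <- readBin(src$con, "raw", n = 2L * b * chunk_size)
    if (length(chunk) == 0L && length(leftover) == 0L) break
    chunk <- c(leftover, chunk)
    usable <- (length(chunk) %/% (2L * b)) * 2L * b
    leftover <- if (usable < length(chunk)) chunk[(usable + 1L):length(chunk)] else raw(0)
    if (usable == 0L) {
      format_error("truncated payload: %d trailing byte(s), not a multiple of 2*%d",
                   length(leftover), b)
    }
    m <- matrix(as.integer(chunk[seq_len(usable)]), nrow = b)
    vals[[length(vals) + 1L]] <- colSums(m * weights)
  }
  x <- unlist(vals)
  mat <- if (is.null(x)) matrix(numeric(0), 0, 2) else
    matrix(x, ncol = 2, byrow = TRUE)
  n <- if (nrow(mat) == 0L) 0 else 1 + max(mat)
  out <- stream_from_matrix(n, mat)
  attr(out, "width") <- b
  out
}
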