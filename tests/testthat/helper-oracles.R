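# Independent brute-force oracles used to check the optimized
# implementations. These deliberately use naive all-pairs / per-base /
# recursive formulations and independent library calls where possible.

# DBSCAN by explicit density-reachability closure: all-pairs distance
# matrix, core = neighbourhood size >= min_reads, clusters = connected
# components of core points, border points attached to the nearest core
# (ties toward the leftmost core, matching the documented contract).
oracle_dbscan <- function(pos, eps, min_reads) {
  n <- length(pos)
  if (!n) return(integer(0))
  D <- abs(outer(pos, pos, "-"))
  core <- rowSums(D <= eps) >= min_reads
  labels <- integer(n)
  if (any(core)) {
    ci <- which(core)
    A <- D[ci, ci, drop = FALSE] <= eps
    comp <- rep(NA_integer_, length(ci))
    cid <- 0L
    for (s in seq_along(ci)) {
      if (!is.na(comp[s])) next
      cid <- cid + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[[1]]
        queue <- queue[-1]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        queue <- c(queue, which(A[v, ] & is.na(comp)))
      }
    }
    labels[ci] <- comp
    for (b in which(!core)) {
      d <- D[b, ci]
      ok <- d <= eps
      if (any(ok)) {
        cand <- which(ok & d == min(d[ok]))
        left <- cand[which.min(pos[ci][cand])]
        labels[b] <- comp[left]
      }
    }
  }
  labels
}

# canonical renumbering: clusters numbered by first appearance when
# scanning reads in position order (noise stays 0)
canon_labels <- function(pos, labels) {
  ord <- order(pos)
  lab <- labels[ord]
  seen <- unique(lab[lab > 0L])
  out_sorted <- integer(length(lab))
  out_sorted[lab > 0L] <- match(lab[lab > 0L], seen)
  res <- integer(length(lab))
  res[ord] <- out_sorted
  res
}

# k-dist by all-pairs distances, k-th smallest per point
oracle_kdist <- function(pos, k) {
  n <- length(pos)
  if (n <= k) return(numeric(0))
  vapply(seq_len(n), function(i) {
    sort(abs(pos[-i] - pos[i]))[k]
  }, numeric(1))
}

# all cross-strand intersecting pairs with 5' overlap, O(n^2), vectorized
oracle_pp_pairs <- function(reads) {
  reads <- as.data.frame(reads)
  pi <- which(reads$strand == "+")
  mi <- which(reads$strand == "-")
  if (!length(pi) || !length(mi)) {
    return(data.frame(plus_id = character(), minus_id = character(),
                      overlap_len = integer()))
  }
  g <- expand.grid(p = pi, m = mi)
  same <- reads$chrom[g$p] == reads$chrom[g$m]
  p5 <- reads$start[g$p]
  q5 <- reads$end[g$m] - 1L
  intersects <- reads$start[g$p] < reads$end[g$m] &
    reads$start[g$m] < reads$end[g$p]
  ov <- q5 - p5 + 1L
  keep <- same & intersects & ov >= 1L
  data.frame(plus_id = reads$read_id[g$p[keep]],
             minus_id = reads$read_id[g$m[keep]],
             overlap_len = as.integer(ov[keep]))
}

# per-base overlap of one interval [s,e) with a set of intervals
oracle_perbase_overlap <- function(s, e, feat_starts, feat_ends) {
  if (e <= s) return(0L)
  covered <- logical(e - s)
  for (i in seq_along(feat_starts)) {
    lo <- max(s, feat_starts[i])
    hi <- min(e, feat_ends[i])
    if (lo < hi) covered[(lo - s + 1L):(hi - s)] <- TRUE
  }
  sum(covered)
}

# duplex alignment score by top-down recursion over (query index, target
# index, state) with memoisation; independent reverse-complement via
# Biostrings. States: M = column pairs q[i] with t[j]; X = gap in target
# (consumes query); Y = gap in query (consumes target).
oracle_duplex_score <- function(pirna, target, params) {
  q <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pirna)))
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(toupper(target), "")[[1]]
  m <- length(qc)
  n <- length(tc)
  subsc <- function(i, j) {
    pos <- m - i + 1L
    w <- if (pos >= params$seed_start && pos <= params$seed_end) params$seed_scale else 1
    v <- if (qc[i] == tc[j] && qc[i] %in% c("A", "C", "G", "T")) params$match
    else if ((qc[i] == "C" && tc[j] == "T") || (qc[i] == "A" && tc[j] == "G")) params$wobble
    else params$mismatch
    v * w
  }
  memo <- new.env(parent = emptyenv())
  f <- function(i, j, state) {
    if (state == "M" && (i < 1L || j < 1L)) return(-Inf)
    if (state == "X" && i < 1L) return(-Inf)
    if (state == "Y" && j < 1L) return(-Inf)
    key <- paste0(i, "_", j, "_", state)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- switch(state,
      M = max(0, f(i - 1L, j - 1L, "M"), f(i - 1L, j - 1L, "X"),
              f(i - 1L, j - 1L, "Y")) + subsc(i, j),
      X = max(f(i - 1L, j, "M") + params$gap_open,
              f(i - 1L, j, "X") + params$gap_extend),
      Y = max(f(i, j - 1L, "M") + params$gap_open,
              f(i, j - 1L, "Y") + params$gap_extend)
    )
    memo[[key]] <- val
    val
  }
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) best <- max(best, f(i, j, "M"))
  best
}

# exhaustive enumeration of every gapped local alignment (no memoisation;
# tiny instances only): explores all starts and all move sequences
oracle_duplex_enum <- function(query_chars, target_chars, params) {
  m <- length(query_chars)
  n <- length(target_chars)
  subsc <- function(i, j) {
    pos <- m - i + 1L
    w <- if (pos >= params$seed_start && pos <= params$seed_end) params$seed_scale else 1
    v <- if (query_chars[i] == target_chars[j]) params$match
    else if ((query_chars[i] == "C" && target_chars[j] == "T") ||
             (query_chars[i] == "A" && target_chars[j] == "G")) params$wobble
    else params$mismatch
    v * w
  }
  best <- 0
  recurse <- function(i, j, score, state) {
    # i, j: next unconsumed indices
    # trailing gaps never precede another pair, so stop when either
    # sequence is exhausted (alignments are scored at their last pair)
    if (i > m || j > n) return(invisible(NULL))
    s2 <- score + subsc(i, j)
    best <<- max(best, s2)
    recurse(i + 1L, j + 1L, s2, "M")
    recurse(i + 1L, j, score + if (state == "X") params$gap_extend else params$gap_open, "X")
    recurse(i, j + 1L, score + if (state == "Y") params$gap_extend else params$gap_open, "Y")
    invisible(NULL)
  }
  for (i0 in seq_len(m)) for (j0 in seq_len(n)) {
    recurse(i0, j0, 0, "start")
  }
  best
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
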