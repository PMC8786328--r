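#' 5'-to-5' overlap of an opposite-strand read pair
#'
#' Secondary piRNA biogenesis (the ping-pong cycle) leaves partner reads on
#' opposite strands whose 5' ends overlap by exactly 10 nt. With `p` the
#' plus read's 5' position (its `start`) and `q` the minus read's 5'
#' position (its `end - 1`), the overlap is `q - p + 1` provided the two
#' read intervals intersect and `q >= p`; otherwise there is no overlap.
#' Sequence content is not consulted: the signature is purely positional.
#'
#' @param plus_read,minus_read single-row read records (`chrom`, `start`,
#'   `end`, `strand`) on the same chromosome, strands `+` and `-`.
#' @return integer overlap length, or `NA_integer_` if the pair does not
#'   overlap 5'-to-5'.
#' @export
five_prime_overlap <- function(plus_read, minus_read) {
  if (plus_read$strand != "+" || minus_read$strand != "-") {
    stop("five_prime_overlap expects a plus-strand and a minus-strand read")
  }
  if (plus_read$chrom != minus_read$chrom) return(NA_integer_)
  p <- plus_read$start
  q <- minus_read$end - 1L
  intersects <- plus_read$start < minus_read$end && minus_read$start < plus_read$end
  if (!intersects || q < p) return(NA_integer_)
  as.integer(q - p + 1L)
}

# internal: all intersecting cross-strand pairs with their 5' overlap,
# per-chromosome sorted sweep (window bounded by the longest read)
pk_overlap_pairs <- function(reads) {
  pk_check_reads(reads)
  reads <- as.data.table(reads)
  reads[, idx := .I]
  plus <- reads[strand == "+"]
  minus <- reads[strand == "-"]
  if (!nrow(plus) || !nrow(minus)) {
    return(data.table(plus_idx = integer(), minus_idx = integer(),
                      chrom = character(), plus_pos5 = integer(),
                      minus_pos5 = integer(), overlap_len = integer()))
  }
  data.table::setkey(minus, chrom, start, end)
  ov <- data.table::foverlaps(
    plus[, .(chrom, start, end, idx, pos5 = start)],
    minus[, .(chrom, start, end, idx, pos5 = end - 1L)],
    by.x = c("chrom", "start", "end"), type = "any", nomatch = NULL
  )
  # foverlaps works on closed [start,end]; our intervals are half-open, so
  # drop abutting pairs that only touch at the shared endpoint
  ov <- ov[i.start < end & start < i.end]
  out <- data.table(
    plus_idx = ov$i.idx, minus_idx = ov$idx, chrom = ov$chrom,
    plus_pos5 = ov$i.pos5, minus_pos5 = ov$pos5,
    overlap_len = as.integer(ov$pos5 - ov$i.pos5 + 1L)
  )
  out[overlap_len >= 1L]
}

#' Find ping-pong partner pairs
#'
#' Returns every opposite-strand read pair whose 5' ends overlap by exactly
#' `target_overlap` nt (default 10, the canonical ping-pong signature). A
#' read may participate in several pairs; multi-mapping reads participate
#' per locus.
#'
#' @param reads stranded read table.
#' @param target_overlap required 5' overlap in nt, `>= 1`.
#' @return `data.table` sorted by chromosome then plus-read 5' position,
#'   with columns `chrom`, `plus_id`, `minus_id`, `plus_pos5`,
#'   `minus_pos5`, `overlap_len`.
#' @export
find_pingpong_pairs <- function(reads, target_overlap = 10L) {
  if (target_overlap < 1L) stop("target_overlap must be >= 1")
  reads <- as.data.table(reads)
  if (!"read_id" %in% names(reads)) reads[, read_id := paste0("read_", .I)]
  pairs <- pk_overlap_pairs(reads)[overlap_len == target_overlap]
  out <- data.table(
    chrom = pairs$chrom,
    plus_id = reads$read_id[pairs$plus_idx],
    minus_id = reads$read_id[pairs$minus_idx],
    plus_pos5 = pairs$plus_pos5,
    minus_pos5 = pairs$minus_pos5,
    overlap_len = pairs$overlap_len
  )
  setorderv(out, c("chrom", "plus_pos5", "minus_pos5"))
  out[]
}

#' Overlap-length signature of opposite-strand read pairs
#'
#' Histogram of 5'-to-5' overlap lengths over all intersecting cross-strand
#' pairs — the data behind the classic ping-pong signature bar plot, which
#' peaks at 10 nt when the ping-pong cycle is active.
#'
#' @param reads stranded read table.
#' @param max_overlap largest overlap length tallied.
#' @return object of class `overlap_signature`: list with `counts` (named
#'   integer vector over 1..max_overlap), `peak` (overlap length with the
#'   maximal count, `NA` if no pairs), `n_pairs`.
#' @export
overlap_signature <- function(reads, max_overlap = 30L) {
  if (max_overlap < 1L) stop("max_overlap must be >= 1")
  pairs <- pk_overlap_pairs(reads)
  pairs <- pairs[overlap_len <= max_overlap]
  counts <- tabulate(pairs$overlap_len, nbins = max_overlap)
  names(counts) <- seq_len(max_overlap)
  peak <- if (sum(counts)) as.integer(which.max(counts)) else NA_integer_
  structure(list(counts = counts, peak = peak, n_pairs = sum(counts)),
            class = "overlap_signature")
}

#' @export
print.overlap_signature <- function(x, ...) {
  cat("ping-pong overlap signature:", x$n_pairs, "pairs; peak at",
      ifelse(is.na(x$peak), "none", x$peak), "nt\n")
  nz <- x$counts[x$counts > 0]
  if (length(nz)) print(nz)
  invisible(x)
}
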