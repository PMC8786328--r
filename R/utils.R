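#' @importFrom data.table data.table as.data.table setorder setorderv := .N .SD
#' @importFrom stats rnbinom rgeom runif sd quantile setNames
#' @importFrom utils head
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".I", "chrom", "start", "end", "strand", "read_id", "copy_count",
  "pos5", "overlap_len", "pirna_id", "sequence", "id",
  "score", "i.start", "i.end", "plus_pos5", "minus_pos5",
  "idx", "i.idx", "i.pos5", "family", "bp", "locus", "txt", "direction",
  "cpm", "members"
))

#' Strand-aware 5' positions of aligned reads
#'
#' For a plus-strand read the 5' end is `start`; for a minus-strand read it
#' is `end - 1` (0-based half-open coordinates throughout the package).
#'
#' @param reads a read table as returned by [read_bed()].
#' @return integer vector of 5' genomic positions, one per read.
#' @export
five_prime_pos <- function(reads) {
  stopifnot(all(c("start", "end", "strand") %in% names(reads)))
  ifelse(reads$strand == "-", reads$end - 1L, reads$start)
}

# internal: validate a read table's coordinate invariants
pk_check_reads <- function(reads, require_strand = FALSE) {
  req <- c("chrom", "start", "end", "strand")
  miss <- setdiff(req, names(reads))
  if (length(miss)) stop("read table missing columns: ", paste(miss, collapse = ", "))
  if (any(reads$start < 0L)) stop("negative start coordinate")
  if (any(reads$start >= reads$end)) stop("start >= end in read table")
  if (!all(reads$strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  if (require_strand && any(reads$strand == ".")) {
    stop("strand '.' not allowed here: stranded reads required")
  }
  invisible(reads)
}

# derive a reproducible substream seed from a master seed; keeps results
# independent across operations while fully determined by the master seed
pk_substream <- function(seed, offset) {
  (as.integer(seed) * 97L + as.integer(offset) * 1009L) %% 2147483647L
}

pk_revcomp <- function(x) {
  chartr("ACGTUN", "TGCAAN", x) |>
    strsplit("") |>
    vapply(function(s) paste(rev(s), collapse = ""), character(1))
}
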