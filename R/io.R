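#' Read aligned small-RNA loci from a BED file
#'
#' Reads a BED3+ file into a read table. Coordinates are kept 0-based
#' half-open exactly as in the file; a missing strand column yields `"."`.
#' No deduplication is performed at this stage (see [collapse_redundant()]).
#'
#' @param path path to a whitespace-separated BED file with at least 3
#'   columns (`chrom`, `start`, `end`); column 4 is taken as the read id,
#'   column 5 as a score (ignored), column 6 as the strand.
#' @return a `data.table` with columns `chrom`, `start`, `end`, `read_id`,
#'   `strand`, `copy_count` (initialised to 1).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      read_id = character(), strand = character(),
                      copy_count = integer()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad)) stop("malformed BED line ", bad[1], ": fewer than 3 columns")
  starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad)) stop("malformed BED line ", bad[1], ": non-integer coordinates")
  bad <- which(starts >= ends)
  if (length(bad)) {
    stop("invalid interval at line ", bad[1], ": start >= end (",
         starts[bad[1]], " >= ", ends[bad[1]], ")")
  }
  if (any(starts < 0L)) stop("negative start coordinate in ", path)
  reads <- data.table(
    chrom = vapply(fields, `[`, "", 1L),
    start = starts,
    end = ends,
    read_id = ifelse(nf >= 4L, vapply(fields, function(f) f[4L], ""), NA_character_),
    strand = ifelse(nf >= 6L, vapply(fields, function(f) f[6L], ""), ".")
  )
  noid <- which(is.na(reads$read_id))
  if (length(noid)) reads[noid, read_id := paste0("read_", noid)]
  if (!all(reads$strand %in% c("+", "-", "."))) {
    stop("invalid strand value in ", path, " (expected +, - or .)")
  }
  reads[, copy_count := 1L]
  reads[]
}

#' Write aligned reads to BED6
#'
#' Inverse of [read_bed()] for canonical input: coordinates and strands are
#' reproduced byte-identically. `copy_count` is written in the score column.
#'
#' @param reads read table with `chrom`, `start`, `end`, `read_id`, `strand`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(reads, path) {
  pk_check_reads(reads)
  score <- if ("copy_count" %in% names(reads)) reads$copy_count else 0L
  lines <- paste(reads$chrom, reads$start, reads$end, reads$read_id,
                 score, reads$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Collapse redundant sequences
#'
#' Collapses a set of read sequences to its non-redundant representatives.
#' U and T are treated as equivalent (RNA input is normalised to the DNA
#' alphabet before hashing), so `UGCA` and `TGCA` collapse together. Output
#' is ordered by descending copy count, ties broken lexicographically.
#'
#' @param ids character vector of read identifiers.
#' @param sequences character vector of sequences over `A C G T U N`
#'   (case-insensitive), parallel to `ids`.
#' @return `data.table` with columns `sequence` (DNA alphabet),
#'   `copy_count`, and list-column `member_ids`.
#' @export
collapse_redundant <- function(ids, sequences) {
  if (length(ids) != length(sequences)) stop("ids and sequences differ in length")
  if (!length(sequences)) {
    return(data.table(sequence = character(), copy_count = integer(),
                      member_ids = list()))
  }
  seqs <- chartr("u", "t", toupper(sequences))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTUN character in sequence for id '", ids[which(bad)[1]], "'")
  }
  dt <- data.table(id = ids, sequence = seqs)
  out <- dt[, .(copy_count = .N, member_ids = list(id)), by = sequence]
  setorderv(out, c("copy_count", "sequence"), order = c(-1L, 1L))
  stopifnot(sum(out$copy_count) == length(sequences))
  out[]
}

#' Assign species-prefixed piRNA identifiers
#'
#' Assigns ids of the form `{abbr}_piRNA_{i}` (e.g. `hsa_piRNA_1`) to an
#' ordered set of non-redundant sequences, with `i` running 1..N in input
#' order. Deterministic for a fixed input order.
#'
#' @param species_abbr three-letter lower-case species abbreviation
#'   (e.g. `"hsa"`, `"mmu"`, `"cel"`).
#' @param sequences character vector of unique sequences, already collapsed.
#' @return `data.table` with columns `pirna_id`, `sequence`, `length`,
#'   `gc_fraction`.
#' @export
assign_ids <- function(species_abbr, sequences) {
  if (!grepl("^[a-z]{3}$", species_abbr)) {
    stop("species_abbr must be exactly three lower-case letters, got '",
         species_abbr, "'")
  }
  if (!length(sequences)) {
    return(data.table(pirna_id = character(), sequence = character(),
                      length = integer(), gc_fraction = numeric()))
  }
  if (anyDuplicated(sequences)) stop("sequences must be unique (collapse first)")
  n <- length(sequences)
  len <- nchar(sequences)
  gc <- (nchar(gsub("[^GCgc]", "", sequences))) / len
  data.table(
    pirna_id = paste0(species_abbr, "_piRNA_", seq_len(n)),
    sequence = sequences,
    length = as.integer(len),
    gc_fraction = gc
  )
}

#' Screen putative piRNA records by length and ncRNA exclusion
#'
#' Retains records whose length lies in `[min_len, max_len]` and, when an
#' exclusion annotation is given, whose loci overlap none of the excluded
#' intervals (e.g. known miRNA/tRNA/rRNA loci). The default 24-33 nt window
#' fits most species; set `min_len = max_len = 21` for nematode 21U-RNAs.
#'
#' @param records piRNA record table from [assign_ids()], optionally with a
#'   `loci` list-column of `data.frame(chrom, start, end, strand)`.
#' @param min_len,max_len inclusive length window in nt.
#' @param exclude optional annotation of loci to exclude, as a
#'   `data.frame(chrom, start, end)` or a `GRanges`.
#' @return the filtered record table.
#' @export
screen_putative_pirnas <- function(records, min_len = 24L, max_len = 33L,
                                   exclude = NULL) {
  if (min_len > max_len) stop("min_len > max_len")
  records <- as.data.table(records)
  keep <- records$length >= min_len & records$length <= max_len
  if (!is.null(exclude) && "loci" %in% names(records)) {
    ex_gr <- if (inherits(exclude, "GRanges")) exclude else pk_df_to_granges(exclude)
    hits_excl <- vapply(records$loci, function(loci) {
      if (is.null(loci) || !nrow(loci)) return(FALSE)
      gr <- pk_df_to_granges(loci)
      length(GenomicRanges::findOverlaps(gr, ex_gr)) > 0L
    }, logical(1))
    keep <- keep & !hits_excl
  }
  records[keep]
}

# internal: 0-based half-open data.frame -> GRanges (1-based closed)
pk_df_to_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}
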