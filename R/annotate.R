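# findOverlaps, quiet about disjoint seqlevel sets (the package-level
# warning in classify_loci covers the user-facing case)
pk_overlaps <- function(query, subject, min_overlap) {
  suppressWarnings(GenomicRanges::findOverlaps(
    query, subject, minoverlap = min_overlap, ignore.strand = TRUE))
}

#' Build an annotation set for overlap queries
#'
#' Wraps a BED-like interval table into a `GRanges` tagged with a feature
#' category. Repeat annotations may carry a family (LINE, SINE, LTR, DNA,
#' Simple_repeat, Low_complexity, Satellite); families outside the seven
#' canonical ones are reported as `"other"`.
#'
#' @param intervals `data.frame(chrom, start, end[, strand][, family][, feature_id])`
#'   in 0-based half-open coordinates.
#' @param category one of `gene`, `exon`, `CDS`, `utr5`, `utr3`, `intron`,
#'   `repeat`, `pseudogene`, `lncRNA`.
#' @return a `GRanges` with metadata columns `category`, `family`,
#'   `feature_id`.
#' @export
annotation_set <- function(intervals,
                           category = c("gene", "exon", "CDS", "utr5", "utr3",
                                        "intron", "repeat", "pseudogene",
                                        "lncRNA")) {
  category <- match.arg(category)
  intervals <- as.data.frame(intervals)
  gr <- pk_df_to_granges(intervals)
  canonical <- c("LINE", "SINE", "LTR", "DNA", "Simple_repeat",
                 "Low_complexity", "Satellite")
  fam <- if (category == "repeat" && "family" %in% names(intervals)) {
    ifelse(intervals$family %in% canonical, intervals$family, "other")
  } else NA_character_
  fid <- if ("feature_id" %in% names(intervals)) intervals$feature_id else
    paste0(category, "_", seq_along(gr))
  S4Vectors::mcols(gr)$category <- category
  S4Vectors::mcols(gr)$family <- fam
  S4Vectors::mcols(gr)$feature_id <- fid
  sort(gr)
}

#' Classify piRNA loci against genomic features
#'
#' Assigns each locus exactly one primary genomic category by fixed
#' precedence — CDS > 5'UTR > 3'UTR > other-exonic > intron > intergenic —
#' on at least `min_overlap` bp of overlap. Repeat, pseudogene and lncRNA
#' overlaps are reported independently (non-exclusive) alongside.
#'
#' @param loci `data.frame(chrom, start, end[, strand])` of piRNA loci,
#'   0-based half-open.
#' @param annotations named list of annotation `GRanges` built with
#'   [annotation_set()]; recognised names: `CDS`, `utr5`, `utr3`, `exon`,
#'   `intron`, `repeat`, `pseudogene`, `lncRNA`.
#' @param min_overlap minimum overlap in bp for a feature call (default 1).
#' @param precedence category precedence for the primary call,
#'   most-specific first.
#' @return `data.table` with one row per locus: `primary_category`,
#'   `repeat_families` (comma-separated `family:bp` entries),
#'   `pseudogene_overlap`, `lncRNA_overlap`.
#' @export
classify_loci <- function(loci, annotations, min_overlap = 1L,
                          precedence = c("CDS", "utr5", "utr3", "exon",
                                         "intron")) {
  loci <- as.data.frame(loci)
  n <- nrow(loci)
  gr <- pk_df_to_granges(loci)
  GenomicRanges::strand(gr) <- "*" # annotation overlap is strand-agnostic
  ann_chroms <- unique(unlist(lapply(annotations, function(a) {
    as.character(unique(GenomicRanges::seqnames(a)))
  })))
  orphan <- setdiff(unique(loci$chrom), ann_chroms)
  if (length(orphan)) {
    warning("chromosome(s) absent from annotation, classified intergenic: ",
            paste(orphan, collapse = ", "))
  }
  primary <- rep("intergenic", n)
  assigned <- rep(FALSE, n)
  for (cat in precedence) {
    ann <- annotations[[cat]]
    if (is.null(ann) || !length(ann)) next
    hits <- pk_overlaps(gr, ann, min_overlap)
    hit_loci <- unique(S4Vectors::queryHits(hits))
    take <- hit_loci[!assigned[hit_loci]]
    label <- if (cat == "exon") "exon_other" else cat
    primary[take] <- label
    assigned[take] <- TRUE
  }
  repeat_families <- character(n)
  rep_ann <- annotations[["repeat"]]
  if (!is.null(rep_ann) && length(rep_ann)) {
    hits <- pk_overlaps(gr, rep_ann, min_overlap)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ovbp <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(gr)[qi], IRanges::ranges(rep_ann)[si]))
      fam <- S4Vectors::mcols(rep_ann)$family[si]
      agg <- data.table(locus = qi, family = fam, bp = ovbp)[
        , .(bp = sum(bp)), by = .(locus, family)]
      lab <- agg[, .(txt = paste(paste0(family, ":", bp), collapse = ",")),
                 by = locus]
      repeat_families[lab$locus] <- lab$txt
    }
  }
  flag_overlap <- function(ann) {
    out <- rep(FALSE, n)
    if (!is.null(ann) && length(ann)) {
      h <- pk_overlaps(gr, ann, min_overlap)
      out[unique(S4Vectors::queryHits(h))] <- TRUE
    }
    out
  }
  data.table(
    chrom = loci$chrom, start = loci$start, end = loci$end,
    primary_category = primary,
    repeat_families = repeat_families,
    pseudogene_overlap = flag_overlap(annotations[["pseudogene"]]),
    lncRNA_overlap = flag_overlap(annotations[["lncRNA"]])
  )
}

#' Overlap of clusters with a feature annotation
#'
#' For each cluster reports whether it overlaps the feature set, the total
#' overlapped length (union of intersections, so nested or overlapping
#' features are not double-counted) and the ids of the touched features.
#'
#' @param clusters cluster table with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [detect_clusters()].
#' @param features an [annotation_set()] `GRanges`.
#' @return `data.table` with `overlapped` (logical), `overlap_bp`,
#'   `feature_ids` (comma-separated).
#' @export
cluster_feature_overlap <- function(clusters, features) {
  clusters <- as.data.frame(clusters)
  gr <- pk_df_to_granges(clusters)
  GenomicRanges::strand(gr) <- "*"
  n <- length(gr)
  overlap_bp <- integer(n)
  feature_ids <- character(n)
  if (length(features)) {
    hits <- pk_overlaps(gr, features, 1L)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      for (q in unique(qi)) {
        fs <- si[qi == q]
        inter <- IRanges::intersect(
          IRanges::ranges(gr)[q],
          IRanges::reduce(IRanges::ranges(features)[fs]))
        overlap_bp[q] <- sum(IRanges::width(inter))
        feature_ids[q] <- paste(S4Vectors::mcols(features)$feature_id[fs],
                                collapse = ",")
      }
    }
  }
  data.table(
    chrom = clusters$chrom, start = clusters$start, end = clusters$end,
    overlapped = overlap_bp > 0L, overlap_bp = overlap_bp,
    feature_ids = feature_ids
  )
}

#' Remap a cluster interval through synteny blocks
#'
#' Maps the portion of a source-genome interval contained in each
#' intersecting synteny block onto the block's target interval by linear
#' interpolation, reflecting coordinates for orientation-flipped blocks.
#' Useful for asking whether a piRNA cluster is conserved at the syntenic
#' position of another species.
#'
#' @param interval single-row `data.frame(chrom, start, end)` on the source
#'   genome, 0-based half-open.
#' @param blocks `data.frame` with columns `chrom`, `start`, `end`
#'   (source), `target_species`, `target_chrom`, `target_start`,
#'   `target_end`, `orientation` (`"same"`/`"flipped"`); blocks must not
#'   overlap on the source.
#' @return `data.table` of target intervals (possibly empty) with columns
#'   `target_species`, `target_chrom`, `target_start`, `target_end`,
#'   `orientation`.
#' @export
remap_through_synteny <- function(interval, blocks) {
  interval <- as.data.frame(interval)
  stopifnot(nrow(interval) == 1L)
  blocks <- as.data.frame(blocks)
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (b$chrom != interval$chrom) next
    s <- max(interval$start, b$start)
    e <- min(interval$end, b$end)
    if (s >= e) next
    scale <- (b$target_end - b$target_start) / (b$end - b$start)
    if (identical(b$orientation, "flipped")) {
      ts <- b$target_start + round((b$end - e) * scale)
      te <- b$target_start + round((b$end - s) * scale)
    } else {
      ts <- b$target_start + round((s - b$start) * scale)
      te <- b$target_start + round((e - b$start) * scale)
    }
    if (te <= ts) te <- ts + 1 # degenerate after rounding: keep 1 bp
    out[[length(out) + 1L]] <- data.table(
      target_species = b$target_species, target_chrom = b$target_chrom,
      target_start = as.integer(ts), target_end = as.integer(te),
      orientation = b$orientation
    )
  }
  if (!length(out)) {
    return(data.table(target_species = character(), target_chrom = character(),
                      target_start = integer(), target_end = integer(),
                      orientation = character()))
  }
  data.table::rbindlist(out)
}

#' Infer introns from a gene span and its exons
#'
#' Helper producing intron intervals as the within-gene complement of the
#' exon set (no GTF dialect parsing).
#'
#' @param gene single-row `data.frame(chrom, start, end)`.
#' @param exons `data.frame(chrom, start, end)` of the gene's exons.
#' @return `data.table(chrom, start, end)` of introns.
#' @export
infer_introns <- function(gene, exons) {
  gene <- as.data.frame(gene)
  stopifnot(nrow(gene) == 1L)
  exons <- as.data.frame(exons)
  gene_ir <- IRanges::IRanges(gene$start + 1L, gene$end)
  exon_ir <- IRanges::reduce(IRanges::IRanges(exons$start + 1L, exons$end))
  introns <- IRanges::setdiff(gene_ir, exon_ir)
  data.table(chrom = gene$chrom,
             start = IRanges::start(introns) - 1L,
             end = IRanges::end(introns))
}
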