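#' Simulate clustered piRNA reads with planted ground truth
#'
#' Places `n_clusters` dense read blocks on one synthetic chromosome —
#' consecutive 5' positions within a block are separated by
#' `1 + Geometric` gaps with mean `intra_spacing_mean` bp — plus uniform
#' background reads. Cluster anchor positions are drawn uniformly subject
#' to a minimum separation so planted clusters never merge. Defaults mirror
#' a piRNA-dense locus: 3 clusters of 50 reads at ~20 bp spacing on a 1 Mb
#' chromosome over 100 background reads (mean background spacing 10 kb).
#'
#' @param chrom_len chromosome length in bp.
#' @param n_clusters planted cluster count.
#' @param reads_per_cluster reads per planted cluster.
#' @param intra_spacing_mean mean gap between consecutive cluster reads, bp.
#' @param noise_reads background read count.
#' @param read_len read length in nt.
#' @param strandedness per-cluster strandedness: `"dual"` (strands drawn
#'   50/50 within each cluster), `"uni"` (one random strand per cluster) or
#'   a character vector of length `n_clusters` over `{"+","-","dual"}`.
#' @param seed master RNG seed.
#' @param chrom chromosome name.
#' @return list with `reads` (read table as from [read_bed()]) and `truth`
#'   (list: `clusters` table with planted `start`, `end`, `n_reads`,
#'   `strandedness`; `noise_ids`; `intra_spacing_mean`;
#'   `background_spacing_mean`; `seed`).
#' @export
simulate_clustered_reads <- function(chrom_len = 1e6, n_clusters = 3L,
                                     reads_per_cluster = 50L,
                                     intra_spacing_mean = 20,
                                     noise_reads = 100L, read_len = 28L,
                                     strandedness = "dual", seed = 1L,
                                     chrom = "chrSim") {
  set.seed(pk_substream(seed, 11L))
  span_est <- reads_per_cluster * (intra_spacing_mean + 2) + read_len
  min_sep <- max(10L * span_est, 5e4)
  if (n_clusters * (span_est + min_sep) > chrom_len && n_clusters > 0L) {
    stop("infeasible packing: clusters do not fit in chrom_len")
  }
  # anchors on a jittered regular grid: guaranteed separation, random offsets
  anchors <- if (n_clusters > 0L) {
    slot <- chrom_len / n_clusters
    sort(floor((seq_len(n_clusters) - 1L) * slot +
                 runif(n_clusters, 0.1, 0.6) * (slot - span_est)))
  } else numeric(0)
  if (length(strandedness) == 1L && n_clusters > 0L) {
    strandedness <- if (strandedness == "uni") {
      sample(c("+", "-"), n_clusters, replace = TRUE)
    } else rep(strandedness, n_clusters)
  }
  reads <- list()
  truth_rows <- list()
  rid <- 0L
  for (ci in seq_len(n_clusters)) {
    gaps <- 1 + rgeom(reads_per_cluster - 1L,
                      prob = 1 / intra_spacing_mean)
    pos5 <- anchors[ci] + cumsum(c(0, gaps))
    strands <- switch(strandedness[ci],
      dual = {
        s <- sample(c("+", "-"), reads_per_cluster, replace = TRUE)
        # guarantee the planted label: force at least one of each strand
        s[1L] <- "+"; s[2L] <- "-"
        s
      },
      rep(strandedness[ci], reads_per_cluster)
    )
    start <- ifelse(strands == "-", pos5 - read_len + 1L, pos5)
    reads[[ci]] <- data.table(
      chrom = chrom, start = as.integer(start),
      end = as.integer(start + read_len),
      read_id = paste0("c", ci, "_r", seq_len(reads_per_cluster)),
      strand = strands, copy_count = 1L
    )
    rid <- rid + reads_per_cluster
    truth_rows[[ci]] <- data.table(
      cluster = ci,
      start = as.integer(min(start)), end = as.integer(max(start) + read_len),
      n_reads = reads_per_cluster,
      strandedness = if (strandedness[ci] == "dual") "dual" else
        if (strandedness[ci] == "+") "uni_plus" else "uni_minus"
    )
  }
  noise_ids <- character(0)
  if (noise_reads > 0L) {
    npos <- sort(floor(runif(noise_reads, 0, chrom_len - read_len)))
    nstr <- sample(c("+", "-"), noise_reads, replace = TRUE)
    noise_ids <- paste0("noise_", seq_len(noise_reads))
    reads[[length(reads) + 1L]] <- data.table(
      chrom = chrom, start = as.integer(npos),
      end = as.integer(npos + read_len), read_id = noise_ids,
      strand = nstr, copy_count = 1L
    )
  }
  reads <- data.table::rbindlist(reads)
  setorderv(reads, c("chrom", "start"))
  truth <- list(
    clusters = if (length(truth_rows)) data.table::rbindlist(truth_rows) else
      data.table(cluster = integer(), start = integer(), end = integer(),
                 n_reads = integer(), strandedness = character()),
    noise_ids = noise_ids,
    intra_spacing_mean = intra_spacing_mean,
    background_spacing_mean = if (noise_reads > 0L) chrom_len / noise_reads else NA_real_,
    seed = seed
  )
  list(reads = reads, truth = truth)
}

#' Simulate ping-pong read pairs
#'
#' Generates opposite-strand read pairs with exact requested 5'-to-5'
#' overlaps (drawn from `overlap_dist`), optionally buried among decoy
#' reads placed far enough apart never to overlap anything.
#'
#' @param n_pairs number of planted pairs.
#' @param overlap_dist named numeric vector, overlap length -> weight
#'   (default: all pairs at the canonical 10 nt).
#' @param read_len read length in nt.
#' @param n_decoys isolated single reads added as background.
#' @param seed master RNG seed.
#' @param chrom chromosome name.
#' @return list with `reads` and `truth` (table of planted pair ids and
#'   overlap lengths).
#' @export
simulate_pingpong_reads <- function(n_pairs = 50L,
                                    overlap_dist = c("10" = 1),
                                    read_len = 28L, n_decoys = 0L,
                                    seed = 1L, chrom = "chrSim") {
  set.seed(pk_substream(seed, 23L))
  lens <- as.integer(names(overlap_dist))
  if (any(lens >= read_len)) stop("overlap lengths must be < read_len")
  # each unit (pair or decoy) gets its own non-overlapping 1 kb slot
  n_units <- n_pairs + n_decoys
  slots <- (seq_len(n_units) - 1L) * 1000L + 100L
  slots <- slots[sample.int(n_units)]
  reads <- list()
  truth_rows <- list()
  for (i in seq_len(n_pairs)) {
    ov <- if (length(lens) == 1L) lens else
      sample(lens, 1L, prob = overlap_dist)
    p <- slots[i] # plus 5' position
    q <- p + ov - 1L # minus 5' position
    reads[[length(reads) + 1L]] <- data.table(
      chrom = chrom,
      start = c(p, q - read_len + 1L),
      end = c(p + read_len, q + 1L),
      read_id = paste0("pp", i, c("_plus", "_minus")),
      strand = c("+", "-"), copy_count = 1L
    )
    truth_rows[[i]] <- data.table(
      plus_id = paste0("pp", i, "_plus"), minus_id = paste0("pp", i, "_minus"),
      overlap_len = as.integer(ov)
    )
  }
  if (n_decoys > 0L) {
    dpos <- slots[n_pairs + seq_len(n_decoys)]
    reads[[length(reads) + 1L]] <- data.table(
      chrom = chrom, start = dpos, end = dpos + read_len,
      read_id = paste0("decoy_", seq_len(n_decoys)),
      strand = sample(c("+", "-"), n_decoys, replace = TRUE),
      copy_count = 1L
    )
  }
  reads <- if (length(reads)) data.table::rbindlist(reads) else
    data.table(chrom = character(), start = integer(), end = integer(),
               read_id = character(), strand = character(),
               copy_count = integer())
  reads[, start := as.integer(start)][, end := as.integer(end)]
  setorderv(reads, c("chrom", "start"))
  truth <- if (length(truth_rows)) data.table::rbindlist(truth_rows) else
    data.table(plus_id = character(), minus_id = character(),
               overlap_len = integer())
  list(reads = reads, truth = truth)
}

#' Simulate a piRNA count matrix with planted differential expression
#'
#' Negative-binomial counts with per-piRNA expression levels drawn from a
#' log-normal; a `de_fraction` of piRNAs is shifted by a planted log2 fold
#' change (alternating up/down) in the second condition half of the
#' samples.
#'
#' @param n_pirnas,n_samples matrix dimensions (samples split evenly into
#'   control / condition).
#' @param library_size expected column sum.
#' @param de_fraction fraction of piRNAs differentially expressed.
#' @param lfc_mean mean absolute planted log2 fold change.
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param seed master RNG seed.
#' @return list with `counts` (integer matrix, dimnames set), `de_truth`
#'   (`data.table(id, log2fc, direction)` of planted DE piRNAs) and
#'   `groups` (sample condition labels).
#' @export
simulate_counts <- function(n_pirnas = 500L, n_samples = 6L,
                            library_size = 1e6, de_fraction = 0.1,
                            lfc_mean = 2, dispersion = 0.2, seed = 1L) {
  stopifnot(n_pirnas > 0L, n_samples >= 2L, library_size > 0)
  set.seed(pk_substream(seed, 37L))
  ids <- paste0("sim_piRNA_", seq_len(n_pirnas))
  rel <- stats::rlnorm(n_pirnas, meanlog = 0, sdlog = 1.5)
  n_de <- round(de_fraction * n_pirnas)
  de_idx <- if (n_de > 0L) sort(sample.int(n_pirnas, n_de)) else integer(0)
  lfc <- numeric(n_pirnas)
  if (n_de > 0L) {
    sign <- rep_len(c(1, -1), n_de)
    lfc[de_idx] <- sign * (lfc_mean + stats::rexp(n_de, rate = 2))
  }
  grp <- rep(c("control", "condition"), length.out = n_samples)
  grp <- grp[order(grp, decreasing = TRUE)] # controls first
  counts <- matrix(0L, n_pirnas, n_samples,
                   dimnames = list(ids, paste0("s", seq_len(n_samples), "_", grp)))
  for (j in seq_len(n_samples)) {
    mu_rel <- rel * ifelse(grp[j] == "condition", 2^lfc, 1)
    mu <- mu_rel / sum(mu_rel) * library_size
    counts[, j] <- rnbinom(n_pirnas, size = 1 / dispersion, mu = mu)
  }
  de_truth <- data.table(
    id = ids[de_idx], log2fc = lfc[de_idx],
    direction = ifelse(lfc[de_idx] > 0, "up", "down")
  )
  list(counts = counts, de_truth = de_truth, groups = grp)
}

pk_random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate piRNA and target sequences with planted target sites
#'
#' Generates random piRNA sequences and random target (3'UTR-like)
#' sequences; each planted (piRNA, target) pair embeds the reverse
#' complement of the piRNA in the target, with optional point mutations.
#'
#' @param n_pirnas,n_targets counts of each sequence set.
#' @param planted_pairs number of planted true interactions (piRNA i ->
#'   target i, `i = 1..planted_pairs`).
#' @param pirna_len,target_len sequence lengths in nt.
#' @param mutation_rate per-base probability of mutating the embedded site.
#' @param seed master RNG seed.
#' @return list with `pirna_seqs`, `target_seqs` (named character vectors)
#'   and `truth` (`data.table(pirna_id, target_id, site_start)`).
#' @export
simulate_target_sequences <- function(n_pirnas = 5L, n_targets = 5L,
                                      planted_pairs = 3L, pirna_len = 30L,
                                      target_len = 200L, mutation_rate = 0,
                                      seed = 1L) {
  if (planted_pairs > min(n_pirnas, n_targets)) {
    stop("planted_pairs exceeds available piRNA/target combinations")
  }
  set.seed(pk_substream(seed, 53L))
  pirna_seqs <- setNames(
    vapply(seq_len(n_pirnas), function(i) pk_random_seq(pirna_len), ""),
    paste0("sim_piRNA_", seq_len(n_pirnas)))
  target_seqs <- setNames(
    vapply(seq_len(n_targets), function(i) pk_random_seq(target_len), ""),
    paste0("target_", seq_len(n_targets)))
  truth_rows <- list()
  for (i in seq_len(planted_pairs)) {
    site <- pk_revcomp(pirna_seqs[[i]])
    schars <- strsplit(site, "")[[1]]
    if (mutation_rate > 0) {
      mut <- runif(length(schars)) < mutation_rate
      schars[mut] <- vapply(schars[mut], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, "")
    }
    pos <- sample.int(target_len - pirna_len + 1L, 1L)
    tchars <- strsplit(target_seqs[[i]], "")[[1]]
    tchars[pos:(pos + pirna_len - 1L)] <- schars
    target_seqs[[i]] <- paste(tchars, collapse = "")
    truth_rows[[i]] <- data.table(
      pirna_id = names(pirna_seqs)[i], target_id = names(target_seqs)[i],
      site_start = pos - 1L
    )
  }
  truth <- if (length(truth_rows)) data.table::rbindlist(truth_rows) else
    data.table(pirna_id = character(), target_id = character(),
               site_start = integer())
  list(pirna_seqs = pirna_seqs, target_seqs = target_seqs, truth = truth)
}

#' Recall and precision of detected clusters against planted truth
#'
#' A detected cluster matches a planted one when their genomic intervals
#' overlap. Recall = matched planted clusters / planted; precision =
#' matched detected clusters / detected.
#'
#' @param detected cluster table from [detect_clusters()].
#' @param truth_clusters the `truth$clusters` table from
#'   [simulate_clustered_reads()].
#' @return list with `recall`, `precision`, `n_detected`, `n_planted`.
#' @export
cluster_recovery <- function(detected, truth_clusters) {
  n_d <- nrow(detected)
  n_p <- nrow(truth_clusters)
  if (!n_p) return(list(recall = NA_real_, precision = NA_real_,
                        n_detected = n_d, n_planted = 0L))
  overlaps <- function(a_start, a_end, b_start, b_end) {
    a_start < b_end & b_start < a_end
  }
  matched_p <- vapply(seq_len(n_p), function(i) {
    any(overlaps(detected$start, detected$end,
                 truth_clusters$start[i], truth_clusters$end[i]))
  }, logical(1))
  matched_d <- if (n_d) vapply(seq_len(n_d), function(i) {
    any(overlaps(truth_clusters$start, truth_clusters$end,
                 detected$start[i], detected$end[i]))
  }, logical(1)) else logical(0)
  list(recall = mean(matched_p),
       precision = if (n_d) mean(matched_d) else NA_real_,
       n_detected = n_d, n_planted = n_p)
}
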