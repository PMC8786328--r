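#' k-distance profile of read 5' positions on one chromosome
#'
#' For every read with at least `k` other reads on the chromosome, computes
#' the distance (bp) to its k-th nearest neighbouring read, measured between
#' strand-aware 5' positions. The distribution of these k-distances guides
#' the choice of the DBSCAN neighbourhood radius: within clusters k-dist is
#' small and repeats often, in the background it is large and diffuse.
#'
#' @param positions integer vector of 5' positions (any order; sorted
#'   internally). Positions may repeat (multi-read positions).
#' @param k neighbour order, `k >= 1`.
#' @param chrom chromosome label carried through to the profile.
#' @return object of class `kdist_profile`: list with `chrom`, `k`,
#'   `distances` (one per usable read), `n_omitted` (reads with fewer than
#'   `k` neighbours).
#' @export
kdist_profile <- function(positions, k, chrom = NA_character_) {
  if (k < 1L) stop("k must be >= 1")
  positions <- sort(as.numeric(positions))
  n <- length(positions)
  if (n <= k) {
    if (n > 0L) warning("fewer than k+1 reads on ", chrom, ": empty k-dist profile")
    prof <- list(chrom = chrom, k = as.integer(k),
                 distances = numeric(0), n_omitted = n)
    class(prof) <- "kdist_profile"
    return(prof)
  }
  # the k nearest neighbours of a sorted point lie among its k predecessors
  # and k successors; merge both flanks and take the k-th smallest gap
  dists <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - k)
    hi <- min(n, i + k)
    d <- abs(positions[c(lo:hi)] - positions[i])
    d <- d[-(i - lo + 1L)]
    sort(d, partial = k)[k]
  }, numeric(1))
  prof <- list(chrom = chrom, k = as.integer(k), distances = dists,
               n_omitted = 0L)
  class(prof) <- "kdist_profile"
  prof
}

#' @export
print.kdist_profile <- function(x, ...) {
  cat("k-dist profile", if (!is.na(x$chrom)) paste0("[", x$chrom, "]"),
      "k =", x$k, "| n =", length(x$distances),
      "| omitted =", x$n_omitted, "\n")
  if (length(x$distances)) print(summary(x$distances))
  invisible(x)
}

# Freedman-Diaconis bin width for the modal (low-distance) regime.
# The k-dist distribution of clustered reads over sparse background is a
# strongly right-skewed mixture; FD on the full data is dominated by the
# background tail and over-smooths the cluster mode, so the width is
# computed on the sub-median distances (falling back to all distances when
# that subset is degenerate).
pk_fd_binwidth <- function(x) {
  lo <- x[x <= stats::median(x)]
  if (length(lo) < 4L || stats::IQR(lo) == 0) lo <- x
  bw <- 2 * stats::IQR(lo) / length(lo)^(1 / 3)
  if (!is.finite(bw) || bw <= 0) {
    bw <- max(1, diff(range(x)) / max(1, ceiling(sqrt(length(x)))))
  }
  max(1, bw)
}

#' Estimate the DBSCAN radius (eps) from a k-distance profile
#'
#' Bins the k-distances into a histogram and returns the upper edge of the
#' modal bin: the distance that repeats itself most often, i.e. the typical
#' inter-read spacing inside clusters. Ties between equally tall bins are
#' broken toward the smaller distance.
#'
#' @param profile a [kdist_profile()].
#' @param bin_width histogram bin width in bp; default Freedman-Diaconis.
#' @return integer eps (>= 1), with attributes `bin_width` and
#'   `modal_count`.
#' @export
estimate_eps <- function(profile, bin_width = NULL) {
  d <- profile$distances
  if (!length(d)) {
    stop("empty k-dist profile: too few reads; supply eps manually")
  }
  if (is.null(bin_width)) bin_width <- pk_fd_binwidth(d)
  if (bin_width <= 0) stop("bin_width must be positive")
  # bins [0,bw), [bw,2bw), ...; modal bin, ties -> smaller distance
  bin <- floor(d / bin_width)
  tab <- table(bin)
  counts <- as.integer(tab)
  edges <- as.numeric(names(tab))
  modal <- edges[which.max(counts)] # which.max takes first max = smallest bin
  eps <- max(1L, as.integer(ceiling((modal + 1) * bin_width)))
  structure(eps, bin_width = bin_width, modal_count = max(counts))
}

#' One-dimensional DBSCAN over genomic positions
#'
#' Classic DBSCAN semantics in one dimension: a read is a core point if at
#' least `min_reads` reads (including itself) lie within `eps` bp of it;
#' clusters are maximal sets of density-connected reads; non-core reads
#' within `eps` of a core point join that core's cluster (border points,
#' assigned to the nearest core, ties toward the leftmost cluster); all
#' remaining reads are noise. Labels are invariant to input order up to
#' renumbering (clusters are numbered left to right along the chromosome).
#'
#' @param positions numeric vector of read 5' positions (one chromosome).
#' @param eps neighbourhood radius in bp, `>= 1`.
#' @param min_reads minimum neighbourhood size to seed a cluster, `>= 2`.
#' @return integer vector of cluster labels parallel to `positions`;
#'   `0` marks noise.
#' @export
dbscan_1d <- function(positions, eps, min_reads) {
  if (eps < 1) stop("eps must be >= 1")
  if (min_reads < 2) stop("min_reads must be >= 2")
  n <- length(positions)
  if (!n) return(integer(0))
  ord <- order(positions)
  p <- as.numeric(positions[ord])
  # neighbourhood size by binary search on the sorted vector
  lo <- findInterval(p - eps, p, left.open = TRUE) + 1L
  hi <- findInterval(p + eps, p)
  nn <- hi - lo + 1L
  core <- nn >= min_reads
  labels_sorted <- integer(n)
  if (any(core)) {
    ci <- which(core)
    # consecutive core points chain into one cluster when their gap <= eps
    newcl <- c(TRUE, diff(p[ci]) > eps)
    core_cl <- cumsum(newcl)
    labels_sorted[ci] <- core_cl
    # border points: non-core within eps of a core; nearest core wins,
    # ties toward the leftward (smaller-id) cluster
    bi <- which(!core)
    if (length(bi)) {
      pos_core <- p[ci]
      ins <- findInterval(p[bi], pos_core)
      left_i <- pmax(ins, 1L)
      right_i <- pmin(ins + 1L, length(pos_core))
      dl <- abs(p[bi] - pos_core[left_i])
      dr <- abs(p[bi] - pos_core[right_i])
      dl[ins < 1L] <- Inf
      dr[ins >= length(pos_core)] <- Inf
      best <- ifelse(dl <= dr, left_i, right_i)
      bestd <- pmin(dl, dr)
      ok <- bestd <= eps
      labels_sorted[bi[ok]] <- core_cl[best[ok]]
    }
  }
  labels <- integer(n)
  labels[ord] <- labels_sorted
  labels
}

#' Cluster score
#'
#' Score of a cluster: total number of piRNA reads in the cluster divided
#' by the minimum number of reads needed to form a cluster (the MinReads
#' parameter derived from the neighbour order k). A minimal cluster scores
#' 1; denser clusters score proportionally higher.
#'
#' @param n_reads reads in the cluster.
#' @param min_reads MinReads used for detection, `>= 1`.
#' @return numeric score `n_reads / min_reads`.
#' @export
score_cluster <- function(n_reads, min_reads) {
  if (any(min_reads < 1)) stop("min_reads must be >= 1")
  if (any(n_reads < min_reads)) stop("n_reads must be >= min_reads")
  n_reads / min_reads
}

#' Classify cluster strandedness
#'
#' A cluster producing piRNAs from both genomic strands is dual-strand;
#' otherwise it is a uni-strand cluster of the corresponding strand.
#'
#' @param strands character vector of member strands (`"+"`/`"-"`).
#' @return list with `strandedness` (one of `"uni_plus"`, `"uni_minus"`,
#'   `"dual"`), `n_plus`, `n_minus`.
#' @export
classify_strandedness <- function(strands) {
  if (!length(strands)) stop("cannot classify an empty cluster")
  if (any(strands == ".")) stop("strand required for strandedness classification")
  if (!all(strands %in% c("+", "-"))) stop("invalid strand value")
  n_plus <- sum(strands == "+")
  n_minus <- sum(strands == "-")
  s <- if (n_plus > 0L && n_minus > 0L) "dual" else if (n_plus > 0L) "uni_plus" else "uni_minus"
  list(strandedness = s, n_plus = n_plus, n_minus = n_minus)
}

#' Detect piRNA clusters genome-wide
#'
#' Runs 1-D DBSCAN on strand-aware 5' positions per chromosome. Both
#' strands are clustered jointly (strand is ignored for density and used
#' only to label strandedness, so dual-strand clusters can be called).
#' In auto mode (`eps = NULL`) eps is estimated per chromosome from the
#' k-distance profile via [estimate_eps()].
#'
#' @param reads read table (`chrom`, `start`, `end`, `strand`, ...).
#' @param k neighbour order for the k-dist analysis; `min_reads` defaults
#'   to `k + 1` (the point itself plus its k neighbours).
#' @param eps fixed radius in bp, or `NULL` to estimate per chromosome.
#' @param min_reads MinReads; default `k + 1`.
#' @param bin_width histogram bin width forwarded to [estimate_eps()].
#' @param score_denominator either `"min_reads"` (score = n/MinReads) or
#'   `"min_reads_k"` (score = n/(MinReads*k)); the former is the default
#'   reading of the cluster-score ratio.
#' @return object of class `pirna_clusters`: a `data.table` with one row
#'   per cluster (`chrom`, `start`, `end`, `n_reads`, `score`,
#'   `strandedness`, `n_plus`, `n_minus`, `eps`, `min_reads`, list-column
#'   `members` of row indices into `reads`), sorted by chromosome then
#'   start. Attributes: `noise` (row indices of noise reads), `params`
#'   (per-chromosome parameter log).
#' @export
detect_clusters <- function(reads, k = 4L, eps = NULL, min_reads = k + 1L,
                            bin_width = NULL,
                            score_denominator = c("min_reads", "min_reads_k")) {
  pk_check_reads(reads, require_strand = TRUE)
  score_denominator <- match.arg(score_denominator)
  reads <- as.data.table(reads)
  reads[, pos5 := five_prime_pos(reads)]
  out <- list()
  noise_idx <- integer(0)
  params <- list()
  for (ch in sort(unique(reads$chrom))) {
    idx <- which(reads$chrom == ch)
    pos <- reads$pos5[idx]
    eps_ch <- eps
    if (is.null(eps_ch)) {
      prof <- kdist_profile(pos, k = k, chrom = ch)
      if (!length(prof$distances)) {
        noise_idx <- c(noise_idx, idx)
        params[[ch]] <- list(chrom = ch, eps = NA_integer_, min_reads = min_reads,
                             note = "too few reads; all noise")
        next
      }
      eps_ch <- as.integer(estimate_eps(prof, bin_width = bin_width))
    }
    labels <- dbscan_1d(pos, eps = eps_ch, min_reads = min_reads)
    params[[ch]] <- list(chrom = ch, eps = eps_ch, min_reads = min_reads)
    noise_idx <- c(noise_idx, idx[labels == 0L])
    for (cl in sort(unique(labels[labels > 0L]))) {
      m <- idx[labels == cl]
      sc <- classify_strandedness(reads$strand[m])
      denom <- if (score_denominator == "min_reads") min_reads else min_reads * k
      out[[length(out) + 1L]] <- data.table(
        chrom = ch,
        start = min(reads$start[m]),
        end = max(reads$end[m]),
        n_reads = length(m),
        score = length(m) / denom,
        strandedness = sc$strandedness,
        n_plus = sc$n_plus,
        n_minus = sc$n_minus,
        eps = eps_ch,
        min_reads = as.integer(min_reads),
        members = list(m)
      )
    }
  }
  clusters <- if (length(out)) data.table::rbindlist(out) else
    data.table(chrom = character(), start = integer(), end = integer(),
               n_reads = integer(), score = numeric(), strandedness = character(),
               n_plus = integer(), n_minus = integer(), eps = integer(),
               min_reads = integer(), members = list())
  setorderv(clusters, c("chrom", "start"))
  data.table::setattr(clusters, "noise", noise_idx)
  data.table::setattr(clusters, "params", params)
  data.table::setattr(clusters, "class", c("pirna_clusters", class(clusters)))
  clusters[]
}

#' Write cluster spans as BED
#'
#' Column 5 carries the cluster score, column 6 the strandedness encoded as
#' `+` (uni-plus), `-` (uni-minus) or `.` (dual).
#'
#' @param clusters result of [detect_clusters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_bed <- function(clusters, path) {
  strand_code <- c(uni_plus = "+", uni_minus = "-", dual = ".")
  lines <- paste(clusters$chrom, clusters$start, clusters$end,
                 paste0("cluster_", seq_len(nrow(clusters))),
                 format(clusters$score, trim = TRUE),
                 strand_code[clusters$strandedness], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
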