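#' Counts-per-million normalization
#'
#' Scales each sample (column) so its counts sum to one million:
#' `cpm[i,j] = counts[i,j] / colsum(j) * 1e6`.
#'
#' @param counts non-negative integer matrix, rows = piRNAs, columns =
#'   samples; must have column names.
#' @return numeric matrix of CPM values with the same dimnames.
#' @export
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  libsize <- colSums(counts)
  zero <- which(libsize == 0)
  if (length(zero)) {
    nm <- if (!is.null(colnames(counts))) colnames(counts)[zero[1]] else zero[1]
    stop("zero library size in sample '", nm, "'")
  }
  sweep(counts, 2, libsize, "/") * 1e6
}

#' Per-sample z-score screen of expressed piRNAs
#'
#' Computes z-scores within one sample across its expressed piRNAs
#' (CPM > 0) and flags outliers: entries are retained when
#' `-3 <= z <= +3`. Unexpressed piRNAs get `z = NA` and are not retained.
#' With zero variance all expressed entries get `z = 0` and are retained,
#' with a warning.
#'
#' @param cpm numeric vector of CPM values for one sample.
#' @return list with `z` (numeric vector) and `retained` (logical mask),
#'   both parallel to `cpm`.
#' @export
zscore_screen <- function(cpm) {
  expressed <- !is.na(cpm) & cpm > 0
  z <- rep(NA_real_, length(cpm))
  retained <- rep(FALSE, length(cpm))
  x <- cpm[expressed]
  if (length(x) < 2L) {
    warning("fewer than 2 expressed values: nothing to screen")
    z[expressed] <- 0
    retained[expressed] <- TRUE
    return(list(z = z, retained = retained))
  }
  s <- sd(x)
  if (s == 0) {
    warning("zero variance: all z = 0, all retained")
    z[expressed] <- 0
    retained[expressed] <- TRUE
    return(list(z = z, retained = retained))
  }
  zz <- (x - mean(x)) / s
  z[expressed] <- zz
  retained[expressed] <- zz >= -3 & zz <= 3
  list(z = z, retained = retained)
}

#' Top abundant piRNAs in one sample
#'
#' Ranks expressed piRNAs by CPM, descending; ties broken by id in
#' lexicographic order. Returns fewer than `n` entries when fewer piRNAs
#' are expressed.
#'
#' @param cpm named numeric vector of CPM values (names = piRNA ids).
#' @param n number of entries to return (default 200).
#' @return `data.table(pirna_id, cpm)` of at most `n` rows, descending CPM.
#' @export
top_abundant <- function(cpm, n = 200L) {
  if (n < 1L) stop("n must be >= 1")
  if (is.null(names(cpm))) stop("cpm must carry piRNA ids as names")
  dt <- data.table(pirna_id = names(cpm), cpm = as.numeric(cpm))
  dt <- dt[cpm > 0]
  setorderv(dt, c("cpm", "pirna_id"), order = c(-1L, 1L))
  head(dt, n)
}

#' Anticorrelated piRNA-target candidate pairs
#'
#' piRNAs silence their targets, so candidate interactions pair
#' up-regulated piRNAs with down-regulated targets (mRNAs/lncRNAs) and vice
#' versa: the output is the cross product
#' `{up piRNAs x down targets} U {down piRNAs x up targets}`.
#'
#' @param pirna_de `data.frame(id, log2fc, direction)` with `direction` in
#'   `{"up","down"}` consistent with the sign of `log2fc`.
#' @param target_de same layout for targets; may carry a `kind` column.
#' @return `data.table(pirna_id, target_id, pirna_direction,
#'   target_direction)`.
#' @export
anticorrelated_pairs <- function(pirna_de, target_de) {
  pirna_de <- as.data.table(pirna_de)
  target_de <- as.data.table(target_de)
  for (dt in list(pirna_de, target_de)) {
    if (nrow(dt) && !all(dt$direction %in% c("up", "down"))) {
      stop("direction must be 'up' or 'down'")
    }
    if (nrow(dt) && "log2fc" %in% names(dt)) {
      bad <- (dt$direction == "up" & dt$log2fc < 0) |
        (dt$direction == "down" & dt$log2fc > 0)
      if (any(bad)) stop("direction inconsistent with log2fc sign for id '",
                         dt$id[which(bad)[1]], "'")
    }
  }
  cross <- function(p, t) {
    if (!length(p) || !length(t)) return(NULL)
    data.table(pirna_id = rep(p, each = length(t)),
               target_id = rep(t, times = length(p)))
  }
  up_p <- pirna_de[direction == "up"]$id
  down_p <- pirna_de[direction == "down"]$id
  up_t <- target_de[direction == "up"]$id
  down_t <- target_de[direction == "down"]$id
  a <- cross(up_p, down_t)
  if (!is.null(a)) a[, `:=`(pirna_direction = "up", target_direction = "down")]
  b <- cross(down_p, up_t)
  if (!is.null(b)) b[, `:=`(pirna_direction = "down", target_direction = "up")]
  out <- data.table::rbindlist(Filter(Negate(is.null), list(a, b)))
  if (!nrow(out)) {
    out <- data.table(pirna_id = character(), target_id = character(),
                      pirna_direction = character(),
                      target_direction = character())
  }
  out[]
}
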