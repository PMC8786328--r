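#' Default duplex-alignment scoring parameters
#'
#' miRanda-class complementarity scoring: Watson-Crick match +5, G:U wobble
#' +1, mismatch -3, gap open -9, gap extend -4, with substitution scores in
#' piRNA 5'-end positions 2-8 (the seed-like region) scaled x2. Score units
#' are therefore comparable in structure, not identical, to miRanda's; the
#' companion gates of [predict_targets()] default to score >= 170 and
#' energy <= -20 kcal/mol.
#'
#' @param match,wobble,mismatch substitution scores.
#' @param gap_open cost of the first gapped position; `gap_extend` for each
#'   further one.
#' @param gap_extend see `gap_open`.
#' @param seed_start,seed_end piRNA positions (1 = 5' end) whose
#'   substitution scores are scaled by `seed_scale`.
#' @param seed_scale multiplier for the seed region.
#' @param wobble_stack_dg,loop_penalty_dg energy-model knobs, kcal/mol: the
#'   pinned stacking value for stacks touching a G:U pair, and the penalty
#'   per interior loop/bulge.
#' @return named list of parameters.
#' @export
duplex_params <- function(match = 5, wobble = 1, mismatch = -3,
                          gap_open = -9, gap_extend = -4,
                          seed_start = 2L, seed_end = 8L, seed_scale = 2,
                          wobble_stack_dg = -0.5, loop_penalty_dg = 4) {
  list(match = match, wobble = wobble, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend,
       seed_start = seed_start, seed_end = seed_end, seed_scale = seed_scale,
       wobble_stack_dg = wobble_stack_dg, loop_penalty_dg = loop_penalty_dg)
}

# Watson-Crick nearest-neighbor stacking free energies (kcal/mol, 37 C),
# keyed by the target-strand dinucleotide 5'->3' (RNA alphabet); the
# paired strand is implied by complementarity. Symmetric entries share the
# published value for the corresponding stack.
PK_NN_STACK <- c(
  AA = -0.93, UU = -0.93,
  AU = -1.10,
  UA = -1.33,
  CU = -2.08, AG = -2.08,
  CA = -2.11, UG = -2.11,
  GU = -2.24, AC = -2.24,
  GA = -2.35, UC = -2.35,
  CG = -2.36,
  GG = -3.26, CC = -3.26,
  GC = -3.42
)

# classify (revcomp-piRNA char, target char) columns, DNA alphabet:
# equal chars = Watson-Crick pair of the underlying duplex; C/T and A/G
# are the two G:U wobble geometries; anything else (incl. N) mismatches
pk_pair_class <- function(q, t) {
  ifelse(q == t & q %in% c("A", "C", "G", "T"), "match",
         ifelse((q == "C" & t == "T") | (q == "A" & t == "G"),
                "wobble", "mismatch"))
}

pk_norm_seq <- function(x, what) {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  if (grepl("[^ACGTN]", x)) stop("non-nucleotide character in ", what)
  x
}

# Affine-gap local alignment (three-state Gotoh) of the reverse-complement
# piRNA against the target. Returns the state matrices; traceback is done
# by the caller. Query rows, target columns; gap switching (Ix <-> Iy
# directly) is disallowed.
pk_duplex_dp <- function(qchars, tchars, params) {
  m <- length(qchars)
  n <- length(tchars)
  # substitution scores with seed scaling: query index i is piRNA
  # position m - i + 1 (the query is the reversed complement)
  pir_pos <- m - seq_len(m) + 1L
  wt <- ifelse(pir_pos >= params$seed_start & pir_pos <= params$seed_end,
               params$seed_scale, 1)
  base <- c(match = params$match, wobble = params$wobble,
            mismatch = params$mismatch)
  NEG <- -1e9
  M <- matrix(NEG, m + 1L, n + 1L)
  Ix <- matrix(NEG, m + 1L, n + 1L) # gap in target (consumes query)
  Iy <- matrix(NEG, m + 1L, n + 1L) # gap in query (consumes target)
  M[1L, ] <- NEG; M[, 1L] <- NEG
  sub <- matrix(0, m, n)
  for (i in seq_len(m)) {
    cls <- pk_pair_class(qchars[i], tchars)
    sub[i, ] <- base[cls] * wt[i]
    prev_best <- pmax(M[i, ], Ix[i, ], Iy[i, ], 0)
    M[i + 1L, 2L:(n + 1L)] <- prev_best[1L:n] + sub[i, ]
    Ix[i + 1L, ] <- pmax(M[i, ] + params$gap_open, Ix[i, ] + params$gap_extend)
    # Iy within the row: running max over gap openings from M on this row
    g <- M[i + 1L, 1L:n] + params$gap_open - params$gap_extend * (1L:n)
    Iy[i + 1L, 2L:(n + 1L)] <- cummax(g) + params$gap_extend * (1L:n)
  }
  list(M = M, Ix = Ix, Iy = Iy, sub = sub, m = m, n = n)
}

# deterministic traceback from an M cell; prefers ending/starting early and
# diagonal moves, yielding the shortest alignment among score ties
pk_traceback <- function(dp, params, i, j) {
  qa <- character(0); ta <- character(0); state <- "M"
  ii <- i; jj <- j
  eps <- 1e-9
  repeat {
    if (state == "M") {
      qa <- c("Q", qa); ta <- c("T", ta)
      v <- dp$M[ii + 1L, jj + 1L] - dp$sub[ii, jj]
      ii <- ii - 1L; jj <- jj - 1L
      if (abs(v) < eps) break
      prev <- c(M = dp$M[ii + 1L, jj + 1L], Ix = dp$Ix[ii + 1L, jj + 1L],
                Iy = dp$Iy[ii + 1L, jj + 1L])
      state <- names(prev)[which(abs(prev - v) < eps)][1L]
      if (is.na(state)) break
    } else if (state == "Ix") {
      qa <- c("Q", qa); ta <- c("-", ta)
      v <- dp$Ix[ii + 1L, jj + 1L]
      ii <- ii - 1L
      from_m <- dp$M[ii + 1L, jj + 1L] + params$gap_open
      state <- if (abs(from_m - v) < eps) "M" else "Ix"
    } else {
      qa <- c("-", qa); ta <- c("T", ta)
      v <- dp$Iy[ii + 1L, jj + 1L]
      jj <- jj - 1L
      from_m <- dp$M[ii + 1L, jj + 1L] + params$gap_open
      state <- if (abs(from_m - v) < eps) "M" else "Iy"
    }
  }
  list(q_from = ii + 1L, t_from = jj + 1L, q_cols = qa, t_cols = ta)
}

#' Align a piRNA against a target sequence
#'
#' Smith-Waterman-style local alignment of the reverse-complemented piRNA
#' against the target with wobble-aware scoring (see [duplex_params()]).
#' The traceback is deterministic: highest score, ties broken by smallest
#' target start, then shortest alignment.
#'
#' @param pirna piRNA sequence (RNA or DNA alphabet), length >= 16.
#' @param target target sequence, at least as long as the piRNA.
#' @param params scoring parameters from [duplex_params()].
#' @return object of class `duplex_alignment`: list with `score`,
#'   `target_start`/`target_end` (0-based half-open window on the target),
#'   `pirna_span` (positions of the piRNA involved), `pairing` (one char
#'   per alignment column: `|` match, `:` G:U wobble, `.` mismatch, `-`
#'   gap), `query_aln`/`target_aln` (aligned strings, query = reverse
#'   complement of the piRNA), and `energy` (kcal/mol, via
#'   [duplex_energy()]).
#' @export
duplex_align <- function(pirna, target, params = duplex_params()) {
  pirna <- pk_norm_seq(pirna, "pirna")
  target <- pk_norm_seq(target, "target")
  if (nchar(pirna) < 16L) stop("piRNA shorter than 16 nt")
  if (nchar(target) < nchar(pirna)) stop("target shorter than the piRNA")
  query <- pk_revcomp(pirna)
  qchars <- strsplit(query, "")[[1]]
  tchars <- strsplit(target, "")[[1]]
  dp <- pk_duplex_dp(qchars, tchars, params)
  body <- dp$M[-1L, -1L, drop = FALSE]
  best <- max(body, 0)
  if (best <= 0) {
    aln <- list(score = 0, target_start = NA_integer_, target_end = NA_integer_,
                pirna_span = c(NA_integer_, NA_integer_), pairing = "",
                query_aln = "", target_aln = "", energy = 0)
    class(aln) <- "duplex_alignment"
    return(aln)
  }
  hits <- which(abs(body - best) < 1e-9, arr.ind = TRUE)
  cand <- lapply(seq_len(nrow(hits)), function(h) {
    tb <- pk_traceback(dp, params, hits[h, 1L], hits[h, 2L])
    list(i = hits[h, 1L], j = hits[h, 2L], tb = tb,
         t_start = tb$t_from, len = length(tb$q_cols))
  })
  key <- order(vapply(cand, `[[`, 0L, "t_start"),
               vapply(cand, `[[`, 0L, "len"),
               vapply(cand, `[[`, 0L, "j"))
  ch <- cand[[key[1L]]]
  tb <- ch$tb
  qi <- tb$q_from; ti <- tb$t_from
  qa <- ta <- pairing <- character(length(tb$q_cols))
  for (c0 in seq_along(tb$q_cols)) {
    if (tb$q_cols[c0] == "Q") { qa[c0] <- qchars[qi]; qi <- qi + 1L } else qa[c0] <- "-"
    if (tb$t_cols[c0] == "T") { ta[c0] <- tchars[ti]; ti <- ti + 1L } else ta[c0] <- "-"
    pairing[c0] <- if (qa[c0] == "-" || ta[c0] == "-") "-" else
      switch(pk_pair_class(qa[c0], ta[c0]), match = "|", wobble = ":", ".")
  }
  m <- dp$m
  # query indices [q_from, i] correspond to piRNA positions m-i+1 .. m-q_from+1
  aln <- list(
    score = best,
    target_start = unname(tb$t_from - 1L),
    target_end = unname(ch$j),
    pirna_span = unname(c(m - ch$i + 1L, m - tb$q_from + 1L)),
    pairing = paste(pairing, collapse = ""),
    query_aln = paste(qa, collapse = ""),
    target_aln = paste(ta, collapse = "")
  )
  aln$energy <- duplex_energy(aln, params = params)
  class(aln) <- "duplex_alignment"
  aln
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat("duplex alignment: score", x$score, "| energy",
      round(x$energy, 2), "kcal/mol | target window [",
      x$target_start, ",", x$target_end, ")\n", sep = " ")
  if (nzchar(x$pairing)) {
    cat("  5'-", x$target_aln, "-3' target\n", sep = "")
    cat("     ", x$pairing, "\n", sep = "")
    cat("  3'-", x$query_aln, "-5' piRNA (rc)\n", sep = "")
  }
  invisible(x)
}

#' Duplex free-energy estimate
#'
#' Nearest-neighbor stacking-energy sum over consecutive paired alignment
#' columns (Watson-Crick stacks from a pinned published 37 C parameter
#' table; stacks touching a G:U wobble use a single pinned value), plus a
#' penalty per interior loop/bulge (any maximal run of mismatch or gap
#' columns between paired columns). More negative = more stable. Helix
#' initiation and terminal penalties are not modelled: the value gates
#' candidate duplexes, it is not a folding prediction.
#'
#' @param alignment a `duplex_alignment` (or a list with `pairing` and
#'   `target_aln`).
#' @param params parameters from [duplex_params()].
#' @return energy in kcal/mol (0 with a warning if nothing is paired).
#' @export
duplex_energy <- function(alignment, params = duplex_params()) {
  pairing <- strsplit(alignment$pairing, "")[[1]]
  tchars <- strsplit(chartr("T", "U", alignment$target_aln), "")[[1]]
  paired <- pairing %in% c("|", ":")
  if (!any(paired)) {
    warning("no paired positions: energy 0")
    return(0)
  }
  e <- 0
  ncol <- length(pairing)
  if (ncol >= 2L) {
    for (c0 in seq_len(ncol - 1L)) {
      if (paired[c0] && paired[c0 + 1L]) {
        if (pairing[c0] == "|" && pairing[c0 + 1L] == "|") {
          e <- e + PK_NN_STACK[paste0(tchars[c0], tchars[c0 + 1L])]
        } else {
          e <- e + params$wobble_stack_dg
        }
      }
    }
  }
  # interior loops/bulges: unpaired runs strictly between paired columns
  idx <- which(paired)
  inner <- pairing[idx[1L]:idx[length(idx)]]
  runs <- rle(inner %in% c("|", ":"))
  n_loops <- sum(!runs$values)
  e <- e + n_loops * params$loop_penalty_dg
  unname(e)
}

#' Predict piRNA targets over anticorrelated candidate pairs
#'
#' Aligns each candidate (piRNA, target) pair and retains duplexes passing
#' both gates: alignment score >= `score_min` and free energy <=
#' `energy_max` kcal/mol. Pairs whose sequences cannot be resolved are
#' recorded as errors and skipped; the run continues.
#'
#' @param pairs `data.frame(pirna_id, target_id)`, e.g. from
#'   [anticorrelated_pairs()].
#' @param pirna_seqs,target_seqs named character vectors id -> sequence.
#' @param score_min,energy_max the two gates (defaults 170 and -20).
#' @param params scoring parameters from [duplex_params()].
#' @return `data.table` sorted by descending score with columns `pirna_id`,
#'   `target_id`, `score`, `energy`, `window_start`, `window_end`,
#'   `pairing`; attribute `errors` lists unresolvable pairs.
#' @export
predict_targets <- function(pairs, pirna_seqs, target_seqs,
                            score_min = 170, energy_max = -20,
                            params = duplex_params()) {
  pairs <- as.data.frame(pairs)
  rows <- list()
  errors <- list()
  for (i in seq_len(nrow(pairs))) {
    pid <- pairs$pirna_id[i]; tid <- pairs$target_id[i]
    ps <- unname(pirna_seqs[match(pid, names(pirna_seqs))])
    ts <- unname(target_seqs[match(tid, names(target_seqs))])
    if (is.na(ps) || is.na(ts)) {
      errors[[length(errors) + 1L]] <-
        data.table(pirna_id = pid, target_id = tid,
                   error = "missing sequence")
      next
    }
    aln <- tryCatch(duplex_align(ps, ts, params = params), error = function(e) e)
    if (inherits(aln, "error")) {
      errors[[length(errors) + 1L]] <-
        data.table(pirna_id = pid, target_id = tid,
                   error = conditionMessage(aln))
      next
    }
    if (aln$score >= score_min && aln$energy <= energy_max) {
      rows[[length(rows) + 1L]] <- data.table(
        pirna_id = pid, target_id = tid, score = aln$score,
        energy = aln$energy, window_start = aln$target_start,
        window_end = aln$target_end, pairing = aln$pairing
      )
    }
  }
  out <- if (length(rows)) data.table::rbindlist(rows) else
    data.table(pirna_id = character(), target_id = character(),
               score = numeric(), energy = numeric(),
               window_start = integer(), window_end = integer(),
               pairing = character())
  setorderv(out, c("score", "pirna_id", "target_id"), order = c(-1L, 1L, 1L))
  err <- if (length(errors)) data.table::rbindlist(errors) else
    data.table(pirna_id = character(), target_id = character(),
               error = character())
  data.table::setattr(out, "errors", err)
  out[]
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random shuffle preserving the exact dinucleotide composition (random
#' Eulerian-walk construction), the standard negative control for
#' complementarity scoring.
#'
#' @param seq sequence to shuffle.
#' @param seed optional integer seed for reproducibility.
#' @return shuffled sequence of identical length and dinucleotide counts.
#' @export
shuffle_dinucleotide <- function(seq, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- strsplit(pk_norm_seq(seq, "seq"), "")[[1]]
  n <- length(s)
  if (n <= 2L) return(paste(s, collapse = ""))
  verts <- unique(s)
  edges <- lapply(setNames(verts, verts),
                  function(v) s[which(s[-n] == v) + 1L])
  last <- s[n]
  # pick random terminal edges forming a tree into the final vertex
  repeat {
    term <- vapply(verts, function(v) {
      if (v == last || !length(edges[[v]])) NA_character_
      else edges[[v]][sample.int(length(edges[[v]]), 1L)]
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last || !length(edges[[v]])) next
      cur <- v; steps <- 0L
      while (cur != last && steps <= length(verts)) {
        cur <- term[[cur]]
        if (is.na(cur)) break
        steps <- steps + 1L
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  pools <- lapply(setNames(verts, verts), function(v) {
    e <- edges[[v]]
    if (v != last && length(e)) {
      drop <- match(term[[v]], e)
      e <- e[-drop]
    }
    if (length(e) > 1L) e <- e[sample.int(length(e))]
    e
  })
  out <- character(n)
  out[1L] <- s[1L]
  ptr <- setNames(rep(1L, length(verts)), verts)
  for (i in 2L:n) {
    v <- out[i - 1L]
    if (ptr[[v]] <= length(pools[[v]])) {
      out[i] <- pools[[v]][ptr[[v]]]
      ptr[[v]] <- ptr[[v]] + 1L
    } else {
      out[i] <- term[[v]]
    }
  }
  paste(out, collapse = "")
}
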