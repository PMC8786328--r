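test_that("kdist_profile matches the all-pairs oracle", {
  expect_equal(kdist_profile(c(0, 10, 20), k = 1)$distances, c(10, 10, 10))
  expect_equal(kdist_profile(c(0, 1, 100), k = 2)$distances,
               oracle_kdist(c(0, 1, 100), 2))
  set.seed(11)
  for (k in c(1L, 3L, 5L)) {
    pos <- sort(sample.int(10000, 60))
    expect_equal(kdist_profile(pos, k)$distances, oracle_kdist(pos, k))
  }
})

test_that("kdist_profile reports reads without enough neighbours", {
  prof <- suppressWarnings(kdist_profile(5, k = 1))
  expect_length(prof$distances, 0)
  expect_equal(prof$n_omitted, 1L)
  expect_warning(kdist_profile(c(5, 9), k = 3), "fewer than k\\+1")
})

test_that("estimate_eps picks the modal bin, ties toward smaller distance", {
  mkprof <- function(d) structure(list(chrom = "c", k = 1L, distances = d,
                                       n_omitted = 0L), class = "kdist_profile")
  # dominant mode near 10 beats a sparse tail at 50
  eps <- estimate_eps(mkprof(c(rep(10, 40), rep(50, 3))), bin_width = 5)
  expect_equal(as.integer(eps), 15L) # upper edge of the [10,15) bin
  # single repeated distance
  eps <- estimate_eps(mkprof(rep(7, 20)), bin_width = 2)
  expect_true(7 >= as.integer(eps) - 2 && 7 < as.integer(eps))
  # bimodal tie resolves toward the smaller distance
  eps <- estimate_eps(mkprof(c(rep(10, 8), rep(100, 8))), bin_width = 5)
  expect_equal(as.integer(eps), 15L)
  expect_error(estimate_eps(mkprof(numeric(0))), "supply eps manually")
})

test_that("dbscan_1d follows the spec examples", {
  # 10 consecutive reads, spacing 100 < eps: one cluster of all 10
  lab <- dbscan_1d(seq(0, 900, by = 100), eps = 150, min_reads = 3)
  expect_equal(lab, rep(1L, 10))
  # below MinReads: noise
  expect_equal(dbscan_1d(c(0, 10), eps = 100, min_reads = 3), c(0L, 0L))
  # two far blocks: two clusters
  pos <- c(1:5, 10000 + 1:5)
  lab <- dbscan_1d(pos, eps = 10, min_reads = 3)
  expect_equal(lab, rep(c(1L, 2L), each = 5))
})

test_that("dbscan_1d equals the density-reachability closure oracle", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(5:200, 1)
    pos <- sample.int(5000, n, replace = TRUE)
    eps <- sample(1:300, 1)
    min_reads <- sample(2:8, 1)
    got <- canon_labels(pos, dbscan_1d(pos, eps, min_reads))
    want <- canon_labels(pos, oracle_dbscan(pos, eps, min_reads))
    expect_equal(got, want,
                 info = sprintf("n=%d eps=%d min_reads=%d", n, eps, min_reads))
  }
})

test_that("dbscan_1d is permutation invariant up to renumbering", {
  set.seed(7)
  pos <- sample.int(2000, 150, replace = TRUE)
  base <- canon_labels(pos, dbscan_1d(pos, 40, 4))
  for (i in 1:5) {
    perm <- sample.int(length(pos))
    lab <- canon_labels(pos[perm], dbscan_1d(pos[perm], 40, 4))
    expect_equal(lab, base[perm])
  }
})

test_that("enlarging eps only merges clusters, never splits them", {
  set.seed(13)
  pos <- sort(sample.int(20000, 300, replace = TRUE))
  lab1 <- dbscan_1d(pos, 50, 4)
  lab2 <- dbscan_1d(pos, 200, 4)
  # every eps-50 cluster maps into a single eps-200 cluster
  for (cl in unique(lab1[lab1 > 0])) {
    parent <- unique(lab2[lab1 == cl])
    expect_length(parent, 1)
    expect_gt(parent, 0)
  }
})

test_that("score_cluster is the reads/MinReads ratio", {
  grid <- expand.grid(m = 1:10, mult = 1:10)
  n <- grid$m * grid$mult
  expect_equal(score_cluster(n, grid$m), n / grid$m)
  expect_equal(score_cluster(50, 5), 10)
  expect_equal(score_cluster(7, 2), 3.5)
  expect_equal(score_cluster(4, 4), 1)
  expect_error(score_cluster(5, 0), "min_reads")
  expect_error(score_cluster(3, 5), "n_reads")
})

test_that("classify_strandedness applies the dual-strand rule", {
  expect_equal(classify_strandedness(rep("+", 5))$strandedness, "uni_plus")
  expect_equal(classify_strandedness(rep("-", 3))$strandedness, "uni_minus")
  res <- classify_strandedness(c("+", "+", "+", "+", "-"))
  expect_equal(res$strandedness, "dual")
  expect_equal(res$n_plus, 4L)
  expect_equal(res$n_minus, 1L)
  expect_error(classify_strandedness(character(0)), "empty")
  expect_error(classify_strandedness(c("+", ".")), "strand required")
})

test_that("detect_clusters recovers planted blocks and labels members", {
  sim <- simulate_clustered_reads(seed = 5)
  cl <- detect_clusters(sim$reads, k = 4, eps = 150, min_reads = 5)
  expect_equal(nrow(cl), 3L)
  rec <- cluster_recovery(cl, sim$truth$clusters)
  expect_equal(rec$recall, 1)
  expect_equal(rec$precision, 1)
  expect_equal(cl$strandedness, sim$truth$clusters$strandedness)
  # member reads lie within the cluster interval; intervals are sorted
  for (i in seq_len(nrow(cl))) {
    m <- cl$members[[i]]
    expect_true(all(sim$reads$start[m] >= cl$start[i]))
    expect_true(all(sim$reads$end[m] <= cl$end[i]))
    expect_equal(cl$n_reads[i], length(m))
    expect_equal(cl$score[i], cl$n_reads[i] / cl$min_reads[i])
  }
  expect_false(is.unsorted(cl$start))
  # noise side channel covers exactly the unclustered reads
  expect_equal(sort(c(unlist(cl$members), attr(cl, "noise"))),
               seq_len(nrow(sim$reads)))
})

test_that("detect_clusters handles empty and sparse chromosomes", {
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), read_id = character(),
                                  strand = character(), copy_count = integer())
  expect_equal(nrow(detect_clusters(empty, eps = 100)), 0L)
  sparse <- data.table::data.table(
    chrom = "chr1", start = seq(0, 9000, by = 1000),
    end = seq(0, 9000, by = 1000) + 28L,
    read_id = paste0("r", 1:10), strand = "+", copy_count = 1L)
  cl <- detect_clusters(sparse, eps = 100, min_reads = 5)
  expect_equal(nrow(cl), 0L)
  expect_length(attr(cl, "noise"), 10L)
})

test_that("auto-eps lies between intra-cluster and background spacing", {
  sim <- simulate_clustered_reads(seed = 9)
  cl <- detect_clusters(sim$reads, k = 4)
  eps <- attr(cl, "params")[["chrSim"]]$eps
  expect_gt(eps, sim$truth$intra_spacing_mean)
  expect_lt(eps, sim$truth$background_spacing_mean)
  rec <- cluster_recovery(cl, sim$truth$clusters)
  expect_equal(rec$recall, 1)
})

test_that("alternative cluster-score denominator is selectable", {
  sim <- simulate_clustered_reads(seed = 3)
  a <- detect_clusters(sim$reads, k = 4, eps = 150, min_reads = 5)
  b <- detect_clusters(sim$reads, k = 4, eps = 150, min_reads = 5,
                       score_denominator = "min_reads_k")
  expect_equal(b$score, a$score / 4)
})

test_that("cluster BED export encodes score and strandedness", {
  sim <- simulate_clustered_reads(seed = 2, strandedness = c("+", "-", "dual"))
  cl <- detect_clusters(sim$reads, k = 4, eps = 150, min_reads = 5)
  f <- withr::local_tempfile(fileext = ".bed")
  write_cluster_bed(cl, f)
  fields <- strsplit(readLines(f), "\t")
  expect_equal(vapply(fields, `[`, "", 6L), c("+", "-", "."))
  expect_equal(as.numeric(vapply(fields, `[`, "", 5L)), cl$score)
})
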