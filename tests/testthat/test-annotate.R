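ann_fixture <- function() {
  list(
    CDS = annotation_set(data.frame(chrom = "chr1", start = 1000, end = 2000),
                         "CDS"),
    utr5 = annotation_set(data.frame(chrom = "chr1", start = 900, end = 1000),
                          "utr5"),
    utr3 = annotation_set(data.frame(chrom = "chr1", start = 2000, end = 2300),
                          "utr3"),
    exon = annotation_set(data.frame(chrom = "chr1",
                                     start = c(900, 2000), end = c(2300, 2300)),
                          "exon"),
    intron = annotation_set(data.frame(chrom = "chr1", start = 2300, end = 5000),
                            "intron"),
    "repeat" = annotation_set(
      data.frame(chrom = "chr1", start = c(2400, 6000), end = c(2600, 6500),
                 family = c("SINE", "Weird_family")), "repeat"),
    pseudogene = annotation_set(data.frame(chrom = "chr1", start = 7000,
                                           end = 7500), "pseudogene"),
    lncRNA = annotation_set(data.frame(chrom = "chr1", start = 8000,
                                       end = 9000), "lncRNA")
  )
}

test_that("classify_loci applies the precedence order and totality", {
  ann <- ann_fixture()
  loci <- data.frame(
    chrom = "chr1",
    start = c(1500, 950, 2100, 2450, 20000, 100),
    end = c(1530, 980, 2130, 2480, 20030, 130)
  )
  got <- classify_loci(loci, ann)
  # CDS beats the surrounding exon; 5'UTR beats exon; 3'UTR beats exon;
  # intron locus reports its SINE overlap; everything else is intergenic
  expect_equal(got$primary_category,
               c("CDS", "utr5", "utr3", "intron", "intergenic", "intergenic"))
  expect_equal(got$repeat_families[4], "SINE:30")
  expect_true(all(nchar(got$primary_category) > 0))
})

test_that("classification is exhaustive and exclusive on random loci", {
  ann <- ann_fixture()
  set.seed(5)
  start <- sample.int(25000, 300)
  got <- classify_loci(data.frame(chrom = "chr1", start = start,
                                  end = start + 30), ann)
  expect_equal(nrow(got), 300L)
  expect_true(all(got$primary_category %in%
                    c("CDS", "utr5", "utr3", "exon_other", "intron",
                      "intergenic")))
})

test_that("repeat families outside the canonical seven report as other", {
  ann <- ann_fixture()
  got <- classify_loci(data.frame(chrom = "chr1", start = 6100, end = 6130), ann)
  expect_equal(got$repeat_families, "other:30")
})

test_that("unknown chromosome classifies intergenic with a warning", {
  ann <- ann_fixture()
  expect_warning(
    got <- classify_loci(data.frame(chrom = "chrUn", start = 10, end = 40), ann),
    "absent from annotation")
  expect_equal(got$primary_category, "intergenic")
  expect_false(got$pseudogene_overlap)
})

test_that("pseudogene and lncRNA overlaps are reported independently", {
  ann <- ann_fixture()
  got <- classify_loci(data.frame(chrom = "chr1", start = c(7100, 8100),
                                  end = c(7130, 8130)), ann)
  expect_equal(got$primary_category, c("intergenic", "intergenic"))
  expect_equal(got$pseudogene_overlap, c(TRUE, FALSE))
  expect_equal(got$lncRNA_overlap, c(FALSE, TRUE))
})

test_that("cluster_feature_overlap computes union-of-intersection lengths", {
  feats <- annotation_set(data.frame(chrom = "chr1", start = 500, end = 700),
                          "lncRNA")
  got <- cluster_feature_overlap(
    data.frame(chrom = "chr1", start = 0, end = 1000), feats)
  expect_equal(got$overlap_bp, 200L)
  # overlapping features are not double-counted
  feats2 <- annotation_set(data.frame(chrom = "chr1", start = c(0, 50),
                                      end = c(100, 150)), "repeat")
  got2 <- cluster_feature_overlap(
    data.frame(chrom = "chr1", start = 0, end = 1000), feats2)
  expect_equal(got2$overlap_bp, 150L)
  # no features on the chromosome
  got3 <- cluster_feature_overlap(
    data.frame(chrom = "chr9", start = 0, end = 1000), feats)
  expect_equal(got3$overlap_bp, 0L)
  expect_false(got3$overlapped)
})

test_that("overlap lengths equal the per-base oracle on random instances", {
  set.seed(17)
  for (rep in 1:10) {
    nf <- sample(1:8, 1)
    fs <- sample.int(9e4, nf)
    fe <- fs + sample.int(5000, nf)
    feats <- annotation_set(data.frame(chrom = "chr1", start = fs, end = fe),
                            "repeat")
    cs <- sample.int(8e4, 1)
    ce <- cs + sample.int(2e4, 1)
    got <- cluster_feature_overlap(data.frame(chrom = "chr1", start = cs,
                                              end = ce), feats)
    expect_equal(got$overlap_bp, oracle_perbase_overlap(cs, ce, fs, fe))
  }
})

test_that("synteny remapping interpolates, reflects and inverts", {
  blocks <- data.frame(chrom = "chr1", start = 1000, end = 2000,
                       target_species = "mmu", target_chrom = "chr5",
                       target_start = 50000, target_end = 52000,
                       orientation = "same")
  # contained interval maps proportionally (2x scale here)
  got <- remap_through_synteny(data.frame(chrom = "chr1", start = 1250,
                                          end = 1500), blocks)
  expect_equal(got$target_start, 50500L)
  expect_equal(got$target_end, 51000L)
  # flipped block reflects within the target
  blocks$orientation <- "flipped"
  got <- remap_through_synteny(data.frame(chrom = "chr1", start = 1250,
                                          end = 1500), blocks)
  expect_equal(got$target_start, 51000L)
  expect_equal(got$target_end, 51500L)
  # outside all blocks
  expect_equal(nrow(remap_through_synteny(
    data.frame(chrom = "chr1", start = 5000, end = 6000), blocks)), 0L)
  # invertibility: map forward then back through the inverse block
  inverse <- data.frame(chrom = "chr5", start = 50000, end = 52000,
                        target_species = "hsa", target_chrom = "chr1",
                        target_start = 1000, target_end = 2000,
                        orientation = "flipped")
  set.seed(3)
  for (i in 1:10) {
    s <- sample(1000:1900, 1)
    e <- s + sample(10:90, 1)
    fwd <- remap_through_synteny(data.frame(chrom = "chr1", start = s, end = e),
                                 blocks)
    back <- remap_through_synteny(
      data.frame(chrom = "chr5", start = fwd$target_start,
                 end = fwd$target_end), inverse)
    expect_lte(abs(back$target_start - s), 1)
    expect_lte(abs(back$target_end - e), 1)
  }
})

test_that("partially contained intervals map only their contained part", {
  blocks <- data.frame(chrom = "chr1", start = 1000, end = 2000,
                       target_species = "mmu", target_chrom = "chr5",
                       target_start = 0, target_end = 1000,
                       orientation = "same")
  got <- remap_through_synteny(data.frame(chrom = "chr1", start = 500,
                                          end = 1500), blocks)
  expect_equal(got$target_start, 0L)
  expect_equal(got$target_end, 500L)
})

test_that("infer_introns complements exons within the gene span", {
  introns <- infer_introns(
    data.frame(chrom = "chr1", start = 0, end = 1000),
    data.frame(chrom = "chr1", start = c(0, 400, 900), end = c(100, 500, 1000)))
  expect_equal(introns$start, c(100L, 500L))
  expect_equal(introns$end, c(400L, 900L))
})
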