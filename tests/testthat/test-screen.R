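# A matrix where every marker is a clean 4D survivor unless noted.
screen_fixture <- function() {
  n <- 40L  # samples
  mk <- data.frame(id = sprintf("k%02d", 1:6), chrom = "chr1",
                   pos = seq(1000L, by = 1000L, length.out = 6),
                   ref = "A", alt = "G")
  good <- function(n_het, n_alt, n_miss = 0L) {
    c(rep(1L, n_het), rep(2L, n_alt),
      rep(NA_integer_, n_miss), rep(0L, n - n_het - n_alt - n_miss))
  }
  calls <- cbind(
    good(4L, 14L),            # k01 het .1, maf (2*14+4)/80 = .4 -> pass
    good(8L, 12L),            # k02 het .2 exactly -> boundary reject
    good(4L, 14L, 4L),        # k03 missing .1 -> reject
    good(4L, 10L),            # k04 maf (24)/80 = .3 exactly -> boundary reject
    good(0L, 16L),            # k05 maf .4, het 0 -> pass
    good(4L, 14L))            # k06 pass unless flank decoy planted
  genotype_matrix(calls, mk, sprintf("s%02d", 1:n))
}

test_that("each criterion rejects strictly at its boundary and passes inside it", {
  x <- screen_fixture()
  fold <- rep("FOURFOLD", 6)
  av <- rbind(x$markers[, c("chrom", "pos")],
              data.frame(chrom = "chr1", pos = 6050L))  # decoy 50 bp from k06
  res <- filter_candidates(x, filter_criteria(), fold, av)
  expect_identical(res$matrix$markers$id, c("k01", "k05"))
  expect_equal(res$report$input_count, 6)
  expect_equal(res$report$surviving_count, 2)
  r <- res$report$rejections
  expect_equal(unname(r["heterozygosity"]), 1L)  # k02 at 0.2 exactly
  expect_equal(unname(r["missing"]), 1L)         # k03 at 0.1
  expect_equal(unname(r["maf"]), 1L)             # k04 at 0.3 exactly
  expect_equal(unname(r["flank"]), 1L)           # k06 decoy at +50
  expect_equal(sum(r), res$report$input_count - res$report$surviving_count)
})

test_that("markers failing 4D or biallelic criteria are attributed first", {
  x <- screen_fixture()
  x$markers$is_biallelic[1] <- FALSE  # simulate a triallelic record
  fold <- c("FOURFOLD", "NONCODING", rep("FOURFOLD", 4))
  res <- filter_candidates(x, filter_criteria(), fold,
                           x$markers[, c("chrom", "pos")])
  r <- res$report$rejections
  expect_equal(unname(r["biallelic"]), 1L)
  # k02 fails both 4D and heterozygosity; attribution goes to 4D, the
  # earlier criterion in the stated order
  expect_equal(unname(r["fourfold"]), 1L)
  expect_equal(unname(r["heterozygosity"]), 0L)
  expect_identical(res$detail$rejected_by[res$detail$id == "k02"], "fourfold")
})

test_that("the surviving set is an intersection: order-independent and idempotent", {
  plan <- synth_plan(n_samples = 30, n_markers = 12, fraction_4d = 0.75,
                     n_decoy_variants = 2, het_rate = 0.1,
                     missing_rate = 0.02, seed = 21)
  fx <- synth_fixture(plan, withr::local_tempdir())
  g <- read_genome(fx$fasta)
  cds <- read_cds(fx$gff3, g)
  x <- read_vcf(fx$vcf)
  fold <- classify_sites(x$markers[, c("chrom", "pos")], cds, g)
  av <- x$markers[, c("chrom", "pos")]
  res <- filter_candidates(x, filter_criteria(), fold, av)
  # intersection of individual criterion sets equals the survivors
  det <- res$detail
  masks <- det[, c("biallelic", "fourfold", "heterozygosity", "missing",
                   "maf", "flank")]
  expect_identical(res$matrix$markers$id, det$id[Reduce(`&`, masks)])
  # idempotence: filtering the survivors again changes nothing
  keep_ids <- res$matrix$markers$id
  fold2 <- fold[match(keep_ids, x$markers$id)]
  res2 <- filter_candidates(res$matrix, filter_criteria(), fold2, av)
  expect_identical(res2$matrix$markers$id, keep_ids)
  expect_equal(res2$report$surviving_count, res$report$surviving_count)
  expect_equal(sum(res2$report$rejections), 0L)
})

test_that("requiring 4D without fold classes is an explicit error", {
  x <- screen_fixture()
  expect_error(filter_candidates(x, filter_criteria()), "fold_classes")
  # disabled 4D criterion needs none
  res <- filter_candidates(x, filter_criteria(require_4d = FALSE),
                           all_variants = x$markers[, c("chrom", "pos")])
  expect_gt(res$report$surviving_count, 0)
})

test_that("KASP window checks: GC boundary, flank cleanliness, uniqueness", {
  # 601-bp chromosome, marker at 301: full 100-bp flanks
  withr::with_seed(3, {
    seq1 <- paste(sample(c("A", "C", "G", "T"), 601, replace = TRUE),
                  collapse = "")
  })
  g <- Biostrings::DNAStringSet(c(chr1 = seq1))
  mk <- data.frame(id = "m1", chrom = "chr1", pos = 301L, ref = "A", alt = "G")
  av <- mk[, c("chrom", "pos")]
  k <- validate_kasp_candidate(mk, g, av)
  expect_equal(nchar(k$flank_up), 100)
  expect_equal(nchar(k$flank_down), 100)
  expect_equal(nchar(k$window), 201)
  w <- Biostrings::DNAString(k$window)
  gc_hand <- sum(Biostrings::letterFrequency(w, c("G", "C"))) / 201
  expect_equal(k$gc_content, gc_hand)
  expect_true(k$flank_clean)
  expect_true(k$unique_in_genome)
  expect_false(k$at_contig_edge)
  expect_true(k$designable)
  # 120 G/C in 201 bp is 59.7%, passing the strict < 60% bound
  expect_true(120 / 201 < 0.60)
  expect_false(round(121 / 201, 10) < 0.60)

  # a variant at -37 bp poisons the flank
  av2 <- rbind(av, data.frame(chrom = "chr1", pos = 301L - 37L))
  expect_false(validate_kasp_candidate(mk, g, av2)$flank_clean)
  expect_false(validate_kasp_candidate(mk, g, av2)$designable)

  # duplicating the window elsewhere kills uniqueness
  g2 <- Biostrings::DNAStringSet(c(chr1 = seq1, chr2 = k$window))
  expect_false(validate_kasp_candidate(mk, g2, av)$unique_in_genome)

  # near the contig edge: truncated flank is flagged, not fatal
  mk_edge <- data.frame(id = "m2", chrom = "chr1", pos = 30L,
                        ref = "A", alt = "G")
  ke <- validate_kasp_candidate(mk_edge, g, mk_edge[, c("chrom", "pos")])
  expect_true(ke$at_contig_edge)
  expect_equal(nchar(ke$flank_up), 29)
})

test_that("kasp_screen summarizes designability across a matrix", {
  plan <- synth_plan(n_samples = 10, n_markers = 6, n_decoy_variants = 1,
                     seed = 31)
  fx <- synth_fixture(plan, withr::local_tempdir())
  g <- read_genome(fx$fasta)
  x <- read_vcf(fx$vcf)
  av <- x$markers[, c("chrom", "pos")]
  scr <- kasp_screen(fx$matrix, g, av)
  expect_equal(nrow(scr), 6)
  decoy_id <- fx$manifest$markers$id[fx$manifest$markers$role == "decoy"]
  expect_false(scr$flank_clean[scr$id == decoy_id])
  expect_true(all(scr$flank_clean[scr$id != decoy_id]))
})
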