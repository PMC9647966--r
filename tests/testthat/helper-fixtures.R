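# In-code fixture builders shared across test files.

# Small deterministic matrix with known structure:
# 5 samples x 3 markers; samples s1 and s2 collide on markers {m1, m2}
# but are separated by m3.
toy_matrix <- function() {
  markers <- data.frame(id = c("m1", "m2", "m3"),
                        chrom = "chr1", pos = c(100L, 300L, 500L),
                        ref = c("A", "C", "G"), alt = c("G", "T", "C"))
  calls <- rbind(
    s1 = c(0L, 1L, 0L),
    s2 = c(0L, 1L, 2L),
    s3 = c(1L, 0L, 0L),
    s4 = c(2L, 2L, 1L),
    s5 = c(2L, 0L, NA))
  genotype_matrix(calls, markers, rownames(calls))
}

# Random biallelic SNP matrix (no flagged records), seeded.
random_matrix <- function(n_samples, n_markers, seed,
                          missing_rate = 0.05) {
  withr::with_seed(seed, {
    nuc <- c("A", "C", "G", "T")
    ref <- sample(nuc, n_markers, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nuc, r), 1), character(1))
    markers <- data.frame(id = sprintf("m%03d", seq_len(n_markers)),
                          chrom = "chr1",
                          pos = seq(100L, by = 250L, length.out = n_markers),
                          ref = ref, alt = alt)
    calls <- matrix(sample(0:2, n_samples * n_markers, replace = TRUE),
                    nrow = n_samples)
    calls[matrix(runif(length(calls)) < missing_rate,
                 nrow = n_samples)] <- NA_integer_
    genotype_matrix(calls, markers, sprintf("s%03d", seq_len(n_samples)))
  })
}

# Hand-written VCF text fixture: 3 samples, 2 records.
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsA\tsB\tsC",
    "chr1\t100\trec1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\trec2\tC\tT\t.\tPASS\t.\tGT\t./.\t1|0\t./1"),
    path)
  path
}

# Brute-force fold-class oracle built directly from the codon table,
# independent of the classifier's codon reconstruction.
fold_oracle <- function(codon, pos) {
  nuc <- c("A", "C", "G", "T")
  code <- Biostrings::GENETIC_CODE
  b <- strsplit(codon, "")[[1]]
  aa <- code[[codon]]
  n <- sum(vapply(nuc, function(x) {
    v <- b; v[pos] <- x
    code[[paste(v, collapse = "")]] == aa
  }, logical(1)))
  c("NONDEGENERATE", "TWOFOLD", "THREEFOLD", "FOURFOLD")[n]
}

# Brute-force discernibility recount used as the oracle against the
# genotype-string implementation: tabulates call-code columns directly.
discernibility_oracle <- function(x, panel) {
  idx <- match(panel, x$markers$id)
  cl <- x$calls[, idx, drop = FALSE]
  cl[is.na(cl)] <- 9L
  keys <- apply(cl, 1, paste, collapse = ",")
  length(unique(keys)) / nrow(cl)
}
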