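NUC <- c("A", "C", "G", "T")

#' Plan a synthetic fingerprinting fixture
#'
#' Describes a self-contained toy dataset — genome FASTA, GFF3 annotation
#' and multi-sample VCF — whose statistical structure is fully known in
#' advance, so that every pipeline stage can be tested against a ground
#' truth manifest. The defaults emulate an inbred germplasm panel: low
#' observed heterozygosity (selfed lines), low missingness, and
#' intermediate allele frequencies, the regime in which markers survive
#' the candidate filter.
#'
#' @param n_samples number of samples (default 50).
#' @param n_markers number of SNP marker sites (default 20).
#' @param maf target alternate-allele frequency per marker, scalar or
#'   length-`n_markers` (default 0.4; values are drawn binomially around
#'   the target, they are not forced).
#' @param het_rate target observed heterozygosity, scalar or per-marker
#'   (default 0.05, inbred-like; hybrid panels run around 0.3-0.5).
#' @param missing_rate per-call missing probability, scalar or per-marker
#'   (default 0.02).
#' @param duplicate_groups integer vector of clone-group sizes; each group
#'   is produced by cloning one drawn sample row *after* missing-masking,
#'   so clones are exact string duplicates. Sizes must sum to at most
#'   `n_samples`.
#' @param n_decoy_variants number of markers that get a decoy InDel
#'   planted 50 bp downstream (inside the clean-flank window, so these
#'   markers fail the flank criterion).
#' @param n_multiallelic number of markers written as triallelic records
#'   (fail the biallelic criterion).
#' @param fraction_4d fraction of markers placed at fourfold-degenerate
#'   codon third positions inside synthetic genes; the rest are placed in
#'   intergenic (noncoding) sequence and fail the 4D criterion.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return an object of class `synth_plan`.
#' @export
synth_plan <- function(n_samples = 50L, n_markers = 20L, maf = 0.4,
                       het_rate = 0.05, missing_rate = 0.02,
                       duplicate_groups = integer(0),
                       n_decoy_variants = 0L, n_multiallelic = 0L,
                       fraction_4d = 1.0, seed = 1L) {
  rep_n <- function(v, what) {
    if (length(v) == 1) v <- rep(v, n_markers)
    if (length(v) != n_markers)
      stop(what, " must be scalar or length n_markers")
    if (any(v < 0 | v > 1)) stop(what, " must be in [0, 1]")
    v
  }
  stopifnot(n_samples >= 1, n_markers >= 1,
            fraction_4d >= 0, fraction_4d <= 1,
            n_decoy_variants >= 0, n_multiallelic >= 0)
  if (sum(duplicate_groups) > n_samples)
    stop("duplicate group sizes exceed n_samples")
  if (any(duplicate_groups < 2))
    stop("duplicate groups must have size >= 2")
  n_noncoding <- round((1 - fraction_4d) * n_markers)
  if (n_noncoding + n_decoy_variants + n_multiallelic > n_markers)
    stop("more planted violations than markers")
  structure(list(n_samples = as.integer(n_samples),
                 n_markers = as.integer(n_markers),
                 maf = rep_n(maf, "maf"),
                 het_rate = rep_n(het_rate, "het_rate"),
                 missing_rate = rep_n(missing_rate, "missing_rate"),
                 duplicate_groups = as.integer(duplicate_groups),
                 n_decoy_variants = as.integer(n_decoy_variants),
                 n_multiallelic = as.integer(n_multiallelic),
                 fraction_4d = fraction_4d,
                 n_noncoding = as.integer(n_noncoding),
                 seed = as.integer(seed)),
            class = "synth_plan")
}

all_codons <- function() {
  paste0(rep(NUC, each = 16), rep(rep(NUC, each = 4), 4), rep(NUC, 16))
}

complement1 <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

# Marker roles, assigned in marker order: noncoding sites first, then
# triallelic records, then decoy-flanked markers, then clean 4D markers.
marker_roles <- function(plan) {
  roles <- rep("clean", plan$n_markers)
  i <- 0
  if (plan$n_noncoding > 0) {
    roles[seq_len(plan$n_noncoding)] <- "noncoding"; i <- plan$n_noncoding
  }
  if (plan$n_multiallelic > 0) {
    roles[i + seq_len(plan$n_multiallelic)] <- "multiallelic"
    i <- i + plan$n_multiallelic
  }
  if (plan$n_decoy_variants > 0)
    roles[i + seq_len(plan$n_decoy_variants)] <- "decoy"
  roles
}

#' Generate the toy genome and annotation of a synthetic plan
#'
#' Writes `genome.fa` and `annotation.gff3` under `dir`. The genome has
#' two chromosomes: `chrT`, carrying two genes whose CDS tile all 64
#' codons, one on each strand (the substrate for exhaustive degeneracy
#' checks), and `chr1`, where the plan's marker sites are planted 400 bp
#' apart. Markers of fold target `FOURFOLD` sit at the third position of a
#' GG[N] (glycine) codon inside a 12 bp single-exon gene — on alternating
#' strands, so minus-strand codon reconstruction is exercised — and the
#' genome base at each site equals the marker's reference allele.
#' Noncoding markers sit in intergenic sequence.
#'
#' @param plan a [synth_plan()].
#' @param dir output directory (created if needed).
#' @return list with `fasta`, `gff3`, `markers` (id, chrom, pos, ref,
#'   alt, role, fold_target, strand), `tiling` (per codon-position truth
#'   table for `chrT`) and the chromosome sequences.
#' @export
make_genome <- function(plan, dir) {
  stopifnot(inherits(plan, "synth_plan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(plan$seed, {
    codons <- all_codons()
    codon_seq <- paste(codons, collapse = "")
    spacer <- function(n) paste(sample(NUC, n, replace = TRUE), collapse = "")

    # chrT: plus-strand tiling gene, then minus-strand tiling gene
    p_start <- 61L
    m_start <- p_start + 192L + 60L
    chrT <- paste0(spacer(60), codon_seq, spacer(60),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(codon_seq))), spacer(60))
    tiling <- do.call(rbind, lapply(seq_along(codons), function(i) {
      rbind(
        data.frame(chrom = "chrT", strand = "+",
                   codon = codons[i], codon_pos = 1:3,
                   pos = p_start + 3L * (i - 1L) + 0:2),
        data.frame(chrom = "chrT", strand = "-",
                   codon = codons[i], codon_pos = 1:3,
                   pos = m_start + 192L - (3L * (i - 1L) + 1:3)))
    }))

    # chr1: markers every 400 bp
    roles <- marker_roles(plan)
    n <- plan$n_markers
    pos <- 500L + 400L * (seq_len(n) - 1L)
    chr1_len <- 500L + 400L * n + 200L
    chr1 <- sample(NUC, chr1_len, replace = TRUE)
    ref <- sample(NUC, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(NUC, r), 1), character(1))
    strand <- ifelse(seq_len(n) %% 2 == 1, "+", "-")
    genes <- list()
    for (i in seq_len(n)) {
      if (roles[i] == "noncoding") {
        chr1[pos[i]] <- ref[i]
        next
      }
      if (strand[i] == "+") {
        cds <- paste0("ATGGG", ref[i], "TGGTAA")
        g_start <- pos[i] - 5L
      } else {
        cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
          paste0("ATGGG", complement1(ref[i]), "TGGTAA"))))
        g_start <- pos[i] - 6L
      }
      chr1[g_start:(g_start + 11L)] <- strsplit(cds, "")[[1]]
      stopifnot(chr1[pos[i]] == ref[i])
      genes[[length(genes) + 1]] <-
        data.frame(start = g_start, end = g_start + 11L,
                   strand = strand[i], tx = paste0("tx", i))
    }
    chr1 <- paste(chr1, collapse = "")

    fasta <- file.path(dir, "genome.fa")
    seqs <- Biostrings::DNAStringSet(c(chr1 = chr1, chrT = chrT))
    Biostrings::writeXStringSet(seqs, fasta)

    gff3 <- file.path(dir, "annotation.gff3")
    feat <- rbind(
      data.frame(chrom = "chrT", start = p_start, end = p_start + 191L,
                 strand = "+", tx = "txTplus"),
      data.frame(chrom = "chrT", start = m_start, end = m_start + 191L,
                 strand = "-", tx = "txTminus"),
      if (length(genes)) cbind(chrom = "chr1", do.call(rbind, genes)))
    write_gff3(feat, gff3)

    markers <- data.frame(
      id = sprintf("M%03d", seq_len(n)), chrom = "chr1", pos = pos,
      ref = ref, alt = alt, role = roles,
      fold_target = ifelse(roles == "noncoding", "NONCODING", "FOURFOLD"),
      strand = ifelse(roles == "noncoding", "*", strand),
      stringsAsFactors = FALSE)
    list(fasta = fasta, gff3 = gff3, markers = markers, tiling = tiling,
         sequences = seqs)
  })
}

# Minimal single-exon gene/mRNA/CDS GFF3 writer for the synthetic
# annotation (phase always 0); output parses with rtracklayer/read_cds.
write_gff3 <- function(feat, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(feat))) {
    g <- paste0("gene_", feat$tx[i])
    lines <- c(lines,
      paste(feat$chrom[i], "synth", "gene", feat$start[i], feat$end[i],
            ".", feat$strand[i], ".", paste0("ID=", g), sep = "\t"),
      paste(feat$chrom[i], "synth", "mRNA", feat$start[i], feat$end[i],
            ".", feat$strand[i], ".",
            paste0("ID=", feat$tx[i], ";Parent=", g), sep = "\t"),
      paste(feat$chrom[i], "synth", "CDS", feat$start[i], feat$end[i],
            ".", feat$strand[i], "0",
            paste0("ID=cds_", feat$tx[i], ";Parent=", feat$tx[i]),
            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Draw genotypes for a synthetic plan and write the fixture VCF
#'
#' Per marker, sample genotypes are drawn independently to hit the target
#' heterozygosity and alternate-allele frequency: a sample is het with
#' probability `het_rate`, otherwise hom-alt with probability
#' `(p - het/2) / (1 - het)` (so the expected allele frequency is `p`).
#' Missing calls are then masked at `missing_rate`, and clone groups are
#' copied row-wise *after* masking. Triallelic markers are written with a
#' second alternate allele (one sample carries it); decoy InDels are
#' written as extra records 50 bp downstream of their markers. The
#' ground-truth manifest records both the planted intent and the realized
#' per-marker tallies from the generator's own bookkeeping.
#'
#' @param plan a [synth_plan()].
#' @param genome_info result of [make_genome()].
#' @param dir output directory.
#' @return list with `vcf`, `manifest_path`, `manifest` (list), and the
#'   in-memory `genotype_matrix` of the SNP marker records.
#' @export
make_genotypes <- function(plan, genome_info, dir) {
  stopifnot(inherits(plan, "synth_plan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mk <- genome_info$markers
  n <- plan$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  withr::with_seed(plan$seed + 1L, {
    calls <- matrix(NA_integer_, nrow = n, ncol = plan$n_markers,
                    dimnames = list(samples, mk$id))
    for (j in seq_len(plan$n_markers)) {
      het <- plan$het_rate[j]; p <- plan$maf[j]
      p_hom <- if (het >= 1) 0 else (p - het / 2) / (1 - het)
      p_hom <- min(max(p_hom, 0), 1)
      u <- runif(n)
      cj <- ifelse(u < het, 1L, ifelse(runif(n) < p_hom, 2L, 0L))
      cj[runif(n) < plan$missing_rate[j]] <- NA_integer_
      calls[, j] <- cj
    }
    # clone duplicate groups (after masking, so clones are exact)
    dup_members <- list()
    at <- 1L
    for (g in plan$duplicate_groups) {
      members <- samples[at:(at + g - 1L)]
      calls[members, ] <- rep(calls[members[1], ], each = g)
      dup_members[[length(dup_members) + 1]] <- members
      at <- at + g
    }

    # assemble records: markers plus decoy InDels
    alt <- mk$alt
    third <- vapply(seq_len(nrow(mk)), function(i)
      sample(setdiff(NUC, c(mk$ref[i], mk$alt[i])), 1), character(1))
    alt[mk$role == "multiallelic"] <-
      paste0(mk$alt, ",", third)[mk$role == "multiallelic"]
    gt <- matrix(call_to_gt(calls), nrow = n, dimnames = dimnames(calls))
    # third-allele carrier: first sample outside the clone blocks, so that
    # planting a triallelic record never splits a planted duplicate group
    carrier <- if (sum(plan$duplicate_groups) < n)
      sum(plan$duplicate_groups) + 1L else NA_integer_
    for (j in which(mk$role == "multiallelic")) {
      if (is.na(carrier)) break
      gt[carrier, j] <- "0/2"
      calls[carrier, j] <- NA_integer_  # not representable as a biallelic call
    }
    rec <- data.frame(id = mk$id, chrom = mk$chrom, pos = mk$pos,
                      ref = mk$ref, alt = alt, stringsAsFactors = FALSE)
    decoys <- NULL
    if (any(mk$role == "decoy")) {
      di <- which(mk$role == "decoy")
      dpos <- mk$pos[di] + 50L
      dref <- vapply(dpos, function(p)
        genome_fetch(genome_info$sequences, "chr1", p, p + 1L), character(1))
      decoys <- data.frame(id = paste0("D", mk$id[di]), chrom = "chr1",
                           pos = dpos, ref = dref,
                           alt = substr(dref, 1, 1),
                           stringsAsFactors = FALSE)
    }
    all_rec <- rbind(rec, decoys)
    gt_all <- rbind(t(gt), matrix("0/0", nrow = NROW(decoys), ncol = n))
    ord <- order(all_rec$chrom, all_rec$pos)
    vcf <- file.path(dir, "genotypes.vcf")
    writeLines(c(vcf_header_lines(samples),
                 vcf_record_lines(all_rec[ord, ], gt_all[ord, , drop = FALSE])),
               vcf)

    realized <- data.frame(
      id = mk$id,
      n_het = colSums(calls == 1L, na.rm = TRUE),
      n_hom_alt = colSums(calls == 2L, na.rm = TRUE),
      n_missing = colSums(is.na(calls)),
      n_called = colSums(!is.na(calls)))
    realized$p_alt <- (2 * realized$n_hom_alt + realized$n_het) /
      (2 * realized$n_called)

    manifest <- list(
      plan = unclass(plan), samples = samples,
      markers = cbind(mk, alt_written = alt,
                      target_maf = plan$maf, target_het = plan$het_rate,
                      target_missing = plan$missing_rate),
      realized = realized,
      duplicate_groups = dup_members,
      decoys = decoys)
    manifest_path <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    x <- genotype_matrix(calls, rec, samples)
    list(vcf = vcf, manifest_path = manifest_path, manifest = manifest,
         matrix = x)
  })
}

#' Generate a complete synthetic fixture
#'
#' Convenience wrapper running [make_genome()] then [make_genotypes()].
#'
#' @inheritParams make_genome
#' @return list combining both results: `fasta`, `gff3`, `vcf`,
#'   `manifest_path`, `manifest`, `genome_info`, `matrix`.
#' @export
synth_fixture <- function(plan, dir) {
  gi <- make_genome(plan, dir)
  gg <- make_genotypes(plan, gi, dir)
  c(list(fasta = gi$fasta, gff3 = gi$gff3, genome_info = gi), gg)
}
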