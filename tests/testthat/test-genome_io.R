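# Readers/writers, coordinate conventions, promoter extraction and
# back-translation.

make_gff <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

test_that("GFF coordinates convert to 0-based half-open and ranks follow starts", {
  p <- make_gff(c(
    "chr1\tsrc\tgene\t1\t3\t.\t+\t.\tID=gA",
    "chr1\tsrc\tgene\t101\t200\t.\t-\t.\tID=gB",
    "chr1\tsrc\tgene\t51\t90\t.\t+\t.\tID=gC"))
  g <- read_gff(p)
  genes <- g$genes
  expect_equal(genes$start[genes$gene_id == "gA"], 0L)
  expect_equal(genes$end[genes$gene_id == "gA"], 3L)
  # two genes at starts 100 and 50 -> ranks 1 and 0
  expect_equal(genes$rank[genes$gene_id == "gB"], 2L)
  expect_equal(genes$rank[genes$gene_id == "gC"], 1L)
})

test_that("GFF round-trip is the identity on well-formed files", {
  p <- make_gff(c(
    "chr1\tsrc\tgene\t10\t99\t.\t+\t.\tID=g1",
    "chr2\tsrc\tgene\t5\t64\t.\t-\t.\tID=g2"))
  g <- read_gff(p)
  out <- tempfile(fileext = ".gff3")
  write_gff(g, out)
  g2 <- read_gff(out)
  expect_equal(g2$genes[, c("gene_id", "chrom", "start", "end", "strand")],
               g$genes[, c("gene_id", "chrom", "start", "end", "strand")])
})

test_that("malformed GFF lines and duplicate IDs are rejected with context", {
  bad <- make_gff(c("chr1\tsrc\tgene\t1\t3\t.\t+\t.\tID=g1",
                    "chr1\tsrc\tgene\tbroken"))
  expect_error(read_gff(bad), "line 3")
  dup <- make_gff(c("chr1\tsrc\tgene\t1\t3\t.\t+\t.\tID=g1",
                    "chr1\tsrc\tgene\t10\t30\t.\t+\t.\tID=g1"))
  expect_error(read_gff(dup), "duplicate")
  noid <- make_gff("chr1\tsrc\tgene\t1\t3\t.\t+\t.\tName=g1")
  expect_error(read_gff(noid), "ID")
})

test_that("FASTA reading uppercases, round-trips, and rejects bad records", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">g1", "acGT"), p)
  expect_equal(read_fasta(p), c(g1 = "ACGT"))
  seqs <- c(a = "ACGTACGT", b = "TTTT")
  out <- tempfile(fileext = ".fa")
  write_fasta(seqs, out)
  expect_equal(read_fasta(out), seqs)
  writeLines(c(">g1", "AC", ">g1", "GG"), p)
  expect_error(read_fasta(p), "duplicate")
  writeLines(c(">g1", "AC", ">g2"), p)
  expect_error(read_fasta(p), "empty")
})

test_that("promoters follow strand, are 5'->3', and truncate at boundaries", {
  chrom <- paste0(paste(rep("A", 3000), collapse = ""),
                  paste(rep("C", 2000), collapse = ""),
                  paste(rep("G", 4000), collapse = ""))  # 9000 bp
  genes <- data.frame(
    gene_id = c("plus", "minus", "short"),
    chrom = "chr1",
    start = c(5000L, 5000L, 500L),
    end = c(6000L, 6000L, 900L),
    strand = c("+", "-", "+"))
  # build three single-gene genomes to avoid rank interference
  for (i in 1:3) {
    g <- new_genome(genes[i, ], c(chr1 = 9000), sequences = c(chr1 = chrom))
    prom <- extract_promoters(g, 2000L)
    if (genes$gene_id[i] == "plus") {
      expect_equal(prom[["plus"]], substr(chrom, 3001, 5000))
    } else if (genes$gene_id[i] == "minus") {
      expect_equal(prom[["minus"]],
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(substr(chrom, 6001, 8000)))))
    } else {
      expect_equal(nchar(prom[["short"]]), 500L)
      expect_equal(prom[["short"]], substr(chrom, 1, 500))
    }
  }
})

test_that("promoter lengths never exceed the request or cross boundaries", {
  set.seed(11)
  cfg <- simulation_config(seed = 11, n_chroms = 1L, genes_per_chrom = 20L,
                           wgd_events = list(list(target_ks = 0.3,
                                                  retention_rate = 1)),
                           cds_length_codons = 50L, intergenic_bp = 1200L)
  sim <- simulate_genome(cfg)
  prom <- extract_promoters(sim$genome, 2000L)
  expect_true(all(nchar(prom) <= 2000L))
  expect_true(all(nchar(prom) > 0L))
})

test_that("back-translation maps residue columns to codons and gaps to ---", {
  aln <- backtranslate_alignment(c("MA", "MA"), "ATGGCT", "ATGGCA")
  expect_equal(aln$aligned_a, "ATGGCT")
  expect_equal(aln$aligned_b, "ATGGCA")
  aln2 <- backtranslate_alignment(c("M-A", "MKA"), "ATGGCT", "ATGAAAGCA")
  expect_equal(aln2$aligned_a, "ATG---GCT")
  expect_equal(aln2$aligned_b, "ATGAAAGCA")
  # translation mismatch identifies the offending residue
  expect_error(backtranslate_alignment(c("MA", "MA"), "ATGGTT", "ATGGCA"),
               "residue 2")
  expect_error(backtranslate_alignment(c("MA", "MA"), "ATGGC", "ATGGCA"),
               "divisible")
})

test_that("back-translation with gaps removed reconstitutes the CDS exactly", {
  set.seed(21)
  for (rep in 1:5) {
    cds_a <- random_cds(30)
    cds_b <- random_cds(33)
    pa <- translate_cds(cds_a)
    pb <- translate_cds(cds_b)
    al <- align_proteins_global(pa, pb)
    bt <- backtranslate_alignment(al$aligned, cds_a, cds_b)
    expect_equal(gsub("-", "", bt$aligned_a), cds_a)
    expect_equal(gsub("-", "", bt$aligned_b), cds_b)
    expect_equal(nchar(bt$aligned_a), 3L * nchar(al$aligned[1L]))
  }
})

test_that("codon pairs drop gap/N/stop columns and count exclusions", {
  aln <- list(aligned_a = "ATG---GCTNNGTAA", aligned_b = "ATGAAAGCTGGGTAG")
  # columns: ATG|---|GCT|NNG|TAA vs ATG|AAA|GCT|GGG|TAG
  cp <- codon_pairs(aln)
  expect_equal(cp$codon_a, c("ATG", "GCT"))
  expect_equal(cp$n_excluded, 3L)
})

test_that("expression matrices validate sample structure", {
  m <- matrix(runif(8), 2, 4,
              dimnames = list(c("g1", "g2"),
                              c("CK_day_1", "CK_day_2", "D_night_1",
                                "D_night_2")))
  em <- new_expr_matrix(m)
  expect_equal(em$samples$condition, c("CK", "CK", "D", "D"))
  p <- tempfile(fileext = ".tsv")
  write_expression(em, p)
  em2 <- read_expression(p)
  expect_equal(em2$values, em$values, tolerance = 1e-12)
  m2 <- m
  colnames(m2)[1] <- "XX_day_1"
  expect_error(new_expr_matrix(m2), "condition")
  m3 <- m
  m3[1, 1] <- -1
  expect_error(new_expr_matrix(m3), "negative")
})
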