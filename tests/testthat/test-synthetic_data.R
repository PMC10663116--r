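# Simulator contracts: determinism, WGD retention accounting, divergence
# calibration, expression phasing and motif planting.

test_that("full retention of one WGD doubles the genome and labels all genes", {
  cfg <- simulation_config(seed = 7, n_chroms = 2L, genes_per_chrom = 50L,
                           wgd_events = list(list(target_ks = 0.5,
                                                  retention_rate = 1)),
                           tandem_rate = 0, cds_length_codons = 30L,
                           emit_sequences = FALSE)
  sim <- simulate_genome(cfg)
  expect_equal(length(sim$genome$chrom_lengths), 4L)
  expect_equal(nrow(sim$genome$genes), 200L)
  expect_true(all(sim$truth$genes$origin == "WGD1"))
  expect_equal(nrow(sim$truth$pairs), 100L)
})

test_that("the same seed reproduces the genome byte for byte", {
  cfg <- simulation_config(seed = 12, n_chroms = 1L, genes_per_chrom = 30L,
                           wgd_events = list(list(target_ks = 0.3,
                                                  retention_rate = 0.7)),
                           cds_length_codons = 30L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$genome$genes, b$genome$genes)
  expect_identical(a$genome$sequences, b$genome$sequences)
  expect_identical(a$truth, b$truth)
  ea <- simulate_expression(a$truth, cfg)
  eb <- simulate_expression(b$truth, cfg)
  expect_identical(ea$values, eb$values)
})

test_that("tandem_rate 0 plants no TD labels; tandem copies sit adjacent", {
  cfg0 <- simulation_config(seed = 3, n_chroms = 1L, genes_per_chrom = 40L,
                            wgd_events = list(list(target_ks = 0.2,
                                                   retention_rate = 0.5)),
                            tandem_rate = 0, cds_length_codons = 30L,
                            emit_sequences = FALSE)
  sim0 <- simulate_genome(cfg0)
  expect_false(any(sim0$truth$genes$origin == "TD"))
  cfg1 <- simulation_config(seed = 3, n_chroms = 1L, genes_per_chrom = 60L,
                            wgd_events = list(list(target_ks = 0.2,
                                                   retention_rate = 1)),
                            tandem_rate = 0.2, cds_length_codons = 30L,
                            emit_sequences = FALSE)
  sim1 <- simulate_genome(cfg1)
  td_pairs <- sim1$truth$pairs[sim1$truth$pairs$event == "TD", ]
  expect_gt(nrow(td_pairs), 0L)
  g <- sim1$genome$genes
  for (i in seq_len(nrow(td_pairs))) {
    ra <- g$rank[g$gene_id == td_pairs$gene_a[i]]
    rb <- g$rank[g$gene_id == td_pairs$gene_b[i]]
    expect_lte(abs(ra - rb), cfg1$tandem_max_copies)
    expect_equal(g$chrom[g$gene_id == td_pairs$gene_a[i]],
                 g$chrom[g$gene_id == td_pairs$gene_b[i]])
  }
})

test_that("gene counts after WGD respect retention within binomial bounds", {
  for (rho in c(0.3, 0.7)) {
    cfg <- simulation_config(seed = round(rho * 100), n_chroms = 2L,
                             genes_per_chrom = 150L,
                             wgd_events = list(list(target_ks = 0.4,
                                                    retention_rate = rho)),
                             tandem_rate = 0, cds_length_codons = 30L,
                             emit_sequences = FALSE)
    sim <- simulate_genome(cfg)
    n0 <- 300
    expected <- (1 + rho) * n0
    sd3 <- 3 * sqrt(n0 * rho * (1 - rho))
    expect_lt(abs(nrow(sim$genome$genes) - expected), sd3 + 1)
  }
})

test_that("evolve_pair hits its Ks target and zero divergence is a no-op", {
  cds <- random_cds(200)
  expect_identical(evolve_pair(cds, 0, 0), cds)
  set.seed(41)
  long <- random_cds(10000)
  ev <- evolve_pair(long, 0.5)
  r <- ng86_pair(list(codon_a = split_codons(long),
                      codon_b = split_codons(ev)))
  expect_lt(abs(r$Ks - 0.5), 0.05)
  # evolved sequences stay sense-codon only
  expect_false(any(Biostrings::GENETIC_CODE[split_codons(ev)] == "*"))
})

test_that("a planted Ks of 0.1126 dates to ~7.47 Mya under the default clock", {
  ev <- date_wgd(0.1126, clock_params(7.54e-9))
  expect_equal(ev$age_mya, 7.467, tolerance = 1e-3)
})

test_that("simulated expression obeys the generator contract", {
  classes <- data.frame(
    gene_id = sprintf("g%03d", 1:60),
    diel_class = c(rep("C4-like", 10), rep("CAM-like", 10), rep("none", 40)))
  cfg <- simulation_config(seed = 5)
  expr <- simulate_expression(classes, cfg)
  expect_equal(dim(expr$values), c(60L, 24L))
  means <- sapply(split(seq_len(24),
                        paste(expr$samples$condition, expr$samples$time,
                              sep = "_")),
                  function(cols) rowMeans(expr$values[, cols, drop = FALSE]))
  cam <- classes$diel_class == "CAM-like"
  expect_true(all(means[cam, "D_night"] / means[cam, "CK_night"] > 20))
  # contract is on generator means: pooled over 10 genes the 100x induction
  # is clearly visible
  expect_gt(mean(means[cam, "D_night"]) / mean(means[cam, "CK_night"]), 100 / 2)
  c4 <- classes$diel_class == "C4-like"
  expect_true(all(means[c4, "CK_day"] > 4 * means[c4, "CK_night"]))
})

test_that("motif planting respects rates, bounds and recording", {
  set.seed(6)
  pwm <- demo_pwm()
  promoters <- setNames(
    vapply(1:30, function(i) paleodup:::.random_dna(300), ""),
    sprintf("g%02d", 1:30))
  module <- names(promoters)[1:10]
  pl <- plant_motifs(promoters, pwm, module, rate_module = 1,
                     rate_background = 0)
  expect_equal(nrow(pl$planted), 10L)
  expect_true(all(pl$planted$gene_id %in% module))
  expect_true(all(pl$planted$offset >= 0))
  expect_true(all(pl$planted$offset <= 300 - nrow(pwm$matrix)))
  # promoter shorter than the motif is skipped but recorded
  short <- c(pl0 = "ACGT")
  pl2 <- plant_motifs(short, pwm, "pl0", 1, 0)
  expect_true(is.na(pl2$planted$offset[1]))
  expect_identical(pl2$promoters, short)
})
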