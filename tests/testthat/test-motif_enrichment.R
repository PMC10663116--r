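# PWM parsing, exact p-value scanning, Fisher enrichment, FDR and cluster
# rollup.

jaspar_text <- c(
  ">MA0001.1 testA",
  "A  [ 0 20  0  0 ]",
  "C  [20  0  0  0 ]",
  "G  [ 0  0 20  0 ]",
  "T  [ 0  0  0 20 ]",
  ">MA0002.1 testB",
  "A  [ 5  5 ]",
  "C  [ 5  5 ]",
  "G  [ 5  5 ]",
  "T  [ 5  5 ]")

test_that("JASPAR parsing yields L x 4 matrices with cluster attachment", {
  p <- tempfile(fileext = ".jaspar")
  writeLines(jaspar_text, p)
  pwms <- read_jaspar(p, clusters = c(MA0001.1 = "cl1"))
  expect_length(pwms, 2L)
  expect_equal(dim(pwms$MA0001.1$matrix), c(4L, 4L))
  expect_equal(pwms$MA0001.1$cluster_id, "cl1")
  expect_true(is.na(pwms$MA0002.1$cluster_id))
  expect_equal(unname(pwms$MA0001.1$matrix[1, "C"]), 20)
  cl <- tempfile(fileext = ".tsv")
  writeLines(c("MA0001.1\tcl1", "MA0002.1\tcl2"), cl)
  expect_equal(read_motif_clusters(cl),
               c(MA0001.1 = "cl1", MA0002.1 = "cl2"))
})

test_that("a probability-1 PWM scores ~8 bits with p ~ 1/256 on its consensus", {
  m <- matrix(0, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(1:4, 1:4)] <- 1  # consensus ACGT
  pwm <- new_pwm("one", NA, m)
  hits <- scan_pwm("GGACGTGG", pwm, pseudocount = 1e-6,
                   p_threshold = 0.01)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$offset, 2L)
  expect_equal(plus$score, 8, tolerance = 1e-3)
  expect_equal(plus$p_value, 1 / 256, tolerance = 1e-6)
})

test_that("scanning is strand-symmetric and skips N windows", {
  set.seed(81)
  pwm <- demo_pwm()
  prom <- paste0(paleodup:::.random_dna(400),
                 "TGACGTCAGT", paleodup:::.random_dna(100))
  fwd <- scan_pwm(prom, pwm)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(prom)))
  rev_ <- scan_pwm(rc, pwm)
  # hit sets mirror with strands swapped
  L <- nrow(pwm$matrix)
  n <- nchar(prom)
  key_f <- sort(paste(fwd$offset, fwd$strand))
  key_r <- sort(paste(n - rev_$offset - L,
                      ifelse(rev_$strand == "+", "-", "+")))
  expect_equal(key_f, key_r)
  expect_equal(sort(fwd$p_value), sort(rev_$p_value), tolerance = 1e-12)
  expect_equal(nrow(scan_pwm(strrep("N", 100), pwm)), 0L)
  expect_error(scan_pwm("ACGT", demo_pwm()), "shorter")
  expect_error(scan_pwm(strrep("A", 50), pwm, background = c(0, 1, 1, 1)),
               "positive")
})

test_that("DP tail equals direct enumeration of the discretised distribution", {
  set.seed(82)
  for (L in c(3L, 5L)) {
    counts <- matrix(sample(1:30, L * 4, replace = TRUE), L, 4)
    pwm <- new_pwm("bf", NA, counts)
    bg <- c(0.3, 0.2, 0.2, 0.3)
    tabs <- paleodup:::.pwm_score_tables(pwm, bg, 0.1, 1e-3)
    grid <- as.matrix(expand.grid(rep(list(1:4), L)))
    o_int <- integer(nrow(grid))
    probs <- rep(1, nrow(grid))
    for (l in seq_len(L)) {
      o_int <- o_int + tabs$K[l, grid[, l]]
      probs <- probs * bg[grid[, l]]
    }
    probe <- sample(nrow(grid), min(50L, nrow(grid)))
    for (i in probe) {
      p_dp <- tabs$tail[o_int[i] - tabs$lo + 1L]
      expect_lt(abs(p_dp - sum(probs[o_int >= o_int[i]])), 1e-12)
    }
  }
})

test_that("Fisher enrichment matches the hypergeometric closed form", {
  f <- fisher_enrichment(c(2, 0, 0, 2))
  expect_equal(f$p_value, 1 / 6, tolerance = 1e-12)
  # equal frequencies: OR 1, p >= 0.5
  f2 <- fisher_enrichment(c(10, 90, 10, 90))
  expect_equal(f2$odds_ratio, 1)
  expect_gte(f2$p_value, 0.5)
  set.seed(83)
  for (rep in 1:300) {
    x <- sample(0:12, 4, replace = TRUE)
    if (sum(x) == 0) next
    got <- fisher_enrichment(x)
    want <- oracle_fisher_p(x[1], x[2], x[3], x[4])
    expect_lt(abs(got$p_value - want), 1e-12)
    # cross-check against stats::fisher.test one-sided greater
    ft <- stats::fisher.test(matrix(x, 2, byrow = TRUE),
                             alternative = "greater")
    expect_equal(got$p_value, ft$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_enrichment(c(0, 0, 0, 0)), "all-zero")
})

test_that("BH q-values follow the step-up arithmetic", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(84)
  p <- runif(100)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("gene-level counting and the null identity of enrichment scores", {
  hits <- data.frame(motif_id = "m1",
                     gene_id = c("g1", "g1", "g1", "g2"),
                     offset = c(1, 5, 9, 2), strand = "+",
                     score = 5, p_value = 1e-5)
  modules <- data.frame(gene_id = c("g1", "g2", "g3"),
                        module = "green",
                        membership = c(0.9, 0.79, 0.95))
  cnt <- count_module_occurrences(hits, modules, "green",
                                  expressed = c("g1", "g2", "g3"))
  # g2 at membership 0.79 is excluded from the module
  expect_equal(cnt$module_size, 2L)
  expect_equal(cnt$genes_with_hit_module, 1L)  # g1 counted once
  expect_equal(cnt$genes_with_hit_background, 2L)
  expect_equal(cnt$hits_module, 3L)
  # module == all genes -> enrichment score 0
  modules_all <- data.frame(gene_id = c("g1", "g2"), module = "green",
                            membership = 0.99)
  cnt2 <- count_module_occurrences(hits, modules_all, "green",
                                   expressed = c("g1", "g2"))
  res <- motif_enrichment(cnt2)
  expect_equal(res$enrichment_score, 0)
  expect_warning(
    count_module_occurrences(hits, modules, "absent", expressed = "g1"),
    "empty")
})

test_that("cluster rollup highlights clusters with more than 3 enriched motifs", {
  res <- data.frame(
    motif_id = sprintf("m%d", 1:9),
    cluster_id = c(rep("c1", 4), rep("c2", 3), rep("c3", 2)),
    enriched = c(rep(TRUE, 4), rep(TRUE, 3), FALSE, FALSE))
  expect_equal(aggregate_clusters(res), "c1")
  expect_equal(aggregate_clusters(res, min_enriched = 3L), c("c1", "c2"))
  res$enriched <- FALSE
  expect_length(aggregate_clusters(res), 0L)
})
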