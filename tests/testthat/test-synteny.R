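# Homolog search, chain DP vs exhaustive enumeration, depth profiles,
# tandem arrays and origin classification.

toy_genome <- function(n, chrom = "chr1", prefix = "g") {
  genes <- data.frame(
    gene_id = sprintf("%s%02d", prefix, seq_len(n)),
    chrom = chrom, start = seq_len(n) * 1000L,
    end = seq_len(n) * 1000L + 500L, strand = "+")
  new_genome(genes, setNames(n * 1000L + 1000L, chrom))
}

test_that("identical proteomes pair each gene with its duplicate copy", {
  set.seed(51)
  prots <- setNames(
    vapply(1:6, function(i) translate_cds(random_cds(60)), ""),
    sprintf("p%02d", 1:6))
  dup <- c(prots, setNames(prots, sprintf("q%02d", 1:6)))
  pairs <- find_homolog_pairs(dup, top_n = 1L, min_score = 50)
  expect_equal(nrow(pairs), 6L)  # unordered pairs, self-hits removed
  expect_true(all(substr(pairs$gene_a, 2, 3) == substr(pairs$gene_b, 2, 3)))
  # unrelated random proteins with a high cutoff give nothing
  set.seed(52)
  rnd <- setNames(vapply(1:8, function(i) translate_cds(random_cds(60)), ""),
                  sprintf("r%02d", 1:8))
  expect_equal(nrow(find_homolog_pairs(rnd, min_score = 1e4)), 0L)
  expect_error(find_homolog_pairs(character(0)), "empty")
})

test_that("perfectly collinear anchors chain into one block; thresholds bite", {
  anc <- data.frame(gene_a = sprintf("a%d", 1:5), gene_b = sprintf("b%d", 1:5),
                    score = 100, chrom_a = "c1", chrom_b = "c2",
                    rank_a = 1:5, rank_b = 11:15)
  blocks <- chain_anchors(anc, min_block = 5L)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$n_anchors, 5L)
  expect_equal(blocks[[1]]$orientation, "same")
  expect_length(chain_anchors(anc[1:4, ], min_block = 5L), 0L)
  expect_length(chain_anchors(anc[0, ], min_block = 5L), 0L)
  # inverted collinearity is detected as such
  inv <- anc
  inv$rank_b <- rev(inv$rank_b)
  binv <- chain_anchors(inv, min_block = 5L)
  expect_length(binv, 1L)
  expect_equal(binv[[1]]$orientation, "inverted")
  expect_true(all(diff(binv[[1]]$anchors$rank_a) > 0))
  expect_true(all(diff(binv[[1]]$anchors$rank_b) < 0))
})

test_that("best chain score equals exhaustive enumeration on random anchor sets", {
  set.seed(53)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    anc <- data.frame(
      gene_a = sprintf("a%d", 1:n), gene_b = sprintf("b%d", 1:n),
      score = round(runif(n, 10, 100)), chrom_a = "c1", chrom_b = "c2",
      rank_a = sample(1:12, n), rank_b = sample(1:12, n))
    anc <- anc[!duplicated(paste(anc$rank_a, anc$rank_b)), ]
    max_gap <- sample(c(3L, 25L), 1)
    gp <- sample(c(0, 1, 5), 1)
    blocks <- chain_anchors(anc, min_block = 1L, max_gap = max_gap,
                            gap_penalty = gp)
    got <- max(vapply(blocks, `[[`, 0, "chain_score"))
    anc$rb <- anc$rank_b
    best_same <- oracle_best_chain(anc, max_gap, gp)
    anc$rb <- -anc$rank_b
    best_inv <- oracle_best_chain(anc, max_gap, gp)
    expect_equal(got, max(best_same, best_inv), tolerance = 1e-9)
  }
})

test_that("anchors are strictly monotone within blocks and never reused", {
  set.seed(54)
  anc <- data.frame(
    gene_a = sprintf("a%d", 1:40), gene_b = sprintf("b%d", 1:40),
    score = runif(40, 50, 100), chrom_a = "c1", chrom_b = "c2",
    rank_a = sample(1:60, 40), rank_b = sample(1:60, 40))
  blocks <- chain_anchors(anc, min_block = 3L, max_gap = 25L)
  seen <- character(0)
  for (b in blocks) {
    expect_true(all(diff(b$anchors$rank_a) > 0))
    rb <- b$anchors$rank_b
    expect_true(all(diff(rb) > 0) || all(diff(rb) < 0))
    ids <- paste(b$anchors$gene_a, b$anchors$gene_b)
    expect_length(intersect(ids, seen), 0L)
    seen <- c(seen, ids)
  }
})

test_that("syntenic depth counts covering block spans", {
  ref <- toy_genome(10)
  mk_block <- function(lo, hi) {
    list(chrom_a = "chr1", chrom_b = "x", orientation = "same",
         anchors = data.frame(gene_a = "a", gene_b = "b",
                              rank_a = c(lo, hi), rank_b = c(1, 2)))
  }
  prof <- syntenic_depth(list(mk_block(0, 4), mk_block(2, 9), mk_block(3, 4)),
                         ref)
  expect_equal(unname(prof$coverage[3]), 2L)   # rank 2: blocks 1 and 2
  expect_equal(unname(prof$coverage[4]), 3L)   # rank 3: all three
  expect_equal(unname(prof$coverage[10]), 1L)  # rank 9
  empty <- syntenic_depth(list(), ref)
  expect_equal(empty$modal_depth, 0L)
  expect_true(all(empty$coverage == 0L))
  expect_equal(depth_ratio_label(prof), paste0(prof$modal_depth, ":1"))
})

test_that("tandem arrays form transitive components within the spacing limit", {
  g <- toy_genome(10)
  pairs <- data.frame(gene_a = c("g01", "g02"), gene_b = c("g02", "g03"))
  arrays <- detect_tandem(g, pairs, max_intervening = 1L)
  expect_length(arrays, 1L)
  expect_equal(arrays[[1]]$members, c("g01", "g02", "g03"))
  # too far apart: ranks 0 and 5
  far <- data.frame(gene_a = "g01", gene_b = "g06")
  expect_length(detect_tandem(g, far, max_intervening = 1L), 0L)
  # order invariance
  arrays2 <- detect_tandem(g, pairs[2:1, ], max_intervening = 1L)
  expect_identical(arrays, arrays2)
})

test_that("duplicate-origin classification follows the precedence rules", {
  g <- toy_genome(8)
  fams <- setNames(c("f1", "f1", "f1", "f1", "f2", "f2", "f3", "f4"),
                   sprintf("g%02d", 1:8))
  # family f1 of 4, all anchors of one self-block
  blk <- list(list(chrom_a = "chr1", chrom_b = "chr1", orientation = "same",
                   anchors = data.frame(gene_a = c("g01", "g02"),
                                        gene_b = c("g03", "g04"),
                                        rank_a = c(0, 1), rank_b = c(2, 3))))
  arr <- list(list(chrom = "chr1", members = c("g05", "g06"),
                   max_intervening_used = 1L))
  cls <- classify_duplicates(g, blk, arr, fams, min_copies = 3L)
  expect_true(all(cls[c("g01", "g02", "g03", "g04")] == "WGD"))
  expect_true(all(cls[c("g05", "g06")] == "TD"))
  expect_equal(unname(cls["g07"]), "singleton")
  expect_equal(unname(cls["g08"]), "singleton")
  # min_copies above the family syntenic count demotes to dispersed
  cls4 <- classify_duplicates(g, blk, arr, fams, min_copies = 5L)
  expect_true(all(cls4[c("g01", "g02", "g03", "g04")] == "dispersed"))
  # TD precedence over WGD is switchable
  arr2 <- list(list(chrom = "chr1", members = c("g01", "g02"),
                    max_intervening_used = 1L))
  cls2 <- classify_duplicates(g, blk, arr2, fams, min_copies = 3L)
  expect_equal(unname(cls2["g01"]), "TD")
  cls3 <- classify_duplicates(g, blk, arr2, fams, min_copies = 3L,
                              td_precedence = FALSE)
  expect_equal(unname(cls3["g01"]), "WGD")
  expect_error(classify_duplicates(g, blk, arr, fams[-1]), "missing")
})
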