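# Homolog-pair detection, collinear block chaining (MCScanX-style weighted
# DAG chaining), syntenic depth profiles, tandem arrays, and duplicate-origin
# classification.

# minimal union-find over integer ids
.uf_new <- function(n) seq_len(n)
.uf_find <- function(uf, i) {
  while (uf[i] != i) { uf[i] <- uf[uf[i]]; i <- uf[i] }
  i
}
.uf_union <- function(uf, i, j) {
  ri <- .uf_find(uf, i); rj <- .uf_find(uf, j)
  if (ri != rj) uf[ri] <- rj
  uf
}

.kmerize <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
}

#' Find homologous protein pairs between (or within) proteomes
#'
#' Shared k-mer prefilter followed by deterministic global alignment
#' (Needleman-Wunsch, BLOSUM62) of candidate pairs. For each gene in A at
#' most `top_n` best-scoring partners with score `>= min_score` are kept;
#' in self-comparison mode (omit `proteome_b`) self-hits are removed and
#' each unordered pair is reported once.
#'
#' @param proteome_a,proteome_b named character vectors of protein
#'   sequences; omit `proteome_b` for a self-comparison.
#' @param top_n partners kept per query.
#' @param min_score minimum alignment score.
#' @param k k-mer size of the prefilter.
#' @param min_shared_kmers candidate threshold on shared k-mers.
#' @return data.frame `gene_a`, `gene_b`, `score`, ordered by score
#'   descending then lexicographic ids.
#' @export
find_homolog_pairs <- function(proteome_a, proteome_b = NULL, top_n = 5L,
                               min_score = 50, k = 6L,
                               min_shared_kmers = 5L) {
  if (length(proteome_a) == 0L) stop("empty proteome")
  self <- is.null(proteome_b)
  if (self) proteome_b <- proteome_a
  if (length(proteome_b) == 0L) stop("empty proteome")
  ka <- .kmerize(proteome_a, k)
  kb <- .kmerize(proteome_b, k)
  kb_map <- split(rep(seq_along(kb), lengths(kb)), unlist(kb))
  au <- unlist(ka, use.names = FALSE)
  ai <- rep(seq_along(ka), lengths(ka))
  hits <- kb_map[au]
  null_hit <- vapply(hits, is.null, TRUE)
  hits <- hits[!null_hit]
  ai <- ai[!null_hit]
  ib <- unlist(hits, use.names = FALSE)
  ia <- rep(ai, lengths(hits))
  if (self) {
    keep <- ia != ib
    ia <- ia[keep]; ib <- ib[keep]
  }
  if (!length(ia)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0)))
  }
  key <- (as.numeric(ia) - 1) * length(proteome_b) + as.numeric(ib)
  key <- sort(key)
  r <- rle(key)
  cand <- r$values[r$lengths >= min_shared_kmers]
  if (!length(cand)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0)))
  }
  ci <- floor((cand - 1) / length(proteome_b)) + 1
  cj <- cand - (ci - 1) * length(proteome_b)
  scores <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(proteome_a[ci])),
    Biostrings::AAStringSet(unname(proteome_b[cj])),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global", scoreOnly = TRUE)
  keep <- scores >= min_score
  df <- data.frame(gene_a = names(proteome_a)[ci][keep],
                   gene_b = names(proteome_b)[cj][keep],
                   score = scores[keep], stringsAsFactors = FALSE)
  if (self) {
    a <- pmin(df$gene_a, df$gene_b)
    b <- pmax(df$gene_a, df$gene_b)
    df$gene_a <- a; df$gene_b <- b
    df <- df[!duplicated(paste(a, b)), , drop = FALSE]
  }
  df <- df[order(-df$score, df$gene_a, df$gene_b), , drop = FALSE]
  # top_n best partners per query gene
  df <- do.call(rbind, lapply(split(df, df$gene_a), head, n = top_n))
  df <- df[order(-df$score, df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Attach chromosome and rank coordinates to homolog pairs
#'
#' @param pairs data.frame with `gene_a`, `gene_b` (and usually `score`).
#' @param genome_a,genome_b `genome` objects providing coordinates;
#'   `genome_b` defaults to `genome_a` (self-comparison).
#' @return anchor data.frame with `chrom_a`, `rank_a`, `chrom_b`, `rank_b`
#'   columns appended. In self-comparison each pair is oriented so that
#'   `(chrom_a, rank_a) <= (chrom_b, rank_b)`.
#' @export
as_anchors <- function(pairs, genome_a, genome_b = genome_a) {
  ga <- genome_a$genes
  gb <- genome_b$genes
  ia <- match(pairs$gene_a, ga$gene_id)
  ib <- match(pairs$gene_b, gb$gene_id)
  if (anyNA(ia) || anyNA(ib)) stop("gene in pairs missing from genome")
  out <- pairs
  out$chrom_a <- ga$chrom[ia]; out$rank_a <- ga$rank[ia]
  out$chrom_b <- gb$chrom[ib]; out$rank_b <- gb$rank[ib]
  self <- identical(genome_a, genome_b)
  if (self) {
    swap <- out$chrom_a > out$chrom_b |
      (out$chrom_a == out$chrom_b & out$rank_a > out$rank_b)
    if (any(swap)) {
      tmp <- out[swap, ]
      out[swap, c("gene_a", "chrom_a", "rank_a")] <-
        tmp[, c("gene_b", "chrom_b", "rank_b")]
      out[swap, c("gene_b", "chrom_b", "rank_b")] <-
        tmp[, c("gene_a", "chrom_a", "rank_a")]
    }
  }
  out
}

# score-maximal chain DP over anchors sorted by rank_a; edges require rank
# deltas in [1, max_gap] in both genomes with the orientation's monotonicity.
# Returns the single best chain with length >= min_block, or NULL.
.best_single_chain <- function(anc, max_gap, gap_penalty, min_block) {
  n <- nrow(anc)
  if (n < min_block) return(NULL)
  ord <- order(anc$rank_a, anc$rb)
  anc <- anc[ord, , drop = FALSE]
  best <- anc$score
  len <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- anc$rank_a[i] - anc$rank_a[j]
      db <- anc$rb[i] - anc$rb[j]
      if (da < 1L || da > max_gap || db < 1L || db > max_gap) next
      cand <- best[j] + anc$score[i] - gap_penalty * ((da - 1L) + (db - 1L))
      if (cand > best[i]) {
        best[i] <- cand
        prev[i] <- j
        len[i] <- len[j] + 1L
      }
    }
  }
  ok <- which(len >= min_block)
  if (!length(ok)) return(NULL)
  end <- ok[which.max(best[ok])]
  path <- integer(0)
  i <- end
  while (!is.na(i)) { path <- c(i, path); i <- prev[i] }
  list(rows = anc$row[path], chain_score = best[end])
}

#' Chain anchor pairs into collinear (syntenic) blocks
#'
#' Per chromosome pair and orientation, finds score-maximal monotone chains
#' by longest-path dynamic programming over anchors (edges allowed when rank
#' deltas are within `max_gap` in both genomes), extracts chains greedily
#' best-first with used anchors removed, and discards chains shorter than
#' `min_block`. Defaults mirror MCScanX's default parameters.
#'
#' @param anchors anchor data.frame from [as_anchors()].
#' @param min_block minimum anchors per block (default 5).
#' @param max_gap maximum rank gap between consecutive anchors (default 25).
#' @param gap_penalty per-rank gap cost subtracted from the chain score.
#' @return list of blocks; each block is a list with `block_id`, `chrom_a`,
#'   `chrom_b`, `orientation`, `n_anchors`, `chain_score`, `median_ks`
#'   (NA until Ks values are attached) and `anchors` (data.frame, rank_a
#'   strictly increasing).
#' @export
chain_anchors <- function(anchors, min_block = 5L, max_gap = 25L,
                          gap_penalty = 1) {
  if (is.null(anchors) || nrow(anchors) == 0L) return(list())
  anchors$row <- seq_len(nrow(anchors))
  blocks <- list()
  for (cp in split(anchors,
                   paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))) {
    remaining <- cp
    repeat {
      cand <- list()
      for (orientation in c("same", "inverted")) {
        anc <- remaining
        anc$rb <- if (orientation == "same") anc$rank_b else -anc$rank_b
        # one anchor per (rank_a, rank_b) cell: keep the best-scoring
        anc <- anc[order(-anc$score), , drop = FALSE]
        anc <- anc[!duplicated(paste(anc$rank_a, anc$rb)), , drop = FALSE]
        ch <- .best_single_chain(anc, max_gap, gap_penalty, min_block)
        if (!is.null(ch)) {
          ch$orientation <- orientation
          cand[[orientation]] <- ch
        }
      }
      if (!length(cand)) break
      ch <- cand[[which.max(vapply(cand, `[[`, 0, "chain_score"))]]
      adf <- anchors[ch$rows, , drop = FALSE]
      adf <- adf[order(adf$rank_a), , drop = FALSE]
      adf$row <- NULL
      rownames(adf) <- NULL
      blocks[[length(blocks) + 1L]] <- list(
        block_id = NA_integer_,
        chrom_a = adf$chrom_a[1L], chrom_b = adf$chrom_b[1L],
        orientation = ch$orientation,
        n_anchors = nrow(adf), chain_score = ch$chain_score,
        median_ks = NA_real_, anchors = adf)
      remaining <- remaining[!remaining$row %in% ch$rows, , drop = FALSE]
    }
  }
  # stable ordering: by chain score descending
  blocks <- blocks[order(-vapply(blocks, `[[`, 0, "chain_score"))]
  for (i in seq_along(blocks)) blocks[[i]]$block_id <- i
  blocks
}

#' Write blocks in an MCScanX-like .collinearity text layout
#'
#' One `## Alignment` header per block followed by its anchor pairs, for
#' interoperability with tools that consume MCScanX output.
#'
#' @param blocks list of blocks from [chain_anchors()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collinearity <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("############### Statistics ###############", con)
  writeLines(sprintf("# Number of collinear blocks: %d", length(blocks)), con)
  for (b in blocks) {
    writeLines(sprintf(
      "## Alignment %d: score=%.1f e_value=NA N=%d %s&%s %s",
      b$block_id, b$chain_score, b$n_anchors, b$chrom_a, b$chrom_b,
      if (b$orientation == "inverted") "minus" else "plus"), con)
    writeLines(sprintf("%3d-%3d:\t%s\t%s", b$block_id,
                       seq_len(b$n_anchors) - 1L,
                       b$anchors$gene_a, b$anchors$gene_b), con)
  }
  invisible(path)
}

#' Summarise a block list as a data.frame
#' @param blocks list of blocks from [chain_anchors()].
#' @return data.frame with one row per block.
#' @export
blocks_summary <- function(blocks) {
  if (!length(blocks)) {
    return(data.frame(block_id = integer(0), chrom_a = character(0),
                      chrom_b = character(0), orientation = character(0),
                      n_anchors = integer(0), chain_score = numeric(0),
                      median_ks = numeric(0)))
  }
  do.call(rbind, lapply(blocks, function(b) {
    data.frame(block_id = b$block_id, chrom_a = b$chrom_a,
               chrom_b = b$chrom_b, orientation = b$orientation,
               n_anchors = b$n_anchors, chain_score = b$chain_score,
               median_ks = b$median_ks, stringsAsFactors = FALSE)
  }))
}

#' Per-gene syntenic depth profile of a reference genome
#'
#' The coverage of a reference gene is the number of blocks whose anchor
#' rank span on its chromosome (A side of the blocks) contains the gene's
#' rank. The modal depth is the most frequent nonzero coverage (0 when no
#' gene is covered).
#'
#' @param blocks list of blocks computed with the reference as genome A.
#' @param reference the reference `genome`.
#' @return list with `coverage` (named integer vector per gene),
#'   `modal_depth`, and `depth_histogram` (table of depth -> gene count).
#' @export
syntenic_depth <- function(blocks, reference) {
  g <- reference$genes
  cov <- setNames(integer(nrow(g)), g$gene_id)
  for (b in blocks) {
    span <- range(b$anchors$rank_a)
    hit <- g$chrom == b$chrom_a & g$rank >= span[1L] & g$rank <= span[2L]
    cov[hit] <- cov[hit] + 1L
  }
  hist <- table(cov)
  nz <- cov[cov > 0L]
  modal <- if (length(nz)) {
    t <- table(nz)
    as.integer(names(t)[which.max(t)])
  } else 0L
  list(coverage = cov, modal_depth = modal, depth_histogram = hist)
}

#' Depth-ratio label between two comparisons
#'
#' @param profile_a a [syntenic_depth()] profile.
#' @param profile_b optional second profile; defaults to depth 1.
#' @return string like `"4:1"`.
#' @export
depth_ratio_label <- function(profile_a, profile_b = NULL) {
  b <- if (is.null(profile_b)) 1L else profile_b$modal_depth
  paste0(profile_a$modal_depth, ":", b)
}

#' Detect tandem arrays from self-comparison homolog pairs
#'
#' Same-chromosome homolog pairs separated by at most `max_intervening`
#' non-member genes (by rank) are linked; arrays are the connected
#' components of size >= 2, members ordered by rank.
#'
#' @param genome a `genome` object.
#' @param homolog_pairs self-comparison pairs (`gene_a`, `gene_b`).
#' @param max_intervening maximum intervening genes between linked members.
#' @return list of arrays; each a list with `chrom`, `members` (gene ids by
#'   rank) and `max_intervening_used`.
#' @export
detect_tandem <- function(genome, homolog_pairs, max_intervening = 1L) {
  g <- genome$genes
  if (!nrow(homolog_pairs)) return(list())
  ia <- match(homolog_pairs$gene_a, g$gene_id)
  ib <- match(homolog_pairs$gene_b, g$gene_id)
  if (anyNA(ia) || anyNA(ib)) stop("pair gene missing from genome")
  link <- which(g$chrom[ia] == g$chrom[ib] &
                  abs(g$rank[ia] - g$rank[ib]) <= max_intervening + 1L &
                  ia != ib)
  if (!length(link)) return(list())
  uf <- .uf_new(nrow(g))
  for (e in link) uf <- .uf_union(uf, ia[e], ib[e])
  roots <- vapply(seq_len(nrow(g)), function(i) .uf_find(uf, i), 0L)
  comps <- split(seq_len(nrow(g)), roots)
  comps <- comps[lengths(comps) >= 2L]
  arrays <- lapply(comps, function(idx) {
    idx <- idx[order(g$rank[idx])]
    list(chrom = g$chrom[idx[1L]], members = g$gene_id[idx],
         max_intervening_used = max_intervening)
  })
  names(arrays) <- NULL
  arrays[order(vapply(arrays, function(a) a$members[1L], ""))]
}

#' Group genes into homolog families
#'
#' Families are connected components of the homolog-pair graph; genes with
#' no pair form singleton families.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param all_genes character vector of every gene id.
#' @return named character vector gene_id -> family id.
#' @export
gene_families <- function(pairs, all_genes) {
  idx <- setNames(seq_along(all_genes), all_genes)
  uf <- .uf_new(length(all_genes))
  for (e in seq_len(nrow(pairs))) {
    uf <- .uf_union(uf, idx[[pairs$gene_a[e]]], idx[[pairs$gene_b[e]]])
  }
  roots <- vapply(seq_along(all_genes), function(i) .uf_find(uf, i), 0L)
  setNames(paste0("fam", match(roots, unique(roots))), all_genes)
}

#' Classify duplicate gene origins
#'
#' A gene is `TD` when it belongs to a tandem array; otherwise `WGD` when it
#' is an anchor in at least one self-synteny block and its family has at
#' least `min_copies` syntenic copies; otherwise `dispersed` when its family
#' has >= 2 members; otherwise `singleton`. The default `min_copies = 3`
#' follows the convention of requiring at least 3 retained copies after two
#' WGD rounds; use 2 to accept a single surviving duplicate pair.
#'
#' @param genome a `genome` object.
#' @param self_blocks self-synteny blocks from [chain_anchors()].
#' @param tandem_arrays arrays from [detect_tandem()].
#' @param families named vector gene -> family (see [gene_families()]).
#' @param min_copies syntenic-copy threshold for the WGD call.
#' @param td_precedence if TRUE (default), TD beats WGD when both apply.
#' @return named character vector gene_id -> {WGD, TD, dispersed, singleton}.
#' @export
classify_duplicates <- function(genome, self_blocks, tandem_arrays, families,
                                min_copies = 3L, td_precedence = TRUE) {
  ids <- genome$genes$gene_id
  missing <- setdiff(ids, names(families))
  if (length(missing)) stop("gene missing from families: ", missing[1L])
  syntenic <- unique(unlist(lapply(self_blocks, function(b) {
    c(b$anchors$gene_a, b$anchors$gene_b)
  })))
  td_genes <- unique(unlist(lapply(tandem_arrays, `[[`, "members")))
  fam <- families[ids]
  fam_sizes <- table(fam)
  synt_by_fam <- table(fam[ids %in% syntenic])
  n_synt <- as.integer(synt_by_fam[fam])
  n_synt[is.na(n_synt)] <- 0L
  is_wgd <- ids %in% syntenic & n_synt >= min_copies
  is_td <- ids %in% td_genes
  out <- rep("singleton", length(ids))
  out[as.integer(fam_sizes[fam]) >= 2L] <- "dispersed"
  if (td_precedence) {
    out[is_wgd] <- "WGD"
    out[is_td] <- "TD"
  } else {
    out[is_td] <- "TD"
    out[is_wgd] <- "WGD"
  }
  setNames(out, ids)
}
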