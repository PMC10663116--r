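# PWM scanning of promoters with exact score p-values (dynamic programming
# over the discretised score distribution, FIMO-style), module-vs-background
# occurrence counting, Fisher exact enrichment with BH FDR, log2 enrichment
# scores, and motif-cluster rollup.

#' Construct a PWM object
#'
#' @param motif_id motif identifier.
#' @param cluster_id motif-cluster identifier (may be NA).
#' @param matrix L x 4 matrix of position frequency counts (or
#'   probabilities) over A, C, G, T.
#' @return a `pwm` object.
#' @export
new_pwm <- function(motif_id, cluster_id, matrix) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) stop("PWM matrix must have 4 columns (A,C,G,T)")
  if (nrow(matrix) < 1L) stop("PWM must have at least one position")
  if (any(matrix < 0) || any(rowSums(matrix) <= 0)) {
    stop("PWM rows must have positive totals")
  }
  colnames(matrix) <- DNA_BASES
  structure(list(motif_id = motif_id, cluster_id = cluster_id,
                 matrix = matrix),
            class = "pwm")
}

#' Normalised per-position base probabilities of a PWM
#'
#' Applies the pseudocount (distributed by background composition) and
#' normalises each row to sum to 1.
#'
#' @param pwm a `pwm` object.
#' @param pseudocount total pseudocount per position (default 0.1).
#' @param background base composition used to distribute the pseudocount.
#' @return L x 4 probability matrix.
#' @export
normalize_pwm <- function(pwm, pseudocount = 0.1,
                          background = rep(0.25, 4)) {
  m <- pwm$matrix
  p <- sweep(m, 2L, background * pseudocount, `+`)
  p / rowSums(p)
}

#' Read motifs from a JASPAR PFM text file
#'
#' @param path JASPAR-format file (`>ID name` header, then four
#'   `A [ ... ]`-style rows).
#' @param clusters optional named vector motif_id -> cluster_id to attach.
#' @return named list of `pwm` objects.
#' @export
read_jaspar <- function(path, clusters = NULL) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no motifs in JASPAR file: ", path)
  out <- list()
  for (h in seq_along(heads)) {
    from <- heads[h]
    to <- if (h < length(heads)) heads[h + 1L] - 1L else length(lines)
    id <- strsplit(sub("^>\\s*", "", lines[from]), "\\s+")[[1L]][1L]
    body <- lines[(from + 1L):to]
    body <- body[nzchar(trimws(body))]
    rows <- lapply(DNA_BASES, function(b) {
      ln <- grep(paste0("^\\s*", b, "\\b"), body, value = TRUE)
      if (length(ln) != 1L) stop("motif ", id, ": missing row for base ", b)
      nums <- gsub("[^0-9eE+.-]", " ", sub(paste0("^\\s*", b), "", ln))
      as.numeric(strsplit(trimws(nums), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("motif ", id, ": ragged matrix rows")
    }
    cl <- if (!is.null(clusters) && id %in% names(clusters))
      clusters[[id]] else NA_character_
    out[[id]] <- new_pwm(id, cl, do.call(cbind, rows))
  }
  out
}

#' Read a two-column motif -> cluster map from TSV
#' @param path TSV with columns motif_id, cluster_id (no header required;
#'   a header line is auto-detected).
#' @return named character vector motif_id -> cluster_id.
#' @export
read_motif_clusters <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(df[1L, 1L]), "motif_id")) df <- df[-1L, , drop = FALSE]
  setNames(as.character(df[[2L]]), df[[1L]])
}

# log-odds score matrix (bits), integerised at `granularity`, plus the exact
# tail distribution of the integer score under the 0-order background
.pwm_score_tables <- function(pwm, background, pseudocount, granularity) {
  probs <- normalize_pwm(pwm, pseudocount, background)
  S <- log2(sweep(probs, 2L, background, `/`))
  K <- round(S / granularity)
  storage.mode(K) <- "integer"
  lo <- sum(apply(K, 1L, min))
  hi <- sum(apply(K, 1L, max))
  dist <- 1
  off <- 0  # dist[i] = P(int score == off + i - 1)
  for (l in seq_len(nrow(K))) {
    kmin <- min(K[l, ])
    kmax <- max(K[l, ])
    new <- numeric(length(dist) + (kmax - kmin))
    for (j in 1:4) {
      sh <- K[l, j] - kmin
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * background[j]
    }
    dist <- new
    off <- off + kmin
  }
  tail <- rev(cumsum(rev(dist)))
  list(S = S, K = K, offset = off, tail = tail, lo = lo, hi = hi)
}

# integer codes for a DNA string: A/C/G/T -> 1..4, anything else NA
.dna_codes <- function(x) {
  map <- rep(NA_integer_, 128L)
  map[utf8ToInt("A")] <- 1L
  map[utf8ToInt("C")] <- 2L
  map[utf8ToInt("G")] <- 3L
  map[utf8ToInt("T")] <- 4L
  map[utf8ToInt(x)]
}

# reverse-complemented score tables: position l, base j of the minus-strand
# occurrence read on the plus strand
.rc_pwm <- function(pwm) {
  m <- pwm$matrix[rev(seq_len(nrow(pwm$matrix))), c(4L, 3L, 2L, 1L),
                  drop = FALSE]
  new_pwm(pwm$motif_id, pwm$cluster_id, m)
}

# scan integer-coded sequence with one strand's tables; returns start
# positions (1-based), real-bit scores and exact p-values for windows with
# p <= p_threshold
.scan_codes <- function(codes, tabs, p_threshold) {
  L <- nrow(tabs$K)
  n <- length(codes)
  if (n < L) {
    return(data.frame(pos = integer(0), score = numeric(0),
                      p_value = numeric(0)))
  }
  acc_int <- .window_scores_int(codes, tabs$K)
  # smallest integer score whose exact tail probability clears the threshold
  idx_min <- match(TRUE, tabs$tail <= p_threshold)
  hit <- if (is.na(idx_min)) integer(0) else
    which(!is.na(acc_int) & acc_int >= tabs$lo + idx_min - 1L)
  if (!length(hit)) {
    return(data.frame(pos = integer(0), score = numeric(0),
                      p_value = numeric(0)))
  }
  # exact real-bit scores, computed only at the (few) hit windows
  sc <- vapply(hit, function(i) {
    sum(tabs$S[cbind(seq_len(L), codes[i:(i + L - 1L)])])
  }, 0)
  pv <- tabs$tail[pmin(pmax(acc_int[hit] - tabs$lo + 1L, 1L),
                       length(tabs$tail))]
  data.frame(pos = hit, score = sc, p_value = pv)
}

#' Scan a promoter with a PWM (both strands, exact p-values)
#'
#' Windows are scored as log-odds in bits against a 0-order background; the
#' p-value of a score is computed exactly by dynamic programming over the
#' discretised score distribution. Hits with `p <= p_threshold` on either
#' strand are reported; windows containing non-ACGT bases are skipped;
#' overlapping hits are allowed.
#'
#' @examples
#' hits <- scan_pwm(strrep("ACGTGGTCATGACGTCAGTAC", 20), demo_pwm())
#' head(hits)
#' @param promoter promoter nucleotide string.
#' @param pwm a `pwm` object.
#' @param background length-4 base probabilities (A,C,G,T); must be
#'   positive.
#' @param p_threshold report hits with p-value at or below this (1e-4, the
#'   FIMO-style default).
#' @param pseudocount PWM pseudocount.
#' @param granularity score discretisation in bits for the p-value DP.
#' @return data.frame `motif_id`, `offset` (0-based window start on the
#'   promoter), `strand`, `score` (bits), `p_value`.
#' @export
scan_pwm <- function(promoter, pwm, background = rep(0.25, 4),
                     p_threshold = 1e-4, pseudocount = 0.1,
                     granularity = 1e-3) {
  if (any(background <= 0)) stop("background probabilities must be positive")
  background <- background / sum(background)
  L <- nrow(pwm$matrix)
  if (nchar(promoter) < L) stop("promoter shorter than motif")
  codes <- .dna_codes(promoter)
  fwd <- .pwm_score_tables(pwm, background, pseudocount, granularity)
  rev_ <- .pwm_score_tables(.rc_pwm(pwm), background, pseudocount, granularity)
  hf <- .scan_codes(codes, fwd, p_threshold)
  hr <- .scan_codes(codes, rev_, p_threshold)
  out <- rbind(
    if (nrow(hf)) data.frame(motif_id = pwm$motif_id, offset = hf$pos - 1L,
                             strand = "+", score = hf$score,
                             p_value = hf$p_value) else NULL,
    if (nrow(hr)) data.frame(motif_id = pwm$motif_id, offset = hr$pos - 1L,
                             strand = "-", score = hr$score,
                             p_value = hr$p_value) else NULL)
  if (is.null(out)) {
    out <- data.frame(motif_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      p_value = numeric(0))
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Scan a set of promoters with one or more PWMs
#'
#' Efficient batch scan: promoters are concatenated with N separators so
#' each PWM is scanned in one vectorised pass per strand.
#'
#' @param promoters named character vector of promoter sequences.
#' @param pwms a `pwm` object or list of them.
#' @param background base probabilities; when NULL, estimated (0-order)
#'   from the scanned promoters.
#' @inheritParams scan_pwm
#' @return data.frame `motif_id`, `gene_id`, `offset`, `strand`, `score`,
#'   `p_value`.
#' @export
scan_promoters <- function(promoters, pwms, background = NULL,
                           p_threshold = 1e-4, pseudocount = 0.1,
                           granularity = 1e-3) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  big <- paste(promoters, collapse = "N")
  codes <- .dna_codes(big)
  if (is.null(background)) {
    tab <- tabulate(codes[!is.na(codes)], 4L)
    if (any(tab == 0L)) tab <- tab + 1L
    background <- tab / sum(tab)
  }
  background <- background / sum(background)
  starts <- cumsum(c(1L, head(nchar(promoters) + 1L, -1L)))
  res <- list()
  for (pwm in pwms) {
    fwd <- .pwm_score_tables(pwm, background, pseudocount, granularity)
    rev_ <- .pwm_score_tables(.rc_pwm(pwm), background, pseudocount,
                              granularity)
    for (strand in c("+", "-")) {
      h <- .scan_codes(codes, if (strand == "+") fwd else rev_, p_threshold)
      if (!nrow(h)) next
      gi <- findInterval(h$pos, starts)
      res[[length(res) + 1L]] <- data.frame(
        motif_id = pwm$motif_id, gene_id = names(promoters)[gi],
        offset = h$pos - starts[gi], strand = strand,
        score = h$score, p_value = h$p_value, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(motif_id = character(0), gene_id = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-motif module-vs-background occurrence counts
#'
#' Gene-level occurrence: a gene counts once per motif when its promoter has
#' at least one hit. The module gene set is the module's members with
#' membership above `membership_min` (restricted to expressed genes); the
#' background is all expressed genes and includes the module.
#'
#' @param hits hit table from [scan_promoters()].
#' @param module_assignments data.frame `gene_id`, `module`, `membership`.
#' @param module module name to test.
#' @param membership_min module-membership threshold (default 0.8).
#' @param expressed character vector of expressed gene ids (the background).
#' @return data.frame with one row per motif: `motif_id`,
#'   `genes_with_hit_module`, `module_size`, `genes_with_hit_background`,
#'   `background_size`, `hits_module`, `hits_background`.
#' @export
count_module_occurrences <- function(hits, module_assignments, module,
                                     membership_min = 0.8, expressed) {
  mod_genes <- module_assignments$gene_id[
    module_assignments$module == module &
      module_assignments$membership > membership_min]
  mod_genes <- intersect(mod_genes, expressed)
  if (!length(mod_genes)) {
    warning("module '", module, "' empty after membership/expression filter")
    return(NULL)
  }
  hits <- hits[hits$gene_id %in% expressed, , drop = FALSE]
  motifs <- unique(hits$motif_id)
  out <- lapply(motifs, function(m) {
    h <- hits[hits$motif_id == m, , drop = FALSE]
    g <- unique(h$gene_id)
    data.frame(motif_id = m,
               genes_with_hit_module = sum(g %in% mod_genes),
               module_size = length(mod_genes),
               genes_with_hit_background = length(g),
               background_size = length(expressed),
               hits_module = sum(h$gene_id %in% mod_genes),
               hits_background = nrow(h),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' One-sided Fisher exact enrichment test on a 2x2 table
#'
#' Exact hypergeometric upper-tail probability (enrichment direction) and
#' the sample odds ratio `(a/b)/(c/d)` with a Haldane correction of 0.5
#' applied when any cell is zero.
#'
#' @examples
#' fisher_enrichment(c(2, 0, 0, 2))  # p = 1/6
#' @param counts 2x2 matrix or length-4 vector `c(a, b, c, d)` read
#'   row-wise: a = module genes with hit, b = module genes without,
#'   c = background genes with hit, d = background genes without.
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_enrichment <- function(counts) {
  x <- as.vector(t(counts))
  if (length(x) != 4L || any(x < 0) || any(x != round(x))) {
    stop("counts must be 4 nonnegative integers")
  }
  a <- x[1L]; b <- x[2L]; c <- x[3L]; d <- x[4L]
  if (a + b + c + d == 0) stop("all-zero table")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    p <- 1
  } else {
    p <- phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  }
  hal <- if (any(x == 0)) 0.5 else 0
  or <- ((a + hal) / (b + hal)) / ((c + hal) / (d + hal))
  list(odds_ratio = or, p_value = p)
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up q-values mapped back to input order, clipped at 1.
#'
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @param p_values numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Motif enrichment of a coexpression module against the genomic background
#'
#' Runs the gene-level Fisher test per motif on [count_module_occurrences()]
#' output, applies BH FDR, computes the log2 enrichment score
#' `log2((hit_mod/module_size) / (hit_bg/background_size))`, and flags
#' motifs with `q < q_threshold` as enriched.
#'
#' @param counts data.frame from [count_module_occurrences()].
#' @param clusters optional named vector motif_id -> cluster_id.
#' @param q_threshold FDR threshold defining enrichment (default 0.1).
#' @return data.frame of enrichment results, one row per motif.
#' @export
motif_enrichment <- function(counts, clusters = NULL, q_threshold = 0.1) {
  if (is.null(counts) || !nrow(counts)) {
    return(data.frame(motif_id = character(0), cluster_id = character(0),
                      genes_with_hit_module = integer(0),
                      module_size = integer(0),
                      genes_with_hit_background = integer(0),
                      background_size = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      enrichment_score = numeric(0), enriched = logical(0)))
  }
  tests <- lapply(seq_len(nrow(counts)), function(i) {
    a <- counts$genes_with_hit_module[i]
    b <- counts$module_size[i] - a
    c <- counts$genes_with_hit_background[i]
    d <- counts$background_size[i] - c
    fisher_enrichment(c(a, b, c, d))
  })
  freq_mod <- counts$genes_with_hit_module / counts$module_size
  freq_bg <- counts$genes_with_hit_background / counts$background_size
  out <- data.frame(
    motif_id = counts$motif_id,
    cluster_id = if (!is.null(clusters))
      unname(clusters[counts$motif_id]) else NA_character_,
    counts[, c("genes_with_hit_module", "module_size",
               "genes_with_hit_background", "background_size")],
    odds_ratio = vapply(tests, `[[`, 0, "odds_ratio"),
    p_value = vapply(tests, `[[`, 0, "p_value"),
    stringsAsFactors = FALSE)
  out$q_value <- bh_fdr(out$p_value)
  out$enrichment_score <- log2(freq_mod / freq_bg)
  out$enriched <- out$q_value < q_threshold
  out[order(out$q_value, out$p_value), , drop = FALSE]
}

#' Highlight motif clusters with many enriched members
#'
#' A cluster is highlighted when it contains at least `min_enriched`
#' enriched motifs (default 4, i.e. "more than 3").
#'
#' @param results enrichment table from [motif_enrichment()].
#' @param min_enriched minimum enriched motifs per highlighted cluster.
#' @return character vector of highlighted cluster ids.
#' @export
aggregate_clusters <- function(results, min_enriched = 4L) {
  if (!nrow(results)) return(character(0))
  res <- results[results$enriched & !is.na(results$cluster_id), ,
                 drop = FALSE]
  if (!nrow(res)) return(character(0))
  tab <- table(res$cluster_id)
  sort(names(tab)[tab >= min_enriched])
}
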