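# Independent oracles used across test files. They deliberately avoid the
# package's lookup tables and DP code paths: pathway enumeration is done
# recursively on codon strings, chaining by exhaustive subset enumeration,
# Fisher by direct hypergeometric summation, and PWM p-values by complete
# window enumeration.

GC_TABLE <- Biostrings::GENETIC_CODE

# all permutations of a vector (k <= 3 in the NG86 use)
perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (r in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], r)
  }
  out
}

# brute-force NG86 site fractions for one codon
oracle_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (GC_TABLE[[alt]] == "*") next
      if (GC_TABLE[[alt]] == GC_TABLE[[codon]]) s <- s + 1 / 3
    }
  }
  c(syn = s, nonsyn = 3 - s)
}

# brute-force pathway-averaged (Sd, Nd) for one codon pair
oracle_pair_counts <- function(c1, c2) {
  a <- strsplit(c1, "")[[1L]]
  b <- strsplit(c2, "")[[1L]]
  pos <- which(a != b)
  if (!length(pos)) return(c(Sd = 0, Nd = 0))
  sds <- numeric(0)
  nds <- numeric(0)
  for (ord in perms_of(pos)) {
    cur <- c1
    sd <- 0
    nd <- 0
    blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- b[p]
      if (GC_TABLE[[nxt]] == "*") { blocked <- TRUE; break }
      if (GC_TABLE[[nxt]] == GC_TABLE[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!blocked) { sds <- c(sds, sd); nds <- c(nds, nd) }
  }
  if (!length(sds)) return(c(Sd = length(pos) / 2, Nd = length(pos) / 2))
  c(Sd = mean(sds), Nd = mean(nds))
}

# full NG86 result for two codon vectors, via the brute-force oracles
oracle_ng86 <- function(ca, cb) {
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    sa <- oracle_sites(ca[i]); sb <- oracle_sites(cb[i])
    S <- S + (sa["syn"] + sb["syn"]) / 2
    N <- N + (sa["nonsyn"] + sb["nonsyn"]) / 2
    cnt <- oracle_pair_counts(ca[i], cb[i])
    Sd <- Sd + cnt["Sd"]; Nd <- Nd + cnt["Nd"]
  }
  list(S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd))
}

# exhaustive best monotone chain score over <= ~10 anchors
oracle_best_chain <- function(anc, max_gap, gap_penalty, min_len = 1L) {
  n <- nrow(anc)
  best <- -Inf
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) < min_len) next
    sub <- anc[idx[order(anc$rank_a[idx], anc$rb[idx])], , drop = FALSE]
    ok <- TRUE
    sc <- sub$score[1L]
    if (nrow(sub) > 1L) for (i in 2:nrow(sub)) {
      da <- sub$rank_a[i] - sub$rank_a[i - 1L]
      db <- sub$rb[i] - sub$rb[i - 1L]
      if (da < 1L || da > max_gap || db < 1L || db > max_gap) { ok <- FALSE; break }
      sc <- sc + sub$score[i] - gap_penalty * ((da - 1L) + (db - 1L))
    }
    if (ok && sc > best) best <- sc
  }
  best
}

# exhaustive affine-gap global alignment score (for short sequences)
oracle_nw_score <- function(a, b, mat, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  gap_cost <- function(len) if (len == 0L) 0 else gap_open + gap_extend * len
  rec <- function(i, j, state) {
    # state: 0 = none/match, 1 = in gap of a (consuming b), 2 = gap of b
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, mat[av[i], bv[j]] + rec(i + 1L, j + 1L, 0L))
    }
    if (j <= length(bv)) {
      open <- if (state == 1L) 0 else gap_open
      best <- max(best, -open - gap_extend + rec(i, j + 1L, 1L))
    }
    if (i <= length(av)) {
      open <- if (state == 2L) 0 else gap_open
      best <- max(best, -open - gap_extend + rec(i + 1L, j, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# direct hypergeometric-sum upper tail for a 2x2 table (a,b,c,d)
oracle_fisher_p <- function(a, b, c, d) {
  K <- a + c          # successes in population
  n <- a + b          # draws
  N <- a + b + c + d
  amax <- min(n, K)
  sum(vapply(a:amax, function(x) dhyper(x, K, N - K, n), 0))
}

# brute-force PWM window p-values over all 4^L windows (real scores)
oracle_pwm_pvalues <- function(score_matrix, background) {
  L <- nrow(score_matrix)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(grid))
  probs <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    scores[i] <- sum(score_matrix[cbind(seq_len(L), grid[i, ])])
    probs[i] <- prod(background[grid[i, ]])
  }
  list(scores = scores, probs = probs,
       pval = function(s) sum(probs[scores >= s - 1e-12]))
}

# random CDS helpers
random_cds <- function(n_codons, pool = NULL) {
  gc <- Biostrings::GENETIC_CODE
  if (is.null(pool)) pool <- names(gc)[gc != "*"]
  paste0(sample(pool, n_codons, replace = TRUE), collapse = "")
}

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}
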