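# Nei-Gojobori (1986) synonymous/nonsynonymous counting with Jukes-Cantor
# correction, plus a deterministic global protein aligner for gene pairs.
#
# Site and pathway tables over the 61 sense codons are precomputed once per
# session and cached; ng86_pair() is then a vectorised table lookup.

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# all k! orderings of a small index vector (k <= 3 here)
.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' NG86 synonymous and nonsynonymous site counts for one codon
#'
#' For each of the three codon positions the synonymous fraction is the
#' number of the three possible single-nucleotide changes that preserve the
#' amino acid, divided by 3; changes to stop codons are excluded from the
#' numerator but remain in the denominator. Nonsynonymous sites are
#' `3 - synonymous sites`.
#'
#' @examples
#' ng86_sites("TTT")  # 1/3 synonymous site: only TTT->TTC preserves Phe
#' ng86_sites("GGG")  # fully degenerate third position
#' @param codon a single sense codon (3-mer over ACGT).
#' @return named numeric vector `c(syn_sites=, nonsyn_sites=)`.
#' @export
ng86_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  if (!codon %in% names(gc)) stop("not a codon: ", codon)
  if (gc[[codon]] == "*") stop("stop codon has no NG86 sites: ", codon)
  s <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (nt in setdiff(DNA_BASES, ref)) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (gc[[alt]] == "*") next
      if (gc[[alt]] == gc[[codon]]) s <- s + 1 / 3
    }
  }
  c(syn_sites = s, nonsyn_sites = 3 - s)
}

# Pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair. Pathways through stop codons are excluded from the average; if all
# pathways are blocked the differing positions are split half synonymous,
# half nonsynonymous.
.ng86_pair_counts <- function(c1, c2, gc) {
  a <- strsplit(c1, "")[[1L]]
  b <- strsplit(c2, "")[[1L]]
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0L) return(c(0, 0))
  syn <- numeric(0)
  nonsyn <- numeric(0)
  for (ord in .perms(pos)) {
    cur <- c1
    s <- 0
    n <- 0
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- b[p]
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      if (gc[[nxt]] == gc[[cur]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { syn <- c(syn, s); nonsyn <- c(nonsyn, n) }
  }
  if (length(syn) == 0L) return(c(k / 2, k / 2))
  c(mean(syn), mean(nonsyn))
}

# Lazily built lookup tables: per-codon site counts and 61x61 pathway-averaged
# difference counts.
ng86_tables <- function() {
  tab <- .paleodup_cache$ng86
  if (!is.null(tab)) return(tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- sense_codons()
  sites <- t(vapply(codons, ng86_sites, numeric(2)))
  n <- length(codons)
  Sd <- matrix(0, n, n, dimnames = list(codons, codons))
  Nd <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cnt <- .ng86_pair_counts(codons[i], codons[j], gc)
      Sd[i, j] <- cnt[1L]
      Nd[i, j] <- cnt[2L]
    }
  }
  tab <- list(codons = codons, syn_sites = sites[, 1L],
              nonsyn_sites = sites[, 2L], Sd = Sd, Nd = Nd)
  .paleodup_cache$ng86 <- tab
  tab
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) * log(1 - 4p/3)`. Returns `NA` with a saturated flag when
#' `p >= 0.75` (correction undefined).
#'
#' @examples
#' jukes_cantor_correct(0.05)$d   # 0.0517...
#' jukes_cantor_correct(0.8)$saturated
#' @param p proportion of differences per site, `p >= 0`.
#' @return list with `d` (corrected distance, NA when saturated) and
#'   `saturated` (logical).
#' @export
jukes_cantor_correct <- function(p) {
  if (any(p < 0)) stop("p must be nonnegative")
  saturated <- p >= 0.75
  d <- ifelse(saturated, NA_real_, -0.75 * log(1 - 4 * p / 3))
  list(d = d, saturated = saturated)
}

#' NG86 Ka and Ks for a pair of coding sequences
#'
#' Takes a codon alignment (see [backtranslate_alignment()]), drops columns
#' with gaps, Ns or stop codons, and computes Nei-Gojobori site and
#' difference counts with pathway averaging and Jukes-Cantor correction.
#'
#' @examples
#' aln <- backtranslate_alignment(c("MA", "MA"), "ATGGCT", "ATGGCA")
#' ng86_pair(aln)  # one synonymous difference
#' @param aln a `codon_alignment` object, or a list with `codon_a`/`codon_b`
#'   codon vectors as returned by [codon_pairs()].
#' @return an object of class `kaks_result`: list with fields `S`, `N_sites`,
#'   `Sd`, `Nd`, `ps`, `pn`, `Ks`, `Ka`, `saturated`, `n_pairs`, `n_excluded`.
#' @export
ng86_pair <- function(aln) {
  if (inherits(aln, "codon_alignment")) aln <- codon_pairs(aln)
  ca <- aln$codon_a
  cb <- aln$codon_b
  if (length(ca) == 0L) stop("empty codon alignment")
  tab <- ng86_tables()
  ia <- match(ca, tab$codons)
  ib <- match(cb, tab$codons)
  if (anyNA(ia) || anyNA(ib)) stop("non-sense codon in filtered alignment")
  S <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
  N_sites <- (sum(tab$nonsyn_sites[ia]) + sum(tab$nonsyn_sites[ib])) / 2
  Sd <- sum(tab$Sd[cbind(ia, ib)])
  Nd <- sum(tab$Nd[cbind(ia, ib)])
  ps <- Sd / S
  pn <- Nd / N_sites
  jcs <- jukes_cantor_correct(min(ps, 0.75))
  jcn <- jukes_cantor_correct(min(pn, 0.75))
  saturated <- ps >= 0.75 || pn >= 0.75
  structure(list(S = S, N_sites = N_sites, Sd = Sd, Nd = Nd,
                 ps = ps, pn = pn,
                 Ks = if (ps >= 0.75) NA_real_ else jcs$d,
                 Ka = if (pn >= 0.75) NA_real_ else jcn$d,
                 saturated = saturated,
                 n_pairs = length(ca),
                 n_excluded = if (is.null(aln$n_excluded)) 0L else aln$n_excluded),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks: Ks=%.4f Ka=%.4f (S=%.1f N=%.1f Sd=%.2f Nd=%.2f%s)>\n",
              x$Ks, x$Ka, x$S, x$N_sites, x$Sd, x$Nd,
              if (x$saturated) ", saturated" else ""))
  invisible(x)
}

#' Deterministic global protein alignment
#'
#' Needleman-Wunsch with affine gaps over a substitution matrix
#' (BLOSUM62 by default), via Biostrings. Ties are resolved
#' deterministically by the aligner.
#'
#' @param a,b amino-acid strings.
#' @param substitution_matrix a substitution matrix name or matrix
#'   (default "BLOSUM62").
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return list with `aligned` (character vector of the two gapped strings)
#'   and `score`.
#' @export
align_proteins_global <- function(a, b, substitution_matrix = "BLOSUM62",
                                  gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  ok <- "^[ACDEFGHIKLMNPQRSTVWYX*]+$"
  if (!grepl(ok, a) || !grepl(ok, b)) stop("non-amino-acid symbol in input")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  list(aligned = c(as.character(Biostrings::alignedPattern(al)),
                   as.character(Biostrings::alignedSubject(al))),
       score = Biostrings::score(al))
}

#' Ka/Ks for a pair of CDS sequences (align, back-translate, NG86)
#'
#' Convenience wrapper: translate both CDSs, align the proteins globally,
#' back-translate, and run [ng86_pair()].
#'
#' @param cds_a,cds_b CDS nucleotide strings.
#' @param ... passed to [align_proteins_global()].
#' @return a `kaks_result`.
#' @export
kaks_cds_pair <- function(cds_a, cds_b, ...) {
  strip <- function(cds) {
    last <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (Biostrings::GENETIC_CODE[[last]] == "*") substr(cds, 1L, nchar(cds) - 3L) else cds
  }
  cds_a <- strip(cds_a)
  cds_b <- strip(cds_b)
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  al <- align_proteins_global(pa, pb, ...)
  ng86_pair(backtranslate_alignment(al$aligned, cds_a, cds_b))
}
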