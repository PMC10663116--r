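# Domain containers and readers/writers for genomes, gene models, expression
# tables and PWMs; promoter extraction; codon-aware back-translation.
#
# Internal coordinates are 0-based half-open; GFF3 I/O converts to and from
# the 1-based inclusive convention on the fly.

#' Construct a genome object
#'
#' A genome is a light container: ordered gene models on named chromosomes,
#' with optional chromosome sequences. Gene ranks (0-based ordinal position by
#' start, per chromosome) are (re)computed on construction.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `cds`. Coordinates are 0-based half-open.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param sequences optional named character vector of chromosome sequences.
#' @param name genome name.
#' @return an object of class `genome`.
#' @export
new_genome <- function(genes, chrom_lengths, sequences = NULL, name = "genome") {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene IDs")
  if (any(genes$start < 0) || any(genes$start >= genes$end)) {
    stop("gene coordinates must satisfy 0 <= start < end")
  }
  if (!all(genes$chrom %in% names(chrom_lengths))) {
    stop("gene on a chromosome absent from chrom_lengths")
  }
  if (any(genes$end > chrom_lengths[genes$chrom])) {
    stop("gene end exceeds chromosome length")
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!is.null(genes$cds)) {
    has <- !is.na(genes$cds) & nzchar(genes$cds)
    if (any(nchar(genes$cds[has]) %% 3 != 0)) {
      stop("CDS lengths must be divisible by 3")
    }
  }
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  genes$rank <- as.integer(stats::ave(genes$start, genes$chrom,
                                      FUN = function(x) seq_along(x) - 1L))
  rownames(genes) <- NULL
  structure(list(name = name,
                 chrom_lengths = chrom_lengths,
                 genes = genes,
                 sequences = sequences),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome '%s': %d chromosomes, %d genes%s>\n", x$name,
              length(x$chrom_lengths), nrow(x$genes),
              if (is.null(x$sequences)) "" else ", with sequences"))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Only `gene` features are consumed (one model per gene; see package
#' vignette). GFF 1-based inclusive coordinates are converted to internal
#' 0-based half-open; ranks are assigned per chromosome by start.
#'
#' @param path path to a GFF3 file.
#' @param chrom_lengths optional named lengths; defaults to per-chromosome
#'   max gene end (or `##sequence-region` pragmas when present).
#' @return a `genome` object (without sequences).
#' @export
read_gff <- function(path, chrom_lengths = NULL) {
  lines <- readLines(path)
  region <- grep("^##sequence-region", lines, value = TRUE)
  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body_idx) == 0L) stop("no features in GFF file: ", path)
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop(sprintf("malformed GFF line %d: expected 9 tab-separated fields, got %d",
                 body_idx[which(nf != 9L)[1L]], nf[nf != 9L][1L]))
  }
  m <- do.call(rbind, fields)
  keep <- m[, 3L] == "gene"
  m <- m[keep, , drop = FALSE]
  kept_lines <- body_idx[keep]
  starts <- suppressWarnings(as.integer(m[, 4L]))
  ends <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(starts) | is.na(ends) | starts < 1L | ends < starts)
  if (length(bad)) {
    stop(sprintf("malformed GFF line %d: invalid coordinates", kept_lines[bad[1L]]))
  }
  ids <- sub(".*ID=([^;]+).*", "\\1", m[, 9L])
  noid <- !grepl("(^|;)ID=", m[, 9L])
  if (any(noid)) {
    stop(sprintf("malformed GFF line %d: gene feature without ID attribute",
                 kept_lines[which(noid)[1L]]))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene ID in GFF: ", ids[duplicated(ids)][1L])
  }
  genes <- data.frame(gene_id = ids, chrom = m[, 1L],
                      start = starts - 1L, end = ends,
                      strand = m[, 7L], stringsAsFactors = FALSE)
  if (is.null(chrom_lengths)) {
    if (length(region)) {
      parts <- strsplit(region, "\\s+")
      chrom_lengths <- setNames(
        vapply(parts, function(p) as.numeric(p[4L]), numeric(1)),
        vapply(parts, function(p) p[2L], character(1)))
    } else {
      chrom_lengths <- tapply(genes$end, genes$chrom, max)
      chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
    }
  }
  new_genome(genes, chrom_lengths, name = basename(path))
}

#' Write gene models to a GFF3 file
#'
#' @param genome a `genome` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genome, path) {
  g <- genome$genes
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d",
                      names(genome$chrom_lengths),
                      as.integer(genome$chrom_lengths)))
  body <- sprintf("%s\tpaleodup\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  g$chrom, g$start + 1L, g$end, g$strand, g$gene_id)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; duplicate headers and empty records are errors.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(set))) {
    stop("duplicate FASTA header: ", names(set)[duplicated(names(set))][1L])
  }
  if (any(Biostrings::width(set) == 0L)) {
    stop("empty FASTA record: ", names(set)[Biostrings::width(set) == 0L][1L])
  }
  # keep only the first whitespace-delimited token of each header
  setNames(toupper(as.character(set)), sub("\\s.*", "", names(set)))
}

#' Write a named character vector of sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Extract promoter sequences upstream of each gene
#'
#' The transcription start site is taken as the annotated gene start. For a
#' `+` strand gene the promoter is `sequence[start - length, start)`; for a
#' `-` strand gene it is the reverse complement of `sequence[end, end +
#' length)`. Promoters are truncated at chromosome boundaries and returned
#' 5'->3' relative to the gene.
#'
#' @param genome a `genome` object with `sequences` present.
#' @param length promoter length in bp (default 2000, the usual upstream
#'   window taken from the TSS).
#' @return named character vector, one promoter per gene.
#' @export
extract_promoters <- function(genome, length = 2000L) {
  if (is.null(genome$sequences)) stop("genome has no chromosome sequences")
  g <- genome$genes
  missing_chr <- setdiff(unique(g$chrom), names(genome$sequences))
  if (length(missing_chr)) {
    stop("missing chromosome sequence: ", missing_chr[1L])
  }
  out <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    seq <- genome$sequences[[g$chrom[i]]]
    clen <- nchar(seq)
    if (g$strand[i] == "+") {
      from <- max(0L, g$start[i] - length)
      out[i] <- substr(seq, from + 1L, g$start[i])
    } else {
      to <- min(clen, g$end[i] + length)
      out[i] <- if (to > g$end[i]) revcomp(substr(seq, g$end[i] + 1L, to)) else ""
    }
  }
  setNames(out, g$gene_id)
}

#' Back-translate a pairwise protein alignment onto codon sequences
#'
#' Forces the nucleotide sequences to fit an existing amino-acid alignment:
#' each aligned residue column becomes one codon column, and each gap column
#' becomes `---`.
#'
#' @param protein_aln character vector of length 2: the aligned (gapped)
#'   amino-acid strings.
#' @param cds_a,cds_b ungapped CDS nucleotide strings whose translations
#'   (terminal stop stripped) equal the ungapped protein sequences.
#' @return an object of class `codon_alignment` with fields `aligned_a`,
#'   `aligned_b` (gapped nucleotide strings of length `3 * alignment length`).
#' @export
backtranslate_alignment <- function(protein_aln, cds_a, cds_b) {
  stopifnot(length(protein_aln) == 2L)
  if (nchar(protein_aln[1L]) != nchar(protein_aln[2L])) {
    stop("aligned protein strings differ in length")
  }
  if (nchar(cds_a) %% 3 != 0 || nchar(cds_b) %% 3 != 0) {
    stop("CDS length not divisible by 3")
  }
  strip_stop <- function(cds) {
    last <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (Biostrings::GENETIC_CODE[[last]] == "*") substr(cds, 1L, nchar(cds) - 3L) else cds
  }
  cds <- c(strip_stop(cds_a), strip_stop(cds_b))
  aligned <- character(2L)
  for (k in 1:2) {
    prot <- translate_cds(cds[k])
    ungapped <- gsub("-", "", protein_aln[k], fixed = TRUE)
    if (nchar(ungapped) != nchar(prot)) {
      stop("translation mismatch: protein length ", nchar(ungapped),
           " vs translated CDS length ", nchar(prot))
    }
    pa <- strsplit(prot, "")[[1L]]
    ua <- strsplit(ungapped, "")[[1L]]
    diff <- which(pa != ua)
    if (length(diff)) {
      stop(sprintf("translation mismatch at residue %d: '%s' vs '%s'",
                   diff[1L], ua[diff[1L]], pa[diff[1L]]))
    }
    cols <- strsplit(protein_aln[k], "")[[1L]]
    codons <- substring(cds[k], seq(1L, nchar(cds[k]), 3L), seq(3L, nchar(cds[k]), 3L))
    out <- character(length(cols))
    j <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") {
        out[i] <- "---"
      } else {
        j <- j + 1L
        out[i] <- codons[j]
      }
    }
    aligned[k] <- paste0(out, collapse = "")
  }
  structure(list(aligned_a = aligned[1L], aligned_b = aligned[2L]),
            class = "codon_alignment")
}

#' Extract filtered codon pairs from a codon alignment
#'
#' Codon columns containing gaps, ambiguous bases (N) or stop codons are
#' excluded and counted in `n_excluded`.
#'
#' @param aln a `codon_alignment` object (or a list with `aligned_a`,
#'   `aligned_b`).
#' @return list with `codon_a`, `codon_b` (character vectors of kept codon
#'   columns) and `n_excluded`.
#' @export
codon_pairs <- function(aln) {
  n <- nchar(aln$aligned_a)
  stopifnot(n == nchar(aln$aligned_b), n %% 3 == 0)
  idx <- seq(1L, n, 3L)
  ca <- substring(aln$aligned_a, idx, idx + 2L)
  cb <- substring(aln$aligned_b, idx, idx + 2L)
  gc <- Biostrings::GENETIC_CODE
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ok[ok] <- gc[ca[ok]] != "*" & gc[cb[ok]] != "*"
  list(codon_a = ca[ok], codon_b = cb[ok], n_excluded = sum(!ok))
}

#' Read an expression matrix from TSV
#'
#' Expected layout: header `gene_id<TAB>CK_day_1<TAB>...` where each sample
#' column is named `<condition>_<time>_<replicate>` with condition in
#' CK/D/H/DH and time in day/night.
#'
#' @param path TSV path.
#' @return an `expr_matrix` object: list with `values` (genes x samples TPM
#'   matrix) and `samples` (data.frame condition/time/replicate).
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df[[1L]]
  new_expr_matrix(vals)
}

#' Construct an expression-matrix object from a TPM matrix
#'
#' @param values numeric matrix, rows = genes, columns named
#'   `<condition>_<time>_<replicate>`.
#' @return an `expr_matrix` object.
#' @export
new_expr_matrix <- function(values) {
  if (any(values < 0)) stop("negative TPM values")
  parts <- strsplit(colnames(values), "_", fixed = TRUE)
  ok <- lengths(parts) == 3L
  if (!all(ok)) stop("bad sample column name: ", colnames(values)[!ok][1L])
  samples <- data.frame(condition = vapply(parts, `[`, "", 1L),
                        time = vapply(parts, `[`, "", 2L),
                        replicate = as.integer(vapply(parts, `[`, "", 3L)),
                        stringsAsFactors = FALSE)
  if (!all(samples$condition %in% c("CK", "D", "H", "DH"))) {
    stop("unknown condition in sample names")
  }
  if (!all(samples$time %in% c("day", "night"))) {
    stop("unknown time in sample names")
  }
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' Write an expression matrix to TSV
#' @param expr an `expr_matrix` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
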