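# End-to-end orchestration: simulate (optional) -> homologs -> chaining ->
# Ka/Ks -> Ks peaks -> WGD dating -> tandem/origin classification ->
# phasing/residues -> motif enrichment, with per-stage TSV outputs and a
# JSON summary.

#' Ka/Ks table for a set of gene pairs
#'
#' Aligns each pair's proteins globally (one vectorised pass),
#' back-translates onto the CDSs and runs NG86.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param cds named character vector of CDS sequences.
#' @return data.frame `gene_a`, `gene_b`, `S`, `N`, `Sd`, `Nd`, `Ka`, `Ks`,
#'   `saturated`.
#' @export
kaks_table <- function(pairs, cds) {
  if (!nrow(pairs)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      S = numeric(0), N = numeric(0), Sd = numeric(0),
                      Nd = numeric(0), Ka = numeric(0), Ks = numeric(0),
                      saturated = logical(0)))
  }
  prot <- translate_cds(cds)
  names(prot) <- names(cds)
  qa <- unname(prot[pairs$gene_a])
  qb <- unname(prot[pairs$gene_b])
  opt <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(qa), Biostrings::AAStringSet(qb),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global", scoreOnly = TRUE)
  # gap-free fast path: when the ungapped score attains the optimum, the
  # ungapped alignment is an optimal alignment (ties prefer substitutions)
  b62 <- .blosum62()
  pa <- qa
  pb <- qb
  direct <- nchar(qa) == nchar(qb)
  direct[direct] <- vapply(which(direct), function(i) {
    sc <- sum(b62[cbind(strsplit(qa[i], "")[[1L]],
                        strsplit(qb[i], "")[[1L]])])
    abs(sc - opt[i]) < 1e-9
  }, TRUE)
  if (any(!direct)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(qa[!direct]),
      Biostrings::AAStringSet(qb[!direct]),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    pa[!direct] <- as.character(Biostrings::alignedPattern(al))
    pb[!direct] <- as.character(Biostrings::alignedSubject(al))
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    aln <- backtranslate_alignment(c(pa[i], pb[i]),
                                   cds[[pairs$gene_a[i]]],
                                   cds[[pairs$gene_b[i]]])
    r <- ng86_pair(aln)
    data.frame(gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
               S = r$S, N = r$N_sites, Sd = r$Sd, Nd = r$Nd,
               Ka = r$Ka, Ks = r$Ks, saturated = r$saturated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' @param seed master seed; it also seeds the simulator unless `sim`
#'   overrides it.
#' @param outdir output directory for per-stage TSVs and the JSON summary
#'   (NULL = do not write files).
#' @param sim a [simulation_config()]; the default runs the pipeline on a
#'   simulated two-WGD genome.
#' @param clock_r synonymous substitution rate per site per year used for
#'   WGD dating.
#' @param min_block,max_gap,gap_penalty chaining parameters (MCScanX-style
#'   defaults).
#' @param top_n,min_score homolog-search parameters.
#' @param max_intervening tandem-array spacing.
#' @param min_copies syntenic-copy threshold of the WGD origin call.
#' @param ks_cap Ks cap of the anchor distribution.
#' @param max_components mixture components tried for Ks peaks.
#' @param run_ccm,run_motifs include the CCM-classification / the
#'   motif-enrichment stage (simulated study inputs).
#' @param motif_n_genes,motif_n_module motif-study dimensions.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = NULL, sim = NULL,
                            clock_r = 7.54e-9,
                            min_block = 5L, max_gap = 25L, gap_penalty = 1,
                            top_n = 5L, min_score = 50,
                            max_intervening = 1L, min_copies = 2L,
                            ks_cap = 3.0, max_components = 4L,
                            run_ccm = TRUE, run_motifs = TRUE,
                            motif_n_genes = 800L, motif_n_module = 80L) {
  if (is.null(sim)) sim <- simulation_config(seed = seed, emit_sequences = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

.write_tsv <- function(df, outdir, file) {
  if (is.null(outdir)) return(invisible(NULL))
  write.table(df, file.path(outdir, file), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Run the full duplication-analysis pipeline
#'
#' Executes every stage on simulated inputs (the default) and returns a
#' summary list; when `config$outdir` is set, per-stage TSVs and
#' `summary.json` are written there. Identical configs give identical
#' summaries.
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly when files are written.
#' @export
run_all <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$outdir) &&
      !dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)

  sim <- .stage("simulate", simulate_genome(config$sim))
  genome <- sim$genome
  cds <- setNames(genome$genes$cds, genome$genes$gene_id)
  prot <- translate_cds(cds)
  names(prot) <- names(cds)

  pairs <- .stage("homologs", find_homolog_pairs(
    prot, top_n = config$top_n, min_score = config$min_score))
  anchors <- as_anchors(pairs, genome)
  blocks <- .stage("chaining", chain_anchors(
    anchors, min_block = config$min_block, max_gap = config$max_gap,
    gap_penalty = config$gap_penalty))

  anchor_pairs <- unique(do.call(rbind, lapply(blocks, function(b) {
    b$anchors[, c("gene_a", "gene_b")]
  })))
  kaks <- .stage("kaks", kaks_table(anchor_pairs, cds))
  dist <- .stage("ks_distribution",
                 anchor_ks_distribution(blocks, kaks, ks_cap = config$ks_cap))
  blocks <- dist$blocks

  peaks <- .stage("ks_peaks", fit_ks_peaks(
    dist$ks, max_components = config$max_components, seed = config$seed))
  events <- lapply(seq_len(peaks$n_components), function(i) {
    date_wgd(peaks$means[i], clock_params(config$clock_r),
             label = paste0("WGD", i))
  })

  tandem <- .stage("tandem", detect_tandem(
    genome, pairs, max_intervening = config$max_intervening))
  families <- gene_families(pairs, genome$genes$gene_id)
  classes <- .stage("classification", classify_duplicates(
    genome, blocks, tandem, families, min_copies = config$min_copies))

  # syntenic depth against the pre-WGD ancestor
  anc_cds <- setNames(sim$ancestor$genes$cds, sim$ancestor$genes$gene_id)
  names(anc_cds) <- paste0("anc_", names(anc_cds))
  anc_prot <- translate_cds(anc_cds)
  names(anc_prot) <- names(anc_cds)
  depth <- .stage("depth", {
    cross <- find_homolog_pairs(anc_prot, prot, top_n = 8L,
                                min_score = config$min_score)
    anc_genome <- sim$ancestor
    anc_genome$genes$gene_id <- paste0("anc_", anc_genome$genes$gene_id)
    cross_anchors <- as_anchors(cross, anc_genome, genome)
    cross_blocks <- chain_anchors(cross_anchors,
                                  min_block = config$min_block,
                                  max_gap = config$max_gap,
                                  gap_penalty = config$gap_penalty)
    syntenic_depth(cross_blocks, anc_genome)
  })

  summary <- list(
    seed = config$seed,
    parameters = list(clock_r = config$clock_r,
                      min_block = config$min_block,
                      max_gap = config$max_gap,
                      min_copies = config$min_copies,
                      ks_cap = config$ks_cap),
    n_genes = nrow(genome$genes),
    n_blocks = length(blocks),
    n_anchor_pairs = nrow(anchor_pairs),
    wgd_events = lapply(events, function(e) {
      list(label = e$label, ks_mode = e$ks_mode, age_mya = e$age_mya)
    }),
    depth_modal = depth$modal_depth,
    depth_ratio = depth_ratio_label(depth),
    origin_counts = as.list(table(classes)))

  if (config$run_ccm) {
    ccm <- .stage("ccm", {
      fam <- simulate_ccm_family(seed = config$seed)
      expressed <- filter_expressed(fam$expr)
      phases <- phase_genes(fam$expr)
      diag <- diagnose_residues(fam$alignment, fam$reference_id)
      calls <- classify_ccm(diag, phases)
      list(fam = fam, calls = calls, diag = diag, phases = phases,
           expressed = expressed)
    })
    summary$ccm_counts <- as.list(table(ccm$calls))
  }

  if (config$run_motifs) {
    motifs <- .stage("motif_enrichment", {
      study <- simulate_motif_study(seed = config$seed,
                                    n_genes = config$motif_n_genes,
                                    n_module = config$motif_n_module)
      hits <- scan_promoters(study$promoters, study$pwm)
      counts <- count_module_occurrences(
        hits, study$modules, module = "green",
        expressed = names(study$promoters))
      res <- motif_enrichment(
        counts, clusters = setNames(study$pwm$cluster_id,
                                    study$pwm$motif_id))
      list(results = res, highlighted = aggregate_clusters(res, 1L))
    })
    summary$n_enriched_motifs <- sum(motifs$results$enriched)
    summary$highlighted_clusters <- motifs$highlighted
  }

  if (!is.null(config$outdir)) {
    write_gff(genome, file.path(config$outdir, "genome.gff3"))
    write_fasta(cds, file.path(config$outdir, "cds.fa"))
    .write_tsv(blocks_summary(blocks), config$outdir, "blocks.tsv")
    .write_tsv(kaks, config$outdir, "kaks.tsv")
    .write_tsv(data.frame(ks = dist$ks), config$outdir, "ks_values.tsv")
    .write_tsv(data.frame(
      component = seq_len(peaks$n_components),
      ks_mode = peaks$means, weight = peaks$weights,
      age_mya = vapply(events, `[[`, 0, "age_mya")),
      config$outdir, "wgd.tsv")
    .write_tsv(data.frame(gene_id = names(classes), origin = classes),
               config$outdir, "origin_classes.tsv")
    .write_tsv(data.frame(gene_id = sim$truth$genes$gene_id,
                          origin = sim$truth$genes$origin,
                          diel_class = sim$truth$genes$diel_class),
               config$outdir, "truth.tsv")
    if (config$run_ccm) {
      .write_tsv(data.frame(gene_id = names(ccm$calls),
                            residue_call = unname(ccm$diag$calls),
                            diel_label = unname(phase_labels(ccm$phases)[names(ccm$calls)]),
                            final_class = unname(ccm$calls)),
                 config$outdir, "ccm_calls.tsv")
    }
    if (config$run_motifs) {
      .write_tsv(motifs$results, config$outdir, "enrichment.tsv")
    }
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(summary))
  }
  summary
}
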