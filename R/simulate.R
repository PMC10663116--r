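# Synthetic genomes with planted ground truth: WGD collinear blocks, tandem
# arrays, codon divergence to target Ks, diel/stress expression phases, and
# promoter motif planting. Every downstream stage of the pipeline is
# exercisable against the truth tables produced here.

#' Simulation configuration
#'
#' Defaults emulate the two-WGD regime of a paleopolyploid Caryophyllales
#' genome: an ancient event near Ks 1.0 and a recent one near Ks 0.113
#' (the Ks modes implied by WGD ages of ~66.3 and ~7.5 My under a clock of
#' r = 7.54e-9 substitutions/site/year), with moderate duplicate retention.
#'
#' @param seed integer RNG seed; a fixed seed makes every emitted artifact
#'   byte-identical across runs.
#' @param n_chroms,genes_per_chrom ancestral genome dimensions.
#' @param wgd_events list of `list(target_ks=, retention_rate=)`, oldest
#'   first; each event duplicates every chromosome and then deletes each
#'   duplicated gene independently with probability `1 - retention_rate`.
#' @param tandem_rate per-gene probability of spawning a tandem array.
#' @param tandem_max_copies maximum total copies in a planted tandem array.
#' @param tandem_ks divergence of tandem copies (near-identical by default).
#' @param ortholog_divergence_ks optional extra divergence applied to the
#'   retained pre-WGD ancestor snapshot (an outgroup-like lineage).
#' @param cds_length_codons CDS length of every simulated gene.
#' @param ka_ks_ratio nonsynonymous/synonymous divergence ratio applied
#'   along every lineage (mild purifying-selection regime; kept small so
#'   amino-acid change does not distort synonymous-site counting).
#' @param transition_bias extra weight on transition substitutions when an
#'   alternative base is drawn (0 = unbiased, the calibrated default).
#' @param expression_noise_cv lognormal coefficient of variation of
#'   replicate noise in [simulate_expression()].
#' @param cam_induction_fold mean night-stress induction of CAM-like genes
#'   relative to control nights (generator contract: >= 100).
#' @param n_c4_genes,n_cam_genes how many genes receive C4-like / CAM-like
#'   diel classes.
#' @param motif_plant_rate_module,motif_plant_rate_background default
#'   planting rates for [plant_motifs()].
#' @param intergenic_bp intergenic spacer length used when chromosome
#'   sequences are emitted (long enough for 2-kb promoters).
#' @param emit_sequences generate chromosome sequences (needed for promoter
#'   extraction; can be disabled for speed).
#' @return a `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 2L,
                              genes_per_chrom = 500L,
                              wgd_events = list(
                                list(target_ks = 1.0, retention_rate = 0.6),
                                list(target_ks = 0.113, retention_rate = 0.4)),
                              tandem_rate = 0.02,
                              tandem_max_copies = 3L,
                              tandem_ks = 0.02,
                              ortholog_divergence_ks = NULL,
                              cds_length_codons = 200L,
                              ka_ks_ratio = 0.02,
                              transition_bias = 0,
                              expression_noise_cv = 0.25,
                              cam_induction_fold = 150,
                              n_c4_genes = 4L,
                              n_cam_genes = 2L,
                              motif_plant_rate_module = 0.6,
                              motif_plant_rate_background = 0.1,
                              intergenic_bp = 2500L,
                              emit_sequences = TRUE) {
  for (ev in wgd_events) {
    stopifnot(ev$target_ks > 0,
              ev$retention_rate > 0, ev$retention_rate <= 1)
  }
  stopifnot(tandem_rate >= 0, tandem_rate < 1, tandem_max_copies >= 2,
            transition_bias >= 0, expression_noise_cv >= 0,
            motif_plant_rate_module >= 0, motif_plant_rate_module <= 1,
              motif_plant_rate_background >= 0, motif_plant_rate_background <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# ---- calibrated codon evolution ---------------------------------------

# Per-codon, per-position alternative-base sets: synonymous alternatives and
# nonsynonymous non-stop alternatives.
.evo_tables <- function() {
  tab <- .paleodup_cache$evo
  if (!is.null(tab)) return(tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- sense_codons()
  n <- length(codons)
  syn_alts <- vector("list", n)
  non_alts <- vector("list", n)
  k_syn <- matrix(0L, n, 3)
  k_non <- matrix(0L, n, 3)
  for (i in seq_len(n)) {
    cd <- codons[i]
    sa <- vector("list", 3)
    na <- vector("list", 3)
    for (pos in 1:3) {
      ref <- substr(cd, pos, pos)
      s <- character(0)
      ns <- character(0)
      for (nt in setdiff(DNA_BASES, ref)) {
        alt <- cd
        substr(alt, pos, pos) <- nt
        if (gc[[alt]] == "*") next
        if (gc[[alt]] == gc[[cd]]) s <- c(s, nt) else ns <- c(ns, nt)
      }
      sa[[pos]] <- s
      na[[pos]] <- ns
      k_syn[i, pos] <- length(s)
      k_non[i, pos] <- length(ns)
    }
    syn_alts[[i]] <- sa
    non_alts[[i]] <- na
  }
  tab <- list(codons = codons, syn_alts = syn_alts, non_alts = non_alts,
              k_syn = k_syn, k_non = k_non)
  .paleodup_cache$evo <- tab
  tab
}

# Total path jump intensity for a site class with `s` states (current base
# plus s-1 alternatives) such that, after the jumps, the probability of
# observing a difference equals f * p_JC(d) with f = (s-1)/3 the NG86 site
# fraction and p_JC(d) = 3/4 (1 - exp(-4d/3)). Inverting the s-state uniform
# chain makes the NG86 + Jukes-Cantor estimate of d asymptotically unbiased.
.lambda_path <- function(d, s) {
  if (s <= 1 || d <= 0) return(0)
  q <- 0.75 * (1 - exp(-4 * d / 3)) * (s - 1) / 3
  -((s - 1) / s) * log(1 - q * s / (s - 1))
}

# Evolve a vector of codons, applying mean jump intensity lam_syn[k+1] to
# positions with k synonymous alternatives (and likewise lam_non for the
# nonsynonymous process). Jump counts are Poisson; the endpoint after n
# uniform jumps on s states stays put with probability
# 1/s + (s-1)/s * (-1/(s-1))^n. The nonsynonymous process runs first and
# site classes are re-evaluated on the current codon before each pass, so
# planted synonymous changes always preserve the amino acid and no stop
# codon can ever be assembled.
.evolve_codons <- function(codons, lam_syn, lam_non, transition_bias = 0) {
  tab <- .evo_tables()
  cur <- codons
  mat <- matrix(unlist(strsplit(codons, ""), use.names = FALSE),
                ncol = 3, byrow = TRUE)
  L <- length(codons)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  pick_alt <- function(base, alts) {
    if (length(alts) == 1L) return(alts)
    if (transition_bias > 0) {
      w <- ifelse(alts == transition[[base]], 1 + transition_bias, 1)
      return(sample(alts, 1L, prob = w))
    }
    sample(alts, 1L)
  }
  for (proc in c("non", "syn")) {
    kmat <- if (proc == "syn") tab$k_syn else tab$k_non
    amat <- if (proc == "syn") tab$syn_alts else tab$non_alts
    lam_by_k <- if (proc == "syn") lam_syn else lam_non
    if (all(lam_by_k == 0)) next
    for (pos in 1:3) {
      idx <- match(cur, tab$codons)
      k <- kmat[idx, pos]
      lam <- lam_by_k[k + 1L]
      n <- rpois(L, lam)
      act <- which(n > 0L)
      if (!length(act)) next
      s <- k[act] + 1L
      stay <- 1 / s + (s - 1) / s * (-1 / (s - 1))^n[act]
      flip <- act[runif(length(act)) >= stay]
      for (i in flip) {
        alts <- amat[[idx[i]]][[pos]]
        mat[i, pos] <- pick_alt(mat[i, pos], alts)
      }
      if (length(flip)) {
        cur[flip] <- paste0(mat[flip, 1L], mat[flip, 2L], mat[flip, 3L])
      }
    }
  }
  cur
}

.split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Evolve a coding sequence to a target pairwise Ks (and Ka)
#'
#' Returns a diverged copy of `cds` such that the NG86 + Jukes-Cantor
#' estimate of Ks (Ka) between input and output is asymptotically unbiased
#' for `target_ks` (`target_ka`). Substitutions are Poisson per site with
#' multiple hits permitted; jump intensities are calibrated per degeneracy
#' class (see the methods vignette).
#'
#' @param cds CDS nucleotide string (sense codons only).
#' @param target_ks,target_ka target synonymous / nonsynonymous divergence
#'   per (non)synonymous site; any nonnegative value is allowed. The default
#'   `target_ka = 0` holds the protein fixed (a pure synonymous clock);
#'   amino-acid divergence couples synonymous-site classification across
#'   codon positions and reintroduces the counting method's own downward
#'   bias at high Ks (see the methods vignette).
#' @param transition_bias weight on transitions when drawing alternatives.
#' @return the evolved CDS string.
#' @export
evolve_pair <- function(cds, target_ks, target_ka = 0,
                        transition_bias = 0) {
  stopifnot(target_ks >= 0, target_ka >= 0)
  if (target_ks == 0 && target_ka == 0) return(cds)
  lam_syn <- vapply(0:3, function(k) .lambda_path(target_ks, k + 1L), 0)
  lam_non <- vapply(0:3, function(k) .lambda_path(target_ka, k + 1L), 0)
  paste0(.evolve_codons(.split_codons(cds), lam_syn, lam_non,
                        transition_bias), collapse = "")
}

# Evolve one lineage over a tree segment running from pair-divergence level
# ks_from down to ks_to (ks_from > ks_to >= 0). Intensities are differences
# of the calibrated path map, so divergence is additive along lineages and
# every leaf pair split at level K ends up at pairwise Ks ~ K.
.evolve_segment <- function(codons, ks_from, ks_to, ka_ratio = 0.02,
                            transition_bias = 0) {
  lam_syn <- vapply(0:3, function(k) {
    (.lambda_path(ks_from, k + 1L) - .lambda_path(ks_to, k + 1L)) / 2
  }, 0)
  lam_non <- vapply(0:3, function(k) {
    (.lambda_path(ks_from * ka_ratio, k + 1L) -
       .lambda_path(ks_to * ka_ratio, k + 1L)) / 2
  }, 0)
  .evolve_codons(codons, lam_syn, lam_non, transition_bias)
}

# ---- genome simulation ------------------------------------------------

.random_dna <- function(n) {
  paste0(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Ancestral codon pool for simulated genes: sense codons whose synonymous
# family is closed at the third position with position-independent
# degeneracy. The leucine and arginine six-fold boxes are excluded: their
# first-position degeneracy couples site classes across codon positions,
# which the NG86 counting model cannot represent consistently, so sequences
# evolved through them acquire a small systematic Ks deficit (the methods
# vignette quantifies this).
.stable_codon_pool <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- sense_codons()
  codons[!gc[codons] %in% c("L", "R")]
}

#' Simulate a genome with planted WGDs and tandem arrays
#'
#' Builds an ancestral genome of random coding genes, applies each WGD event
#' (whole-chromosome duplication followed by independent gene loss on the
#' duplicated copy), evolves all lineages along the implied duplication tree
#' so that duplicate pairs diverge to the event's target Ks, and finally
#' inserts near-identical tandem copies. A snapshot of the pre-WGD ancestor
#' is retained for outgroup-style comparisons (e.g. syntenic depth).
#'
#' @param config a [simulation_config()] object.
#' @return list with elements `genome` (the final `genome` object),
#'   `ancestor` (pre-WGD `genome`), and `truth` (list of `genes`, `pairs`,
#'   `blocks` data frames plus `warnings`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  for (ev in config$wgd_events) {
    if (!is.numeric(ev$target_ks) || ev$target_ks <= 0) {
      stop("wgd_events target_ks must be positive")
    }
    if (ev$retention_rate <= 0 || ev$retention_rate > 1) {
      stop("wgd_events retention_rate must be in (0, 1]")
    }
  }
  set.seed(config$seed)
  codons <- .stable_codon_pool()
  ncod <- config$cds_length_codons

  # ancestral gene set, one data.frame per chromosome
  sub <- list()
  anc_genes <- list()
  for (c in seq_len(config$n_chroms)) {
    ids <- sprintf("g%02d_%04d", c, seq_len(config$genes_per_chrom))
    cds <- vapply(seq_along(ids), function(i) {
      paste0(sample(codons, ncod, replace = TRUE), collapse = "")
    }, character(1))
    df <- data.frame(gene_id = ids, ancestor_id = ids, cds = cds,
                     origin = "singleton", birth_ks = NA_real_,
                     stringsAsFactors = FALSE)
    sub[[sprintf("chr%02d", c)]] <- df
    anc_genes[[c]] <- df
  }
  ancestor_snapshot <- sub

  events <- config$wgd_events
  ks_levels <- vapply(events, function(e) e$target_ks, 0)
  if (is.unsorted(rev(ks_levels))) {
    stop("wgd_events must be ordered oldest (largest target_ks) first")
  }
  pairs <- list()
  blocks <- list()
  warnings <- character(0)

  for (ei in seq_along(events)) {
    ev <- events[[ei]]
    ev_label <- paste0("WGD", ei)
    new_sub <- list()
    for (chrom in names(sub)) {
      df <- sub[[chrom]]
      dup_chrom <- paste0(chrom, letters[ei])
      keep <- runif(nrow(df)) <= ev$retention_rate
      dup <- df[keep, , drop = FALSE]
      if (nrow(dup)) {
        dup$gene_id <- paste0(dup$gene_id, ".", ev_label)
        dup$origin <- ev_label
        dup$birth_ks <- ev$target_ks
        pairs[[length(pairs) + 1L]] <- data.frame(
          gene_a = df$gene_id[keep], gene_b = dup$gene_id,
          event = ev_label, true_ks = ev$target_ks, stringsAsFactors = FALSE)
        # the surviving parent copy also participates in this event
        df$origin[keep] <- ev_label
        df$birth_ks[keep] <- ev$target_ks
      }
      if (sum(keep) < 5L) {
        warnings <- c(warnings, sprintf(
          "planted block %s/%s has only %d anchors (< 5)",
          chrom, dup_chrom, sum(keep)))
      }
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom_a = chrom, chrom_b = dup_chrom, event = ev_label,
        n_retained = sum(keep), stringsAsFactors = FALSE)
      new_sub[[chrom]] <- df
      new_sub[[dup_chrom]] <- dup
    }
    sub <- new_sub
    # evolve every lineage down to the next event (or the present)
    ks_to <- if (ei < length(events)) ks_levels[ei + 1L] else 0
    for (chrom in names(sub)) {
      if (!nrow(sub[[chrom]])) next
      cods <- unlist(lapply(sub[[chrom]]$cds, .split_codons), use.names = FALSE)
      cods <- .evolve_segment(cods, ks_levels[ei], ks_to,
                              ka_ratio = config$ka_ks_ratio,
                              transition_bias = config$transition_bias)
      ends <- cumsum(rep(ncod, nrow(sub[[chrom]])))
      sub[[chrom]]$cds <- vapply(seq_along(ends), function(i) {
        paste0(cods[(ends[i] - ncod + 1L):ends[i]], collapse = "")
      }, character(1))
    }
  }

  # optional extra divergence of the ancestor snapshot (outgroup lineage)
  if (!is.null(config$ortholog_divergence_ks)) {
    for (chrom in names(ancestor_snapshot)) {
      df <- ancestor_snapshot[[chrom]]
      df$cds <- vapply(df$cds, evolve_pair,
                       target_ks = config$ortholog_divergence_ks,
                       transition_bias = config$transition_bias,
                       FUN.VALUE = character(1), USE.NAMES = FALSE)
      ancestor_snapshot[[chrom]] <- df
    }
  }

  # tandem arrays: adjacent near-identical copies inserted at the present
  for (chrom in names(sub)) {
    df <- sub[[chrom]]
    if (!nrow(df) || config$tandem_rate == 0) next
    spawn <- which(runif(nrow(df)) < config$tandem_rate)
    if (!length(spawn)) next
    rows <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) rows[[i]] <- df[i, , drop = FALSE]
    for (i in spawn) {
      n_extra <- sample.int(config$tandem_max_copies - 1L, 1L)
      parent <- df[i, , drop = FALSE]
      copies <- parent[rep(1L, n_extra), , drop = FALSE]
      copies$gene_id <- paste0(parent$gene_id, ".TD", seq_len(n_extra))
      copies$origin <- "TD"
      copies$birth_ks <- config$tandem_ks
      for (j in seq_len(n_extra)) {
        copies$cds[j] <- evolve_pair(
          parent$cds, config$tandem_ks,
          target_ka = config$tandem_ks * config$ka_ks_ratio,
          transition_bias = config$transition_bias)
        pairs[[length(pairs) + 1L]] <- data.frame(
          gene_a = parent$gene_id, gene_b = copies$gene_id[j],
          event = "TD", true_ks = config$tandem_ks, stringsAsFactors = FALSE)
      }
      rows[[i]] <- rbind(rows[[i]], copies)
      # the parent of a planted array is itself a tandem gene
      rows[[i]]$origin[1L] <- "TD"
    }
    sub[[chrom]] <- do.call(rbind, rows)
  }

  build_genome <- function(sub, name) {
    gl <- list()
    seqs <- if (config$emit_sequences) character(0) else NULL
    clens <- numeric(0)
    for (chrom in names(sub)) {
      df <- sub[[chrom]]
      if (!nrow(df)) { clens[chrom] <- config$intergenic_bp; next }
      glen <- nchar(df$cds)
      starts <- config$intergenic_bp +
        cumsum(c(0L, head(glen + config$intergenic_bp, -1L)))
      strand <- sample(c("+", "-"), nrow(df), replace = TRUE)
      clens[chrom] <- starts[length(starts)] + glen[length(glen)] +
        config$intergenic_bp
      gl[[chrom]] <- data.frame(gene_id = df$gene_id, chrom = chrom,
                                start = starts, end = starts + glen,
                                strand = strand, cds = df$cds,
                                stringsAsFactors = FALSE)
      if (config$emit_sequences) {
        pieces <- character(2L * nrow(df) + 1L)
        for (i in seq_len(nrow(df))) {
          pieces[2L * i - 1L] <- .random_dna(config$intergenic_bp)
          pieces[2L * i] <- if (strand[i] == "+") df$cds[i] else revcomp(df$cds[i])
        }
        pieces[length(pieces)] <- .random_dna(config$intergenic_bp)
        seqs[chrom] <- paste0(pieces, collapse = "")
      }
    }
    new_genome(do.call(rbind, gl), clens, sequences = seqs, name = name)
  }

  genome <- build_genome(sub, "simulated")
  ancestor <- build_genome(ancestor_snapshot, "ancestor")

  gene_truth <- do.call(rbind, lapply(sub, function(df) {
    df[, c("gene_id", "ancestor_id", "origin", "birth_ks")]
  }))
  rownames(gene_truth) <- NULL
  # diel classes
  gene_truth$diel_class <- "none"
  n_special <- config$n_c4_genes + config$n_cam_genes
  if (n_special > 0 && nrow(gene_truth) >= n_special) {
    pick <- sample(nrow(gene_truth), n_special)
    gene_truth$diel_class[pick[seq_len(config$n_c4_genes)]] <- "C4-like"
    if (config$n_cam_genes > 0) {
      gene_truth$diel_class[pick[config$n_c4_genes + seq_len(config$n_cam_genes)]] <- "CAM-like"
    }
  }
  truth <- list(
    genes = gene_truth,
    pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(gene_a = character(0), gene_b = character(0),
                 event = character(0), true_ks = numeric(0)),
    blocks = do.call(rbind, blocks),
    warnings = warnings)
  list(genome = genome, ancestor = ancestor, truth = truth)
}

# ---- expression simulation --------------------------------------------

.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a diel/stress expression matrix from planted diel classes
#'
#' C4-like genes are day-phased under control conditions and downregulated
#' under stress; CAM-like genes are strongly induced at night under drought
#' (D and DH), with mean induction `cam_induction_fold` times the control
#' night level (>= 100 by construction). All genes receive lognormal
#' replicate noise with the configured CV; 3 replicates per condition/time.
#'
#' @param truth truth list from [simulate_genome()] (uses `truth$genes`),
#'   or any data.frame with `gene_id` and `diel_class` columns.
#' @param config a [simulation_config()].
#' @param n_reps replicates per (condition, time).
#' @return an `expr_matrix` object.
#' @export
simulate_expression <- function(truth, config, n_reps = 3L) {
  genes <- if (is.data.frame(truth)) truth else truth$genes
  stopifnot(all(c("gene_id", "diel_class") %in% names(genes)))
  set.seed(config$seed + 101L)
  conds <- c("CK", "D", "H", "DH")
  times <- c("day", "night")
  cols <- as.vector(outer(outer(conds, times, paste, sep = "_"),
                          seq_len(n_reps), paste, sep = "_"))
  nf <- config$cam_induction_fold
  mean_for <- function(class, cond, time) {
    if (class == "C4-like") {
      if (cond == "CK") { if (time == "day") 100 else 5 }
      else { if (time == "day") 8 else 5 }
    } else if (class == "CAM-like") {
      if (cond == "CK") 3
      else if (cond %in% c("D", "DH")) { if (time == "night") 3 * nf else 4 }
      else 4  # heat alone does not induce the CAM programme here
    } else NA_real_  # none: per-gene baseline
  }
  base <- rlnorm(nrow(genes), meanlog = log(8), sdlog = 1.2)
  vals <- matrix(0, nrow(genes), length(cols),
                 dimnames = list(genes$gene_id, cols))
  for (j in seq_along(cols)) {
    p <- strsplit(cols[j], "_")[[1L]]
    mu <- vapply(genes$diel_class, mean_for, 0, cond = p[1L], time = p[2L])
    mu[is.na(mu)] <- base[is.na(mu)]
    vals[, j] <- mu * .lognoise(nrow(genes), config$expression_noise_cv)
  }
  new_expr_matrix(vals)
}

# ---- motif planting ---------------------------------------------------

#' Plant PWM sites into promoters at module-specific rates
#'
#' Each promoter receives one planted site with probability `rate_module`
#' (module genes) or `rate_background` (all other genes), at a uniform
#' random offset. Sites are sampled from the PWM's per-position base
#' probabilities (or its consensus).
#'
#' @param promoters named character vector of promoter sequences.
#' @param pwm a `pwm` object (see [read_jaspar()]).
#' @param module_genes character vector of module gene ids.
#' @param rate_module,rate_background planting probabilities in [0, 1].
#' @param site `"sample"` (draw from PWM probabilities) or `"consensus"`.
#' @return list with `promoters` (modified vector) and `planted`
#'   (data.frame gene_id/offset/motif_id; skipped short promoters recorded
#'   with offset NA).
#' @export
plant_motifs <- function(promoters, pwm, module_genes,
                         rate_module, rate_background,
                         site = c("sample", "consensus")) {
  site <- match.arg(site)
  stopifnot(rate_module >= 0, rate_module <= 1,
            rate_background >= 0, rate_background <= 1)
  probs <- normalize_pwm(pwm)
  L <- nrow(probs)
  consensus <- DNA_BASES[apply(probs, 1L, which.max)]
  planted <- list()
  for (g in names(promoters)) {
    rate <- if (g %in% module_genes) rate_module else rate_background
    if (runif(1) >= rate) next
    n <- nchar(promoters[[g]])
    if (n < L) {
      planted[[length(planted) + 1L]] <- data.frame(
        gene_id = g, offset = NA_integer_, motif_id = pwm$motif_id)
      next
    }
    offset <- sample.int(n - L + 1L, 1L) - 1L
    s <- if (site == "consensus") consensus else
      vapply(seq_len(L), function(i) sample(DNA_BASES, 1L, prob = probs[i, ]),
             character(1))
    substr(promoters[[g]], offset + 1L, offset + L) <- paste0(s, collapse = "")
    planted[[length(planted) + 1L]] <- data.frame(
      gene_id = g, offset = offset, motif_id = pwm$motif_id)
  }
  list(promoters = promoters,
       planted = if (length(planted)) do.call(rbind, planted) else
         data.frame(gene_id = character(0), offset = integer(0),
                    motif_id = character(0)))
}

# ---- higher-level study simulators ------------------------------------

#' Simulate a PEPC-like family with diagnostic residues and diel phasing
#'
#' Builds a reference-anchored protein family alignment in which planted
#' C4-specific copies carry the functional serine at reference position 780
#' (plus M at 890, H at 519) and are day-phased, planted CAM-specific copies
#' carry S780 and are night/stress-induced, and decoys carry either the
#' non-photosynthetic alanine at 780 or an unphased expression profile.
#'
#' @param seed RNG seed.
#' @param n_c4,n_cam,n_decoy_a780,n_decoy_unphased family composition.
#' @param ref_length ungapped reference length (>= 890).
#' @param noise_cv replicate noise CV for the expression matrix.
#' @return list with `alignment` (named character vector), `reference_id`,
#'   `expr` (an `expr_matrix`), and `truth` (data.frame gene_id/class).
#' @export
simulate_ccm_family <- function(seed = 1L, n_c4 = 4L, n_cam = 2L,
                                n_decoy_a780 = 3L, n_decoy_unphased = 2L,
                                ref_length = 950L, noise_cv = 0.25) {
  stopifnot(ref_length >= 890L)
  set.seed(seed)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  ref <- sample(aas, ref_length, replace = TRUE)
  ref[519L] <- "D"; ref[780L] <- "A"; ref[890L] <- "R"
  classes <- c(rep("C4", n_c4), rep("CAM", n_cam),
               rep("decoy_a780", n_decoy_a780),
               rep("decoy_unphased", n_decoy_unphased))
  ids <- sprintf("PEPC_%02d_%s", seq_along(classes), classes)
  rows <- list()
  for (i in seq_along(classes)) {
    q <- ref
    mut <- runif(ref_length) < 0.08
    q[mut] <- sample(aas, sum(mut), replace = TRUE)
    q[519L] <- switch(classes[i], C4 = "H", CAM = "H", "D")
    q[780L] <- if (classes[i] == "decoy_a780") "A" else "S"
    q[890L] <- switch(classes[i], C4 = "M", CAM = "M", "R")
    rows[[ids[i]]] <- q
  }
  aln <- c(list(Zm_ref = ref), rows)
  # insert shared gap columns where the reference has a residue but some
  # queries gain an insertion elsewhere: add 3 all-query insertion columns
  ins_at <- sort(sample(ref_length - 1L, 3L))
  mat <- do.call(rbind, aln)
  out <- matrix("-", nrow(mat), ncol(mat) + length(ins_at))
  keep_cols <- setdiff(seq_len(ncol(out)), ins_at + seq_along(ins_at))
  out[, keep_cols] <- mat
  for (k in seq_along(ins_at)) {
    col <- ins_at[k] + k
    out[-1L, col] <- sample(aas, nrow(mat) - 1L, replace = TRUE)
  }
  alignment <- setNames(apply(out, 1L, paste0, collapse = ""), rownames(mat))

  diel <- data.frame(
    gene_id = ids,
    diel_class = ifelse(classes == "C4", "C4-like",
                        ifelse(classes == "CAM", "CAM-like", "none")),
    stringsAsFactors = FALSE)
  cfg <- simulation_config(seed = seed, expression_noise_cv = noise_cv)
  expr <- simulate_expression(diel, cfg)
  truth <- data.frame(
    gene_id = ids,
    class = ifelse(classes == "C4", "C4-specific",
                   ifelse(classes == "CAM", "CAM-specific", "other")),
    stringsAsFactors = FALSE)
  list(alignment = alignment, reference_id = "Zm_ref", expr = expr,
       truth = truth)
}

#' Simulate a promoter motif-enrichment study
#'
#' Random promoters for `n_genes` expressed genes, of which `n_module` form
#' a coexpression module (membership 0.9; the rest get memberships below the
#' usual 0.8 cut), with one PWM planted at `rate_module` in module promoters
#' and `rate_background` elsewhere.
#'
#' @param seed RNG seed.
#' @param n_genes total expressed genes (background size).
#' @param n_module module size.
#' @param promoter_length promoter length in bp.
#' @param rate_module,rate_background planting rates.
#' @param pwm optional `pwm` object; defaults to [demo_pwm()].
#' @return list with `promoters`, `modules` (gene_id/module/membership),
#'   `module_genes`, `pwm`, and `planted`.
#' @export
simulate_motif_study <- function(seed = 1L, n_genes = 5000L, n_module = 200L,
                                 promoter_length = 2000L,
                                 rate_module = 0.6, rate_background = 0.1,
                                 pwm = NULL) {
  set.seed(seed)
  if (is.null(pwm)) pwm <- demo_pwm()
  ids <- sprintf("gene%05d", seq_len(n_genes))
  big <- .random_dna(n_genes * promoter_length)
  promoters <- setNames(
    substring(big, (seq_len(n_genes) - 1L) * promoter_length + 1L,
              seq_len(n_genes) * promoter_length), ids)
  module_genes <- ids[seq_len(n_module)]
  modules <- data.frame(
    gene_id = ids,
    module = c(rep("green", n_module), rep("grey", n_genes - n_module)),
    membership = c(runif(n_module, 0.85, 0.99),
                   runif(n_genes - n_module, 0.2, 0.79)),
    stringsAsFactors = FALSE)
  pl <- plant_motifs(promoters, pwm, module_genes,
                     rate_module, rate_background)
  list(promoters = pl$promoters, modules = modules,
       module_genes = module_genes, pwm = pwm, planted = pl$planted)
}

#' A small fixed demonstration PWM (10-bp, strongly informative)
#'
#' @param motif_id,cluster_id identifiers to attach.
#' @return a `pwm` object.
#' @export
demo_pwm <- function(motif_id = "MA0001.1", cluster_id = "cluster_03") {
  consensus <- strsplit("TGACGTCAGT", "")[[1L]]
  m <- matrix(1, length(consensus), 4,
              dimnames = list(NULL, DNA_BASES))
  m[cbind(seq_along(consensus), match(consensus, DNA_BASES))] <- 17
  new_pwm(motif_id, cluster_id, m)
}
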