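# Classification of gene-family members as C4- or CAM-specific from
# (a) diel/stress expression phasing and (b) diagnostic residues at
# reference-numbered alignment positions (maize PEPC numbering: the
# functional serine at 780, the inhibitor-affinity residue at 890, and the
# malate-sensitivity position 519).

.group_means <- function(expr) {
  key <- paste(expr$samples$condition, expr$samples$time, sep = "_")
  groups <- split(seq_len(nrow(expr$samples)), key)
  out <- vapply(groups, function(cols) {
    rowMeans(expr$values[, cols, drop = FALSE])
  }, numeric(nrow(expr$values)))
  if (is.null(dim(out))) {
    out <- matrix(out, nrow = 1,
                  dimnames = list(rownames(expr$values), names(groups)))
  }
  out
}

#' Filter to expressed genes
#'
#' A gene is expressed when it has TPM above `tpm_min` in at least
#' `min_reps` replicates of at least one (condition, time) group.
#'
#' @param expr an `expr_matrix` object.
#' @param tpm_min TPM threshold (strict inequality; default 1).
#' @param min_reps minimum replicates above threshold (default 2).
#' @return character vector of expressed gene ids.
#' @export
filter_expressed <- function(expr, tpm_min = 1.0, min_reps = 2L) {
  key <- paste(expr$samples$condition, expr$samples$time, sep = "_")
  groups <- split(seq_len(nrow(expr$samples)), key)
  ok <- Reduce(`|`, lapply(groups, function(cols) {
    rowSums(expr$values[, cols, drop = FALSE] > tpm_min) >= min_reps
  }))
  rownames(expr$values)[ok]
}

#' Classify diel expression phasing (C4-like, CAM-like, none)
#'
#' C4-like: day-phased under control (CK day >= `day_fold` x CK night,
#' CK day >= `min_tpm`) and downregulated during the day under at least one
#' stress condition (stress day <= CK day / `stress_fold`). CAM-like:
#' night-induced under at least one stress condition (stress night >=
#' `cam_induction_fold` x CK night, >= `day_fold` x stress day, and >=
#' `min_tpm`). When both rules fire, CAM wins (stress-night induction is
#' the discriminating CAM signature). A pseudocount of 0.1 is added to
#' denominators.
#'
#' @param expr an `expr_matrix` with CK and at least one stress condition
#'   at both times.
#' @param day_fold,stress_fold,cam_induction_fold,min_tpm rule thresholds.
#' @return named list of `diel_class` objects: `gene_id`, `label`,
#'   `evidence` (fold changes used by each rule).
#' @export
phase_genes <- function(expr, day_fold = 4, stress_fold = 4,
                        cam_induction_fold = 10, min_tpm = 1) {
  means <- .group_means(expr)
  need <- c("CK_day", "CK_night")
  if (!all(need %in% colnames(means))) {
    stop("missing required sample group: ",
         setdiff(need, colnames(means))[1L])
  }
  stress_conds <- setdiff(unique(expr$samples$condition), "CK")
  if (!length(stress_conds)) stop("missing required sample group: stress")
  pc <- 0.1
  out <- vector("list", nrow(expr$values))
  names(out) <- rownames(expr$values)
  for (i in seq_len(nrow(expr$values))) {
    ck_day <- means[i, "CK_day"]
    ck_night <- means[i, "CK_night"]
    ev <- list(ck_day_vs_night = ck_day / (ck_night + pc))
    c4_base <- ck_day >= day_fold * (ck_night + pc) && ck_day >= min_tpm
    c4 <- FALSE
    cam <- FALSE
    for (sc in stress_conds) {
      sd_col <- paste0(sc, "_day")
      sn_col <- paste0(sc, "_night")
      if (!all(c(sd_col, sn_col) %in% colnames(means))) next
      s_day <- means[i, sd_col]
      s_night <- means[i, sn_col]
      ev[[paste0(sc, "_day_repression")]] <- ck_day / (s_day + pc)
      ev[[paste0(sc, "_night_induction")]] <- s_night / (ck_night + pc)
      if (c4_base && s_day <= ck_day / stress_fold) c4 <- TRUE
      if (s_night >= cam_induction_fold * (ck_night + pc) &&
          s_night >= day_fold * (s_day + pc) &&
          s_night >= min_tpm) cam <- TRUE
    }
    label <- if (cam) "CAM-like" else if (c4) "C4-like" else "none"
    out[[i]] <- list(gene_id = rownames(expr$values)[i], label = label,
                     evidence = ev)
  }
  out
}

#' Labels from a phase_genes result
#' @param phases list from [phase_genes()].
#' @return named character vector gene -> label.
#' @export
phase_labels <- function(phases) {
  vapply(phases, `[[`, "", "label")
}

#' Map reference residue numbering to alignment columns
#'
#' Walking the reference row of the family alignment, each non-gap residue
#' i (1-based in the ungapped reference) maps to its alignment column; gaps
#' in the reference produce no mapping.
#'
#' @param family_alignment named character vector of aligned sequences.
#' @param reference_id name of the reference row.
#' @return integer vector: alignment column for each reference position.
#' @export
map_reference_positions <- function(family_alignment, reference_id) {
  if (!reference_id %in% names(family_alignment)) {
    stop("reference '", reference_id, "' absent from alignment")
  }
  ref <- strsplit(family_alignment[[reference_id]], "")[[1L]]
  which(ref != "-")
}

#' Diagnostic residues at reference-numbered positions
#'
#' Records each family member's residue at the alignment columns mapped to
#' the requested reference positions, and calls members
#' `functional-C4/CAM-type` when the residue at position 780 is S,
#' `non-photosynthetic-type` when it is A, and `ambiguous` otherwise
#' (including gaps). Residues at 890 (R = tight inhibitor binding; M/G =
#' low affinity) and 519 are recorded as evidence only.
#'
#' @param family_alignment named character vector of aligned sequences.
#' @param reference_id name of the reference row.
#' @param positions reference positions to extract (default 519, 780, 890).
#' @return a `residue_diagnostics`: list with `reference_id`, `positions`,
#'   `residues` (matrix genes x positions), `calls` (named vector).
#' @export
diagnose_residues <- function(family_alignment, reference_id,
                              positions = c(519L, 780L, 890L)) {
  positions <- sort(as.integer(positions))
  colmap <- map_reference_positions(family_alignment, reference_id)
  if (any(positions > length(colmap))) {
    stop("requested position beyond reference length (",
         length(colmap), ")")
  }
  cols <- colmap[positions]
  queries <- setdiff(names(family_alignment), reference_id)
  residues <- t(vapply(queries, function(id) {
    s <- strsplit(family_alignment[[id]], "")[[1L]]
    s[cols]
  }, character(length(cols))))
  colnames(residues) <- as.character(positions)
  r780 <- if ("780" %in% colnames(residues)) residues[, "780"] else
    rep(NA_character_, length(queries))
  calls <- ifelse(r780 == "S", "functional-C4/CAM-type",
                  ifelse(r780 == "A", "non-photosynthetic-type", "ambiguous"))
  names(calls) <- queries
  structure(list(reference_id = reference_id, positions = positions,
                 residues = residues, calls = calls),
            class = "residue_diagnostics")
}

#' Combine residue diagnostics and diel phasing into final CCM classes
#'
#' C4-specific = functional-type residue call AND C4-like phasing;
#' CAM-specific = functional-type AND CAM-like; everything else `other`.
#'
#' @param diag a `residue_diagnostics` from [diagnose_residues()].
#' @param phases diel labels: a [phase_genes()] result or a named character
#'   vector of labels.
#' @return named character vector gene -> {C4-specific, CAM-specific, other}.
#' @export
classify_ccm <- function(diag, phases) {
  labels <- if (is.character(phases)) phases else phase_labels(phases)
  genes <- names(diag$calls)
  out <- vapply(genes, function(g) {
    functional <- identical(unname(diag$calls[g]), "functional-C4/CAM-type")
    ph <- if (g %in% names(labels)) labels[[g]] else "none"
    if (functional && ph == "C4-like") "C4-specific"
    else if (functional && ph == "CAM-like") "CAM-specific"
    else "other"
  }, character(1))
  setNames(out, genes)
}
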