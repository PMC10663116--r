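# Ks distributions over syntenic anchor pairs, Gaussian-mixture peak
# detection on log-Ks with BIC model selection, and molecular-clock dating
# of WGD events (T = Ks / 2r).

#' @importFrom mclust Mclust mclustBIC
NULL

#' Ks values of anchor pairs, with per-block medians attached
#'
#' Collects the Ks of every block anchor pair, drops saturated pairs and
#' values outside `(0, ks_cap]`, and stores each block's median anchor Ks
#' back on the block.
#'
#' @param blocks list of blocks from [chain_anchors()].
#' @param kaks named list (or environment) mapping `"gene_a|gene_b"` to
#'   `kaks_result` objects (see [ng86_pair()]); or a data.frame with
#'   `gene_a`, `gene_b`, `Ks`, `saturated` columns.
#' @param ks_cap upper Ks bound retained (limits saturation artifacts).
#' @return list with `ks` (numeric vector of retained anchor Ks) and
#'   `blocks` (input blocks with `median_ks` filled in).
#' @export
anchor_ks_distribution <- function(blocks, kaks, ks_cap = 3.0) {
  lookup <- function(a, b) {
    if (is.data.frame(kaks)) {
      i <- match(paste(a, b), paste(kaks$gene_a, kaks$gene_b))
      j <- match(paste(b, a), paste(kaks$gene_a, kaks$gene_b))
      i[is.na(i)] <- j[is.na(i)]
      ks <- kaks$Ks[i]
      ks[which(kaks$saturated[i])] <- NA_real_
      ks
    } else {
      vapply(seq_along(a), function(k) {
        r <- kaks[[paste0(a[k], "|", b[k])]]
        if (is.null(r)) r <- kaks[[paste0(b[k], "|", a[k])]]
        if (is.null(r) || isTRUE(r$saturated)) NA_real_ else r$Ks
      }, 0)
    }
  }
  all_ks <- numeric(0)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    ks <- lookup(b$anchors$gene_a, b$anchors$gene_b)
    keep <- !is.na(ks) & ks > 0 & ks <= ks_cap
    blocks[[i]]$median_ks <- if (any(keep)) median(ks[keep]) else NA_real_
    all_ks <- c(all_ks, ks[keep])
  }
  list(ks = all_ks, blocks = blocks)
}

#' Fit a Gaussian mixture to log-Ks and pick the number of peaks by BIC
#'
#' Ks distributions are right-skewed, so the mixture is fitted on log(Ks);
#' models with 1..`max_components` components (unequal variances) are fitted
#' by EM and the BIC-optimal one selected. Component means are reported
#' back-transformed to the Ks scale, sorted ascending.
#'
#' Because a single skewed Ks peak often needs more than one Gaussian, the
#' BIC-selected mixture is post-processed into peaks: components with
#' weight below `min_peak_weight` are dropped as noise, and components
#' whose log-means lie within `merge_log_tol` of each other (closer than a
#' ~1.6-fold Ks ratio by default, below what Ks peak analysis can resolve)
#' are merged into one peak at their weight-averaged log-mean. The raw
#' mixture is kept in the `mixture` field.
#'
#' @param ks_values numeric vector of Ks values (> 0); at least 50 required.
#' @param max_components largest mixture size tried.
#' @param seed RNG seed (the fit itself uses deterministic hierarchical
#'   initialisation; the seed guards any subsampling).
#' @param sd_floor lower bound applied to component standard deviations.
#' @param min_peak_weight smallest mixture weight accepted as a peak.
#' @param merge_log_tol log-Ks distance under which components merge.
#' @return a `ks_peak_model`: list with `n_components` (number of peaks),
#'   `means` (Ks scale), `sds` (log scale), `weights`, `bic`,
#'   `ks_range_used`, and `mixture` (the unmerged BIC-selected fit).
#' @export
fit_ks_peaks <- function(ks_values, max_components = 4L, seed = 1L,
                         sd_floor = 1e-3, min_peak_weight = 0.05,
                         merge_log_tol = 0.5) {
  ks_values <- ks_values[is.finite(ks_values) & ks_values > 0]
  if (length(ks_values) < 50L) {
    stop("need at least 50 Ks values to fit peaks; ",
         "consider a KDE-mode fallback for smaller samples")
  }
  x <- log(ks_values)
  set.seed(seed)
  if (stats::sd(x) < sd_floor) {
    # degenerate: effectively a point mass
    model <- list(n_components = 1L, means = exp(mean(x)),
                  sds = sd_floor, weights = 1, bic = NA_real_,
                  ks_range_used = range(ks_values))
    class(model) <- "ks_peak_model"
    return(model)
  }
  fit <- Mclust(x, G = seq_len(max_components), modelNames = "V",
                verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  mu <- as.numeric(fit$parameters$mean)
  sds <- pmax(sqrt(as.numeric(fit$parameters$variance$sigmasq)), sd_floor)
  if (length(sds) == 1L) sds <- rep(sds, fit$G)
  w <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  mu <- mu[ord]; sds <- sds[ord]; w <- w[ord]
  mixture <- list(G = fit$G, means = exp(mu), sds = sds, weights = w)
  # peak post-processing: drop trace components, merge unresolvable ones
  keep <- w >= min_peak_weight
  if (!any(keep)) keep <- w == max(w)
  mu <- mu[keep]; sds <- sds[keep]; w <- w[keep]
  i <- 1L
  while (i < length(mu)) {
    if (mu[i + 1L] - mu[i] < merge_log_tol) {
      tot <- w[i] + w[i + 1L]
      mu[i] <- (w[i] * mu[i] + w[i + 1L] * mu[i + 1L]) / tot
      sds[i] <- max(sds[i], sds[i + 1L])
      w[i] <- tot
      mu <- mu[-(i + 1L)]; sds <- sds[-(i + 1L)]; w <- w[-(i + 1L)]
    } else i <- i + 1L
  }
  model <- list(n_components = length(mu),
                means = exp(mu),
                sds = sds,
                weights = w / sum(w),
                bic = -as.numeric(max(fit$BIC, na.rm = TRUE)),
                ks_range_used = range(ks_values),
                mixture = mixture)
  class(model) <- "ks_peak_model"
  model
}

#' @export
print.ks_peak_model <- function(x, ...) {
  cat(sprintf("<ks_peak_model: %d component(s); modes %s>\n",
              x$n_components,
              paste(sprintf("%.3f (w=%.2f)", x$means, x$weights),
                    collapse = ", ")))
  invisible(x)
}

#' Molecular-clock parameters
#'
#' @param r synonymous substitution rate per site per year (> 0); the
#'   default is the Caryophyllales rate 7.54e-9.
#' @return a `clock_params` list.
#' @export
clock_params <- function(r = 7.54e-9) {
  if (!is.numeric(r) || r <= 0) stop("rate r must be positive")
  structure(list(r = r), class = "clock_params")
}

#' Date a WGD event from its Ks mode (T = Ks / 2r)
#'
#' @examples
#' date_wgd(1.0, clock_params(7.54e-9))     # ~66.3 Mya
#' date_wgd(0.113, clock_params(7.54e-9))   # ~7.5 Mya
#' @param ks_mode Ks peak position of the event (> 0).
#' @param clock a [clock_params()] object (or a bare positive rate).
#' @param label optional event label (e.g. "Po-alpha").
#' @return a `wgd_event`: list with `ks_mode`, `age_mya`, `rate_used`,
#'   `label`.
#' @export
date_wgd <- function(ks_mode, clock = clock_params(), label = "") {
  if (is.numeric(clock)) clock <- clock_params(clock)
  if (!is.numeric(ks_mode) || any(ks_mode <= 0)) {
    stop("ks_mode must be positive")
  }
  structure(list(ks_mode = ks_mode,
                 age_mya = ks_mode / (2 * clock$r) / 1e6,
                 rate_used = clock, label = label),
            class = "wgd_event")
}

#' @export
print.wgd_event <- function(x, ...) {
  cat(sprintf("<wgd_event%s: Ks mode %.4f -> %.2f Mya at r=%.3g>\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$ks_mode, x$age_mya, x$rate_used$r))
  invisible(x)
}

#' Estimate the synonymous substitution rate from a calibrated ortholog peak
#'
#' Given the Ks peak of ortholog pairs against a species with known
#' divergence time T (million years), returns r = Ks / (2 T); exact inverse
#' of [date_wgd()].
#'
#' @examples
#' estimate_rate(0.28, 18.57)  # recovers r close to 7.54e-9
#' @param ortholog_ks_peak ortholog Ks peak (> 0).
#' @param calibration_age_mya divergence time in My (> 0).
#' @return a [clock_params()] object.
#' @export
estimate_rate <- function(ortholog_ks_peak, calibration_age_mya) {
  if (ortholog_ks_peak <= 0 || calibration_age_mya <= 0) {
    stop("inputs must be positive")
  }
  clock_params(ortholog_ks_peak / (2 * calibration_age_mya * 1e6))
}
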