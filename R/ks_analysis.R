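## Ks-distribution analysis: block/pair Ks filtering, mixture peak
## detection, LTR insertion-age dating and strict-clock event dating.

#' Filter syntenic gene pairs by block-median and pair Ks
#'
#' Retains pairs that belong to blocks whose median anchor Ks lies in
#' `[median_low, median_high]` and whose own Ks does not exceed
#' `pair_max`. Saturated pairs are always excluded and do not enter the
#' block median.
#'
#' @param blocks blocks from [chain_collinear_blocks()]
#' @param pairs_ks data.frame from [ka_ks_pairs()] covering the block
#'   anchors (`gene_a`, `gene_b`, `Ks`, `saturated`)
#' @param median_low,median_high block median Ks window (defaults 0.2, 1.0)
#' @param pair_max per-pair Ks ceiling (default 1.26)
#' @return data.frame of retained pairs with `block_id` and `Ks`
#' @export
block_median_ks_filter <- function(blocks, pairs_ks, median_low = 0.2,
                                   median_high = 1.0, pair_max = 1.26) {
  key <- paste(pairs_ks$gene_a, pairs_ks$gene_b, sep = "\r")
  key2 <- paste(pairs_ks$gene_b, pairs_ks$gene_a, sep = "\r")
  kept <- list()
  for (bi in seq_along(blocks)) {
    bl <- blocks[[bi]]
    bkey <- paste(bl$anchors$gene_a, bl$anchors$gene_b, sep = "\r")
    idx <- match(bkey, key)
    miss <- is.na(idx)
    idx[miss] <- match(bkey[miss], key2)
    if (any(is.na(idx))) {
      stop("block anchor without a Ks record: ",
           bkey[which(is.na(idx))[1]], call. = FALSE)
    }
    ks <- pairs_ks$Ks[idx]
    sat <- pairs_ks$saturated[idx]
    med <- median(ks[!sat])
    if (is.na(med) || med < median_low || med > median_high) next
    ok <- !sat & ks <= pair_max
    if (!any(ok)) next
    kept[[length(kept) + 1L]] <- data.frame(
      block_id = bi, gene_a = bl$anchors$gene_a[ok],
      gene_b = bl$anchors$gene_b[ok], Ks = ks[ok],
      stringsAsFactors = FALSE)
  }
  out <- if (length(kept)) do.call(rbind, kept) else
    data.frame(block_id = integer(0), gene_a = character(0),
               gene_b = character(0), Ks = numeric(0))
  rownames(out) <- NULL
  pk_log("block_median_ks_filter", n_blocks_in = length(blocks),
         n_pairs_kept = nrow(out), median_window = paste(median_low,
                                                         median_high,
                                                         sep = "-"),
         pair_max = pair_max)
  out
}

#' Detect Ks peaks by Gaussian mixture on log-Ks
#'
#' Fits Gaussian mixtures to `log(Ks)` for 1..`max_components` components,
#' selects the component count by BIC (ties resolved toward fewer
#' components), and reports each peak's mode (back-transformed), mixture
#' weight and log-scale sd.
#'
#' @param ks_values finite positive Ks values (>= 50 required)
#' @param max_components component cap (default 4)
#' @return data.frame of class `ks_peaks`, sorted by mode: `mode`,
#'   `weight`, `sd_log`
#' @export
detect_ks_peaks <- function(ks_values, max_components = 4L) {
  ks <- ks_values[is.finite(ks_values) & ks_values > 0]
  if (length(ks) < 50L) stop("need >= 50 finite positive Ks values",
                             call. = FALSE)
  x <- log(ks)
  if (sd(x) < 1e-10) {
    out <- data.frame(mode = exp(x[1]), weight = 1, sd_log = 0)
    class(out) <- c("ks_peaks", class(out))
    return(out)
  }
  fit <- Mclust(x, G = seq_len(max_components), modelNames = "V",
                verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed", call. = FALSE)
  p <- fit$parameters
  out <- data.frame(mode = exp(as.numeric(p$mean)),
                    weight = as.numeric(p$pro),
                    sd_log = sqrt(as.numeric(p$variance$sigmasq)))
  out <- out[order(out$mode), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ks_peaks", class(out))
  out
}

#' Filter candidate LTR retrotransposons to intact elements
#'
#' An intact element must carry two LTRs of 100-3000 bp with over 80%
#' similarity, sit 1-15 kb away from the nearest other candidate, and
#' possess a complete Gag-Pol sequence (all thresholds configurable).
#'
#' @param candidates data.frame with columns `element_id`, `ltr5_len`,
#'   `ltr3_len`, `spacing_to_next`, `ltr_similarity`, `has_gag_pol`,
#'   `ltr_divergence_K`, `family`
#' @param min_ltr,max_ltr LTR length window in bp (defaults 100, 3000)
#' @param min_similarity LTR-LTR percent similarity floor, exclusive
#'   (default 80)
#' @param min_spacing,max_spacing distance window to the next candidate in
#'   bp (defaults 1000, 15000)
#' @param require_gag_pol require a complete Gag-Pol (default TRUE)
#' @return the retained candidates
#' @export
filter_intact_ltr <- function(candidates, min_ltr = 100, max_ltr = 3000,
                              min_similarity = 80, min_spacing = 1000,
                              max_spacing = 15000, require_gag_pol = TRUE) {
  keep <- candidates$ltr5_len >= min_ltr & candidates$ltr5_len <= max_ltr &
    candidates$ltr3_len >= min_ltr & candidates$ltr3_len <= max_ltr &
    candidates$ltr_similarity > min_similarity &
    candidates$spacing_to_next >= min_spacing &
    candidates$spacing_to_next <= max_spacing
  if (require_gag_pol) keep <- keep & candidates$has_gag_pol
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  pk_log("filter_intact_ltr", n_in = nrow(candidates), n_kept = nrow(out))
  out
}

#' LTR insertion age from 5'-3' LTR divergence
#'
#' The two LTRs are identical at insertion and diverge independently, so
#' `age = K / (2 * rate)` years, with the default substitution rate
#' 1.3e-8 per site per year.
#'
#' @param K substitutions per site between the two LTRs (vectorised)
#' @param rate substitution rate per site per year (default 1.3e-8)
#' @return insertion age in years
#' @export
ltr_insertion_age <- function(K, rate = 1.3e-8) {
  if (any(K < 0)) stop("K must be >= 0", call. = FALSE)
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  K / (2 * rate)
}

#' Strict-clock calibration from a speciation of known age
#'
#' @param ks_orth_peak ortholog Ks peak at the calibration speciation
#' @param t_calibration calibration age in Mya
#' @return list of class `clock_calibration`: `ks_orth_peak`,
#'   `t_calibration`, `rate_2r` (Ks per Mya along both branches combined)
#' @export
clock_calibration <- function(ks_orth_peak, t_calibration) {
  if (ks_orth_peak <= 0 || t_calibration <= 0) {
    stop("calibration values must be positive", call. = FALSE)
  }
  out <- list(ks_orth_peak = ks_orth_peak, t_calibration = t_calibration,
              rate_2r = ks_orth_peak / t_calibration)
  class(out) <- "clock_calibration"
  out
}

#' Date a polyploidy event from its Ks peak under a strict clock
#'
#' `age = mode / rate_2r`, with uncertainty from a bootstrap over the Ks
#' values feeding the peak (the peak is re-detected per replicate).
#'
#' @param wgt_peak_mode Ks mode of the duplication peak, or a `ks_peaks`
#'   row
#' @param calibration a [clock_calibration()]
#' @param ks_values optional Ks sample behind the peak, enabling the
#'   bootstrap interval
#' @param n_boot bootstrap replicates (default 200)
#' @param seed RNG seed for the bootstrap
#' @return list of class `wgt_age`: `age_mya`, and with `ks_values` given,
#'   `ci_mya` (2.5/97.5 percentiles) and `boot_ages`
#' @export
estimate_wgt_age <- function(wgt_peak_mode, calibration, ks_values = NULL,
                             n_boot = 200L, seed = 1L) {
  stopifnot(inherits(calibration, "clock_calibration"))
  if (is.data.frame(wgt_peak_mode)) wgt_peak_mode <- wgt_peak_mode$mode[1]
  if (calibration$rate_2r <= 0) stop("zero calibration rate", call. = FALSE)
  age <- wgt_peak_mode / calibration$rate_2r
  out <- list(age_mya = age)
  if (!is.null(ks_values) && n_boot > 0L) {
    ks <- ks_values[is.finite(ks_values) & ks_values > 0]
    boots <- with_seed(child_seed(seed, 707L), {
      vapply(seq_len(n_boot), function(r) {
        res <- sample(ks, length(ks), replace = TRUE)
        pk <- detect_ks_peaks(res, max_components = 1L)
        pk$mode[1] / calibration$rate_2r
      }, numeric(1))
    })
    out$boot_ages <- boots
    out$ci_mya <- quantile(boots, c(0.025, 0.975), names = FALSE)
  }
  class(out) <- "wgt_age"
  out
}
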