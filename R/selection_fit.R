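## Copy-number-stratified selection inference: gamma-DFE likelihood on the
## folded zero-fold SFS, adaptive divergence (alpha, omega_a), fixation
## index, log-ratio constraint/selection effects, gene bootstrap and
## pairwise class contrasts.

NES_BIN_BREAKS <- c(0, 1, 10, 100, Inf)
NES_BIN_LABELS <- c("0<|Nes|<1", "1<|Nes|<10", "10<|Nes|<100", "|Nes|>100")

# ML theta for the neutral (four-fold) folded SFS: expected counts are
# theta * shape_i, so the ML estimate is total / sum(shape).
neutral_theta_ml <- function(pooled_sfs4, n_chrom) {
  shape <- fold_sfs_vector(1 / seq_len(n_chrom - 1L))
  sum(pooled_sfs4) / sum(shape)
}

dfe_loglik <- function(log_shape, log_mean, pooled_sfs0, n_chrom,
                       theta_ns = NULL) {
  shape <- exp(log_shape); mean_nes <- exp(log_mean)
  if (!is.finite(shape) || !is.finite(mean_nes) ||
      shape < 1e-3 || shape > 100 || mean_nes > 1e8) {
    return(list(ll = -1e12, theta = NA_real_))
  }
  m <- dfe_mixture_shape(shape, mean_nes, n_chrom)
  # theta_ns fixed from the neutral rate identifies the strongly
  # deleterious mass (which leaves no polymorphism); profiled only on
  # request
  theta <- if (is.null(theta_ns)) sum(pooled_sfs0) / sum(m) else theta_ns
  lambda <- theta * m
  ll <- sum(dpois(pooled_sfs0, lambda, log = TRUE))
  list(ll = ll, theta = theta)
}

#' Fit a gamma distribution of fitness effects to a folded SFS
#'
#' Maximises the Poisson likelihood of the pooled zero-fold folded SFS
#' under a gamma distribution of deleterious scaled selection coefficients
#' `|Nes|`, with the nonsynonymous mutation rate profiled out analytically
#' and the four-fold spectrum fixing the neutral rate. Population size is
#' constant (no demographic nuisance epoch). Optimisation is multi-start
#' Nelder-Mead on log parameters; ties resolve to the best log-likelihood,
#' then the smallest shape.
#'
#' The nonsynonymous mutation rate is tied to the neutral one through the
#' zero-fold/four-fold site totals (`theta_ns = theta_syn * L0/L4`), which
#' is what identifies the strongly deleterious mass: mutations that never
#' segregate are seen as the deficit of the zero-fold spectrum against the
#' mutational expectation. Setting `theta_free = TRUE` instead profiles
#' `theta_ns` out analytically (the classical ridge between the tail mass
#' and the rate then applies).
#'
#' @param input a `selection_input` (see [simulate_selection_data()]), or
#'   any list with `pooled_sfs0`, `pooled_sfs4`, `n_chrom` and a `genes`
#'   table carrying `L0`/`L4` site counts
#' @param n_starts number of optimisation starts
#' @param init optional `c(shape, mean_nes)` used as the first start
#' @param theta_free profile the nonsynonymous rate instead of tying it to
#'   the neutral rate (default FALSE)
#' @return a list of class `dfe_fit`: `shape`, `mean_nes`, `theta_ns`,
#'   `theta_syn`, `bin_props` (gamma mass in the |Nes| bins (0,1), (1,10),
#'   (10,100), (100,Inf)), `loglik`, `convergence`
#' @export
fit_gamma_dfe <- function(input, n_starts = 5L, init = NULL,
                          theta_free = FALSE) {
  pooled_sfs0 <- input$pooled_sfs0
  pooled_sfs4 <- input$pooled_sfs4
  n_chrom <- input$n_chrom
  if (length(pooled_sfs0) < 2L) stop("need >= 2 folded classes",
                                     call. = FALSE)
  if (sum(pooled_sfs4) == 0) stop("empty synonymous SFS", call. = FALSE)
  theta_syn <- neutral_theta_ml(pooled_sfs4, n_chrom)
  theta_ns <- if (theta_free) NULL else {
    if (is.null(input$genes)) {
      stop("tying theta_ns to the neutral rate requires L0/L4 site ",
           "counts in input$genes; use theta_free = TRUE otherwise",
           call. = FALSE)
    }
    theta_syn * sum(input$genes$L0) / sum(input$genes$L4)
  }
  starts <- list(c(log(0.5), log(100)), c(log(0.2), log(2000)),
                 c(log(1), log(10)), c(log(0.4), log(1e4)),
                 c(log(2), log(1)))
  if (!is.null(init)) starts <- c(list(log(init)), starts)
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, function(p) {
        -dfe_loglik(p[1], p[2], pooled_sfs0, n_chrom, theta_ns)$ll
      }, method = "Nelder-Mead",
            control = list(maxit = 500L, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-8 ||
        (abs(fit$value - best$value) <= 1e-8 && fit$par[1] < best$par[1])) {
      best <- fit
    }
  }
  if (is.null(best)) stop("DFE optimisation failed from every start",
                          call. = FALSE)
  shape <- exp(best$par[1]); mean_nes <- exp(best$par[2])
  ll <- dfe_loglik(best$par[1], best$par[2], pooled_sfs0, n_chrom, theta_ns)
  bins <- diff(pgamma(NES_BIN_BREAKS, shape = shape,
                      scale = mean_nes / shape))
  names(bins) <- NES_BIN_LABELS
  out <- list(shape = shape, mean_nes = mean_nes, theta_ns = ll$theta,
              theta_syn = theta_syn, bin_props = bins, loglik = ll$ll,
              convergence = best$convergence)
  class(out) <- "dfe_fit"
  out
}

#' Adaptive divergence: alpha and omega_a
#'
#' The expected non-adaptive nonsynonymous divergence is
#' `Ds * (L0/L4) * Fbar`, where `Fbar` is the mean relative fixation rate
#' `E[S/(1 - e^{-S})]` under the fitted DFE. `alpha` is the excess of
#' observed `Dn` over that expectation, as a fraction of `Dn`;
#' `omega_a = alpha * (Dn/L0)/(Ds/L4)`. Uncertainty comes from a gene
#' bootstrap (DFE refitted per replicate).
#'
#' @param fit a `dfe_fit` for the same input
#' @param input a `selection_input`
#' @param n_boot bootstrap replicates (0 disables; default 200)
#' @param seed seed for the bootstrap resampling
#' @return a list of class `adaptive_estimate`: `alpha`, `omega_a`, `Dn`,
#'   `Ds`, `fbar`, and (if bootstrapped) `boot` with the replicate values
#'   and their 2.5/97.5 percentiles
#' @export
estimate_alpha_omega_a <- function(fit, input, n_boot = 200L, seed = 1L) {
  point <- alpha_point(fit, input)
  boot <- NULL
  if (n_boot > 0L) {
    stat <- function(inp) {
      f <- fit_gamma_dfe(inp, n_starts = 1L,
                         init = c(fit$shape, fit$mean_nes))
      a <- alpha_point(f, inp)
      c(alpha = a$alpha, omega_a = a$omega_a)
    }
    reps <- bootstrap_by_gene(input, stat, n_reps = n_boot, seed = seed)
    boot <- list(alpha = reps["alpha", ], omega_a = reps["omega_a", ],
                 ci_alpha = quantile(reps["alpha", ], c(0.025, 0.975),
                                     names = FALSE),
                 ci_omega_a = quantile(reps["omega_a", ], c(0.025, 0.975),
                                       names = FALSE))
  }
  out <- c(point, list(boot = boot))
  class(out) <- "adaptive_estimate"
  out
}

alpha_point <- function(fit, input) {
  g <- input$genes
  Dn <- sum(g$Dn); Ds <- sum(g$Ds)
  L0 <- sum(g$L0); L4 <- sum(g$L4)
  if (Ds <= 0 || Dn <= 0) stop("Dn and Ds must be positive", call. = FALSE)
  fbar <- dfe_mean_fixation_rate(fit$shape, fit$mean_nes)
  dn_na <- Ds * (L0 / L4) * fbar
  alpha <- (Dn - dn_na) / Dn
  omega_a <- alpha * (Dn / L0) / (Ds / L4)
  list(alpha = alpha, omega_a = omega_a, Dn = Dn, Ds = Ds, fbar = fbar)
}

#' Fixation index (McDonald-Kreitman ratio of ratios)
#'
#' `FI = (Dn/Ds) / (Pn/Ps)`. When any cell is zero, 0.5 is added to every
#' cell and the result is flagged `corrected`; when all four are zero the
#' index is undefined (`NA`, flagged).
#'
#' @param Dn,Ds,Pn,Ps divergence and polymorphism counts (vectorised)
#' @return data.frame with `FI`, `corrected`, `undefined`
#' @export
fixation_index <- function(Dn, Ds, Pn, Ps) {
  if (any(c(Dn, Ds, Pn, Ps) < 0)) stop("counts must be >= 0", call. = FALSE)
  k <- cbind(Dn, Ds, Pn, Ps)
  undefined <- rowSums(k) == 0
  corrected <- !undefined & apply(k == 0, 1L, any)
  k[corrected, ] <- k[corrected, , drop = FALSE] + 0.5
  fi <- (k[, 1] / k[, 2]) / (k[, 3] / k[, 4])
  fi[undefined] <- NA_real_
  data.frame(FI = fi, corrected = corrected, undefined = undefined)
}

#' Per-gene constraint and selection effects (log-ratio surrogates)
#'
#' Closed-form effect sizes in the spirit of MK-regression frameworks:
#' `constraint = log((Pn+0.5)/(Ps+0.5)) - log(L0/L4)` (negative under
#' purifying constraint) and
#' `selection = log((Dn+0.5)/(Ds+0.5)) - log((Pn+0.5)/(Ps+0.5))` (positive
#' under excess nonsynonymous fixation). The 0.5 correction is
#' unconditional.
#'
#' @param Dn,Ds,Pn,Ps counts (vectorised)
#' @param L0,L4 zero-fold and four-fold site totals
#' @return data.frame with `constraint_effect`, `selection_effect`
#' @export
snipre_like_effects <- function(Dn, Ds, Pn, Ps, L0, L4) {
  if (any(L0 <= 0) || any(L4 <= 0)) stop("L0 and L4 must be > 0",
                                         call. = FALSE)
  constraint <- log((Pn + 0.5) / (Ps + 0.5)) - log(L0 / L4)
  selection <- log((Dn + 0.5) / (Ds + 0.5)) - log((Pn + 0.5) / (Ps + 0.5))
  data.frame(constraint_effect = constraint, selection_effect = selection)
}

#' Gene bootstrap of a selection statistic
#'
#' Resamples genes with replacement, re-pools SFS and count data per
#' replicate, and applies `statistic` to the resampled `selection_input`.
#'
#' @param input a `selection_input`
#' @param statistic function of a `selection_input` returning a numeric
#'   vector (constant length)
#' @param n_reps bootstrap replicates (default 200)
#' @param seed RNG seed
#' @return matrix with one column per replicate
#' @export
bootstrap_by_gene <- function(input, statistic, n_reps = 200L, seed = 1L) {
  ng <- nrow(input$genes)
  if (ng < 2L) stop("need >= 2 genes to bootstrap", call. = FALSE)
  with_seed(child_seed(seed, 606L), {
    reps <- lapply(seq_len(n_reps), function(r) {
      idx <- sample.int(ng, ng, replace = TRUE)
      statistic(subset_selection_input(input, idx))
    })
    do.call(cbind, reps)
  })
}

#' Pairwise two-tailed t contrasts between retention classes
#'
#' Welch t tests for all pairs of classes, with the conventional star
#' annotation: `*` below 0.05, `***` below 0.001.
#'
#' @param samples named list of numeric vectors, one per copy class
#' @return data.frame with `class_a`, `class_b`, `t`, `p_value`, `stars`,
#'   `degenerate` (flagged when both samples have zero variance)
#' @export
compare_retention_classes <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  if (is.null(names(samples))) names(samples) <- seq_along(samples)
  cmb <- combn(names(samples), 2L)
  rows <- lapply(seq_len(ncol(cmb)), function(j) {
    a <- samples[[cmb[1, j]]]; b <- samples[[cmb[2, j]]]
    degenerate <- sd(a) == 0 && sd(b) == 0
    if (degenerate && isTRUE(all.equal(mean(a), mean(b)))) {
      tt <- list(statistic = 0, p.value = 1)
    } else if (degenerate) {
      tt <- list(statistic = Inf, p.value = 0)
    } else {
      tt <- t.test(a, b)
    }
    p <- tt$p.value
    stars <- if (p < 0.001) "***" else if (p < 0.05) "*" else ""
    data.frame(class_a = cmb[1, j], class_b = cmb[2, j],
               t = unname(tt$statistic), p_value = p, stars = stars,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
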