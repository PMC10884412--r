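## Poisson-random-field expected site frequency spectra under selection,
## and their mixture over a gamma distribution of deleterious effects.
##
## Density of derived allele frequency q for scaled selection coefficient S
## (per unit theta): f(q; S) = (1 - exp(-S(1-q))) / ((1 - exp(-S)) q(1-q)),
## with the neutral limit 1/q at S = 0. Expected sample-SFS entries are the
## binomial mixtures of f over q; folding sums complementary classes.

quad_env <- new.env(parent = emptyenv())

gl_nodes <- function(n, a = 0, b = 1) {
  key <- sprintf("gl%d", n)
  if (is.null(quad_env[[key]])) {
    quad_env[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  g <- quad_env[[key]]
  list(x = a + (b - a) * g$x, w = (b - a) * g$w)
}

# robust (1 - e^{-S(1-q)}) / (1 - e^{-S})
sfs_ratio <- function(q, S) {
  if (abs(S) < 1e-8) return(1 - q)
  if (S < 0) {
    b <- -S
    exp(-b * q) * (-expm1(-b * (1 - q))) / (-expm1(-b))
  } else {
    expm1(-S * (1 - q)) / expm1(-S)
  }
}

# Expected unfolded sample SFS per unit theta: vector over i = 1..n-1.
sfs_shape_unfolded <- function(S, n) {
  b <- abs(S)
  pieces <- if (b <= 30) {
    list(gl_nodes(128L))
  } else if (S < 0) {
    qc <- min(1, 40 / b)
    if (qc < 1) list(gl_nodes(96L, 0, qc), gl_nodes(32L, qc, 1)) else
      list(gl_nodes(128L))
  } else {
    qc <- max(0, 1 - 40 / b)
    if (qc > 0) list(gl_nodes(32L, 0, qc), gl_nodes(96L, qc, 1)) else
      list(gl_nodes(128L))
  }
  i <- seq_len(n - 1L)
  out <- numeric(n - 1L)
  for (p in pieces) {
    q <- p$x
    r <- sfs_ratio(q, S) * p$w
    # B[j, i] = C(n,i) q_j^{i-1} (1-q_j)^{n-i-1}
    B <- exp(outer(log(q), i - 1) + outer(log1p(-q), n - i - 1) +
               rep(lchoose(n, i), each = length(q)))
    out <- out + as.vector(crossprod(B, r))
  }
  out
}

fold_sfs_vector <- function(u) {
  n <- length(u) + 1L
  half <- n %/% 2L
  i <- seq_len(half)
  f <- u[i]
  add <- n - i
  sel <- add != i
  f[sel] <- f[sel] + u[add[sel]]
  f
}

#' Expected folded site frequency spectrum under selection
#'
#' Expected counts per folded frequency class for segregating sites with a
#' common scaled selection coefficient `S = 4*Ne*s` (negative =
#' deleterious), under the Poisson random field model with constant
#' population size. At `S = 0` this reduces to the Watterson expectation
#' `theta/i` (folded).
#'
#' @param gamma_scaled_s scaled selection coefficient S (scalar)
#' @param theta population-scaled mutation rate for the whole sequence
#'   class (expected counts scale linearly in it)
#' @param n_chrom number of sampled chromosomes (>= 2)
#' @return numeric vector of expected counts for folded classes
#'   `1..floor(n_chrom/2)`
#' @examples
#' expected_folded_sfs(0, theta = 1, n_chrom = 4)  # proportions 8/11, 3/11
#' @export
expected_folded_sfs <- function(gamma_scaled_s, theta, n_chrom) {
  stopifnot(length(gamma_scaled_s) == 1L, is.finite(gamma_scaled_s))
  if (n_chrom < 2L) stop("n_chrom must be >= 2", call. = FALSE)
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  theta * fold_sfs_vector(sfs_shape_unfolded(gamma_scaled_s, n_chrom))
}

## ---- gamma-DFE mixture -----------------------------------------------
## The folded-shape vector as a function of |S| is tabulated once per
## n_chrom on a dense log grid and interpolated (log-log cubic splines);
## the gamma mixture is then an equal-probability quantile midpoint rule
## (1024 nodes), which handles the extreme dynamic range of |Nes| that
## defeats fixed polynomial quadratures.

dfe_env <- new.env(parent = emptyenv())

fold_shape_interp <- function(n_chrom) {
  key <- sprintf("n%d", n_chrom)
  if (!is.null(dfe_env[[key]])) return(dfe_env[[key]])
  lb <- seq(log(1e-6), log(1e9), length.out = 500L)
  vals <- vapply(exp(lb), function(b) {
    fold_sfs_vector(sfs_shape_unfolded(-b, n_chrom))
  }, numeric(n_chrom %/% 2L))
  logv <- log(pmax(vals, 1e-300))
  funs <- lapply(seq_len(nrow(logv)), function(i) {
    stats::splinefun(lb, logv[i, ], method = "natural")
  })
  neutral <- fold_sfs_vector(1 / seq_len(n_chrom - 1L))
  obj <- list(lb_min = lb[1], lb_max = lb[length(lb)], funs = funs,
              neutral = neutral,
              tail_val = exp(logv[, ncol(logv)]), tail_b = exp(lb[length(lb)]))
  dfe_env[[key]] <- obj
  obj
}

# folded shape at deleterious strength b = |S| (vectorised over b)
fold_shape_at <- function(b, interp) {
  b <- pmax(b, 0)
  out <- matrix(0, length(interp$funs), length(b))
  small <- b < exp(interp$lb_min)
  big <- b > interp$tail_b
  mid <- !small & !big
  if (any(small)) out[, small] <- interp$neutral
  if (any(mid)) {
    lbm <- log(b[mid])
    for (i in seq_along(interp$funs)) out[i, mid] <- exp(interp$funs[[i]](lbm))
  }
  if (any(big)) {
    # leading-order 1/b decay beyond the tabulated range
    out[, big] <- outer(interp$tail_val, interp$tail_b / b[big])
  }
  out
}

DFE_QUAD_NODES <- 1024L

# Expected folded nonsynonymous shape per unit theta under a gamma DFE of
# deleterious |Nes| with given shape and mean.
dfe_mixture_shape <- function(shape, mean_nes, n_chrom) {
  interp <- fold_shape_interp(n_chrom)
  if (mean_nes <= 0) return(interp$neutral)
  u <- (seq_len(DFE_QUAD_NODES) - 0.5) / DFE_QUAD_NODES
  b <- qgamma(u, shape = shape, scale = mean_nes / shape)
  rowMeans(fold_shape_at(b, interp))
}

# mean relative fixation rate E[ S / (1 - e^{-S}) ] over the gamma DFE
# (S = -|Nes|); equals 1 for a point mass at S = 0.
dfe_mean_fixation_rate <- function(shape, mean_nes) {
  if (mean_nes <= 0) return(1)
  u <- (seq_len(DFE_QUAD_NODES) - 0.5) / DFE_QUAD_NODES
  b <- qgamma(u, shape = shape, scale = mean_nes / shape)
  mean(ifelse(b < 1e-8, 1, b / expm1(pmin(b, 700))))
}
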