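#' Per-sample centering of log quantities
#'
#' Subtracts from each sample (column) its mean over genes, so every
#' sample's centered values sum to zero across genes. Centering removes
#' sample loading (per-sample additive shifts on the log scale) — the model
#' step that makes the downstream variance decomposition loading-invariant.
#'
#' @param y gene x sample matrix of log2 expression values (for Ct input
#'   with efficiency 2, `y = -Ct` up to per-gene constants, which are
#'   immaterial downstream).
#' @return Matrix `z = y - colMeans(y)` with zero column means.
#' @export
sample_center <- function(y) {
  if (!is.matrix(y)) stop("y must be a gene x sample matrix")
  sweep(y, 2L, colMeans(y))
}

#' Intra-group variance estimates
#'
#' Unbiased per-gene, per-group variance estimates for sample-centered data.
#' Centering a sample over k genes deflates each gene's apparent variance
#' and leaks a share of every other gene's variance into it; with
#' `s2(i,g)` the sample variance of `z(i,g,.)` and `s2bar(g)` its mean over
#' genes, the estimator
#' `sigma2(i,g) = max(0, (k/(k-2)) * (s2(i,g) - s2bar(g)/(k-1)))`
#' undoes both effects (for equal true variances, `E[s2] = sigma2 (k-1)/k`
#' and the estimator's expectation is exactly `sigma2`). Negative estimates
#' are clamped to zero; the clamped fraction is recorded.
#'
#' @param z centered matrix from [sample_center()].
#' @param grouping group label per sample (column).
#' @return List: `sigma2` (gene x group matrix), `s2` (raw per-group sample
#'   variances), `n_g` (samples per group), `clamped_fraction`.
#' @export
intragroup_variance <- function(z, grouping) {
  k <- nrow(z)
  if (k < 3L) stop("variance estimator needs at least 3 genes")
  grouping <- as.character(grouping)
  if (length(grouping) != ncol(z)) stop("one group label per sample required")
  groups <- unique(grouping)
  n_g <- vapply(groups, function(g) sum(grouping == g), integer(1L))
  if (any(n_g < 2L)) {
    stop("every group needs at least 2 samples (",
         groups[n_g < 2L][1L], " has ", min(n_g), ")")
  }
  s2 <- sapply(groups, function(g) {
    apply(z[, grouping == g, drop = FALSE], 1L, stats::var)
  })
  s2 <- matrix(s2, nrow = k, dimnames = list(rownames(z), groups))
  s2bar <- colMeans(s2)
  raw <- (k / (k - 2)) * sweep(s2, 2L, s2bar / (k - 1))
  clamped <- raw < 0
  raw[clamped] <- 0
  list(sigma2 = raw, s2 = s2, n_g = stats::setNames(n_g, groups),
       clamped_fraction = mean(clamped))
}

#' Inter-group deviations with empirical-Bayes shrinkage
#'
#' Group deviations `d(i,g)` are each gene's group mean of centered values
#' minus the unweighted mean of its group means (so they sum to zero over
#' groups per gene). The shared inter-group dispersion
#' `gamma2 = max(0, var(d) - mean(sigma2/n_g))` estimates how much of the
#' spread in `d` exceeds sampling noise; each deviation is shrunk toward
#' zero by `d_shrunk = d * gamma2 / (gamma2 + sigma2(i,g)/n_g)`. With a
#' single group all deviations are zero by definition. As group sizes grow
#' with fixed nonzero deviations, the shrinkage factor tends to 1 and
#' `d_shrunk -> d`.
#'
#' @param z centered matrix from [sample_center()].
#' @param grouping group label per sample.
#' @param sigma2 gene x group matrix from [intragroup_variance()].
#' @param n_g named samples-per-group vector.
#' @return List: `d`, `d_shrunk` (gene x group matrices), `gamma2`.
#' @export
intergroup_shrinkage <- function(z, grouping, sigma2, n_g) {
  grouping <- as.character(grouping)
  groups <- colnames(sigma2)
  gm <- sapply(groups, function(g) {
    rowMeans(z[, grouping == g, drop = FALSE])
  })
  gm <- matrix(gm, nrow = nrow(z), dimnames = list(rownames(z), groups))
  if (length(groups) < 2L) {
    d <- gm * 0
    return(list(d = d, d_shrunk = d, gamma2 = 0))
  }
  d <- gm - rowMeans(gm)
  noise <- sweep(sigma2, 2L, as.numeric(n_g[groups]), `/`)
  gamma2 <- max(0, stats::var(as.vector(d)) - mean(noise))
  shrink <- if (gamma2 == 0) d * 0 else d * gamma2 / (gamma2 + noise)
  list(d = d, d_shrunk = shrink, gamma2 = gamma2)
}

#' NormFinder-style stability values
#'
#' Model-based stability estimation decomposing each gene's expression
#' variation into intra-group variance and shrunken inter-group deviation:
#' `rho(i) = mean over groups of [ |d_shrunk(i,g)| + sqrt(sigma2(i,g)/n_g) ]`.
#' With a single group, `rho(i) = sqrt(sigma2(i))`. Smaller rho = more
#' stable. Stability is invariant to per-sample loading shifts and per-gene
#' abundance constants (both removed by centering/deviation construction).
#'
#' @param table a [ct_table()] (Ct converted to log2 expression via `-Ct`),
#'   or a gene x sample matrix of positive relative quantities.
#' @param grouping optional group label per sample; defaults to the table's
#'   group annotation (a single shared label gives the ungrouped analysis).
#' @return List of class `normfinder_result`: `method`, `stability` (named
#'   per-gene rho), `rank` (competition ranks), `diagnostics` data.frame
#'   (`gene, group, sigma2, d, d_shrunk`), `gamma2`, `clamped_fraction`,
#'   `n_g`, `k`.
#' @export
normfinder_stability <- function(table, grouping = NULL) {
  if (inherits(table, "ct_table")) {
    y <- -ct_matrix(table, require_complete = TRUE)
    if (is.null(grouping)) grouping <- unname(sample_groups(table))
  } else {
    check_quantities(table)
    y <- log2(table)
    if (is.null(grouping)) grouping <- rep("all", ncol(y))
  }
  if (nrow(y) < 3L) stop("NormFinder needs at least 3 genes")
  grouping <- as.character(grouping)
  z <- sample_center(y)
  iv <- intragroup_variance(z, grouping)
  sh <- intergroup_shrinkage(z, grouping, iv$sigma2, iv$n_g)
  groups <- colnames(iv$sigma2)
  if (length(groups) < 2L) {
    rho <- sqrt(iv$sigma2[, 1L])
  } else {
    noise_sd <- sqrt(sweep(iv$sigma2, 2L, as.numeric(iv$n_g[groups]), `/`))
    rho <- rowMeans(abs(sh$d_shrunk) + noise_sd)
  }
  diagnostics <- data.frame(
    gene = rep(rownames(y), times = length(groups)),
    group = rep(groups, each = nrow(y)),
    sigma2 = as.vector(iv$sigma2),
    d = as.vector(sh$d),
    d_shrunk = as.vector(sh$d_shrunk),
    stringsAsFactors = FALSE)
  structure(list(method = "normfinder",
                 stability = stats::setNames(rho, rownames(y)),
                 rank = competition_rank(rho),
                 diagnostics = diagnostics, gamma2 = sh$gamma2,
                 clamped_fraction = iv$clamped_fraction,
                 n_g = iv$n_g, k = nrow(y)),
            class = c("normfinder_result", "stability_result"))
}
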