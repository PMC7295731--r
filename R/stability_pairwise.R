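#' Pairwise SD matrix of Ct differences
#'
#' For each gene pair (i, k), the sample standard deviation (n-1
#' denominator) over samples of the Ct difference `Ct_i - Ct_k`. This is
#' the building block of the comparative delta-Ct stability method: a pair of
#' jointly stable genes keeps a near-constant Ct difference across samples.
#'
#' @param table a [ct_table()] with >= 2 genes and >= 2 samples (complete
#'   matrix; technical replicates averaged first).
#' @return Symmetric gene x gene matrix with zero diagonal.
#' @export
pairwise_sd_matrix <- function(table) {
  m <- ct_matrix(table, require_complete = TRUE)
  if (nrow(m) < 2L) stop("need at least two genes")
  if (ncol(m) < 2L) stop("need at least two samples")
  k <- nrow(m)
  s <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      s[i, j] <- s[j, i] <- stats::sd(m[i, ] - m[j, ])
    }
  }
  s
}

#' Comparative delta-Ct stability
#'
#' Ranks candidate reference genes by the mean standard deviation of their
#' pairwise Ct differences: `stability_i = mean over k != i of S(i, k)` with
#' `S` from [pairwise_sd_matrix()]. Smaller is more stable. Operates on raw
#' Ct (base-2 scale, the `Q = 2^dCt` convention); no efficiency correction.
#' With efficiency 2 these values coincide exactly with first-iteration
#' geNorm M values (see [genorm_m()]).
#'
#' @inheritParams pairwise_sd_matrix
#' @return List of class `stability_result`: `method`, `stability` (named
#'   per-gene vector), `rank` (competition ranks, ascending), `sd_matrix`.
#' @export
delta_ct_stability <- function(table) {
  s <- pairwise_sd_matrix(table)
  stab <- rowSums(s) / (nrow(s) - 1L)
  structure(list(method = "delta_ct", stability = stab,
                 rank = competition_rank(stab), sd_matrix = s),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("reference-gene stability (", x$method, "):\n", sep = "")
  ord <- order(x$rank, names(x$stability))
  print(data.frame(gene = names(x$stability)[ord],
                   stability = round(x$stability[ord], 3),
                   rank = x$rank[ord], row.names = NULL))
  invisible(x)
}

#' BestKeeper descriptive stability
#'
#' Descriptive screen on raw Ct: per-gene dispersion about the mean Ct,
#' coefficient of variation, and Pearson correlation with the BestKeeper
#' index (the per-sample geometric mean of Ct across all candidate genes).
#' Genes are ranked by dispersion, ascending. The default dispersion is the
#' mean absolute deviation about the mean (the convention of the original
#' BestKeeper's "SD [+/- Ct]"); `dispersion = "sd"` switches to the sample
#' standard deviation. Unlike the ratio-based methods, BestKeeper dispersion
#' is not invariant to per-sample loading shifts — a documented limitation.
#'
#' @param table a [ct_table()] (complete matrix).
#' @param dispersion `"mad"` (mean absolute deviation, default) or `"sd"`.
#' @return List of class `bestkeeper_result`: `summary` data.frame
#'   (`gene, mean_ct, dispersion, cv_percent, r_index, rank`), `index`
#'   (per-sample geometric mean Ct), `dispersion_type`.
#' @export
bestkeeper <- function(table, dispersion = c("mad", "sd")) {
  dispersion <- match.arg(dispersion)
  m <- ct_matrix(table, require_complete = TRUE)
  if (nrow(m) < 2L) stop("need at least two genes")
  if (ncol(m) < 2L) stop("need at least two samples")
  mean_ct <- rowMeans(m)
  disp <- if (dispersion == "mad") {
    rowMeans(abs(m - mean_ct))
  } else {
    apply(m, 1L, stats::sd)
  }
  index <- exp(colMeans(log(m)))
  r_index <- apply(m, 1L, function(v) {
    if (stats::sd(v) == 0 || stats::sd(index) == 0) NA_real_
    else stats::cor(v, index)
  })
  cv <- 100 * disp / mean_ct
  structure(list(
    summary = data.frame(gene = rownames(m), mean_ct = mean_ct,
                         dispersion = disp, cv_percent = cv,
                         r_index = r_index, rank = competition_rank(disp),
                         row.names = NULL, stringsAsFactors = FALSE),
    index = index, dispersion_type = dispersion),
    class = "bestkeeper_result")
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat("BestKeeper descriptives (dispersion:", x$dispersion_type, "):\n")
  s <- x$summary
  s$mean_ct <- round(s$mean_ct, 2)
  s$dispersion <- round(s$dispersion, 3)
  s$cv_percent <- round(s$cv_percent, 2)
  s$r_index <- round(s$r_index, 3)
  print(s[order(s$rank), ], row.names = FALSE)
  invisible(x)
}
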