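#' geNorm expression-stability M values
#'
#' For each gene i, `M_i` is the mean over all other genes k of the sample
#' standard deviation (n-1 denominator) of the log2 expression ratio
#' `A(i,k) = log2(x_i / x_k)` across samples. Lower M = more stable. A gene
#' whose ratio to every other candidate is constant across samples has
#' M = 0. With all efficiencies equal to 2, M reduces to the comparative
#' delta-Ct stability value (log2 ratios become Ct differences).
#'
#' @param quantities gene x sample matrix of positive relative quantities
#'   (see [relative_quantities()]); >= 2 genes, >= 2 samples.
#' @return Named per-gene vector of M values.
#' @export
genorm_m <- function(quantities) {
  check_quantities(quantities)
  a <- log2(quantities)
  k <- nrow(a)
  m <- vapply(seq_len(k), function(i) {
    mean(vapply(setdiff(seq_len(k), i), function(j) {
      stats::sd(a[i, ] - a[j, ])
    }, numeric(1L)))
  }, numeric(1L))
  stats::setNames(m, rownames(quantities))
}

check_quantities <- function(quantities) {
  if (!is.matrix(quantities)) stop("quantities must be a gene x sample matrix")
  if (nrow(quantities) < 2L) stop("need at least two genes")
  if (ncol(quantities) < 2L) stop("need at least two samples")
  if (anyNA(quantities) || any(quantities <= 0)) {
    stop("quantities must be positive and complete")
  }
  invisible(quantities)
}

#' geNorm stepwise exclusion
#'
#' Repeatedly computes M on the remaining genes and removes the single gene
#' with the highest M until two remain; those two are the tied most-stable
#' pair. The ranking is the reverse exclusion order with the final pair
#' sharing rank 1 under competition ranking (1, 1, 3, 4, ...). A tie at the
#' maximal M is broken by input gene order (the first listed is removed),
#' with a warning.
#'
#' @param quantities gene x sample matrix of positive relative quantities;
#'   >= 3 genes.
#' @return List of class `genorm_stepwise`: `m_trajectory` (data.frame
#'   `iteration, gene, m`), `exclusion_order` (k-2 genes, first removed
#'   first), `final_pair`, `ranking` (named competition ranks), `order`
#'   (gene names, most stable first; final pair in input order), `m`
#'   (initial full-panel M values).
#' @export
genorm_stepwise <- function(quantities) {
  check_quantities(quantities)
  if (nrow(quantities) < 3L) stop("stepwise exclusion needs at least 3 genes")
  genes <- rownames(quantities)
  remaining <- genes
  excluded <- character(0L)
  trajectory <- list()
  m_initial <- NULL
  it <- 0L
  while (length(remaining) > 2L) {
    it <- it + 1L
    m <- genorm_m(quantities[remaining, , drop = FALSE])
    if (is.null(m_initial)) m_initial <- m
    trajectory[[it]] <- data.frame(iteration = it, gene = remaining, m = m,
                                   row.names = NULL, stringsAsFactors = FALSE)
    worst <- which(m == max(m))
    if (length(worst) > 1L) {
      warning("tie at maximal M (",
              paste(remaining[worst], collapse = ", "),
              "); removing the first listed: ", remaining[worst[1L]])
    }
    excluded <- c(excluded, remaining[worst[1L]])
    remaining <- remaining[-worst[1L]]
  }
  it <- it + 1L
  m_final <- genorm_m(quantities[remaining, , drop = FALSE])
  trajectory[[it]] <- data.frame(iteration = it, gene = remaining,
                                 m = m_final, row.names = NULL,
                                 stringsAsFactors = FALSE)
  # ranking: final pair tied at 1, then 3, 4, ... in reverse exclusion order
  ranking <- stats::setNames(integer(length(genes)), genes)
  ranking[remaining] <- 1L
  if (length(excluded) > 0L) {
    ranking[rev(excluded)] <- 2L + seq_along(excluded)
  }
  structure(list(m_trajectory = do.call(rbind, trajectory),
                 exclusion_order = excluded, final_pair = remaining,
                 ranking = ranking,
                 order = c(remaining, rev(excluded)), m = m_initial),
            class = "genorm_stepwise")
}

#' Normalization factor over a gene subset
#'
#' The per-sample geometric mean of the subset genes' relative quantities —
#' geNorm's normalization factor NF_n.
#'
#' @param quantities gene x sample matrix of positive relative quantities.
#' @param genes subset of row names, size >= 2.
#' @return Named per-sample vector of normalization factors (all > 0).
#' @export
normalization_factor <- function(quantities, genes) {
  check_quantities(quantities)
  if (length(genes) < 2L) stop("normalization factor needs >= 2 genes")
  missing_g <- setdiff(genes, rownames(quantities))
  if (length(missing_g) > 0L) {
    stop("unknown gene(s): ", paste(missing_g, collapse = ", "))
  }
  exp(colMeans(log(quantities[genes, , drop = FALSE])))
}

#' geNorm pairwise-variation series
#'
#' `V(n, n+1)` is the standard deviation over samples of
#' `log2(NF_n / NF_{n+1})`, where `NF_n` is the normalization factor built
#' from the n best-ranked genes. A small V(n, n+1) means the (n+1)-th gene
#' adds nothing: n genes suffice.
#'
#' @param quantities gene x sample matrix of positive relative quantities,
#'   >= 3 genes.
#' @param ranking gene order, most stable first (e.g.
#'   [genorm_stepwise()]`$order`); defaults to running the stepwise
#'   exclusion.
#' @return Named numeric vector `V(n, n+1)` for n = 2..k-1; names are the n
#'   values.
#' @export
pairwise_variation_series <- function(quantities, ranking = NULL) {
  check_quantities(quantities)
  k <- nrow(quantities)
  if (k < 3L) stop("pairwise variation needs at least 3 genes")
  if (is.null(ranking)) ranking <- genorm_stepwise(quantities)$order
  if (!setequal(ranking, rownames(quantities))) {
    stop("ranking must be a permutation of the gene names")
  }
  v <- vapply(2L:(k - 1L), function(n) {
    nf_n <- normalization_factor(quantities, ranking[seq_len(n)])
    nf_n1 <- normalization_factor(quantities, ranking[seq_len(n + 1L)])
    stats::sd(log2(nf_n / nf_n1))
  }, numeric(1L))
  stats::setNames(v, 2L:(k - 1L))
}

#' Optimal number of reference genes
#'
#' Applies the geNorm cut-off rule to a pairwise-variation series: the
#' optimal number is the smallest n with `V(n, n+1) < cutoff`. If no n
#' qualifies, all k candidate genes are returned with a warning flag. The
#' conventional cutoff is 0.15; it is not fixed and may be relaxed (e.g. to
#' 0.2) when experimental variability warrants.
#'
#' @param v named V series from [pairwise_variation_series()] (names = n).
#' @param cutoff decision threshold (default 0.15).
#' @return List of class `optimal_gene_number`: `n` (optimal count),
#'   `decided` (`TRUE` if some V fell below the cutoff), `cutoff`, `trace`
#'   (data.frame `n, v, below_cutoff`).
#' @export
optimal_gene_number <- function(v, cutoff = 0.15) {
  if (length(v) == 0L) stop("empty V series")
  ns <- as.integer(names(v))
  if (anyNA(ns)) ns <- seq(2L, length.out = length(v))
  below <- v < cutoff
  trace <- data.frame(n = ns, v = as.numeric(v), below_cutoff = below,
                      row.names = NULL)
  if (any(below)) {
    out <- list(n = ns[which(below)[1L]], decided = TRUE, cutoff = cutoff,
                trace = trace)
  } else {
    warning("no V(n, n+1) below cutoff ", cutoff,
            "; returning all ", max(ns) + 1L, " genes")
    out <- list(n = max(ns) + 1L, decided = FALSE, cutoff = cutoff,
                trace = trace)
  }
  class(out) <- "optimal_gene_number"
  out
}

#' @export
print.optimal_gene_number <- function(x, ...) {
  cat("optimal number of reference genes:", x$n,
      if (x$decided) sprintf("(first V < %.3g)", x$cutoff)
      else sprintf("(no V < %.3g; all genes retained, flagged)", x$cutoff),
      "\n")
  invisible(x)
}

#' Full geNorm analysis
#'
#' Runs the stepwise exclusion, availability check (M below
#' `availability_cutoff`, conventionally 1.5, on the full panel), pairwise
#' variation series and the optimal-gene-number rule in one call.
#'
#' @param table a [ct_table()], or a precomputed quantity matrix.
#' @param efficiency passed to [relative_quantities()] when `table` is a
#'   `ct_table`.
#' @param v_cutoff cutoff for [optimal_gene_number()].
#' @param availability_cutoff M threshold below which a gene counts as an
#'   available reference gene.
#' @return List of class `genorm_result`: everything from
#'   [genorm_stepwise()] plus `stability` (initial M), `rank` (= `ranking`),
#'   `available` (logical per gene), `v_series`, `optimal`, `method`.
#' @export
genorm <- function(table, efficiency = 2, v_cutoff = 0.15,
                   availability_cutoff = 1.5) {
  quantities <- if (inherits(table, "ct_table")) {
    relative_quantities(table, efficiency = efficiency)
  } else table
  step <- genorm_stepwise(quantities)
  v <- pairwise_variation_series(quantities, step$order)
  opt <- suppressWarnings(optimal_gene_number(v, cutoff = v_cutoff))
  if (!opt$decided) {
    warning("geNorm: no V(n, n+1) below cutoff ", v_cutoff)
  }
  out <- c(step, list(stability = step$m, rank = step$ranking,
                      available = step$m < availability_cutoff,
                      availability_cutoff = availability_cutoff,
                      v_series = v, optimal = opt, method = "genorm"))
  class(out) <- c("genorm_result", "stability_result")
  out
}
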