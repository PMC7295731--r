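#' Competition ranking
#'
#' Ranks scores so tied values share the smallest applicable rank and the
#' next distinct value skips the tied count (1, 1, 3, ...). All stability
#' methods in the package rank ascending by default (smaller value = more
#' stable = rank 1).
#'
#' @param values numeric scores, optionally named.
#' @param ascending `TRUE` if smaller is better.
#' @return Integer ranks, named like `values`.
#' @export
competition_rank <- function(values, ascending = TRUE) {
  if (length(values) == 0L) stop("no values to rank")
  v <- if (ascending) values else -values
  r <- rank(v, ties.method = "min")
  stats::setNames(as.integer(r), names(values))
}

#' Assemble the method x gene rank table
#'
#' Builds the four-method rank table that RefFinder aggregation consumes
#' from fitted stability results.
#'
#' @param delta_ct,bestkeeper,genorm,normfinder results from
#'   [delta_ct_stability()], [bestkeeper()], [genorm()] and
#'   [normfinder_stability()] on the same table.
#' @return Integer matrix, methods
#'   (`delta_ct, bestkeeper, genorm, normfinder`) x genes.
#' @export
rank_table <- function(delta_ct, bestkeeper, genorm, normfinder) {
  genes <- names(delta_ct$stability)
  bk <- stats::setNames(bestkeeper$summary$rank, bestkeeper$summary$gene)
  rt <- rbind(delta_ct = delta_ct$rank[genes],
              bestkeeper = bk[genes],
              genorm = genorm$rank[genes],
              normfinder = normfinder$rank[genes])
  colnames(rt) <- genes
  storage.mode(rt) <- "integer"
  rt
}

#' RefFinder comprehensive ranking
#'
#' Aggregates the four method ranks per gene by their (equally weighted)
#' geometric mean — the comprehensive stability value — and orders genes
#' ascending in it. The geometric mean is bounded by the smallest and
#' largest method rank, with equality only when all four agree.
#'
#' @param ranks method x gene rank matrix from [rank_table()] (all four
#'   methods required for every gene).
#' @return List of class `reffinder_result`: `method`, `stability`
#'   (geometric means), `rank` (competition ranks of the geometric means),
#'   `ranks` (the input matrix).
#' @export
reffinder <- function(ranks) {
  required <- c("delta_ct", "bestkeeper", "genorm", "normfinder")
  missing_m <- setdiff(required, rownames(ranks))
  if (length(missing_m) > 0L) {
    stop("missing method rank(s): ", paste(missing_m, collapse = ", "))
  }
  ranks <- ranks[required, , drop = FALSE]
  if (anyNA(ranks) || any(ranks < 1)) stop("ranks must be positive and complete")
  geo <- exp(colMeans(log(ranks)))
  structure(list(method = "reffinder", stability = geo,
                 rank = competition_rank(geo), ranks = ranks),
            class = c("reffinder_result", "stability_result"))
}

#' Cross-condition average ranking
#'
#' Arithmetic mean of a gene's per-condition ranks over the included
#' experimental conditions, with the resulting stability order (ascending
#' mean rank = most stable first). Report tables print the averages at two
#' decimals with round-half-up.
#'
#' @param condition_ranks condition x gene numeric matrix (or a list of
#'   named per-condition rank vectors over a common gene set).
#' @return List of class `average_ranking`: `mean_rank` (named, full
#'   precision), `printed` (two-decimal round-half-up), `order` (genes,
#'   most stable first), `per_condition` (the matrix).
#' @export
average_ranking <- function(condition_ranks) {
  m <- as_condition_matrix(condition_ranks)
  mean_rank <- colMeans(m)
  ord <- names(sort(mean_rank))
  structure(list(mean_rank = mean_rank,
                 printed = round_half_up(mean_rank, 2L),
                 order = ord, per_condition = m),
            class = "average_ranking")
}

as_condition_matrix <- function(condition_ranks) {
  if (is.list(condition_ranks) && !is.data.frame(condition_ranks)) {
    genes <- names(condition_ranks[[1L]])
    for (r in condition_ranks) {
      if (!setequal(names(r), genes)) {
        stop("all conditions must rank the same gene set")
      }
    }
    m <- do.call(rbind, lapply(condition_ranks, function(r) r[genes]))
    rownames(m) <- names(condition_ranks)
  } else {
    m <- as.matrix(condition_ranks)
  }
  if (anyNA(m)) stop("every gene must be ranked in every condition")
  m
}

#' @export
print.average_ranking <- function(x, ...) {
  cat("cross-condition average ranking (most stable first):\n")
  print(data.frame(gene = x$order,
                   mean_rank = x$printed[x$order], row.names = NULL))
  invisible(x)
}

#' Condition-exclusion sensitivity of average rankings
#'
#' Recomputes the cross-condition average ranking with one or more
#' conditions left out (e.g. dropping a mixed-population condition to ask
#' how much of a gene's instability is between-population) and reports the
#' per-gene change in average rank.
#'
#' @param condition_ranks as in [average_ranking()].
#' @param exclude condition names to drop; at least one condition must
#'   remain.
#' @return List of class `exclusion_sensitivity`: `full` and `reduced`
#'   [average_ranking()] results, `excluded`, `shift` data.frame
#'   (`gene, mean_rank_full, mean_rank_reduced, change`; negative change =
#'   improved rank after exclusion).
#' @export
exclusion_sensitivity <- function(condition_ranks, exclude = character(0L)) {
  m <- as_condition_matrix(condition_ranks)
  unknown <- setdiff(exclude, rownames(m))
  if (length(unknown) > 0L) {
    stop("unknown condition(s): ", paste(unknown, collapse = ", "))
  }
  keep <- setdiff(rownames(m), exclude)
  if (length(keep) == 0L) stop("exclusion leaves no conditions")
  full <- average_ranking(m)
  reduced <- average_ranking(m[keep, , drop = FALSE])
  shift <- data.frame(gene = colnames(m),
                      mean_rank_full = full$mean_rank,
                      mean_rank_reduced = reduced$mean_rank,
                      change = reduced$mean_rank - full$mean_rank,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(full = full, reduced = reduced, excluded = exclude,
                 shift = shift),
            class = "exclusion_sensitivity")
}

# round half away from zero (so 2.335 -> 2.34), the convention used for
# printed average rankings; base round() is round-half-even.
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
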