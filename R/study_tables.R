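#' Published study tables bundled as example inputs
#'
#' The package ships the printed summary tables of a published five-gene
#' reference-gene screen in the rice white-tip nematode (candidates 18S
#' rRNA, actin, GAPDH, UBC and alpha-tubulin over three experimental
#' conditions: life stages of two populations plus mixed-stage nematodes of
#' four populations). These printed tables are *inputs* to the
#' rank-arithmetic operations — cross-condition averaging, exclusion
#' sensitivity, the geNorm optimal-gene-number rule — whose outputs the
#' study reports; the raw Ct data itself was never deposited in a public
#' archive.
#'
#' `study_ranks()` returns the per-condition stability ranks of the four
#' methods (long data.frame `method, condition, gene, rank`).
#' `study_ct_summary()` returns the printed per-gene Ct extremes and means.
#' `study_v_series()` returns the printed geNorm V values (the censored N10
#' n = 2 entry encodes "not below the 0.2 cutoff"; see the file header).
#'
#' @return A data.frame (see above).
#' @name study_tables
NULL

read_study_table <- function(name) {
  path <- system.file("extdata", name, package = "refstab")
  if (!nzchar(path)) stop("bundled table not found: ", name)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname study_tables
#' @export
study_ranks <- function() read_study_table("study_ranks.tsv")

#' @rdname study_tables
#' @export
study_ct_summary <- function() read_study_table("study_ct_summary.tsv")

#' @rdname study_tables
#' @export
study_v_series <- function() read_study_table("study_v_series.tsv")

#' Per-condition rank matrix for one method from the bundled study tables
#'
#' Reshapes [study_ranks()] into the condition x gene matrix that
#' [average_ranking()] and [exclusion_sensitivity()] consume.
#'
#' @param method one of `"delta_ct"`, `"genorm"`, `"normfinder"`,
#'   `"reffinder"`.
#' @return Numeric condition x gene matrix.
#' @export
study_rank_matrix <- function(method) {
  r <- study_ranks()
  r <- r[r$method == method, , drop = FALSE]
  if (nrow(r) == 0L) stop("no bundled ranks for method: ", method)
  conditions <- unique(r$condition)
  genes <- unique(r$gene)
  m <- matrix(NA_real_, length(conditions), length(genes),
              dimnames = list(conditions, genes))
  m[cbind(match(r$condition, conditions), match(r$gene, genes))] <- r$rank
  m
}
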