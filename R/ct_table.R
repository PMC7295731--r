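#' Ct tables
#'
#' A `ct_table` holds RT-qPCR threshold-cycle (Ct) values indexed by
#' gene x sample x replicate, together with per-sample group annotations
#' (experimental condition levels such as life stage or population). It is
#' the universal input of every stability method in the package.
#'
#' Invariants enforced by [validate_ct_table()]:
#' * every Ct is finite and in (0, 45] unless missing (`NA`),
#' * gene and sample ids are unique, and every (gene, sample) pair is present,
#' * replicate indices within each (gene, sample) pair are 1..r.
#'
#' @param data data.frame with columns `gene`, `sample`, `replicate`, `ct`.
#' @param samples data.frame with columns `sample`, `group` (one row per
#'   sample; group labels non-empty, each sample in exactly one group).
#' @param genes character vector giving the gene order; defaults to order of
#'   first appearance in `data`.
#' @return An object of class `ct_table`: a list with elements `data`,
#'   `samples` and `genes`.
#' @seealso [read_ct_table()], [average_technical_replicates()], [ct_matrix()]
#' @export
ct_table <- function(data, samples = NULL, genes = NULL) {
  required <- c("gene", "sample", "replicate", "ct")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  data$gene <- as.character(data$gene)
  data$sample <- as.character(data$sample)
  data$replicate <- as.integer(data$replicate)
  if (!is.numeric(data$ct)) stop("'ct' must be numeric")
  if (is.null(samples)) {
    if ("group" %in% names(data)) {
      samples <- unique(data[, c("sample", "group")])
    } else {
      samples <- data.frame(sample = unique(data$sample), group = "all",
                            stringsAsFactors = FALSE)
    }
  }
  samples$sample <- as.character(samples$sample)
  samples$group <- as.character(samples$group)
  if (is.null(genes)) genes <- unique(data$gene)
  x <- structure(
    list(data = data[, required], samples = samples, genes = genes),
    class = "ct_table"
  )
  validate_ct_table(x)
}

#' Validate a Ct table
#'
#' Checks the `ct_table` invariants (see [ct_table()]) and fails with an
#' informative error on the first violation. Missing Ct values (`NA`) are
#' rejected unless `allow_missing = TRUE`; complete-matrix methods require
#' [drop_incomplete()] to be applied first in that case.
#'
#' @param x a `ct_table`.
#' @param allow_missing logical; tolerate `NA` Ct values.
#' @return `x`, invisibly unchanged, for chaining.
#' @export
validate_ct_table <- function(x, allow_missing = TRUE) {
  d <- x$data
  bad <- !is.na(d$ct) & (!is.finite(d$ct) | d$ct <= 0 | d$ct > 45)
  if (any(bad)) {
    stop("Ct values out of range (0, 45]: e.g. gene ", d$gene[bad][1L],
         ", sample ", d$sample[bad][1L], ", ct = ", d$ct[bad][1L])
  }
  if (!allow_missing && anyNA(d$ct)) {
    stop("missing Ct values present; use drop_incomplete() or allow_missing")
  }
  key <- paste(d$gene, d$sample, d$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- d[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (gene, sample, replicate) key: ",
         dup$gene, ", ", dup$sample, ", replicate ", dup$replicate)
  }
  if (anyDuplicated(x$samples$sample)) stop("duplicate sample ids in annotation")
  if (anyDuplicated(x$genes)) stop("duplicate gene ids")
  if (any(!nzchar(x$samples$group) | is.na(x$samples$group))) {
    stop("every sample needs a non-empty group label")
  }
  unknown <- setdiff(d$sample, x$samples$sample)
  if (length(unknown) > 0L) {
    stop("sample(s) without annotation: ", paste(unknown, collapse = ", "))
  }
  # every (gene, sample) pair present; replicate indices 1..r within pair
  pairs <- table(d$gene, d$sample)
  if (any(pairs == 0L)) {
    idx <- which(pairs == 0L, arr.ind = TRUE)[1L, ]
    stop("no Ct entry for gene ", rownames(pairs)[idx[1L]],
         " in sample ", colnames(pairs)[idx[2L]])
  }
  by_pair <- split(d$replicate, paste(d$gene, d$sample, sep = "\r"))
  ok <- vapply(by_pair, function(r) identical(sort(r), seq_along(r)),
               logical(1L))
  if (!all(ok)) {
    stop("replicate indices must be 1..r within each (gene, sample) pair")
  }
  invisible(x)
}

#' @export
print.ct_table <- function(x, ...) {
  cat("ct_table:", length(x$genes), "genes x",
      nrow(x$samples), "samples,", nrow(x$data), "Ct entries\n")
  cat("genes:", paste(x$genes, collapse = ", "), "\n")
  grp <- table(x$samples$group)
  cat("groups:", paste(sprintf("%s (n=%d)", names(grp), grp), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a Ct table from CSV/TSV
#'
#' Long layout requires columns `sample, group, gene, replicate, ct`
#' (the `replicate` column may be omitted when there is one replicate).
#' Wide layout requires `sample, group, <gene1>, <gene2>, ...` with one row
#' per sample; repeated sample rows are interpreted as technical replicates
#' and numbered in file order. The field separator is sniffed from the file
#' extension (`.tsv`/`.txt` = tab, otherwise comma).
#'
#' @param path path to a CSV or TSV file (header required, UTF-8, '.' decimal).
#' @param layout `"long"` or `"wide"`.
#' @param sep field separator; default sniffed from the extension.
#' @return A [ct_table()] with gene order as in the file and group labels
#'   attached.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample,group,gene,replicate,ct",
#'              "s1,egg,actin,1,20.1", "s1,egg,ubc,1,25.0",
#'              "s2,female,actin,1,20.5", "s2,female,ubc,1,25.2"), f)
#' read_ct_table(f, layout = "long")
#' @export
read_ct_table <- function(path, layout = c("long", "wide"), sep = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  if (layout == "long") {
    required <- c("sample", "group", "gene", "ct")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0L) {
      stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
    }
    if (!("replicate" %in% names(raw))) raw$replicate <- 1L
    raw$ct <- parse_ct(raw$ct)
    samples <- unique(raw[, c("sample", "group")])
    ct_table(raw[, c("gene", "sample", "replicate", "ct")],
             samples = samples, genes = unique(raw$gene))
  } else {
    required <- c("sample", "group")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0L) {
      stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
    }
    genes <- setdiff(names(raw), required)
    if (length(genes) == 0L) stop("wide layout has no gene columns")
    # repeated sample rows are technical replicates, numbered in file order
    rep_idx <- stats::ave(seq_len(nrow(raw)), raw$sample, FUN = seq_along)
    long <- do.call(rbind, lapply(genes, function(g) {
      data.frame(gene = g, sample = raw$sample, replicate = rep_idx,
                 ct = parse_ct(raw[[g]]), stringsAsFactors = FALSE)
    }))
    samples <- unique(raw[, c("sample", "group")])
    ct_table(long, samples = samples, genes = genes)
  }
}

# Numeric Ct parser: blank/NA/"Undetermined" -> NA, anything else non-numeric
# is an error (malformed file, not a missing reaction).
parse_ct <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "Undetermined", "undetermined")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) stop("non-numeric ct value: '", x[bad][1L], "'")
  out
}

#' Average technical replicates
#'
#' Collapses a Ct table to one entry per (gene, sample), each the arithmetic
#' mean of that pair's replicate Ct values. With `drop_missing = TRUE`
#' (default) missing replicates are dropped from the mean; a pair with no
#' observed replicate at all stays `NA`.
#'
#' @param table a [ct_table()].
#' @param drop_missing drop `NA` replicates before averaging.
#' @return A `ct_table` with one replicate (index 1) per (gene, sample).
#' @export
average_technical_replicates <- function(table, drop_missing = TRUE) {
  d <- table$data
  key <- interaction(d$gene, d$sample, drop = TRUE)
  means <- tapply(d$ct, key, function(v) {
    v <- if (drop_missing) v[!is.na(v)] else v
    if (length(v) == 0L) NA_real_ else mean(v)
  })
  first <- !duplicated(key)
  lev <- key[first]
  out <- data.frame(gene = d$gene[first], sample = d$sample[first],
                    replicate = 1L,
                    ct = as.numeric(means[match(as.character(lev),
                                                names(means))]),
                    stringsAsFactors = FALSE)
  ct_table(out, samples = table$samples, genes = table$genes)
}

#' Drop samples with incomplete gene coverage
#'
#' Removes every sample that lacks a (replicate-averaged) Ct value for any
#' gene. Complete-matrix methods (geNorm, NormFinder, BestKeeper, delta-Ct)
#' require a complete gene x sample matrix.
#'
#' @param table a [ct_table()].
#' @return A `ct_table` restricted to complete samples.
#' @export
drop_incomplete <- function(table) {
  m <- ct_matrix(table, require_complete = FALSE)
  keep <- colnames(m)[colSums(is.na(m)) == 0L]
  if (length(keep) == 0L) stop("no complete samples remain")
  d <- table$data[table$data$sample %in% keep, , drop = FALSE]
  s <- table$samples[table$samples$sample %in% keep, , drop = FALSE]
  ct_table(d, samples = s, genes = table$genes)
}

#' Gene x sample Ct matrix
#'
#' Technical replicates are averaged first; rows follow the table's gene
#' order, columns its sample order.
#'
#' @param table a [ct_table()].
#' @param require_complete error on any missing cell (default).
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
ct_matrix <- function(table, require_complete = TRUE) {
  avg <- if (max(table(paste(table$data$gene, table$data$sample))) > 1L) {
    average_technical_replicates(table)
  } else table
  d <- avg$data
  m <- matrix(NA_real_, nrow = length(table$genes),
              ncol = nrow(table$samples),
              dimnames = list(table$genes, table$samples$sample))
  m[cbind(match(d$gene, rownames(m)), match(d$sample, colnames(m)))] <- d$ct
  if (require_complete && anyNA(m)) {
    stop("incomplete Ct matrix; use drop_incomplete() first")
  }
  m
}

#' Sample group labels
#'
#' @param table a [ct_table()].
#' @return Named character vector of group labels, one per sample, in the
#'   table's sample order.
#' @export
sample_groups <- function(table) {
  stats::setNames(table$samples$group, table$samples$sample)
}

#' Summary statistics for one gene's Ct values
#'
#' Statistics are computed over the gene's replicate-averaged, sample-level
#' Ct values. Quartiles use Tukey hinges (the inclusive convention: the
#' median belongs to both halves when n is odd), matching the whisker-box
#' descriptions such summaries are read from.
#'
#' @param table a [ct_table()].
#' @param gene gene id present in the table.
#' @return data.frame with columns
#'   `gene, n, min, q1, median, q3, max, range, mean`; `range = max - min`
#'   exactly.
#' @export
summarize_ct <- function(table, gene) {
  if (!(gene %in% table$genes)) stop("unknown gene: ", gene)
  m <- ct_matrix(table, require_complete = FALSE)
  v <- m[gene, ]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no Ct values for gene ", gene)
  fn <- stats::fivenum(v)
  data.frame(gene = gene, n = length(v),
             min = fn[1L], q1 = fn[2L], median = fn[3L], q3 = fn[4L],
             max = fn[5L], range = fn[5L] - fn[1L], mean = mean(v),
             stringsAsFactors = FALSE)
}

#' Summarize all genes
#'
#' @param table a [ct_table()].
#' @return data.frame, one [summarize_ct()] row per gene in table order.
#' @export
summarize_ct_all <- function(table) {
  do.call(rbind, lapply(table$genes, function(g) summarize_ct(table, g)))
}

#' One-way ANOVA on a gene's Ct values
#'
#' Classical one-way ANOVA of the gene's sample-level Ct values against the
#' sample grouping (F with k-1 and N-k degrees of freedom). A degenerate
#' input with zero total variance returns F = 0, p = 1 with a warning so
#' that noiseless synthetic data passes through.
#'
#' @param table a [ct_table()].
#' @param gene gene id.
#' @param grouping optional grouping vector (one label per sample, in table
#'   sample order, or named by sample id); defaults to the table's group
#'   annotation.
#' @return List of class `anova_result`: `gene`, `f`, `p`, `df`,
#'   `group_means`.
#' @export
anova_oneway <- function(table, gene, grouping = NULL) {
  v <- gene_values_by_group(table, gene, grouping)
  counts <- table(v$group)
  if (length(counts) < 2L) stop("need at least two groups")
  if (any(counts < 2L)) {
    stop("every group needs at least two values (",
         names(counts)[counts < 2L][1L], " has ", min(counts), ")")
  }
  group_means <- tapply(v$ct, v$group, mean)
  if (stats::var(v$ct) == 0) {
    warning("zero total variance for gene ", gene, "; returning F = 0, p = 1")
    out <- list(gene = gene, f = 0, p = 1,
                df = c(length(counts) - 1L, length(v$ct) - length(counts)),
                group_means = group_means)
    class(out) <- "anova_result"
    return(out)
  }
  fit <- stats::aov(ct ~ group, data = v)
  tab <- summary(fit)[[1L]]
  out <- list(gene = gene, f = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L],
              df = tab[["Df"]], group_means = group_means)
  class(out) <- "anova_result"
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA for %s: F(%d, %d) = %.4g, p = %.4g\n",
              x$gene, x$df[1L], x$df[2L], x$f, x$p))
  invisible(x)
}

#' Tukey HSD pairwise comparisons for one gene
#'
#' All-pairs comparisons of group mean Ct via the studentized-range
#' distribution ([stats::TukeyHSD()]), flagged significant at `alpha`.
#'
#' @inheritParams anova_oneway
#' @param alpha family-wise significance level.
#' @return data.frame with columns
#'   `pair, diff, lwr, upr, p_adj, significant`.
#' @export
tukey_hsd <- function(table, gene, grouping = NULL, alpha = 0.05) {
  v <- gene_values_by_group(table, gene, grouping)
  counts <- table(v$group)
  if (length(counts) < 2L) stop("need at least two groups")
  if (any(counts < 2L)) stop("every group needs at least two values")
  if (stats::var(v$ct) == 0) {
    pairs <- utils::combn(sort(names(counts)), 2L)
    return(data.frame(pair = paste(pairs[2L, ], pairs[1L, ], sep = "-"),
                      diff = 0, lwr = 0, upr = 0, p_adj = 1,
                      significant = FALSE, stringsAsFactors = FALSE))
  }
  fit <- stats::aov(ct ~ group, data = v)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Sample-level values of one gene with a grouping factor attached.
gene_values_by_group <- function(table, gene, grouping = NULL) {
  if (!(gene %in% table$genes)) stop("unknown gene: ", gene)
  m <- ct_matrix(table, require_complete = FALSE)
  ct <- m[gene, ]
  if (is.null(grouping)) {
    grouping <- sample_groups(table)
  } else if (!is.null(names(grouping))) {
    grouping <- grouping[colnames(m)]
  } else if (length(grouping) != ncol(m)) {
    stop("grouping must have one label per sample")
  }
  keep <- !is.na(ct)
  data.frame(ct = ct[keep], group = factor(as.character(grouping)[keep]),
             stringsAsFactors = FALSE)
}

#' Write a Ct summary table as TSV
#'
#' Fixed column order `gene,n,min,q1,median,q3,max,range,mean`.
#'
#' @param table a [ct_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ct_summary <- function(table, path) {
  s <- summarize_ct_all(table)
  utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
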