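#' Specification of a synthetic Ct-table generator
#'
#' Describes the generative model for synthetic RT-qPCR Ct data with known
#' variance structure:
#' `Ct(i, s, rep) = mu_i + delta(i, g(s)) + L(s) + eps(i, s) + tau(i, s, rep)`
#' with sample loading `L ~ N(0, sigma_L^2)` shared across genes within a
#' sample, gene instability `eps ~ N(0, sigma_i^2)` per gene per sample,
#' technical noise `tau ~ N(0, sigma_tau^2)` per replicate, and fixed
#' per-group effects `delta`. All noise is Normal on the Ct (log2) scale,
#' the scale every implemented statistic operates on.
#'
#' @param genes data.frame with columns `name`, `mu` (base Ct, cycles, in
#'   (5, 40)), `sigma` (instability SD, cycles, >= 0).
#' @param groups data.frame with columns `label`, `n` (samples per group,
#'   >= 1).
#' @param delta gene x group matrix of group effects (cycles); default all
#'   zero. Rows follow `genes$name`, columns `groups$label`.
#' @param sigma_loading SD of the shared per-sample loading shift (cycles).
#' @param sigma_technical SD of per-replicate technical noise (cycles).
#' @param replicates technical replicates per (gene, sample).
#' @return Object of class `synthetic_spec`.
#' @seealso [default_synthetic_spec()], [generate_ct_table()],
#'   [ground_truth_order()]
#' @export
synthetic_spec <- function(genes, groups, delta = NULL,
                           sigma_loading = 0.5, sigma_technical = 0.1,
                           replicates = 3L) {
  stopifnot(is.data.frame(genes), all(c("name", "mu", "sigma") %in%
                                        names(genes)),
            is.data.frame(groups), all(c("label", "n") %in% names(groups)))
  if (any(genes$mu <= 5 | genes$mu >= 40)) {
    stop("base Ct values must lie in (5, 40)")
  }
  if (any(genes$sigma < 0) || sigma_loading < 0 || sigma_technical < 0) {
    stop("all SDs must be >= 0")
  }
  if (any(groups$n < 1L)) stop("every group needs at least one sample")
  if (anyDuplicated(genes$name)) stop("duplicate gene names")
  if (anyDuplicated(groups$label)) stop("duplicate group labels")
  if (is.null(delta)) {
    delta <- matrix(0, nrow(genes), nrow(groups))
  }
  delta <- matrix(as.numeric(delta), nrow(genes), nrow(groups),
                  dimnames = list(genes$name, groups$label))
  structure(list(genes = genes, groups = groups, delta = delta,
                 sigma_loading = sigma_loading,
                 sigma_technical = sigma_technical,
                 replicates = as.integer(replicates)),
            class = "synthetic_spec")
}

#' Default study-like synthetic specification
#'
#' Emulates a five-candidate reference-gene screen across 12 samples in
#' four groups of three with three technical replicates: base Ct levels at
#' the observed mean Ct of a typical nematode candidate panel (18S rRNA
#' 12.89, actin 21.12, GAPDH 24.85, UBC 25.53, a-tubulin 25.68 cycles),
#' gene-specific instability SDs making UBC the most and 18S the least
#' stable, a per-group effect on 18S emulating ribosomal copy-number
#' differences between populations, loading SD 0.5 and technical SD 0.1
#' cycles. The implied ground-truth stability order is
#' UBC < GAPDH < actin < a-tubulin < 18S.
#'
#' @return A [synthetic_spec()].
#' @export
default_synthetic_spec <- function() {
  genes <- data.frame(
    name = c("18S", "actin", "GAPDH", "UBC", "a-tubulin"),
    mu = c(12.89, 21.12, 24.85, 25.53, 25.68),
    sigma = c(0.45, 0.30, 0.25, 0.15, 0.35),
    stringsAsFactors = FALSE)
  groups <- data.frame(label = c("N10", "S24", "X8", "YQ"), n = 3L,
                       stringsAsFactors = FALSE)
  delta <- matrix(0, 5L, 4L, dimnames = list(genes$name, groups$label))
  delta["18S", ] <- c(-0.5, 0.2, 0.5, -0.2)
  synthetic_spec(genes, groups, delta = delta,
                 sigma_loading = 0.5, sigma_technical = 0.1, replicates = 3L)
}

#' Generate a synthetic Ct table
#'
#' Draws one dataset from a [synthetic_spec()], deterministically given the
#' seed (the RNG state of the session is restored afterwards). Draw order is
#' fixed and documented so tables are reproducible across versions: samples
#' are visited group by group in spec order; for each sample one loading
#' draw, then per gene (spec order) one instability draw, then `replicates`
#' technical draws.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed controlling all draws.
#' @return List: `table` (a [ct_table()], samples named `<group>_<j>`),
#'   `truth` (the [ground_truth_order()] of the spec), `spec`, `seed`.
#' @export
generate_ct_table <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  rows <- vector("list", 0L)
  sample_meta <- list()
  idx <- 0L
  for (g in seq_len(nrow(spec$groups))) {
    glab <- spec$groups$label[g]
    for (j in seq_len(spec$groups$n[g])) {
      idx <- idx + 1L
      sid <- sprintf("%s_%d", glab, j)
      loading <- stats::rnorm(1L, 0, spec$sigma_loading)
      for (i in seq_len(nrow(spec$genes))) {
        gene <- spec$genes$name[i]
        eps <- stats::rnorm(1L, 0, spec$genes$sigma[i])
        tau <- stats::rnorm(spec$replicates, 0, spec$sigma_technical)
        ct <- spec$genes$mu[i] + spec$delta[gene, glab] + loading + eps + tau
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, sample = sid, replicate = seq_len(spec$replicates),
          ct = ct, stringsAsFactors = FALSE)
      }
      sample_meta[[idx]] <- data.frame(sample = sid, group = glab,
                                       stringsAsFactors = FALSE)
    }
  }
  table <- ct_table(do.call(rbind, rows),
                    samples = do.call(rbind, sample_meta),
                    genes = spec$genes$name)
  list(table = table, truth = ground_truth_order(spec), spec = spec,
       seed = as.integer(seed))
}

#' Ground-truth stability order of a synthetic spec
#'
#' Orders genes ascending in their total structural instability
#' `sigma_i^2 + Var_g(delta(i, .))` (population variance over groups of the
#' group effects). Loading and technical SDs are shared across genes and do
#' not enter. Exact ties are broken by input order and flagged.
#'
#' @param spec a [synthetic_spec()].
#' @return List of class `ground_truth`: `order` (gene names, most stable
#'   first), `variance` (named total instability variances), `tied`
#'   (logical flag).
#' @export
ground_truth_order <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  delta_var <- apply(spec$delta, 1L, function(d) mean((d - mean(d))^2))
  total <- spec$genes$sigma^2 + delta_var[spec$genes$name]
  names(total) <- spec$genes$name
  ord <- order(total)  # stable sort: ties keep input order
  structure(list(order = spec$genes$name[ord], variance = total,
                 tied = anyDuplicated(total) > 0L),
            class = "ground_truth")
}

#' Write a synthetic Ct table as long-layout CSV
#'
#' Emits the `sample,group,gene,replicate,ct` layout that
#' [read_ct_table()] reads back.
#'
#' @param table a [ct_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(table, path) {
  d <- table$data
  d$group <- sample_groups(table)[d$sample]
  out <- d[, c("sample", "group", "gene", "replicate", "ct")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
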