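# Shared fixtures, built in code.

# The three-gene toy: A drifts one cycle per sample, B is flat, C tracks A.
toy_table <- function() {
  d <- expand.grid(sample = c("s1", "s2", "s3"), gene = c("A", "B", "C"),
                   stringsAsFactors = FALSE)
  d$replicate <- 1L
  d$ct <- c(20, 21, 22, 25, 25, 25, 30, 31, 32)
  ct_table(d, samples = data.frame(sample = c("s1", "s2", "s3"),
                                   group = "all", stringsAsFactors = FALSE))
}

# A seeded random Ct table (one replicate, one group unless given).
random_table <- function(seed, n_genes = 4L, n_samples = 8L, groups = NULL) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  samples <- paste0("s", seq_len(n_samples))
  d <- expand.grid(sample = samples, gene = genes, stringsAsFactors = FALSE)
  d$replicate <- 1L
  d$ct <- round(runif(nrow(d), 18, 30), 3)
  if (is.null(groups)) groups <- rep("all", n_samples)
  ct_table(d, samples = data.frame(sample = samples, group = groups,
                                   stringsAsFactors = FALSE))
}

# Table built directly from a gene x sample Ct matrix.
matrix_table <- function(m, groups = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  d <- data.frame(gene = rep(rownames(m), ncol(m)),
                  sample = rep(colnames(m), each = nrow(m)),
                  replicate = 1L, ct = as.vector(m),
                  stringsAsFactors = FALSE)
  if (is.null(groups)) groups <- rep("all", ncol(m))
  ct_table(d, samples = data.frame(sample = colnames(m), group = groups,
                                   stringsAsFactors = FALSE),
           genes = rownames(m))
}

# Add a per-sample loading shift to every gene of each sample.
shift_samples <- function(table, shifts) {
  d <- table$data
  d$ct <- d$ct + shifts[match(d$sample, names(shifts))]
  ct_table(d, samples = table$samples, genes = table$genes)
}

write_long_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
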