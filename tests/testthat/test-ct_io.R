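test_that("long and wide layouts parse to the same validated table", {
  long <- data.frame(sample = rep(c("s1", "s2"), each = 2L),
                     group = rep(c("egg", "female"), each = 2L),
                     gene = rep(c("actin", "ubc"), 2L),
                     replicate = 1L,
                     ct = c(20.1, 25.0, 20.5, 25.2))
  tb <- read_ct_table(write_long_csv(long), layout = "long")
  expect_s3_class(tb, "ct_table")
  expect_equal(nrow(tb$data), 4L)
  expect_equal(tb$genes, c("actin", "ubc"))
  expect_equal(unname(sample_groups(tb)), c("egg", "female"))

  wide_path <- tempfile(fileext = ".csv")
  writeLines(c("sample,group,actin,ubc",
               "s1,egg,20.1,25.0",
               "s2,female,20.5,25.2"), wide_path)
  tw <- read_ct_table(wide_path, layout = "wide")
  expect_equal(ct_matrix(tw), ct_matrix(tb))
})

test_that("wide layout counts repeated sample rows as technical replicates", {
  path <- tempfile(fileext = ".csv")
  n_samples <- 12L
  lines <- c("sample,group,g1,g2,g3,g4,g5",
             vapply(seq_len(n_samples), function(i) {
               paste0("s", i, ",grp", (i - 1L) %/% 3L + 1L, ",",
                      paste(20 + seq_len(5L) + i / 10, collapse = ","))
             }, character(1L)))
  writeLines(lines, path)
  tb <- read_ct_table(path, layout = "wide")
  expect_equal(nrow(tb$data), 60L)

  writeLines(c("sample,group,g1", "s1,a,20", "s1,a,21", "s2,a,22", "s2,a,23"),
             path)
  tr <- read_ct_table(path, layout = "wide")
  expect_equal(sort(tr$data$replicate[tr$data$sample == "s1"]), 1:2)
  expect_equal(unname(ct_matrix(tr)["g1", ]), c(20.5, 22.5))
})

test_that("malformed files fail with errors naming the problem", {
  bad <- data.frame(sample = "s1", group = "g", gene = "actin",
                    replicate = 1L, value = 20)
  expect_error(read_ct_table(write_long_csv(bad), layout = "long"), "ct")
  path <- tempfile(fileext = ".csv")
  writeLines(c("sample,group,gene,replicate,ct", "s1,g,actin,1,oops"), path)
  expect_error(read_ct_table(path, layout = "long"), "non-numeric")
  dup <- data.frame(sample = "s1", group = "g", gene = "actin",
                    replicate = c(1L, 1L), ct = c(20, 21))
  expect_error(read_ct_table(write_long_csv(dup), layout = "long"),
               "duplicate")
  out_of_range <- data.frame(sample = "s1", group = "g", gene = "actin",
                             replicate = 1L, ct = 50)
  expect_error(read_ct_table(write_long_csv(out_of_range), layout = "long"),
               "range")
})

test_that("technical replicates average arithmetically, dropping missing", {
  d <- data.frame(gene = "g1", sample = "s1", replicate = 1:3,
                  ct = c(20, 21, 22))
  tb <- ct_table(d)
  expect_equal(average_technical_replicates(tb)$data$ct, 21)

  single <- ct_table(data.frame(gene = "g1", sample = "s1", replicate = 1L,
                                ct = 24.5))
  expect_equal(average_technical_replicates(single)$data$ct, 24.5)

  with_na <- ct_table(data.frame(gene = "g1", sample = "s1", replicate = 1:3,
                                 ct = c(20, NA, 22)))
  expect_equal(average_technical_replicates(with_na)$data$ct, 21)
})

test_that("drop_incomplete removes exactly the samples missing any gene", {
  m <- rbind(g1 = c(20, 21, NA), g2 = c(25, 26, 27))
  colnames(m) <- paste0("s", 1:3)
  d <- data.frame(gene = rep(rownames(m), 3L),
                  sample = rep(colnames(m), each = 2L), replicate = 1L,
                  ct = as.vector(m))
  tb <- ct_table(d)
  expect_error(ct_matrix(tb), "incomplete")
  kept <- drop_incomplete(tb)
  expect_equal(kept$samples$sample, c("s1", "s2"))
  expect_false(anyNA(ct_matrix(kept)))
})

test_that("summarize_ct reproduces the published ranges and range = max - min", {
  pub <- study_ct_summary()
  for (i in seq_len(nrow(pub))) {
    # a minimal value set realizing the printed extremes and mean:
    # min, max, and two interior values balancing the mean
    mid <- (4 * pub$mean[i] - pub$min[i] - pub$max[i]) / 2
    vals <- c(pub$min[i], pub$max[i], mid, mid)
    m <- rbind(vals, vals + 1)
    dimnames(m) <- list(c(pub$gene[i], "filler"),
                        paste0("s", seq_along(vals)))
    s <- summarize_ct(matrix_table(m), pub$gene[i])
    expect_equal(s$range, pub$max[i] - pub$min[i])
    expect_equal(s$mean, pub$mean[i], tolerance = 1e-12)
  }
  # constant gene: degenerate box
  const <- matrix_table(rbind(k = c(25, 25, 25), f = c(20, 21, 22)))
  s <- summarize_ct(const, "k")
  expect_equal(s$range, 0)
  expect_equal(unlist(s[c("min", "q1", "median", "q3", "max", "mean")]),
               rep(25, 6L), ignore_attr = TRUE)
  expect_true(with(s, min <= q1 && q1 <= median && median <= q3 && q3 <= max))
})

test_that("range equals max - min at full precision for random inputs", {
  for (seed in 1:20) {
    tb <- random_table(seed, n_genes = 2L, n_samples = 7L)
    s <- summarize_ct(tb, "g1")
    v <- ct_matrix(tb)["g1", ]
    expect_identical(s$range, max(v) - min(v))
  }
})

test_that("one-way ANOVA matches the closed-form F and its invariances", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5, 6), filler = rep(c(10, 11, 12), 2L))
  colnames(m) <- paste0("s", 1:6)
  tb <- matrix_table(m, groups = rep(c("a", "b"), each = 3L))
  res <- anova_oneway(tb, "g1")
  expect_equal(res$f, 13.5, tolerance = 1e-12)  # SSB 13.5 / (SSW 4 / 4)
  expect_equal(res$df, c(1L, 4L))
  expect_equal(res$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))

  shifted <- matrix_table(m + 7, groups = rep(c("a", "b"), each = 3L))
  expect_equal(anova_oneway(shifted, "g1")$f, res$f, tolerance = 1e-9)

  equal_means <- matrix_table(rbind(g1 = c(1, 3, 2, 1, 3, 2), m["filler", ,
                                                               drop = FALSE]),
                              groups = rep(c("a", "b"), each = 3L))
  r0 <- anova_oneway(equal_means, "g1")
  expect_equal(r0$f, 0)
  expect_equal(r0$p, 1)
})

test_that("degenerate and invalid ANOVA inputs are handled as specified", {
  flat <- matrix_table(rbind(g1 = rep(25, 6L), g2 = rep(20, 6L)),
                       groups = rep(c("a", "b"), each = 3L))
  expect_warning(res <- anova_oneway(flat, "g1"), "zero total variance")
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)

  tb <- random_table(3L, n_genes = 2L, n_samples = 4L,
                     groups = c("a", "a", "a", "b"))
  expect_error(anova_oneway(tb, "g1"), "at least two values")
  one_group <- random_table(3L, n_genes = 2L, n_samples = 4L)
  expect_error(anova_oneway(one_group, "g1"), "at least two groups")
  expect_error(anova_oneway(one_group, "nope"), "unknown gene")
})

test_that("Tukey HSD flags the separated pairs and is symmetric in order", {
  m <- rbind(g1 = c(1, 2, 3, 10, 11, 12), filler = rep(20, 6L) + (1:6) / 10)
  colnames(m) <- paste0("s", 1:6)
  tb <- matrix_table(m, groups = rep(c("a", "b"), each = 3L))
  tk <- tukey_hsd(tb, "g1", alpha = 0.05)
  expect_true(all(tk$significant))
  expect_equal(tk$diff, 9, tolerance = 1e-12)

  # three groups, one far away: exactly the two pairs involving it flag
  m3 <- rbind(g1 = c(1, 2, 3, 1.5, 2.5, 2, 30, 31, 32),
              filler = 20 + (1:9) / 10)
  colnames(m3) <- paste0("s", 1:9)
  tb3 <- matrix_table(m3, groups = rep(c("a", "b", "c"), each = 3L))
  tk3 <- tukey_hsd(tb3, "g1")
  expect_equal(sum(tk3$significant), 2L)
  expect_true(all(grepl("c", tk3$pair[tk3$significant])))

  # identical groups: zero difference, not significant
  same <- matrix_table(rbind(g1 = rep(c(1, 2, 3), 2L), filler = 20 + (1:6)),
                       groups = rep(c("a", "b"), each = 3L))
  tks <- tukey_hsd(same, "g1")
  expect_equal(tks$diff, 0, tolerance = 1e-12)
  expect_false(any(tks$significant))
})

test_that("ct summary TSV uses the fixed column order", {
  path <- tempfile(fileext = ".tsv")
  write_ct_summary(toy_table(), path)
  header <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  expect_equal(header,
               c("gene", "n", "min", "q1", "median", "q3", "max", "range",
                 "mean"))
})
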