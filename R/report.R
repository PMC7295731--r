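#' Run the full stability analysis on one Ct table
#'
#' Executes the requested stability methods on a single experimental
#' condition and writes the report bundle: Ct summaries, per-method
#' stability tables, geNorm M-trajectory and V-series, and the RefFinder
#' aggregate. Stability values are printed at 3 decimals and average
#' rankings at 2 (round half up); every number in the tables is taken
#' directly from an operation's output. The pipeline is deterministic: the
#' same input and config give byte-identical output files.
#'
#' @param table a [ct_table()], or a path readable by [read_ct_table()].
#' @param methods subset of
#'   `c("delta_ct", "bestkeeper", "genorm", "normfinder", "reffinder")`;
#'   `reffinder` requires the other four.
#' @param efficiency fold change per cycle for [relative_quantities()]
#'   (scalar or per-gene).
#' @param v_cutoff,availability_cutoff geNorm cutoffs, see [genorm()].
#' @param grouping optional per-sample grouping for NormFinder; defaults to
#'   the table annotation.
#' @param layout file layout when `table` is a path.
#' @param drop_incomplete drop samples missing any gene before analysis.
#' @param out_dir directory for the TSV/JSON bundle; `NULL` skips writing.
#' @param quiet suppress progress messages.
#' @return List of class `analysis_bundle` with elements `table`,
#'   `ct_summary`, and one element per requested method, plus `files`
#'   (paths written) and `config`.
#' @export
run_analysis <- function(table,
                         methods = c("delta_ct", "bestkeeper", "genorm",
                                     "normfinder", "reffinder"),
                         efficiency = 2, v_cutoff = 0.15,
                         availability_cutoff = 1.5, grouping = NULL,
                         layout = "long", drop_incomplete = FALSE,
                         out_dir = NULL, quiet = FALSE) {
  known <- c("delta_ct", "bestkeeper", "genorm", "normfinder", "reffinder")
  bad <- setdiff(methods, known)
  if (length(bad) > 0L) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if ("reffinder" %in% methods &&
      !all(c("delta_ct", "bestkeeper", "genorm", "normfinder") %in% methods)) {
    stop("reffinder requires delta_ct, bestkeeper, genorm and normfinder")
  }
  if (is.character(table)) table <- read_ct_table(table, layout = layout)
  if (drop_incomplete) table <- drop_incomplete(table)
  say <- function(...) if (!quiet) message(...)
  config <- list(methods = methods, efficiency = efficiency,
                 v_cutoff = v_cutoff,
                 availability_cutoff = availability_cutoff,
                 drop_incomplete = drop_incomplete)
  out <- list(table = table, ct_summary = summarize_ct_all(table),
              config = config)

  if ("delta_ct" %in% methods) {
    say("delta-Ct stability ...")
    out$delta_ct <- delta_ct_stability(table)
  }
  if ("bestkeeper" %in% methods) {
    say("BestKeeper descriptives ...")
    out$bestkeeper <- bestkeeper(table)
  }
  if ("genorm" %in% methods) {
    say("geNorm stepwise analysis ...")
    out$genorm <- genorm(table, efficiency = efficiency,
                         v_cutoff = v_cutoff,
                         availability_cutoff = availability_cutoff)
  }
  if ("normfinder" %in% methods) {
    say("NormFinder decomposition ...")
    out$normfinder <- normfinder_stability(table, grouping = grouping)
    if (out$normfinder$clamped_fraction > 0) {
      say(sprintf("  note: %.0f%% of intra-group variance estimates clamped",
                  100 * out$normfinder$clamped_fraction))
    }
  }
  if ("reffinder" %in% methods) {
    say("RefFinder aggregation ...")
    out$reffinder <- reffinder(rank_table(out$delta_ct, out$bestkeeper,
                                          out$genorm, out$normfinder))
  }

  if (!is.null(out_dir)) out$files <- write_bundle(out, out_dir)
  class(out) <- "analysis_bundle"
  out
}

write_bundle <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0L)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  wt(fmt_num(out$ct_summary, 3L), "ct_summary.tsv")
  stab_df <- function(res) {
    data.frame(gene = names(res$stability),
               stability = fmt3(res$stability),
               rank = res$rank[names(res$stability)], row.names = NULL)
  }
  if (!is.null(out$delta_ct)) wt(stab_df(out$delta_ct), "delta_ct.tsv")
  if (!is.null(out$bestkeeper)) {
    wt(fmt_num(out$bestkeeper$summary, 3L), "bestkeeper.tsv")
  }
  if (!is.null(out$genorm)) {
    traj <- out$genorm$m_trajectory
    traj$m <- fmt3(traj$m)
    wt(traj, "genorm_m.tsv")
    wt(data.frame(n = names(out$genorm$v_series),
                  v = fmt3(out$genorm$v_series), row.names = NULL),
       "v_series.tsv")
  }
  if (!is.null(out$normfinder)) wt(stab_df(out$normfinder), "normfinder.tsv")
  if (!is.null(out$reffinder)) {
    rk <- out$reffinder$ranks
    wt(data.frame(gene = colnames(rk),
                  delta_ct_rank = rk["delta_ct", ],
                  bestkeeper_rank = rk["bestkeeper", ],
                  genorm_rank = rk["genorm", ],
                  normfinder_rank = rk["normfinder", ],
                  geomean = fmt3(out$reffinder$stability),
                  final_rank = out$reffinder$rank, row.names = NULL),
       "aggregate.tsv")
  }
  summary_json <- file.path(out_dir, "summary.json")
  methods_run <- intersect(c("delta_ct", "bestkeeper", "genorm",
                             "normfinder", "reffinder"), names(out))
  js <- list(config = out$config[setdiff(names(out$config), "methods")],
             methods = methods_run,
             genes = out$table$genes,
             n_samples = nrow(out$table$samples))
  if (!is.null(out$genorm)) {
    js$genorm_optimal_n <- out$genorm$optimal$n
    js$genorm_all_available <- all(out$genorm$available)
  }
  jsonlite::write_json(js, summary_json, auto_unbox = TRUE, pretty = TRUE)
  c(files, summary_json)
}

fmt3 <- function(x) formatC(round_half_up(x, 3L), format = "f", digits = 3L)

fmt_num <- function(df, digits) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(v)
    formatC(round_half_up(v, digits), format = "f", digits = digits))
  df
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("analysis bundle:", length(x$table$genes), "genes,",
      nrow(x$table$samples), "samples\n")
  for (m in intersect(c("delta_ct", "bestkeeper", "genorm", "normfinder",
                        "reffinder"), names(x))) {
    if (inherits(x[[m]], "stability_result") &&
        !inherits(x[[m]], "bestkeeper_result")) print(x[[m]])
    else print(x[[m]])
  }
  invisible(x)
}

#' Multi-condition analysis with cross-condition rank averaging
#'
#' Runs [run_analysis()] per experimental condition, then averages each
#' method's per-condition ranks across conditions ([average_ranking()]) and,
#' if requested, recomputes the averages with conditions excluded
#' ([exclusion_sensitivity()]).
#'
#' @param tables named list of [ct_table()]s (or paths), one per condition;
#'   all must share the same gene set.
#' @param exclude condition names for the exclusion-sensitivity reanalysis
#'   (default none).
#' @param out_dir directory; per-condition bundles go to subdirectories,
#'   cross-condition tables to the top level. `NULL` skips writing.
#' @param ... passed to [run_analysis()].
#' @return List of class `multi_condition_result`: `conditions` (bundles),
#'   `average` (per method, an [average_ranking()]), `sensitivity` (per
#'   method, when `exclude` is non-empty), `files`.
#' @export
run_multi_condition <- function(tables, exclude = character(0L),
                                out_dir = NULL, ...) {
  if (length(tables) < 1L) stop("need at least one condition")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("conditions must be named")
  }
  bundles <- lapply(names(tables), function(cond) {
    run_analysis(tables[[cond]],
                 out_dir = if (is.null(out_dir)) NULL
                           else file.path(out_dir, cond), ...)
  })
  names(bundles) <- names(tables)
  gene_sets <- lapply(bundles, function(b) b$table$genes)
  for (gs in gene_sets[-1L]) {
    if (!setequal(gs, gene_sets[[1L]])) {
      stop("gene sets differ across conditions")
    }
  }
  methods_run <- intersect(c("delta_ct", "bestkeeper", "genorm",
                             "normfinder", "reffinder"), names(bundles[[1L]]))
  rank_of <- function(b, m) {
    if (m == "bestkeeper") {
      stats::setNames(b$bestkeeper$summary$rank, b$bestkeeper$summary$gene)
    } else b[[m]]$rank
  }
  average <- lapply(methods_run, function(m) {
    average_ranking(lapply(bundles, rank_of, m = m))
  })
  names(average) <- methods_run
  sensitivity <- NULL
  if (length(exclude) > 0L) {
    sensitivity <- lapply(methods_run, function(m) {
      exclusion_sensitivity(lapply(bundles, rank_of, m = m),
                            exclude = exclude)
    })
    names(sensitivity) <- methods_run
  }
  files <- character(0L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    avg_df <- do.call(rbind, lapply(methods_run, function(m) {
      a <- average[[m]]
      data.frame(method = m, gene = names(a$mean_rank),
                 mean_rank = formatC(a$printed, format = "f", digits = 2L),
                 row.names = NULL)
    }))
    path <- file.path(out_dir, "average_ranking.tsv")
    utils::write.table(avg_df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- path
    if (!is.null(sensitivity)) {
      sens_df <- do.call(rbind, lapply(methods_run, function(m) {
        s <- sensitivity[[m]]$shift
        cbind(method = m, fmt_num(s, 2L))
      }))
      path <- file.path(out_dir, "sensitivity.tsv")
      utils::write.table(sens_df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, path)
    }
  }
  structure(list(conditions = bundles, average = average,
                 sensitivity = sensitivity, files = files),
            class = "multi_condition_result")
}
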