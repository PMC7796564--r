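# End-to-end orchestration: simulate a bundle to disk, read a flat run
# configuration, run the full protocol, write artifacts with a manifest.

#' Write a synthetic bundle to a directory
#'
#' Emits one observation-table CSV per expression block, the descriptor
#' matrix, the label table, a ground-truth file and a metadata JSON-like
#' text file recording the configuration (including the seed).  Re-running
#' with the same configuration reproduces the files byte-identically.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @param null use [synth_null_replicates()] instead of [synth_generate()].
#' @return invisibly, the bundle.
#' @export
simulate_to_dir <- function(config = synth_config(), dir, null = FALSE) {
  bundle <- if (null) synth_null_replicates(config) else synth_generate(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in names(bundle$blocks))
    write_observation_table(bundle$blocks[[b]],
                            file.path(dir, paste0("block_", b, ".csv")))
  write_compound_matrix(bundle$descriptors, file.path(dir, "descriptors.csv"))
  write_label_table(bundle$labels, file.path(dir, "labels.csv"))
  gt <- data.frame(
    block = rep(names(bundle$ground_truth),
                lengths(bundle$ground_truth)),
    feature = unlist(bundle$ground_truth, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(gt, file.path(dir, "ground_truth.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  cfg <- bundle$config
  meta <- vapply(names(cfg), function(k)
    sprintf("%s = %s", k, paste(format(cfg[[k]], digits = 15), collapse = " ")),
    character(1))
  writeLines(c("# synthetic bundle metadata", meta),
             file.path(dir, "metadata.txt"))
  invisible(bundle)
}

#' Read a flat key-value run configuration
#'
#' Lines of the form `key = value` (comments start with `#`); values are
#' split on whitespace and converted to numeric where possible.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- strsplit(trimws(kv[2]), "[[:space:]]+")[[1]]
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (anyNA(num)) val else num
  }
  out
}

#' Run the full DILI modelling protocol
#'
#' Orchestrates: representative-sample selection per block, label
#' aggregation, block alignment, nested super-learner evaluation, and
#' risk-category enrichment from the external out-of-fold predictions.
#' Optionally writes all artifacts (metrics JSON-like summary, per-compound
#' predictions, enrichment table) plus a manifest with MD5 checksums.
#'
#' @param bundle a `synth_bundle`, or a list with elements `blocks` (named
#'   list of observation tables or compound matrices), `descriptors`,
#'   `labels` (four-class table).
#' @param scheme label-aggregation scheme (1..5).
#' @param kinds combiner kinds to evaluate.
#' @param external_k,external_repeats,internal_k,internal_repeats CV
#'   geometry, as in [nested_evaluate()].
#' @param expr_filter,chem_filter,model_spec protocol components.
#' @param seed master seed.
#' @param out_dir optional output directory for artifacts.
#' @return list of class `dili_report`: the `sl_evaluation`, the enrichment
#'   tables per kind, the aligned data dimensions, and the configuration.
#' @export
run_pipeline <- function(bundle, scheme = 5L,
                         kinds = c("best_single", "mean_all", "mean_top5",
                                   "nn_linear", "rf_stacker"),
                         external_k = 10L, external_repeats = 5L,
                         internal_k = 5L, internal_repeats = 2L,
                         expr_filter = filter_spec("info1d"),
                         chem_filter = filter_spec("welch"),
                         model_spec = rf_spec(), seed = 1L,
                         out_dir = NULL) {
  blocks <- lapply(bundle$blocks, function(b) {
    if (is.data.frame(b)) select_representative(b) else b
  })
  bl <- aggregate_labels(bundle$labels, scheme)
  al <- align_blocks(c(blocks, list(bundle$descriptors)), bl)
  chem <- al$blocks[[length(al$blocks)]]
  blocks <- al$blocks[-length(al$blocks)]
  names(blocks) <- names(bundle$blocks)
  y <- al$y
  ev <- nested_evaluate(blocks, chem, y, kinds, external_k, external_repeats,
                        internal_k, internal_repeats,
                        expr_filter = expr_filter, chem_filter = chem_filter,
                        model_spec = model_spec, seed = seed)
  cls4 <- bundle$labels$dili_class[match(al$compound_ids,
                                         bundle$labels$compound_id)]
  enr <- lapply(kinds, function(k)
    enrichment(ev$predictions[, k], cls4, al$compound_ids))
  names(enr) <- kinds
  report <- structure(list(evaluation = ev, enrichment = enr,
                           n_compounds = length(y), n_blocks = length(blocks),
                           scheme = scheme, seed = seed),
                      class = "dili_report")
  if (!is.null(out_dir)) write_report(report, ev, out_dir)
  report
}

write_report <- function(report, ev, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(out_dir, "predictions.csv")
  utils::write.csv(data.frame(compound_id = rownames(ev$predictions),
                              ev$predictions, check.names = FALSE),
                   f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "external_auc.csv")
  utils::write.csv(ev$external_auc, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  for (k in names(report$enrichment)) {
    f <- file.path(out_dir, paste0("enrichment_", k, ".csv"))
    utils::write.csv(report$enrichment[[k]], f, row.names = FALSE,
                     quote = FALSE)
    files <- c(files, f)
  }
  summ <- c(
    sprintf('"n_compounds": %d', report$n_compounds),
    sprintf('"n_blocks": %d', report$n_blocks),
    sprintf('"scheme": %d', report$scheme),
    sprintf('"seed": %d', report$seed),
    vapply(colnames(ev$external_auc), function(k)
      sprintf('"external_auc_%s": %.6f', k, mean(ev$external_auc[, k])),
      character(1)))
  f <- file.path(out_dir, "summary.json")
  writeLines(c("{", paste0("  ", summ, c(rep(",", length(summ) - 1), "")),
               "}"), f)
  files <- c(files, f)
  sums <- tools::md5sum(files)
  utils::write.table(data.frame(file = basename(files), md5 = unname(sums)),
                     file.path(out_dir, "MANIFEST.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(files)
}

#' @export
print.dili_report <- function(x, ...) {
  cat(sprintf("DILI pipeline report: %d compounds, %d blocks, scheme %d\n",
              x$n_compounds, x$n_blocks, x$scheme))
  print(x$evaluation)
  best <- names(which.max(colMeans(x$evaluation$external_auc)))
  cat(sprintf("Enrichment (%s combiner):\n", best))
  print(transform(x$enrichment[[best]],
                  prevalence_low = round(prevalence_low, 3),
                  prevalence_high = round(prevalence_high, 3),
                  enrichment = round(enrichment, 2)), row.names = FALSE)
  invisible(x)
}
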