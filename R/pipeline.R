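#' Configuration for the end-to-end recognition experiment
#'
#' @param train_per_class Documents per class used for training in each
#'   split (default 30).
#' @param n_runs Number of repeated random splits averaged (default 5).
#' @param L Block size in pixels (default 8; must divide the image size).
#' @param M Vocabulary size (default 60).
#' @param flow A [flow_config()].
#' @param em An [em_config()].
#' @param codebook_subset Maximum descriptors used for codebook training.
#' @param codebook_restarts k-means restarts per codebook.
#' @param descriptor_mode `"rectified4"` or `"raw2"`; see
#'   [extract_block_descriptors()].
#' @param seed Master seed; run r uses seed + r.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(train_per_class = 30L,
                              n_runs = 5L,
                              L = 8L,
                              M = 60L,
                              flow = flow_config(),
                              em = em_config(),
                              codebook_subset = 10000L,
                              codebook_restarts = 3L,
                              descriptor_mode = c("rectified4", "raw2"),
                              seed = 1L) {
  descriptor_mode <- match.arg(descriptor_mode)
  stopifnot(train_per_class >= 1L, n_runs >= 1L, L >= 1L, M >= 2L,
            inherits(flow, "flow_config"), inherits(em, "em_config"))
  structure(
    list(train_per_class = as.integer(train_per_class),
         n_runs = as.integer(n_runs), L = as.integer(L), M = as.integer(M),
         flow = flow, em = em,
         codebook_subset = as.integer(codebook_subset),
         codebook_restarts = as.integer(codebook_restarts),
         descriptor_mode = descriptor_mode,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Stratified random train/test split
#'
#' Draws exactly `train_per_class` rows per class into the training set
#' (seeded, without replacement); the rest form the test set. The two parts
#' are disjoint and exhaustive.
#'
#' @param data A data frame with a `label` column.
#' @param train_per_class Training rows per class; must be strictly smaller
#'   than every class's size (the test set may not be empty).
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_dataset <- function(data, train_per_class, seed = 1L) {
  data <- tibble::as_tibble(data)
  if (!"label" %in% names(data)) {
    stop("`data` must have a `label` column", call. = FALSE)
  }
  sizes <- table(data$label)
  if (any(sizes <= train_per_class)) {
    stop(sprintf(paste0("every class needs more than train_per_class = %d ",
                        "rows (smallest class has %d)"),
                 train_per_class, min(sizes)), call. = FALSE)
  }
  idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(data)), data$label), function(rows) {
      sample(rows, train_per_class)
    }), use.names = FALSE)
  })
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(nrow(data)), idx), , drop = FALSE])
}

#' Row-normalized confusion matrix
#'
#' Entry (a, b) is the fraction of class-a items predicted as class b; rows
#' with no support are left all-zero and reported in the
#' `"zero_support"` attribute.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param classes Class levels in display order (default: the pain classes).
#' @return K x K numeric matrix with class dimnames.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             classes = pain_classes) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  bad <- setdiff(unique(c(as.character(true_labels),
                          as.character(predicted_labels))), classes)
  if (length(bad)) {
    stop("labels outside the class set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  t_f <- factor(true_labels, levels = classes)
  p_f <- factor(predicted_labels, levels = classes)
  cm <- unclass(table(t_f, p_f))
  dimnames(cm) <- list(true = classes, predicted = classes)
  support <- rowSums(cm)
  out <- cm / pmax(support, 1L)
  attr(out, "zero_support") <- classes[support == 0]
  out
}

# Flatten a dataset into per-document flow channels plus a document table.
# One document per consecutive frame pair; sequence labels propagate to
# their documents.
dataset_documents <- function(dataset, flow_cfg) {
  man <- dataset_manifest(dataset)
  channels <- list()
  doc_seq <- integer(0)
  for (i in seq_along(dataset)) {
    ch <- sequence_flow_channels(dataset[[i]], flow_cfg)
    channels <- c(channels, ch)
    doc_seq <- c(doc_seq, rep.int(i, length(ch)))
  }
  docs <- tibble::tibble(
    doc_id = sprintf("%s_p%02d", man$sequence_id[doc_seq],
                     stats::ave(doc_seq, doc_seq, FUN = seq_along)),
    sequence = doc_seq,
    label = man$class[doc_seq]
  )
  list(docs = docs, channels = channels)
}

#' Run the full recognition experiment with repeated random splits
#'
#' Reproduces the evaluation protocol end to end: motion channels are
#' computed once per document (one document per consecutive frame pair);
#' then, for each of `n_runs` seeded splits, a codebook is built by k-means
#' on training-set blocks only, all documents are encoded against it, the
#' supervised pLSA model is trained on the training histograms, the test
#' histograms are classified by fold-in, and a row-normalized confusion
#' matrix is recorded. Splits are stratified at the sequence level so frames
#' of one sequence never straddle the train/test boundary.
#'
#' @param dataset A `pain_dataset` (e.g. from [generate_dataset()]).
#' @param config An [experiment_config()].
#' @return A `painflow_eval`: list with `per_run` (tibble: run, seed,
#'   accuracy, em_iterations), `confusions` (list of per-run confusion
#'   matrices), `codebooks` (list of per-run `flow_codebook`s, fitted on
#'   training data only), `mean_confusion`, `mean_accuracy`, `config`.
#' @export
run_experiment <- function(dataset, config = experiment_config()) {
  stopifnot(inherits(dataset, "pain_dataset"),
            inherits(config, "experiment_config"))
  size <- nrow(dataset[[1]]$frames)
  if (size %% config$L != 0L) {
    stop(sprintf("block size L = %d must divide the image size %d",
                 config$L, size), call. = FALSE)
  }
  flat <- dataset_documents(dataset, config$flow)
  seq_tbl <- dataset_manifest(dataset) |>
    dplyr::mutate(sequence = dplyr::row_number()) |>
    dplyr::select("sequence", label = "class")
  # Descriptors depend only on (channels, L, mode): compute once, reuse
  # across runs.
  desc <- lapply(flat$channels, extract_block_descriptors,
                 L = config$L, mode = config$descriptor_mode)
  classes <- sort(unique(flat$docs$label))

  runs <- vector("list", config$n_runs)
  confusions <- vector("list", config$n_runs)
  codebooks <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    run_seed <- config$seed + r
    parts <- split_dataset(seq_tbl, config$train_per_class, seed = run_seed)
    in_train <- flat$docs$sequence %in% parts$train$sequence
    train_desc <- do.call(rbind, desc[in_train])
    codebook <- build_codebook(train_desc, config$M, seed = run_seed,
                               subset_size = config$codebook_subset,
                               n_restarts = config$codebook_restarts,
                               L = config$L, mode = config$descriptor_mode)
    assign_counts <- function(which_docs) {
      t(vapply(desc[which_docs], function(d) {
        tabulate(quantize(d, codebook), nbins = config$M)
      }, integer(config$M)))
    }
    em_cfg <- config$em
    em_cfg$seed <- child_seed(run_seed, 1L, salt = 29L)
    train_dtm <- flow_dtm(assign_counts(which(in_train)),
                          labels = factor(flat$docs$label[in_train],
                                          levels = classes),
                          doc_ids = flat$docs$doc_id[in_train])
    model <- splsa_train(train_dtm, em_cfg)
    test_idx <- which(!in_train)
    test_counts <- assign_counts(test_idx)
    preds <- apply(test_counts, 1L, splsa_classify, model = model,
                   config = em_cfg)
    truth <- flat$docs$label[test_idx]
    cm <- confusion_matrix(truth, preds, classes)
    confusions[[r]] <- cm
    codebooks[[r]] <- codebook
    runs[[r]] <- tibble::tibble(
      run = r, seed = run_seed,
      accuracy = mean(diag(cm)[!(classes %in% attr(cm, "zero_support"))]),
      em_iterations = model$n_iter
    )
  }
  per_run <- dplyr::bind_rows(runs)
  mean_cm <- Reduce(`+`, confusions) / length(confusions)
  attr(mean_cm, "zero_support") <- NULL
  structure(
    list(per_run = per_run,
         confusions = confusions,
         codebooks = codebooks,
         mean_confusion = mean_cm,
         mean_accuracy = mean(per_run$accuracy),
         config = config),
    class = "painflow_eval"
  )
}

#' @export
print.painflow_eval <- function(x, ...) {
  cat(sprintf("<painflow_eval> %d runs, mean accuracy %.3f\n",
              nrow(x$per_run), x$mean_accuracy))
  cat("mean confusion matrix (rows = true class):\n")
  print(round(x$mean_confusion, 3))
  invisible(x)
}

#' @describeIn run_experiment Per-run accuracies as a tibble.
#' @param x A `painflow_eval`.
#' @param ... Unused.
#' @export
tidy.painflow_eval <- function(x, ...) {
  x$per_run
}

#' @describeIn run_experiment One-row summary: runs, mean and standard
#'   deviation of accuracy, per-class mean recalls.
#' @export
glance.painflow_eval <- function(x, ...) {
  recalls <- diag(x$mean_confusion)
  out <- tibble::tibble(
    n_runs = nrow(x$per_run),
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = stats::sd(x$per_run$accuracy)
  )
  for (cl in colnames(x$mean_confusion)) {
    out[[paste0("recall_", cl)]] <- recalls[[cl]]
  }
  out
}

#' Sweep one hyperparameter of the experiment
#'
#' Re-runs the full repeated-split experiment for every candidate value of
#' the block size `L` or vocabulary size `M`, sharing the base seed so runs
#' are comparable.
#'
#' @param dataset A `pain_dataset`.
#' @param config Base [experiment_config()].
#' @param parameter `"L"` or `"M"`.
#' @param values Candidate values; every `L` must divide the image size.
#' @return A `painflow_sweep` tibble: `parameter`, `value`,
#'   `mean_accuracy`, `sd_accuracy`.
#' @export
sweep_hyperparameter <- function(dataset, config, parameter = c("L", "M"),
                                 values) {
  parameter <- match.arg(parameter)
  stopifnot(length(values) >= 1L)
  size <- nrow(dataset[[1]]$frames)
  if (parameter == "L" && any(size %% values != 0L)) {
    stop(sprintf("all L values must divide the image size %d (offending: %s)",
                 size, paste(values[size %% values != 0L], collapse = ", ")),
         call. = FALSE)
  }
  rows <- lapply(values, function(v) {
    cfg <- config
    cfg[[parameter]] <- as.integer(v)
    ev <- run_experiment(dataset, cfg)
    tibble::tibble(parameter = parameter, value = v,
                   mean_accuracy = ev$mean_accuracy,
                   sd_accuracy = stats::sd(ev$per_run$accuracy))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("painflow_sweep", class(out))
  out
}

#' Export an evaluation report to disk
#'
#' Writes `report.json` (per-run accuracies, mean accuracy, config) and one
#' CSV per confusion matrix plus the averaged matrix.
#'
#' @param report A `painflow_eval`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "painflow_eval"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  jsonlite::write_json(
    list(per_run = report$per_run,
         mean_accuracy = report$mean_accuracy,
         config = list(train_per_class = cfg$train_per_class,
                       n_runs = cfg$n_runs, L = cfg$L, M = cfg$M,
                       seed = cfg$seed,
                       descriptor_mode = cfg$descriptor_mode)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write_cm <- function(cm, path) {
    readr::write_csv(tibble::as_tibble(as.data.frame.matrix(cm),
                                       rownames = "true"), path)
  }
  for (r in seq_along(report$confusions)) {
    write_cm(report$confusions[[r]],
             file.path(dir, sprintf("confusion_run%d.csv", r)))
  }
  write_cm(report$mean_confusion, file.path(dir, "confusion_mean.csv"))
  invisible(dir)
}
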