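is_tag_level <- function(docs) {
  tokens <- unlist(strsplit(gsub("\\.", " ", docs[[1]]$text), "[[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  length(tokens) > 0L && all(grepl("^[A-Z]+$", tokens))
}

#' Run the full triage workflow on a labelled corpus
#'
#' Tagging, vocabulary building (training documents only), descriptor
#' vectorisation, balanced shuffle-and-slice splits, bagged ensemble
#' training with early stopping, and evaluation of the aggregated
#' predictions on all three sets.
#'
#' @param docs list of labelled `glyco_raw_doc` (e.g. from [read_corpus()]
#'   or [generate_corpus()]); every document must carry a
#'   positive/negative label.
#' @param lexicons lexicons used for tagging; ignored for tag-level corpora
#'   (see `tagger`).
#' @param h training hyperparameters.
#' @param n_models ensemble size.
#' @param min_count vocabulary occurrence threshold.
#' @param fractions,balance_tol split settings (see [make_splits()]).
#' @param z,threshold aggregation settings (see [decide()]).
#' @param seed master seed; all stage seeds derive from it.
#' @param tagger `"auto"` (default), `"lexicon"` ([process_document()]) or
#'   `"tag_level"` ([parse_tag_document()]); auto inspects the first
#'   document.
#' @param out_dir optional directory; when given, the split manifest,
#'   vocabulary, model container, per-document predictions CSV and metrics
#'   JSON are written there.
#' @return list with `metrics` (per set), `ensemble`, `vocab`, `splits`,
#'   `predictions` (validation-set decisions).
#' @export
run_pipeline <- function(docs, lexicons = default_lexicons(),
                         h = nn_hyperparams(), n_models = 5L,
                         min_count = 4L, fractions = c(0.5, 0.25, 0.25),
                         balance_tol = 0.01, z = 1.96, threshold = 0.5,
                         seed = NULL,
                         tagger = c("auto", "lexicon", "tag_level"),
                         out_dir = NULL) {
  tagger <- match.arg(tagger)
  labels <- vapply(docs, `[[`, character(1), "label")
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  if (any(!labels %in% c("positive", "negative")))
    stop("all documents must be labelled positive/negative", call. = FALSE)
  if (tagger == "auto")
    tagger <- if (is_tag_level(docs)) "tag_level" else "lexicon"
  tagged <- if (tagger == "tag_level") lapply(docs, parse_tag_document)
            else lapply(docs, process_document, lexicons = lexicons)
  names(tagged) <- ids
  seeds <- derive_seeds(seed, 2L)
  splits <- make_splits(ids, labels, fractions = fractions,
                        balance_tol = balance_tol, seed = seeds[[1]])
  vocab <- build_vocabulary(tagged[splits$train$doc_id], min_count)
  xs <- lapply(splits, function(s) vectorize_corpus(tagged[s$doc_id], vocab))
  ys <- lapply(splits, function(s) encode_labels(s$label))
  ens <- train_ensemble(xs$train, ys$train, xs$test, ys$test,
                        h = h, n_models = n_models, seed = seeds[[2]])
  metrics <- lapply(names(splits), function(s)
    evaluate_ensemble(ens, xs[[s]], splits[[s]]$label,
                      z = z, threshold = threshold))
  names(metrics) <- names(splits)
  preds <- decide(predict(ens, xs$validation, z = z),
                  truth = splits$validation$label, threshold = threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_split_manifest(splits, file.path(out_dir, "splits.csv"))
    write_vocabulary(vocab, file.path(out_dir, "vocabulary.txt"))
    write_ensemble(ens, file.path(out_dir, "ensemble.json"))
    utils::write.csv(preds[, c("doc_id", "p_hat", "ci_low", "ci_high",
                               "call", "outcome")],
                     file.path(out_dir, "predictions.csv"), row.names = FALSE)
    jsonlite::write_json(c(list(seed = seed), metrics),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(metrics = metrics, ensemble = ens, vocab = vocab, splits = splits,
       predictions = preds)
}
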