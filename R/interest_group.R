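# Sentence-level interest-group classification.  Five mutually exclusive
# author categories: patient (PA), caregiver (CG), patient's association
# (PAA), scientific or medical community (SC), other (O).  The few-shot
# design embeds sentences and trains a multinomial linear head on the
# embeddings; a contrastive Siamese adaptation of the embedder is an
# optional plugin step and is skipped for the deterministic reference
# embedder.

#' The interest-group label inventory, in fixed (tie-break) order
#' @return `c("PA", "CG", "PAA", "SC", "O")`.
#' @export
interest_group_labels <- function() c("PA", "CG", "PAA", "SC", "O")

#' Train the interest-group classifier
#'
#' Embeds the training sentences and fits a multinomial logistic
#' classification head (a convex problem, zero-initialized, hence
#' deterministic under a fixed seed and embedder).  The optional `adapter`
#' hook receives `(embedder, data, seed)` and may return a contrastively
#' fine-tuned embedder with the same contract; by default no adaptation
#' happens.
#'
#' @param data Tibble with columns `text` and `label` (labels from
#'   [interest_group_labels()]).
#' @param embedder Embedding backend; defaults to
#'   [reference_embedding_backend()].
#' @param seed Integer seed recorded in the model and used by adapters.
#' @param decay L2 weight decay of the head.
#' @param adapter Optional embedder-adaptation function.
#' @return A `interest_group_model` object.
#' @export
train_interest_classifier <- function(data,
                                      embedder = reference_embedding_backend(),
                                      seed = 13L, decay = 1e-4,
                                      adapter = NULL) {
  if (nrow(data) == 0) {
    abort_pl("empty training set", class = "patientlens_config_error")
  }
  bad <- setdiff(unique(data$label), interest_group_labels())
  if (length(bad)) {
    abort_pl(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")),
             class = "patientlens_config_error")
  }
  present <- interest_group_labels()[interest_group_labels() %in%
                                       unique(data$label)]
  if (length(present) < 2) {
    abort_pl("training set must contain at least two labels",
             class = "patientlens_config_error")
  }
  if (!is.null(adapter)) {
    embedder <- adapter(embedder, data, seed)
  }
  x <- embed_sentences(data$text, embedder)
  colnames(x) <- paste0("e", seq_len(ncol(x)))
  y <- factor(data$label, levels = present)
  df <- data.frame(.label = y, x, check.names = FALSE)
  n_wts <- (ncol(x) + 1L) * (length(present) + 1L)
  withr::with_seed(seed, {
    head_fit <- nnet::multinom(
      .label ~ ., data = df, trace = FALSE, maxit = 300,
      MaxNWts = max(10000, n_wts + 10), decay = decay)
  })
  structure(
    list(head = head_fit, embedder = embedder, labels = present,
         label_order = interest_group_labels(), seed = seed),
    class = "interest_group_model")
}

#' Predict interest groups for sentences
#'
#' @param texts Character vector of sentence texts.
#' @param model A trained `interest_group_model`.
#' @return Tibble with `label` (argmax; probability ties break by the
#'   fixed label order) and one `p_<label>` column per label in
#'   [interest_group_labels()] (labels unseen in training get probability
#'   0); each probability row sums to 1.
#' @export
predict_interest_group <- function(texts, model) {
  all_labels <- model$label_order
  if (length(texts) == 0) {
    out <- tibble::tibble(label = character())
    for (l in all_labels) out[[paste0("p_", l)]] <- numeric()
    return(out)
  }
  x <- embed_sentences(texts, model$embedder)
  colnames(x) <- paste0("e", seq_len(ncol(x)))
  probs <- predict(model$head, newdata = as.data.frame(x), type = "probs")
  if (is.null(dim(probs))) {  # two-class fit returns P(second level)
    probs <- cbind(1 - probs, probs)
    colnames(probs) <- model$labels
  }
  probs <- matrix(probs, nrow = length(texts),
                  dimnames = list(NULL, model$labels))
  full <- matrix(0, nrow = length(texts), ncol = length(all_labels),
                 dimnames = list(NULL, all_labels))
  full[, model$labels] <- probs[, model$labels]
  full <- full / rowSums(full)
  label <- all_labels[apply(full, 1, which.max)]
  out <- tibble::tibble(label = label)
  for (l in all_labels) out[[paste0("p_", l)]] <- unname(full[, l])
  out
}

#' Aggregate sentence labels into a post-level label set
#'
#' Sentence-level classification yields a multi-label view of the post:
#' the union of its non-`O` sentence labels.  `O` absorbs uninformative
#' sentences, so it only survives when every sentence is `O`.
#' Idempotent and order-insensitive.
#'
#' @param labels Character vector of sentence labels of one post.
#' @return Character vector of post labels (sorted in the fixed label
#'   order); empty input gives an empty set.
#' @export
#' @examples
#' aggregate_post_labels(c("PA", "O", "PA"))
#' aggregate_post_labels(c("CG", "PA"))
aggregate_post_labels <- function(labels) {
  if (length(labels) == 0) return(character(0))
  keep <- unique(labels[labels != "O"])
  if (length(keep) == 0) return("O")
  keep[order(match(keep, interest_group_labels()))]
}

#' Evaluate classifier predictions
#'
#' Standard per-label precision, recall and F1 on the percent scale, plus
#' accuracy and the macro (unweighted over labels with nonzero gold
#' support) and weighted (gold-support-weighted) averages.  Values are
#' unrounded; the print method rounds to two decimals.
#'
#' @param gold,predicted Equal-length character vectors of labels.
#' @param labels Label inventory.
#' @return An `interest_group_eval` object: `per_label` tibble
#'   (`label`, `precision`, `recall`, `f1`, `support`), `accuracy`,
#'   `macro` and `weighted` (each `precision`/`recall`/`f1`), `n`.
#' @export
evaluate_classifier <- function(gold, predicted,
                                labels = interest_group_labels()) {
  if (length(gold) != length(predicted)) {
    abort_pl("gold and predicted must have equal length",
             class = "patientlens_contract_error")
  }
  bad <- setdiff(unique(c(gold, predicted)), labels)
  if (length(bad)) {
    abort_pl(sprintf("label(s) outside the inventory: %s",
                     paste(bad, collapse = ", ")),
             class = "patientlens_contract_error")
  }
  tp <- fp <- fn <- support <- setNames(numeric(length(labels)), labels)
  for (l in labels) {
    tp[[l]] <- sum(gold == l & predicted == l)
    fp[[l]] <- sum(gold != l & predicted == l)
    fn[[l]] <- sum(gold == l & predicted != l)
    support[[l]] <- sum(gold == l)
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp) * 100
  recall <- safe_div(tp, tp + fn) * 100
  f1 <- safe_div(2 * precision * recall, precision + recall)
  supported <- labels[support[labels] > 0]
  macro <- list(precision = mean(precision[supported]),
                recall = mean(recall[supported]),
                f1 = mean(f1[supported]))
  w <- support[supported] / sum(support[supported])
  weighted <- list(precision = sum(w * precision[supported]),
                   recall = sum(w * recall[supported]),
                   f1 = sum(w * f1[supported]))
  structure(list(
    per_label = tibble::tibble(label = labels,
                               precision = unname(precision),
                               recall = unname(recall), f1 = unname(f1),
                               support = unname(as.integer(support))),
    accuracy = mean(gold == predicted) * 100,
    macro = macro, weighted = weighted, n = length(gold)),
    class = "interest_group_eval")
}

#' @export
print.interest_group_eval <- function(x, ...) {
  cat(sprintf("Interest-group evaluation (n = %d)\n", x$n))
  tab <- x$per_label
  tab$precision <- round(tab$precision, 2)
  tab$recall <- round(tab$recall, 2)
  tab$f1 <- round(tab$f1, 2)
  print(as.data.frame(tab), row.names = FALSE)
  cat(sprintf("accuracy %.2f | macro-F1 %.2f | weighted-F1 %.2f\n",
              x$accuracy, x$macro$f1, x$weighted$f1))
  invisible(x)
}

#' Stratified train/validation/test split
#'
#' Class-proportional split with largest-remainder rounding, reproducible
#' under a fixed seed.
#'
#' @param labels Character vector of labels.
#' @param fractions Named fractions summing to 1; defaults to the
#'   60/20/20 train/validation/test scheme.
#' @param seed Integer seed.
#' @return Character vector assigning each element to a split.
#' @export
split_stratified <- function(labels,
                             fractions = c(train = 0.6, validation = 0.2,
                                           test = 0.2),
                             seed = 13L) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort_pl("split fractions must sum to 1",
             class = "patientlens_config_error")
  }
  out <- character(length(labels))
  withr::with_seed(seed, {
    for (l in unique(labels)) {
      idx <- sample(which(labels == l))
      n <- length(idx)
      counts <- floor(fractions * n)
      rem <- n - sum(counts)
      if (rem > 0) {
        frac_part <- fractions * n - counts
        counts[order(-frac_part)[seq_len(rem)]] <-
          counts[order(-frac_part)[seq_len(rem)]] + 1
      }
      splits <- rep(names(fractions), counts)
      out[idx] <- splits
    }
  })
  out
}
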