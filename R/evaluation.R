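#' Confusion matrix with attached accuracy
#'
#' Rows are true classes, columns predicted classes. `extra_pred_classes`
#' registers predicted-only columns (e.g. the "XX" no-response pattern in
#' behavior scoring); any label outside the registered sets is an error.
#'
#' @param true_labels,pred_labels Equal-length vectors (factors, strings or
#'   integers).
#' @param class_names Ordered class set for the rows (and columns, before any
#'   extras). Defaults to the sorted union of observed labels.
#' @param extra_pred_classes Additional allowed predicted classes (columns).
#' @return A `confusion_matrix`: integer matrix with attributes `accuracy`
#'   and `n`.
#' @export
confusion <- function(true_labels, pred_labels, class_names = NULL,
                      extra_pred_classes = character()) {
  if (length(true_labels) != length(pred_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  true_labels <- as.character(true_labels)
  pred_labels <- as.character(pred_labels)
  if (is.null(class_names)) class_names <- sort(unique(true_labels))
  class_names <- as.character(class_names)
  pred_classes <- c(class_names, setdiff(extra_pred_classes, class_names))
  if (!all(true_labels %in% class_names)) {
    stop("true label outside the class set", call. = FALSE)
  }
  if (!all(pred_labels %in% pred_classes)) {
    stop("predicted label outside the class set", call. = FALSE)
  }
  counts <- table(factor(true_labels, levels = class_names),
                  factor(pred_labels, levels = pred_classes))
  m <- matrix(as.integer(counts), nrow = length(class_names),
              dimnames = list(true = class_names, predicted = pred_classes))
  matched <- sum(diag(m[, class_names, drop = FALSE]))
  structure(m, accuracy = matched / length(true_labels),
            n = length(true_labels), class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  cat(sprintf("accuracy: %.4g%% (n = %d)\n", 100 * attr(x, "accuracy"),
              attr(x, "n")))
  invisible(x)
}

#' Accuracy of a confusion matrix
#' @param x A [confusion()] result.
#' @return Fraction of matched trials in `[0, 1]`.
#' @export
accuracy <- function(x) attr(x, "accuracy")

#' Write a confusion matrix as TSV
#' @param x A [confusion()] result.
#' @param path Output file.
#' @export
write_confusion_tsv <- function(x, path) {
  utils::write.table(cbind(true = rownames(x), as.data.frame(unclass(x))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Parameter sweep over re-trained decoders
#'
#' For each grid value a fresh dataset is built and a model trained and
#' evaluated from scratch (no warm starting), repeated over `n_seeds` seeds.
#' Failed runs are recorded, never silently dropped.
#'
#' @param dataset_factory `function(value, seed)` returning whatever
#'   `train_eval_fn` consumes.
#' @param train_eval_fn `function(dataset, seed)` returning a held-out
#'   accuracy in `[0, 1]`.
#' @param parameter Name of the swept parameter (bookkeeping only).
#' @param grid Non-empty vector of parameter values.
#' @param n_seeds Seeds per grid value (default 3). Single-seed sweeps carry
#'   no dispersion and are flagged via the `single_seed` attribute.
#' @return A data.frame (`value`, `mean_acc`, `sd_acc`, `n_ok`) with
#'   attributes `parameter`, `single_seed` and `failures`.
#' @export
sweep_parameter <- function(dataset_factory, train_eval_fn, parameter, grid,
                            n_seeds = 3L) {
  if (length(grid) == 0L) stop("grid must be non-empty", call. = FALSE)
  failures <- list()
  rows <- lapply(seq_along(grid), function(i) {
    accs <- rep(NA_real_, n_seeds)
    for (s in seq_len(n_seeds)) {
      res <- tryCatch(train_eval_fn(dataset_factory(grid[i], s), s),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <<-
          list(value = grid[i], seed = s, message = conditionMessage(res))
      } else {
        accs[s] <- res
      }
    }
    data.frame(value = grid[i], mean_acc = mean(accs, na.rm = TRUE),
               sd_acc = stats::sd(accs[!is.na(accs)]),
               n_ok = sum(!is.na(accs)))
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  attr(out, "single_seed") <- n_seeds == 1L
  attr(out, "failures") <- failures
  out
}

#' Exact t-SNE embedding of decoder features
#'
#' A deterministic (seeded) exact t-distributed stochastic neighbor embedding
#' used to visualize how class features cluster as training progresses.
#' Suitable for the few hundred to few thousand points produced here.
#'
#' @param embeddings Numeric matrix, one row per point.
#' @param seed Integer seed (fully determines the layout).
#' @param perplexity Target perplexity (default 30). Requires at least
#'   `3 * perplexity + 1` points.
#' @param n_iter Gradient-descent iterations (default 500).
#' @return A `nrow(embeddings) x 2` matrix of 2-D coordinates.
#' @export
tsne_embed <- function(embeddings, seed = 1L, perplexity = 30,
                       n_iter = 500L) {
  x <- as.matrix(embeddings)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (n - 1 < 3 * perplexity) {
    stop(sprintf(paste0("perplexity %g too large for %d points; ",
                        "reduce it below (n - 1)/3 = %.1f"),
                 perplexity, n, (n - 1) / 3), call. = FALSE)
  }
  d2 <- as.matrix(stats::dist(x))^2
  # per-point precision search to hit entropy log(perplexity)
  p <- matrix(0, n, n)
  target <- log(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 0; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        pr <- w / sw
        h <- -sum(ifelse(pr > 0, pr * log(pr), 0))
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (lo + beta) / 2 }
    }
    p[i, -i] <- w / max(sum(w), .Machine$double.eps)
  }
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)
  with_seed(seed, {
    y <- matrix(stats::rnorm(n * 2, 0, 1e-4), n, 2)
    gain <- matrix(1, n, 2)
    inc <- matrix(0, n, 2)
    eta <- 200
    for (iter in seq_len(n_iter)) {
      ex <- if (iter <= 100) 4 else 1      # early exaggeration
      momentum <- if (iter <= 250) 0.5 else 0.8
      yd2 <- as.matrix(stats::dist(y))^2
      qnum <- 1 / (1 + yd2)
      diag(qnum) <- 0
      q <- pmax(qnum / sum(qnum), 1e-12)
      stiff <- 4 * (ex * p - q) * qnum
      grad <- (diag(rowSums(stiff)) - stiff) %*% y
      gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
      gain[gain < 0.01] <- 0.01
      inc <- momentum * inc - eta * gain * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
    }
    dimnames(y) <- list(rownames(x), c("x", "y"))
    y
  })
}
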