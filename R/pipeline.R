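#' Run the full classification pipeline
#'
#' Executes the end-to-end chain: texture feature extraction (when images
#' are supplied), ADASYN oversampling, ReliefF feature selection, network
#' training and confusion-matrix evaluation.  Either `images` (with
#' labels in its manifest) or a precomputed feature table `X`/`y` must be
#' given.  Every stage is seeded from the single global `seed` through
#' fixed per-stage offsets, so stages are individually reproducible; the
#' evaluation is computed on the held-out test split of the trained
#' network.
#'
#' @param images optional `texture_dataset` (see [make_texture_dataset()])
#'   or list of [gray_image] objects with `labels`.
#' @param X,y optional feature matrix and labels (used when `images` is
#'   `NULL`).
#' @param labels labels for `images` when it is a bare list.
#' @param oversample apply ADASYN before selection/training (default
#'   `TRUE`).
#' @param beta,K ADASYN balance level and neighbor count.
#' @param relieff_k ReliefF neighbors per class (default 3).
#' @param n_select features kept after ReliefF ranking (default 10).
#' @param hidden network hidden layer sizes (default `c(40, 20, 10)`).
#' @param max_epochs training epoch budget (default 60).
#' @param feature_cfg a [feature_config()] for extraction.
#' @param seed global seed.
#' @param out_dir optional directory for stage outputs (feature CSV,
#'   selected-feature list, report JSON).
#' @param verbose log row counts per stage (default `FALSE`).
#' @return list of class `mammotex_report`: selected feature names,
#'   ReliefF weights, the fitted [lm_mlp] model, test-split confusion
#'   matrix, per-class and pooled metric tables, and row counts per
#'   stage.
#' @export
run_pipeline <- function(images = NULL, X = NULL, y = NULL, labels = NULL,
                         oversample = TRUE, beta = 1, K = 5L,
                         relieff_k = 3L, n_select = 10L,
                         hidden = c(40L, 20L, 10L), max_epochs = 60L,
                         feature_cfg = feature_config(), seed = 1L,
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage_seed <- function(k) (seed + k * 101L) %% .Machine$integer.max
  counts <- list()

  if (!is.null(images)) {
    tab <- feature_table(images, labels = labels, config = feature_cfg)
    if (is.null(tab$label)) stop("image input requires labels")
    y <- tab$label
    X <- as.matrix(tab[setdiff(names(tab), c("label", "path"))])
    say("extracted features: %d images x %d features", nrow(X), ncol(X))
  } else if (is.null(X) || is.null(y)) {
    stop("supply either 'images' or both 'X' and 'y'")
  }
  X <- as.matrix(X)
  counts$extracted <- nrow(X)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(data.frame(X, label = y),
                        file.path(out_dir, "features.csv"))
  }

  if (oversample) {
    bal <- adasyn(X, y, beta = beta, K = K, seed = stage_seed(2L))
    Xb <- bal$X; yb <- bal$y
    say("oversampled: %d -> %d rows", nrow(X), nrow(Xb))
  } else {
    Xb <- X; yb <- y
  }
  counts$balanced <- nrow(Xb)

  w <- relieff_weights(Xb, yb, k = relieff_k)
  keep <- select_top(w, n_select)
  say("selected %d of %d features", length(keep), ncol(Xb))
  counts$selected <- length(keep)
  if (!is.null(out_dir))
    utils::write.csv(
      data.frame(feature = colnames(Xb)[w$ranking],
                 weight = w$weights[w$ranking]),
      file.path(out_dir, "relieff_ranking.csv"), row.names = FALSE)

  fit <- lm_mlp(Xb[, keep, drop = FALSE], yb, hidden = hidden,
                max_epochs = max_epochs, seed = stage_seed(4L))
  te <- fit$split == "test"
  pred <- predict(fit, Xb[te, keep, drop = FALSE])
  cm <- confusion_matrix(yb[te], pred, labels = sort(unique(yb)))
  rep <- classification_report(cm)
  say("test accuracy: %.3f", sum(diag(cm)) / sum(cm))

  out <- structure(list(
    selected = colnames(Xb)[keep], weights = w, model = fit,
    confusion = cm, per_class = rep$per_class, pooled = rep$pooled,
    counts = counts, seed = seed), class = "mammotex_report")
  if (!is.null(out_dir)) {
    json <- list(seed = seed, counts = counts,
                 selected = colnames(Xb)[keep],
                 per_class = rep$per_class, pooled = rep$pooled,
                 confusion = unclass(cm))
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(unclass(cm), file.path(out_dir, "confusion.csv"))
  }
  out
}

#' @export
print.mammotex_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("rows: %d extracted, %d after balancing; %d features kept\n",
              x$counts$extracted, x$counts$balanced, x$counts$selected))
  cat("selected features:", paste(x$selected, collapse = ", "), "\n\n")
  print(x$confusion)
  cat("\npooled metrics (test split):\n")
  print(round(x$pooled, 4))
  invisible(x)
}
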