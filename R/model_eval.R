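#' Spatial block assignment
#'
#' Partitions points into four spatially contiguous rectangular blocks
#' holding similar numbers of points: split at the median latitude
#' (y coordinate), then each half at its own median longitude
#' (x coordinate), giving a 2 x 2 checkerboard.
#'
#' @param x,y Planar point coordinates (training cell centres).
#' @param n_blocks Number of blocks (fixed at 4).
#' @return Object of class `bn_blocks`: list with integer `block`
#'   (1..4 per point) and the split coordinates.
#' @export
make_blocks <- function(x, y, n_blocks = 4) {
  stopifnot(n_blocks == 4)
  n <- length(x)
  if (n < 4 * n_blocks) stop("need at least 16 points for 4 blocks")
  y_split <- stats::median(y)
  south <- y <= y_split
  if (min(sum(south), sum(!south)) < 2)
    stop("points too heavily duplicated to form balanced blocks")
  x_split_s <- stats::median(x[south])
  x_split_n <- stats::median(x[!south])
  block <- integer(n)
  block[south & x <= x_split_s] <- 1L
  block[south & x > x_split_s] <- 2L
  block[!south & x <= x_split_n] <- 3L
  block[!south & x > x_split_n] <- 4L
  share <- tabulate(block, 4) / n
  if (any(share < 0.15) || any(share > 0.35))
    stop("blocks unbalanced (a block holds ",
         sprintf("%.0f%%", 100 * max(share)),
         " of points); coordinates too heavily duplicated")
  structure(list(block = block,
                 splits = list(y = y_split, x_south = x_split_s,
                               x_north = x_split_n)),
            class = "bn_blocks")
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) form with half-credit for ties.
#'
#' @param labels 0/1 vector (both classes present).
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both labels")
  r <- rank(scores) # average ranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a threshold
#'
#' Positive prediction iff `score >= threshold`. Returns sensitivity,
#' specificity, Cohen's kappa and `TSS = sensitivity + specificity - 1`.
#'
#' @param labels 0/1 vector (both classes present).
#' @param scores Numeric scores.
#' @param threshold Binarization cut-off.
#' @return Named list (sensitivity, specificity, kappa, TSS).
#' @export
confusion_metrics <- function(labels, scores, threshold) {
  if (length(unique(labels)) < 2) stop("need both labels")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  n <- length(labels)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (abs(1 - pe) < 1e-15) 0 else (po - pe) / (1 - pe)
  list(sensitivity = sens, specificity = spec, kappa = kappa,
       TSS = sens + spec - 1)
}

#' Ten-percentile training-presence threshold
#'
#' The 10th percentile (type-7 linear interpolation) of the predicted
#' HSI at the training presences; by construction at least 90% of the
#' training presences score at or above it.
#'
#' @param presence_scores HSI at training presences (>= 10 values).
#' @return List (class `bn_threshold`) with `rule = "P10"` and `value`.
#' @export
threshold_p10 <- function(presence_scores) {
  if (length(presence_scores) < 10)
    stop("need at least 10 presence scores")
  structure(list(rule = "P10",
                 value = stats::quantile(presence_scores, 0.10, type = 7,
                                         names = FALSE)),
            class = "bn_threshold")
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Scans candidate thresholds (midpoints between adjacent distinct
#' scores, plus the extremes) and returns the one maximizing
#' `sensitivity + specificity`; ties resolve to the lowest threshold.
#'
#' @param labels 0/1 vector (both classes present).
#' @param scores Numeric scores.
#' @return List (class `bn_threshold`) with `rule = "MSS"` and `value`.
#' @export
threshold_mss <- function(labels, scores) {
  if (length(unique(labels)) < 2) stop("need both labels")
  s <- sort(unique(scores))
  cand <- if (length(s) > 1)
    c(s[1], (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1e-9)
  else s
  best_val <- -Inf; best_thr <- cand[1]
  for (th in cand) {
    m <- confusion_metrics(labels, scores, th)
    v <- m$sensitivity + m$specificity
    if (v > best_val + 1e-12) { best_val <- v; best_thr <- th }
  }
  structure(list(rule = "MSS", value = best_thr), class = "bn_threshold")
}

#' Accuracy class from AUC and TSS
#'
#' Classifies model accuracy as good (AUC > 0.8 and TSS > 0.6),
#' moderate (0.7 <= AUC <= 0.8 and 0.2 <= TSS <= 0.6) or poor
#' (AUC < 0.7 or TSS < 0.2); when the two metrics disagree the worse
#' class wins.
#'
#' @param auc_value AUC in `[0, 1]`.
#' @param tss_value TSS in `[-1, 1]`.
#' @return `"good"`, `"moderate"` or `"poor"`.
#' @export
accuracy_class <- function(auc_value, tss_value) {
  cls_auc <- if (auc_value > 0.8) "good" else if (auc_value >= 0.7)
    "moderate" else "poor"
  cls_tss <- if (tss_value > 0.6) "good" else if (tss_value >= 0.2)
    "moderate" else "poor"
  lev <- c(poor = 1, moderate = 2, good = 3)
  names(lev)[min(lev[cls_auc], lev[cls_tss])]
}

#' Spatially blocked cross-validation of one model family
#'
#' Each iteration draws one of the four blocks as the test area (uniform
#' draws with replacement across iterations), takes a random 80%
#' subsample of the remaining blocks as training data and an 80%
#' subsample of the test block as evaluation data, fits the family,
#' computes both binarization thresholds on the training data (P10 on
#' the training presences, MSS on training labels/scores) and evaluates
#' AUC, kappa, sensitivity, specificity and TSS on the held-out block.
#' Iterations whose test block lacks a label are skipped and logged;
#' more than `max_skips` skips abort.
#'
#' @param family `"MAXENT"`, `"GAM"` or `"RF"`.
#' @param table Training table with `cell_id`, `label`, covariates.
#' @param blocks A `bn_blocks` for the table rows.
#' @param covariates Covariates to fit.
#' @param iterations Number of CV iterations (default 10).
#' @param subsample Fraction of rows drawn per iteration (default 0.80).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param max_skips Maximum tolerated skipped iterations (default 5).
#' @param fit_args Extra arguments for the family fit.
#' @return Object of class `bn_metrics`: `summary` data.frame (metric x
#'   threshold, mean and sd), per-iteration `detail`, mean `auc`, mean
#'   `tss_mss` (TSS at the MSS threshold, used for ensemble weights),
#'   thresholds, and the skip log.
#' @export
cv_run <- function(family, table, blocks,
                   covariates = training_covariates(table),
                   iterations = 10, subsample = 0.80, seed = 1,
                   max_skips = 5, fit_args = list()) {
  stopifnot(length(blocks$block) == nrow(table))
  rows_by_block <- split(seq_len(nrow(table)), blocks$block)
  detail <- list(); skipped <- 0L
  with_seed(stage_seed(seed, paste0("cv-", family)), {
    for (it in seq_len(iterations)) {
      test_block <- sample(1:4, 1)
      train_rows <- unlist(rows_by_block[-test_block], use.names = FALSE)
      test_rows <- rows_by_block[[test_block]]
      train_rows <- sample(train_rows, round(subsample * length(train_rows)))
      test_rows <- sample(test_rows,
                          max(2, round(subsample * length(test_rows))))
      train <- table[train_rows, , drop = FALSE]
      test <- table[test_rows, , drop = FALSE]
      if (length(unique(train$label)) < 2 ||
          length(unique(test$label)) < 2) {
        skipped <- skipped + 1L
        next
      }
      fit <- do.call(fit_sdm, c(list(family, train, covariates,
                                     seed = sample.int(2^30, 1)),
                                fit_args))
      train_scores <- predict_table(fit, train)
      thr <- list(P10 = threshold_p10(train_scores[train$label == 1])$value,
                  MSS = threshold_mss(train$label, train_scores)$value)
      test_scores <- predict_table(fit, test)
      row <- list(iteration = it, test_block = test_block,
                  auc = auc(test$label, test_scores))
      for (rule in names(thr)) {
        m <- confusion_metrics(test$label, test_scores, thr[[rule]])
        for (nm in names(m)) row[[paste0(nm, "_", rule)]] <- m[[nm]]
        row[[paste0("threshold_", rule)]] <- thr[[rule]]
      }
      detail[[length(detail) + 1L]] <- as.data.frame(row)
    }
  })
  if (skipped > max_skips)
    stop(sprintf("cv_run: %d iterations skipped (single-label test blocks)",
                 skipped))
  if (!length(detail)) stop("cv_run: no usable iterations")
  detail <- do.call(rbind, detail)
  mcols <- setdiff(names(detail), c("iteration", "test_block"))
  summary <- data.frame(
    metric = mcols,
    mean = vapply(mcols, function(c) mean(detail[[c]]), numeric(1)),
    sd = vapply(mcols, function(c)
      if (nrow(detail) > 1) stats::sd(detail[[c]]) else 0, numeric(1)),
    row.names = NULL)
  structure(list(family = family, summary = summary, detail = detail,
                 auc = mean(detail$auc), tss_mss = mean(detail$TSS_MSS),
                 skipped = skipped),
            class = "bn_metrics")
}

#' @exportS3Method base::print
print.bn_metrics <- function(x, ...) {
  cat(sprintf("<bn_metrics:%s> blocked CV over %d iterations\n",
              x$family, nrow(x$detail)))
  print(x$summary, digits = 3)
  invisible(x)
}
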