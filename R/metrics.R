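#' Object-level matching of predicted vs ground-truth regions
#'
#' Predicted and true regions are matched greedily, one-to-one, in
#' descending order of pairwise intersection-over-union; a matched pair
#' counts as a true positive when its IoU reaches `iou_match_threshold`.
#' Unmatched predictions are false positives, unmatched truths false
#' negatives.
#'
#' @param pred,truth [labeled_mask()]s of identical dimensions.
#' @param iou_match_threshold Minimum IoU in `(0, 1]` for a pair to count
#'   as a detection (default 0.5).
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
match_objects <- function(pred, truth, iou_match_threshold = 0.5) {
  if (!identical(dim(pred$labels), dim(truth$labels)))
    .stopf("flowseg_dim_mismatch", "pred and truth must share dimensions")
  if (iou_match_threshold <= 0 || iou_match_threshold > 1)
    .stopf("flowseg_invalid_params", "iou_match_threshold must be in (0, 1]")
  np <- max(pred$labels); nt <- max(truth$labels)
  if (np == 0L || nt == 0L)
    return(c(tp = 0L, fp = np, fn = nt))
  # joint histogram of (pred, truth) labels over overlapping pixels
  pl <- pred$labels; tl <- truth$labels
  both <- pl > 0L & tl > 0L
  inter <- matrix(0L, np, nt)
  if (any(both)) {
    tab <- table(pl[both], tl[both])
    inter[cbind(as.integer(rownames(tab))[row(tab)],
                as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
  }
  pa <- tabulate(pl[pl > 0L], np)
  ta <- tabulate(tl[tl > 0L], nt)
  iou <- inter / (outer(pa, ta, "+") - inter)
  # greedy one-to-one in descending IoU; ties broken by (pred, truth) label
  ord <- order(-as.vector(iou), as.vector(row(iou)), as.vector(col(iou)))
  usedp <- logical(np); usedt <- logical(nt); tp <- 0L
  for (k in ord) {
    if (iou[k] < iou_match_threshold) break
    i <- row(iou)[k]; j <- col(iou)[k]
    if (!usedp[i] && !usedt[j]) {
      usedp[i] <- TRUE; usedt[j] <- TRUE; tp <- tp + 1L
    }
  }
  c(tp = tp, fp = np - tp, fn = nt - tp)
}

#' Detection F-score
#'
#' \eqn{F_1 = TP / (TP + (FN + FP)/2)}. A perfectly empty comparison
#' (no objects predicted, none present) scores 1; zero true positives with
#' any error scores 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return F-score in \[0, 1\].
#' @examples
#' f1_score(2, 1, 1)  # 2/3
#' @export
f1_score <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0)
    .stopf("flowseg_invalid_params", "counts must be nonnegative")
  den <- tp + 0.5 * (fn + fp)
  if (den == 0) 1 else tp / den
}

#' Pixel-level Jaccard index
#'
#' \eqn{J(T, S) = |T \cap S| / |T \cup S|} over all pixels of the
#' ground-truth mask T and the segmentation S. Two empty masks score 1.
#'
#' @param truth,pred [binary_mask()]s (or logical matrices) of identical
#'   dimensions; [labeled_mask()]s are accepted and binarized.
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard_index <- function(truth, pred) {
  t <- .as_binary(truth); s <- .as_binary(pred)
  if (!identical(dim(t), dim(s)))
    .stopf("flowseg_dim_mismatch", "masks must share dimensions")
  un <- sum(t | s)
  if (un == 0L) 1 else sum(t & s) / un
}

.as_binary <- function(x) {
  if (inherits(x, "labeled_mask")) return(x$labels > 0L)
  if (inherits(x, "binary_mask") || is.logical(x)) {
    m <- unclass(x); attributes(m) <- list(dim = dim(x)); return(m)
  }
  .stopf("flowseg_invalid_mask", "expected a binary or labeled mask")
}

#' Evaluate a segmentation against ground truth over a whole dataset
#'
#' TP/FP/FN are accumulated over all images with [match_objects()] and the
#' F-score is computed once on the pooled counts (micro-averaging); the
#' Jaccard index is likewise computed on the pooled pixel counts (global
#' intersection over global union).
#'
#' @param preds,truths Equal-length lists of [labeled_mask()]s with
#'   matching dimensions.
#' @inheritParams match_objects
#' @return An `eval_result` with fields `tp`, `fp`, `fn`, `f1`, `jaccard`,
#'   `iou_match_threshold`, `n_images` and a `per_image` tibble.
#' @export
evaluate_dataset <- function(preds, truths, iou_match_threshold = 0.5) {
  if (inherits(preds, "labeled_mask")) preds <- list(preds)
  if (inherits(truths, "labeled_mask")) truths <- list(truths)
  if (length(preds) != length(truths) || length(preds) == 0L)
    .stopf("flowseg_invalid_params",
           "preds and truths must be nonempty lists of equal length")
  tp <- fp <- fn <- 0L
  inter <- un <- 0
  rows <- vector("list", length(preds))
  for (i in seq_along(preds)) {
    m <- match_objects(preds[[i]], truths[[i]], iou_match_threshold)
    tp <- tp + m[["tp"]]; fp <- fp + m[["fp"]]; fn <- fn + m[["fn"]]
    t <- .as_binary(truths[[i]]); s <- .as_binary(preds[[i]])
    inter <- inter + sum(t & s); un <- un + sum(t | s)
    rows[[i]] <- tibble::tibble(
      image = i, tp = m[["tp"]], fp = m[["fp"]], fn = m[["fn"]],
      f1 = f1_score(m[["tp"]], m[["fp"]], m[["fn"]]),
      jaccard = jaccard_index(truths[[i]], preds[[i]]))
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 f1 = f1_score(tp, fp, fn),
                 jaccard = if (un == 0) 1 else inter / un,
                 iou_match_threshold = iou_match_threshold,
                 n_images = length(preds),
                 per_image = dplyr::bind_rows(rows)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> %d image(s): TP %d, FP %d, FN %d | F1 %.3f, Jaccard %.3f (IoU match >= %.2f)\n",
    x$n_images, x$tp, x$fp, x$fn, x$f1, x$jaccard, x$iou_match_threshold))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-image evaluation rows of an `eval_result`
#'
#' @param x An `eval_result` from [evaluate_dataset()].
#' @param ... Unused.
#' @return Tibble with one row per image: counts, F-score and Jaccard.
#' @export
tidy.eval_result <- function(x, ...) x$per_image

#' One-row pooled summary of an `eval_result`
#'
#' @inheritParams tidy.eval_result
#' @return One-row tibble of pooled TP/FP/FN, micro-averaged F-score and
#'   pooled Jaccard.
#' @export
glance.eval_result <- function(x, ...) {
  tibble::tibble(n_images = x$n_images, tp = x$tp, fp = x$fp, fn = x$fn,
                 f1 = x$f1, jaccard = x$jaccard,
                 iou_match_threshold = x$iou_match_threshold)
}

#' @rdname tidy.eval_result
#' @export
tidy.labeled_mask <- function(x, ...) x$regions
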