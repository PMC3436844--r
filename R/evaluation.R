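#' Read a truth table
#'
#' Tab-separated file with columns `query_id`, `target_id` and optionally
#' `identity` (percent identity of the true pair, used for binning). Lines
#' starting with `#` are ignored.
#'
#' @param path TSV file.
#' @return data.frame with those columns.
#' @export
read_truth <- function(path) {
  df <- read.table(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df) <- c("query_id", "target_id", "identity")[seq_len(ncol(df))]
  df
}

#' Precision-recall curve and AUC of one ranked hit list
#'
#' Walks the ranking from the top; at each depth `P`, `TP` is the number of
#' true targets among the first `P` hits, precision is `TP/P` and recall is
#' `TP/T` where `T` is the size of the truth set. The area under the curve
#' is computed as average precision: the mean over true targets of the
#' precision at the rank where each is recovered (a true target never
#' recovered contributes 0). Its maximum value is 1.
#'
#' @param ranked character vector of target ids, best hit first.
#' @param truth character vector (or set) of true target ids; must be
#'   non-empty.
#' @return A `pr_curve`: list with `points` (data.frame `P`, `TP`,
#'   `precision`, `recall`) and `auc`.
#' @export
pr_curve <- function(ranked, truth) {
  truth <- unique(truth)
  if (length(truth) == 0L) stop("empty truth set")
  tp_flag <- ranked %in% truth
  TP <- cumsum(tp_flag)
  P <- seq_along(ranked)
  precision <- if (length(P)) TP / P else numeric(0)
  auc <- if (length(P)) sum(precision[tp_flag]) / length(truth) else 0
  auc <- min(max(auc, 0), 1)
  structure(list(points = data.frame(P = P, TP = TP, precision = precision,
                                     recall = TP / length(truth)),
                 auc = auc),
            class = "pr_curve")
}

#' Mean per-query AUC
#'
#' @param curves list of [pr_curve()] objects, or a numeric vector of AUCs.
#' @return Arithmetic mean of the per-query AUC values.
#' @export
mean_auc <- function(curves) {
  if (is.numeric(curves)) {
    if (length(curves) == 0L) stop("no curves")
    return(mean(curves))
  }
  if (length(curves) == 0L) stop("no curves")
  mean(vapply(curves, `[[`, numeric(1), "auc"))
}

#' Evaluate a hit table against a truth table
#'
#' Computes a per-query precision-recall AUC over the top `top` hits.
#' Queries present in the hit table but absent from the truth table are
#' skipped with a warning.
#'
#' @param hits a `hit_table` (or data.frame with `query_id`, `target_id`,
#'   `rank`).
#' @param truth data.frame from [read_truth()].
#' @param top evaluation depth (hits per query considered).
#' @return list with `per_query` (data.frame `query_id`, `auc`, `n_true`)
#'   and `mean_auc`.
#' @export
evaluate_hits <- function(hits, truth, top = 1000L) {
  tsets <- split(truth$target_id, truth$query_id)
  queries <- unique(hits$query_id)
  known <- queries %in% names(tsets)
  if (any(!known))
    warning(sprintf("%d quer(ies) absent from truth, skipped", sum(!known)))
  queries <- queries[known]
  # also score queries with truth but no hits at all: auc 0
  queries <- union(queries, names(tsets))
  aucs <- vapply(queries, function(qid) {
    h <- hits[hits$query_id == qid, ]
    h <- h[order(h$rank), ]
    pr_curve(head(h$target_id, top), tsets[[qid]])$auc
  }, numeric(1))
  list(per_query = data.frame(query_id = queries, auc = as.numeric(aucs),
                              n_true = lengths(tsets[queries])),
       mean_auc = mean_auc(as.numeric(aucs)))
}

bin_label <- function(identity, bins) {
  edges <- c(-Inf, bins, Inf)
  labels <- c(paste0("<", bins[1]),
              paste0(bins[-length(bins)], "-", bins[-1]),
              paste0(">", bins[length(bins)]))
  labels[findInterval(identity, edges, left.open = TRUE)]
}

#' Identity-binned relative sensitivity
#'
#' For each sequence-identity bin, sensitivity is the fraction of true pairs
#' in that bin recovered within the top `top` hits of a method; relative
#' sensitivity scales it so the reference method equals one.
#'
#' @param method_hits,reference_hits hit tables evaluated at the same depth.
#' @param truth data.frame with `query_id`, `target_id`, `identity`.
#' @param bins numeric bin edges in percent identity (default 30, 50, 70, 90).
#' @param top evaluation depth.
#' @return data.frame with one row per bin: `bin`, `n_true`, `sens_method`,
#'   `sens_reference`, `relative` (`NA` when undefined).
#' @export
binned_sensitivity <- function(method_hits, reference_hits, truth,
                               bins = c(30, 50, 70, 90), top = 1000L) {
  stopifnot(!is.null(truth$identity))
  recovered <- function(hits) {
    h <- hits[hits$rank <= top, ]
    paste(truth$query_id, truth$target_id) %in%
      paste(h$query_id, h$target_id)
  }
  lab <- bin_label(truth$identity, bins)
  lev <- c(paste0("<", bins[1]),
           paste0(bins[-length(bins)], "-", bins[-1]),
           paste0(">", bins[length(bins)]))
  lab <- factor(lab, levels = lev)
  rm_ <- tapply(recovered(method_hits), lab, sum, default = 0L)
  rr_ <- tapply(recovered(reference_hits), lab, sum, default = 0L)
  nt <- tapply(rep(1L, nrow(truth)), lab, sum, default = 0L)
  sens_m <- ifelse(nt > 0, rm_ / nt, NA_real_)
  sens_r <- ifelse(nt > 0, rr_ / nt, NA_real_)
  data.frame(bin = lev,
             n_true = as.integer(nt),
             sens_method = as.numeric(sens_m),
             sens_reference = as.numeric(sens_r),
             relative = ifelse(!is.na(sens_r) & sens_r > 0,
                               sens_m / sens_r, NA_real_),
             row.names = NULL)
}
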