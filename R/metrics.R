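## Benchmark classification against simulator truth and summary statistics.
##
## Trimming, per read: an adapter-containing read (insert < read length) is a
## true positive when trimmed exactly to the insert length, a false positive
## when trimmed further, and a false negative when adapter bases remain. An
## adapter-free read is a true negative when left untrimmed and a false
## positive when trimmed at all.
##
## Merging, per pair: an overlapping pair (insert < summed read lengths) is a
## true positive when merged to exactly the insert length, a false negative
## when not merged, and a false positive when merged to a wrong length;
## non-overlapping pairs are true negatives when left unmerged and false
## positives when merged.

.CLS <- c("TP", "TN", "FP", "FN")

#' Classify trimming outcomes against truth
#'
#' @param trimmedLength length of each read after trimming.
#' @param insertLength true insert length per read.
#' @param readLength the untrimmed read length.
#' @return a factor with levels `TP`, `TN`, `FP`, `FN`.
#' @examples
#' classifyTrim(c(80, 100, 85, 75), c(80, 150, 80, 80), 100)
#' @export
classifyTrim <- function(trimmedLength, insertLength, readLength) {
  if (anyNA(insertLength)) stop("missing truth for some reads")
  expected <- pmin(readLength, insertLength)
  hasAdapter <- insertLength < readLength
  out <- character(length(trimmedLength))
  out[trimmedLength < expected] <- "FP"
  out[hasAdapter & trimmedLength == expected] <- "TP"
  out[hasAdapter & trimmedLength > expected] <- "FN"
  out[!hasAdapter & trimmedLength == expected] <- "TN"
  factor(out, levels = .CLS)
}

#' Classify merging outcomes against truth
#'
#' @param merged logical: was the pair collapsed?
#' @param mergedLength length of the collapsed read (`NA` when not merged).
#' @param insertLength true insert length per pair.
#' @param readLength the read length (overlap requires insert <
#'   `2 * readLength`).
#' @return a factor with levels `TP`, `TN`, `FP`, `FN`.
#' @export
classifyMerge <- function(merged, mergedLength, insertLength, readLength) {
  if (anyNA(insertLength)) stop("missing truth for some pairs")
  overlapping <- insertLength < 2L * readLength
  out <- character(length(merged))
  out[overlapping & merged & mergedLength == insertLength] <- "TP"
  out[merged & (!overlapping | mergedLength != insertLength)] <- "FP"
  out[overlapping & !merged] <- "FN"
  out[!overlapping & !merged] <- "TN"
  factor(out, levels = .CLS)
}

#' Tally classifications into confusion counts
#'
#' @param classes a factor from [classifyTrim()] or [classifyMerge()].
#' @return a [`ConfusionCounts`][ConfusionCounts-class].
#' @export
tallyClasses <- function(classes) {
  tab <- table(factor(classes, levels = .CLS))
  confusionCounts(tp = tab[["TP"]], tn = tab[["TN"]],
                  fp = tab[["FP"]], fn = tab[["FN"]])
}

#' @describeIn ConfusionCounts-class derive sensitivity `TP/(TP+FN)`,
#'   specificity `TN/(FP+TN)`, positive predictive value `TP/(TP+FP)`,
#'   negative predictive value `TN/(TN+FN)` and the Matthews correlation
#'   coefficient
#'   `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' @export
setMethod("computeMetrics", "ConfusionCounts", function(x) {
  tp <- x@tp; tn <- x@tn; fp <- x@fp; fn <- x@fn
  if (tp + tn + fp + fn == 0)
    stop("all counts are zero")
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  c(sen = if (tp + fn > 0) tp / (tp + fn) else NaN,
    spc = if (fp + tn > 0) tn / (fp + tn) else NaN,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NaN,
    npv = if (tn + fn > 0) tn / (tn + fn) else NaN,
    mcc = if (denom > 0) (tp * tn - fp * fn) / denom else 0)
})

#' Simulate, trim and score one or more replicate datasets
#'
#' Replicates the benchmark protocol: for each replicate a dataset is
#' simulated (seeds `config@seed`, `config@seed + 1`, ...), trimmed (and
#' optionally collapsed), classified against the simulator truth, and
#' summarised. Paired-end trimming classifies each mate separately; merging
#' classifies each pair once.
#'
#' @param config a [`SimulationConfig`] describing each replicate.
#' @param settings a [`TrimSettings`].
#' @param replicates number of replicate datasets.
#' @param collapse also collapse overlapping pairs and report merge metrics.
#' @param merge a [`MergeSettings`] used when `collapse = TRUE`.
#' @return a data frame with one row per replicate and measurement
#'   (`measure` is `"trim"` or `"merge"`), a final `"mean"` row per measure,
#'   the confusion counts, and the derived metrics.
#' @export
runTrimBenchmark <- function(config, settings = trimSettings(),
                             replicates = 1L, collapse = FALSE,
                             merge = mergeSettings()) {
  rows <- list()
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg@seed <- config@seed + r - 1L
    sim <- simulateReads(cfg)
    if (cfg@paired) {
      tr <- trimPairedEnd(sim$reads1, sim$reads2, settings)
      cls <- c(
        classifyTrim(nchar(trimmedReads(tr, 1L)@sequence),
                     sim$truth$insertLength, cfg@readLength),
        classifyTrim(nchar(trimmedReads(tr, 2L)@sequence),
                     sim$truth$insertLength, cfg@readLength))
    } else {
      tr <- trimSingleEnd(sim$reads1, settings)
      cls <- classifyTrim(nchar(trimmedReads(tr, 1L)@sequence),
                          sim$truth$insertLength, cfg@readLength)
    }
    cc <- tallyClasses(cls)
    rows[[length(rows) + 1L]] <-
      data.frame(replicate = as.character(r), measure = "trim",
                 tp = cc@tp, tn = cc@tn, fp = cc@fp, fn = cc@fn,
                 t(computeMetrics(cc)))
    if (collapse) {
      if (!cfg@paired) stop("collapse requires a paired-end config")
      mg <- mergePairs(sim$reads1, sim$reads2, tr, merge)
      mc <- tallyClasses(classifyMerge(isMerged(mg), mergedLengths(mg),
                                       sim$truth$insertLength,
                                       cfg@readLength))
      rows[[length(rows) + 1L]] <-
        data.frame(replicate = as.character(r), measure = "merge",
                   tp = mc@tp, tn = mc@tn, fp = mc@fp, fn = mc@fn,
                   t(computeMetrics(mc)))
    }
  }
  out <- do.call(rbind, rows)
  for (ms in unique(out$measure)) {
    sel <- out$measure == ms
    mean_row <- out[sel, ][1, ]
    mean_row$replicate <- "mean"
    for (col in c("tp", "tn", "fp", "fn", "sen", "spc", "ppv", "npv", "mcc"))
      mean_row[[col]] <- mean(out[[col]][sel])
    out <- rbind(out, mean_row)
  }
  rownames(out) <- NULL
  out
}
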