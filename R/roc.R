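## ROC sensitivity ------------------------------------------------------------
##
## Voxel-level separation of tissue states by each damage score, per patient,
## as ROC curves and AUC, with paired comparisons of metrics across patients.

#' Declared damage directions of the scores
#'
#' Damage lowers FA, MTR and MWF, raises RD; the composite PCA score is
#' oriented with a positive MWF weight, so damage lowers it too.
#' @return named character vector, values `"decrease"` or `"increase"`.
#' @export
default_damage_directions <- function() {
  c(FA = "decrease", RD = "increase", MTR = "decrease", MWF = "decrease",
    PCA = "decrease")
}

#' Orient scores so that larger always means more damaged
#'
#' @param values numeric damage values.
#' @param metric score label.
#' @param directions named direction vector, see
#'   [default_damage_directions()].
#' @return values, negated for damage-decreasing metrics.
#' @export
orient_for_damage <- function(values, metric, directions = default_damage_directions()) {
  if (!metric %in% names(directions))
    stop_wm(sprintf("no damage direction declared for metric '%s'", metric))
  if (directions[[metric]] == "decrease") -values else values
}

#' ROC curve and AUC for lesional vs reference voxels
#'
#' The lesional class is positive. AUC is the probability that a random
#' lesional voxel outscores a random reference voxel, ties counted 1/2
#' (the Mann-Whitney identity); the returned empirical curve integrates to
#' the same value by the trapezoidal rule.
#'
#' @param lesional,reference oriented score vectors (larger = more damaged).
#' @return object of class `roc_result`: `auc`, `curve` (fpr/tpr, from (0,0)
#'   to (1,1)), `n_lesional`, `n_reference`, `low_confidence` (TRUE when a
#'   class has fewer than 10 voxels).
#' @export
roc_auc <- function(lesional, reference) {
  lesional <- lesional[is.finite(lesional)]
  reference <- reference[is.finite(reference)]
  n1 <- length(lesional); n2 <- length(reference)
  if (n1 == 0L || n2 == 0L) stop_wm("both classes must be nonempty")
  r <- rank(c(lesional, reference))  # midranks handle ties as 1/2
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n2)
  ## empirical curve: one sweep over the scores in descending order, moving
  ## through tied values as a block
  scores <- c(lesional, reference)
  is_pos <- rep(c(TRUE, FALSE), c(n1, n2))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- is_pos[o]
  block_end <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tpr <- c(0, cumsum(p)[block_end] / n1)
  fpr <- c(0, cumsum(!p)[block_end] / n2)
  structure(list(auc = auc,
                 curve = data.frame(fpr = fpr, tpr = tpr),
                 n_lesional = n1, n_reference = n2,
                 low_confidence = n1 < 10L || n2 < 10L),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (%d lesional vs %d reference voxels%s)\n",
              x$auc, x$n_lesional, x$n_reference,
              if (x$low_confidence) ", low confidence" else ""))
  invisible(x)
}

#' Per-patient ROC table over the three classification problems
#'
#' For each patient, each score (metrics plus optional composite map) and
#' each problem (T2L vs NAWM, T1L vs NAWM, T1L vs T2L), scores are oriented
#' for damage and the AUC computed; the first-named state is the positive
#' (lesional) class.
#'
#' @param damage_maps nested list `[[patient]][[metric]]`; a `PCA` entry is
#'   treated like any other score.
#' @param tissue list of [segment_tissue_states()] per patient.
#' @param directions damage directions, see [default_damage_directions()].
#' @param patient_ids character vector.
#' @return data.frame: patient, metric, problem, auc, low_confidence.
#' @export
roc_table <- function(damage_maps, tissue, directions = default_damage_directions(),
                      patient_ids = NULL) {
  if (is.null(patient_ids)) patient_ids <- sprintf("pat%03d", seq_along(damage_maps))
  problems <- list("T2L vs NAWM" = c("t2l", "nawm"),
                   "T1L vs NAWM" = c("t1l", "nawm"),
                   "T1L vs T2L" = c("t1l", "t2l"))
  rows <- list()
  for (i in seq_along(damage_maps)) {
    ts <- tissue[[i]]
    if (!isTRUE(ts$included)) next
    for (metric in names(damage_maps[[i]])) {
      z <- damage_maps[[i]][[metric]]
      for (pr in names(problems)) {
        pos <- orient_for_damage(z[ts[[problems[[pr]][1]]]], metric, directions)
        neg <- orient_for_damage(z[ts[[problems[[pr]][2]]]], metric, directions)
        r <- roc_auc(pos, neg)
        rows[[length(rows) + 1L]] <- data.frame(
          patient = patient_ids[i], metric = metric, problem = pr,
          auc = r$auc, low_confidence = r$low_confidence, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Paired comparisons of classification performance between scores
#'
#' Paired t-tests on the per-patient AUCs for every unordered pair of scores
#' within each classification problem, pairwise-complete over patients, with
#' Bonferroni correction (default divisor 10 = the number of pairs among 5
#' scores).
#'
#' @param rocs a [roc_table()].
#' @param n_tests Bonferroni divisor, default 10.
#' @param alpha nominal level, default 0.05.
#' @return data.frame: problem, metric_a, metric_b, mean_diff, t, df, p,
#'   significant.
#' @export
compare_metrics <- function(rocs, n_tests = 10, alpha = 0.05) {
  mets <- unique(rocs$metric)
  out <- list()
  for (pr in unique(rocs$problem)) {
    sub <- rocs[rocs$problem == pr, ]
    for (a in seq_along(mets)[-length(mets)]) for (b in (a + 1):length(mets)) {
      xa <- sub[sub$metric == mets[a], c("patient", "auc")]
      xb <- sub[sub$metric == mets[b], c("patient", "auc")]
      m <- merge(xa, xb, by = "patient")  # pairwise-complete
      if (nrow(m) < nrow(xa) || nrow(m) < nrow(xb))
        message(sprintf("%s: %s vs %s uses %d pairwise-complete patients",
                        pr, mets[a], mets[b], nrow(m)))
      d <- m$auc.x - m$auc.y
      if (stats::sd(d) == 0) {
        tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                   parameter = nrow(m) - 1,
                   p.value = if (mean(d) == 0) 1 else 0)
        message(sprintf("%s: %s vs %s differ by an exact constant", pr, mets[a], mets[b]))
      } else tt <- stats::t.test(d)
      out[[length(out) + 1L]] <- data.frame(
        problem = pr, metric_a = mets[a], metric_b = mets[b],
        mean_diff = mean(d), t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, significant = tt$p.value < alpha / n_tests,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
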