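#' Construct a confusion-count record
#'
#' Holds the four cells of a detection confusion matrix together with the
#' printed total `n` and the four marginals. By default the marginals and
#' `n` are derived from the cells; published tables sometimes print totals
#' that disagree with the cell sum (transcription quirks), so both can be
#' overridden to reproduce such tables exactly, in which case the
#' inconsistency is flagged in the `consistent` field.
#'
#' @param TP,TN,FP,FN Nonnegative integer cells: agreed presences, agreed
#'   absences (whole empty minutes), predicted-only bins, true-only bins.
#' @param n Total evaluation units; defaults to `TP + TN + FP + FN`.
#' @param act_pres,act_abs,pred_pres,pred_abs Optional marginal overrides.
#' @param label Optional label (e.g. station/classifier).
#' @return An object of class `aas_confusion` (a one-row tibble).
#' @export
confusion <- function(TP, TN, FP, FN, n = NULL,
                      act_pres = NULL, act_abs = NULL,
                      pred_pres = NULL, pred_abs = NULL, label = NA_character_) {
  cells <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(cells < 0)) abort("confusion cells must be nonnegative")
  out <- tibble(
    label = label,
    TP = TP, TN = TN, FP = FP, FN = FN,
    n = n %||% (TP + TN + FP + FN),
    act_pres = act_pres %||% (TP + FN),
    act_abs = act_abs %||% (TN + FP),
    pred_pres = pred_pres %||% (TP + FP),
    pred_abs = pred_abs %||% (TN + FN)
  )
  out$consistent <- out$n == out$TP + out$TN + out$FP + out$FN
  if (!out$consistent) {
    warn(sprintf("printed n (%d) differs from cell sum (%d)%s",
                 out$n, TP + TN + FP + FN,
                 if (is.na(label)) "" else paste0(" for ", label)))
  }
  class(out) <- c("aas_confusion", class(out))
  out
}

#' Draw the evaluation minute sample for a station
#'
#' Samples `n_base` minutes uniformly without replacement from the candidate
#' minutes (post interference removal). If the sampled minutes contain fewer
#' than `min_true` true detections, additional uniform draws are appended one
#' at a time until the threshold is met or the candidates are exhausted (in
#' which case the result carries an `exhausted` attribute and a warning).
#'
#' @param minutes Candidate minute records (`station_id`, `minute_start`).
#' @param true_stream True event tibble used to count detections.
#' @param n_base Base sample size (default 200).
#' @param min_true Minimum number of true detections required (default 100).
#' @param seed RNG seed.
#' @return The sampled minute rows (a tibble), with attribute `exhausted`.
#' @export
draw_eval_sample <- function(minutes, true_stream, n_base = 200,
                             min_true = 100, seed = 1L) {
  if (nrow(minutes) < n_base) {
    abort(sprintf("only %d candidate minutes; need at least n_base = %d",
                  nrow(minutes), n_base))
  }
  key <- paste(true_stream$station_id, format_iso(true_stream$minute_start))
  true_per_min <- table(key)
  n_true <- function(mm) {
    k <- paste(mm$station_id, format_iso(mm$minute_start))
    sum(true_per_min[intersect(k, names(true_per_min))])
  }
  with_seed(seed, {
    ord <- sample.int(nrow(minutes)) # one permutation: base + reserve draws
    take <- n_base
    sampled <- minutes[ord[seq_len(take)], ]
    while (n_true(sampled) < min_true && take < nrow(minutes)) {
      take <- take + 1L
      sampled <- minutes[ord[seq_len(take)], ]
    }
    exhausted <- n_true(sampled) < min_true
    if (exhausted) {
      warn("candidate minutes exhausted before reaching `min_true` detections")
    }
    structure(arrange(sampled, .data$station_id, .data$minute_start),
              exhausted = exhausted)
  })
}

#' Build confusion counts from paired true/predicted detection streams
#'
#' Compares the two streams bin by bin over the evaluation minutes: `TP` are
#' 2-s bins claimed by both streams, `FP` bins claimed by the predicted
#' stream only, `FN` bins claimed by the true stream only. Because call
#' presence is rare, bin-level true negatives would swamp the table; a true
#' negative is therefore a whole evaluation minute containing no detection
#' in either stream. `n = TP + TN + FP + FN`.
#'
#' @param true_stream,predicted_stream Event tibbles (`station_id`,
#'   `minute_start`, `bin_index`), each with at most one event per bin.
#' @param minutes The evaluation minute set (`station_id`, `minute_start`).
#' @param label Optional label for the resulting record.
#' @return An `aas_confusion` row.
#' @export
confusion_counts <- function(true_stream, predicted_stream, minutes,
                             label = NA_character_) {
  key_m <- function(x) paste(x$station_id, format_iso(x$minute_start))
  key_b <- function(x) paste(key_m(x), x$bin_index)
  tt <- true_stream[key_m(true_stream) %in% key_m(minutes), ]
  pp <- predicted_stream[key_m(predicted_stream) %in% key_m(minutes), ]
  if (anyDuplicated(key_b(tt)) || anyDuplicated(key_b(pp))) {
    abort("streams must contain at most one event per 2-s bin")
  }
  tb <- key_b(tt)
  pb <- key_b(pp)
  TP <- sum(tb %in% pb)
  FN <- sum(!tb %in% pb)
  FP <- sum(!pb %in% tb)
  busy <- unique(c(key_m(tt), key_m(pp)))
  TN <- sum(!key_m(minutes) %in% busy)
  confusion(TP = TP, TN = TN, FP = FP, FN = FN, label = label)
}

#' Pool confusion counts across stations
#'
#' Cellwise sums of TP/TN/FP/FN and of the member totals `n` (so printed
#' totals propagate); marginals are recomputed from the summed cells.
#'
#' @param counts A list of `aas_confusion` rows, or a tibble of stacked rows.
#' @param label Label for the pooled record.
#' @return An `aas_confusion` row.
#' @export
pool_confusion <- function(counts, label = "pooled") {
  tab <- if (is.data.frame(counts)) counts else bind_rows(counts)
  if (nrow(tab) == 0) abort("`counts` must be nonempty")
  suppressWarnings(confusion(
    TP = sum(tab$TP), TN = sum(tab$TN), FP = sum(tab$FP), FN = sum(tab$FN),
    n = sum(tab$n), label = label
  ))
}

#' Accuracy, rate and kappa metrics for a confusion record
#'
#' Computes the standard evaluation metrics: `accuracy = (TP + TN) / n`,
#' `mcr = 1 - accuracy`, `tpr = TP / act_pres`, `fnr = FN / act_pres`,
#' `tnr = TN / act_abs`, `fpr = FP / act_abs`, and Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o = accuracy` and
#' chance agreement from the marginal products,
#' `p_e = (act_pres * pred_pres + act_abs * pred_abs) / n^2`. Undefined
#' ratios (zero denominators) are returned as `NA`.
#'
#' @param counts An `aas_confusion` row or a tibble of several rows.
#' @return A tibble with one metrics row per input row: `label`, `kappa`,
#'   `accuracy`, `mcr`, `tpr`, `tnr`, `fpr`, `fnr`.
#' @examples
#' confusion_metrics(confusion(TP = 64, TN = 215, FP = 1, FN = 37))
#' @export
confusion_metrics <- function(counts) {
  tab <- as_tibble(counts)
  if (any(tab$n <= 0)) abort("confusion totals must be positive")
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  acc <- (tab$TP + tab$TN) / tab$n
  p_e <- (tab$act_pres * tab$pred_pres + tab$act_abs * tab$pred_abs) / tab$n^2
  tibble(
    label = tab$label,
    kappa = ifelse(p_e < 1, (acc - p_e) / (1 - p_e), NA_real_),
    accuracy = acc,
    mcr = 1 - acc,
    tpr = safe_div(tab$TP, tab$act_pres),
    tnr = safe_div(tab$TN, tab$act_abs),
    fpr = safe_div(tab$FP, tab$act_abs),
    fnr = safe_div(tab$FN, tab$act_pres)
  )
}

#' Published benchmark confusion counts for grouper-call classification
#'
#' Confusion-count table from a field evaluation of automatic (FADAR) versus
#' manual classification of Nassau Grouper aggregation-associated sounds
#' across a five-station hydrophone array, shipped with the package as a
#' worked benchmark for the metric and pooling operations. One row per
#' station and classifier with the printed sample size, total `n`, cells and
#' marginals. The LS5 row's printed `n` disagrees with its cell sum by 5;
#' the row is kept as printed and flagged via `consistent = FALSE`.
#'
#' @return A tibble of `aas_confusion`-compatible rows with `station`,
#'   `classifier` and `sample_size` columns.
#' @export
fadar_benchmark <- function() {
  path <- system.file("extdata", "fadar_eval_counts.csv", package = "aascall")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  rows <- purrr::pmap(raw, function(station, classifier, sample_size,
                                    n, TP, TN, FP, FN, ...) {
    suppressWarnings(
      confusion(TP = TP, TN = TN, FP = FP, FN = FN, n = n,
                label = paste(station, classifier))
    ) %>%
      mutate(station = station, classifier = classifier,
             sample_size = sample_size)
  })
  bind_rows(rows)
}
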