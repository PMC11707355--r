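# Multi-observer, multi-batch score aggregation: qualitative (set 1)
# scores, acquisition-derived (set 2) scores, SNR scores, per-modality
# totals and the final cross-modality decalcifier score.

#' Aggregate qualitative observer scores for one modality and protocol
#'
#' Implements the evaluation-sheet arithmetic: within each (batch,
#' parameter) cell the scores of all observers who evaluated it are
#' averaged; those cell means are averaged across the batches in which the
#' parameter was evaluated; the per-parameter means are summed and
#' normalized by the maximum attainable total (2 x number of parameters
#' actually used).  Parameters missing everywhere (e.g. bone marrow lost
#' during preparation) simply do not enter.
#'
#' @param table A [score_table()].
#' @param modality `"HE"`, `"fluorescence"` or `"raman"`.
#' @param protocol Protocol code.
#' @return A list of class `modality_score` with `protocol`, `modality`,
#'   `normalized_score` (in [0, 1]), `total`, `per_parameter` (named means)
#'   and `n_parameters_used`.
#' @examples
#' tab <- score_table(data.frame(
#'   modality = "raman", protocol = "E_24", batch = 1,
#'   observer = c("obs1", "obs1", "obs2", "obs2"),
#'   parameter = c("p1", "p2", "p1", "p2"), score = c(2, 1, 1, 2)))
#' aggregate_qualitative(tab, "raman", "E_24")$normalized_score  # 0.75
#' @export
aggregate_qualitative <- function(table, modality, protocol) {
  table <- score_table(table)
  parse_protocol(protocol)
  rec <- table[table$modality == modality & table$protocol == protocol, ]
  if (nrow(rec) == 0L)
    stop(sprintf("no records for modality '%s', protocol '%s'",
                 modality, protocol), call. = FALSE)
  per_cell <- stats::aggregate(score ~ batch + parameter, data = rec, FUN = mean)
  per_param <- stats::aggregate(score ~ parameter, data = per_cell, FUN = mean)
  total <- sum(per_param$score)
  n_par <- nrow(per_param)
  structure(
    list(protocol = protocol, modality = modality,
         normalized_score = total / (2 * n_par), total = total,
         per_parameter = stats::setNames(per_param$score, per_param$parameter),
         n_parameters_used = n_par),
    class = "modality_score"
  )
}

#' @export
print.modality_score <- function(x, ...) {
  cat(sprintf("<modality_score> %s / %s: %.3f (total %.2f over %d parameters)\n",
              x$modality, x$protocol, x$normalized_score, x$total,
              x$n_parameters_used))
  invisible(x)
}

#' Flag observer disagreements requiring a third observer
#'
#' For every (protocol, batch) cell of a modality, observer totals are
#' compared pairwise over the parameters both observers scored; when any
#' pair of totals differs by strictly more than 1, the cell is flagged for
#' review by an additional observer.
#'
#' @param table A [score_table()].
#' @param modality Modality to check.
#' @param max_delta Flag when the total difference exceeds this (strictly).
#' @return A data frame with columns `protocol`, `batch`, `max_difference`
#'   (zero rows when there is no disagreement).
#' @export
flag_disagreements <- function(table, modality, max_delta = 1) {
  table <- score_table(table)
  rec <- table[table$modality == modality, ]
  out <- list()
  for (p in unique(rec$protocol)) for (b in unique(rec$batch[rec$protocol == p])) {
    cell <- rec[rec$protocol == p & rec$batch == b, ]
    obs <- unique(cell$observer)
    if (length(obs) < 2L) next
    worst <- 0
    for (i in seq_len(length(obs) - 1L)) for (j in (i + 1L):length(obs)) {
      a <- cell[cell$observer == obs[i], c("parameter", "score")]
      bb <- cell[cell$observer == obs[j], c("parameter", "score")]
      shared <- intersect(a$parameter, bb$parameter)
      if (!length(shared)) next
      da <- sum(a$score[match(shared, a$parameter)])
      db <- sum(bb$score[match(shared, bb$parameter)])
      worst <- max(worst, abs(da - db))
    }
    if (worst > max_delta)
      out[[length(out) + 1L]] <- data.frame(protocol = p, batch = b,
                                            max_difference = worst)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(protocol = character(0), batch = integer(0),
                  max_difference = numeric(0))
}

# map a cohort of values to {0,1,2} by tertiles; direction controls whether
# low values are good (laser power, gain) or high values are (SNR)
#' @noRd
tertile_score <- function(v, low_is_good = TRUE) {
  if (length(v) < 2L)
    stop("need a cohort of at least 2 values to rank", call. = FALSE)
  if (diff(range(v)) < 1e-300) {
    warning("all values identical; assigning middle score 1 to every entry")
    return(rep(1L, length(v)))
  }
  q <- stats::quantile(v, c(1 / 3, 2 / 3), names = FALSE)
  s <- ifelse(v <= q[1], 2L, ifelse(v <= q[2], 1L, 0L))
  if (low_is_good) as.integer(s) else 2L - as.integer(s)
}

#' Acquisition-derived (set 2) fluorescence scores
#'
#' For every imaging channel and each acquisition parameter (laser power,
#' detector gain), the protocols of a batch cohort are ranked and mapped to
#' {0, 1, 2} by tertiles: the highest settings (dimmest staining) score 0,
#' the lowest score 2.  Per protocol, the channel x parameter scores are
#' summed, normalized by the attainable maximum within each batch, and the
#' normalized totals are averaged across batches.
#'
#' @param acquisition Data frame with columns
#'   `protocol,batch,channel,laser_power,detector_gain`
#'   (see [read_acquisition_table()]); needs >= 3 protocols per batch.
#' @return A data frame with columns `protocol` and `set2_score` (in [0, 1]).
#' @export
acquisition_to_set2_scores <- function(acquisition) {
  required <- c("protocol", "batch", "channel", "laser_power", "detector_gain")
  if (!all(required %in% names(acquisition)))
    stop("acquisition table must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  protos <- unique(acquisition$protocol)
  if (length(protos) < 2L)
    stop("ranking needs a cohort of at least 2 protocols", call. = FALSE)
  acc <- list()
  for (b in unique(acquisition$batch)) {
    batch <- acquisition[acquisition$batch == b, ]
    batch$pts <- 0L
    for (ch in unique(batch$channel)) {
      sel <- batch$channel == ch
      batch$pts[sel] <- tertile_score(batch$laser_power[sel]) +
        tertile_score(batch$detector_gain[sel])
    }
    tot <- stats::aggregate(pts ~ protocol, data = batch, FUN = sum)
    n_items <- stats::aggregate(pts ~ protocol, data = batch, FUN = length)
    tot$norm <- tot$pts / (4 * n_items$pts)  # max 2 per LP + 2 per DG per channel
    acc[[length(acc) + 1L]] <- tot[c("protocol", "norm")]
  }
  all_b <- do.call(rbind, acc)
  out <- stats::aggregate(norm ~ protocol, data = all_b, FUN = mean)
  names(out) <- c("protocol", "set2_score")
  out[match(protos, out$protocol), , drop = FALSE]
}

#' Threshold-based scores from SNR values
#'
#' The range of SNR values observed across protocols and batches for one
#' tissue defines tertile thresholds; each value scores 2 (top tertile),
#' 1 (middle) or 0 (bottom).  Compact-bone SNRs vary little and typically
#' land on 1--2; bone-marrow SNRs spread over the full 0--2 range.
#'
#' @param snr_values Numeric vector of SNR values (>= 3) pooled over the
#'   protocols/batches being compared.
#' @param tissue `"compact_bone"` or `"bone_marrow"` (bookkeeping only; the
#'   thresholds always come from the supplied pool).
#' @return Integer vector of scores in {0, 1, 2}, same length/names as the
#'   input, with attribute `thresholds` (the two tertile cut points).
#' @export
snr_to_score <- function(snr_values, tissue = c("compact_bone", "bone_marrow")) {
  tissue <- match.arg(tissue)
  if (length(snr_values) < 3L)
    stop("need at least 3 SNR values to derive thresholds", call. = FALSE)
  s <- tertile_score(snr_values, low_is_good = FALSE)
  names(s) <- names(snr_values)
  attr(s, "thresholds") <- if (diff(range(snr_values)) < 1e-300) c(NA, NA)
    else stats::quantile(snr_values, c(1 / 3, 2 / 3), names = FALSE)
  attr(s, "tissue") <- tissue
  s
}

#' Combine set-1 and set-2 normalized scores for one modality
#'
#' @param set1 Observer-derived normalized score in [0, 1].
#' @param set2 Acquisition- or SNR-derived normalized score in [0, 1].
#' @return The arithmetic mean.
#' @export
modality_total <- function(set1, set2) {
  stopifnot(is.finite(set1), is.finite(set2))
  if (set1 < 0 || set1 > 1 || set2 < 0 || set2 > 1)
    stop("normalized scores must lie in [0, 1]", call. = FALSE)
  (set1 + set2) / 2
}

#' Final cross-modality decalcifier score
#'
#' Averages the normalized scores of the modalities that were evaluated
#' (H&E, fluorescence, Raman); the spread between modalities is reported as
#' the population standard deviation -- the error bar of the final score
#' chart.
#'
#' @param he,fluorescence,raman Normalized modality scores in [0, 1];
#'   `NA` for a modality that was not evaluated.
#' @param protocol Optional protocol code for bookkeeping.
#' @return A list of class `final_score` with `mean_score`,
#'   `sd_across_modalities`, `n_modalities`, `protocol`.
#' @examples
#' final_score(he = 1, fluorescence = 0)          # mean 0.5, sd 0.5
#' final_score(he = 0.9, fluorescence = 0.6, raman = 0.3)
#' @export
final_score <- function(he = NA, fluorescence = NA, raman = NA,
                        protocol = NA_character_) {
  v <- c(HE = he, fluorescence = fluorescence, raman = raman)
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop("at least one modality score is required", call. = FALSE)
  if (any(v < 0 | v > 1))
    stop("normalized scores must lie in [0, 1]", call. = FALSE)
  m <- mean(v)
  sd_pop <- sqrt(mean((v - m)^2))
  structure(
    list(mean_score = m, sd_across_modalities = sd_pop,
         n_modalities = length(v), modalities = names(v),
         protocol = protocol),
    class = "final_score"
  )
}

#' @export
print.final_score <- function(x, ...) {
  cat(sprintf("<final_score>%s %.3f +/- %.3f over %d modalities (%s)\n",
              if (is.na(x$protocol)) "" else paste0(" ", x$protocol),
              x$mean_score, x$sd_across_modalities, x$n_modalities,
              paste(x$modalities, collapse = ", ")))
  invisible(x)
}
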