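#' Relative remaining-substrate intensity
#'
#' Normalizes a lane's substrate band intensity to the time-point-0 lane of
#' the same series (t0 set to 1 by construction).
#'
#' @param laneIntensity Band intensity of the lane (arbitrary units).
#' @param t0Intensity Band intensity of the series' t0 lane; must be > 0.
#' @return `I_rel = laneIntensity / t0Intensity`.
#' @export
relativeIntensity <- function(laneIntensity, t0Intensity) {
  if (any(t0Intensity <= 0))
    stop("normalization error: t0 intensity must be positive", call. = FALSE)
  laneIntensity / t0Intensity
}

#' Percentage digestion from relative intensity
#'
#' `% digestion = (1 - I_rel) * 100`. Values below 0 (a lane brighter than
#' t0, i.e. densitometry noise) are returned raw here; [quantifyDigestion()]
#' additionally carries a clamped display column.
#'
#' @param iRel Relative remaining-substrate intensity, >= 0.
#' @return Percentage digestion.
#' @examples
#' pctDigestion(0.25)  # 75
#' @export
pctDigestion <- function(iRel) {
  if (any(iRel < 0))
    stop("contract error: I_rel must be >= 0", call. = FALSE)
  (1 - iRel) * 100
}

#' Predicted cleavage fragment sizes of a linear substrate
#'
#' @param substrateLength Substrate length in bp.
#' @param cutPosition Cut position in bp from the left end; must be strictly
#'   inside the substrate.
#' @return Integer vector `c(fragment1, fragment2)` =
#'   `c(cutPosition, substrateLength - cutPosition)`.
#' @examples
#' predictFragments(1500, 1000)  # 1000 500
#' @export
predictFragments <- function(substrateLength, cutPosition) {
  if (cutPosition <= 0 || cutPosition >= substrateLength)
    stop("range error: cut must fall strictly inside the substrate",
         call. = FALSE)
  c(cutPosition, substrateLength - cutPosition)
}

#' Quantify digestion for a table of gel lanes
#'
#' Normalizes every lane to the t0 lane of its (assay_id, condition) series
#' and computes % digestion. Each series must contain exactly one lane with
#' `time_or_delay_s == 0`.
#'
#' @param lanes `data.frame` with columns `assay_id, condition,
#'   time_or_delay_s, lane, intensity` (see [readGelTable()]).
#' @return The input with `i_rel`, `pct_digestion` (raw) and
#'   `pct_digestion_display` (clamped to `[0, 100]`) appended.
#' @export
quantifyDigestion <- function(lanes) {
  need <- c("assay_id", "condition", "time_or_delay_s", "lane", "intensity")
  miss <- setdiff(need, names(lanes))
  if (length(miss))
    stop("missing gel table columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- interaction(lanes$assay_id, lanes$condition, drop = TRUE)
  out <- lanes
  out$i_rel <- NA_real_
  for (g in levels(key)) {
    sel <- key == g
    t0 <- lanes$intensity[sel & lanes$time_or_delay_s == 0]
    if (length(t0) != 1L)
      stop(sprintf("normalization error: series '%s' needs exactly one t0 lane",
                   g), call. = FALSE)
    out$i_rel[sel] <- relativeIntensity(lanes$intensity[sel], t0)
  }
  out$pct_digestion <- (1 - out$i_rel) * 100
  out$pct_digestion_display <- pmin(pmax(out$pct_digestion, 0), 100)
  out
}

#' Summarize time-lapse digestion by condition and delay
#'
#' Aggregates replicate measurements to mean and standard deviation per
#' (condition, delay in seconds). A single replicate yields an `NA` SD.
#'
#' @param measurements `data.frame` from [quantifyDigestion()].
#' @return A `data.frame`: `condition, time_or_delay_s, n, mean_pct_digestion,
#'   sd_pct_digestion`, sorted by condition then delay.
#' @export
summarizeTimelapse <- function(measurements) {
  if (nrow(measurements) == 0L)
    return(data.frame(condition = character(0), time_or_delay_s = numeric(0),
                      n = integer(0), mean_pct_digestion = numeric(0),
                      sd_pct_digestion = numeric(0)))
  key <- interaction(measurements$condition, measurements$time_or_delay_s,
                     drop = TRUE)
  rows <- lapply(split(measurements, key), function(g) data.frame(
    condition = g$condition[1],
    time_or_delay_s = g$time_or_delay_s[1],
    n = nrow(g),
    mean_pct_digestion = mean(g$pct_digestion),
    sd_pct_digestion = if (nrow(g) > 1L) sd(g$pct_digestion) else NA_real_,
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$condition, out$time_or_delay_s), , drop = FALSE]
}

#' Read a gel band-intensity TSV
#'
#' Expected columns: `assay_id, condition, time_or_delay_s, lane, intensity`
#' -- the export of any densitometry tool.
#'
#' @param path TSV path.
#' @return A `data.frame`.
#' @export
readGelTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
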