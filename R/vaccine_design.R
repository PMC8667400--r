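#' Design a 27-mer long peptide around a mutant residue
#'
#' The synthesis window centers the mutant residue (offset 14 of 27) whenever
#' at least 13 residues flank it on both sides; near a protein terminus the
#' window slides to stay inside the protein at full length, and proteins
#' shorter than the window are returned whole.
#'
#' @param sequence Amino-acid string of the protein context.
#' @param mutant_position 1-based index of the mutant residue.
#' @param mutant_residue Expected residue at `mutant_position` (checked when
#'   given).
#' @param window Peptide length (default 27).
#' @return A list with `sequence` (the peptide), `mutant_offset` (1-based
#'   index of the mutant residue within the peptide), `start` and `end`
#'   (residue coordinates in the protein).
#' @examples
#' p <- design_long_peptide(strrep("A", 200), 50)
#' p$start; p$end; p$mutant_offset  # 37, 63, 14
#' @export
design_long_peptide <- function(sequence, mutant_position,
                                mutant_residue = NULL, window = 27) {
  len <- nchar(sequence)
  if (mutant_position < 1 || mutant_position > len) {
    abort(paste0("mutant_position ", mutant_position,
                 " outside protein of length ", len))
  }
  if (!is.null(mutant_residue) &&
      substr(sequence, mutant_position, mutant_position) != mutant_residue) {
    abort("residue at mutant_position does not match mutant_residue")
  }
  if (len <= window) {
    start <- 1L
  } else {
    half <- (window - 1L) %/% 2L
    start <- mutant_position - half
    start <- max(1L, min(start, len - window + 1L))
  }
  end <- min(len, start + window - 1L)
  list(sequence = substr(sequence, start, end),
       mutant_offset = as.integer(mutant_position - start + 1L),
       start = as.integer(start), end = as.integer(end))
}

#' Partition ranked peptides into dose pools
#'
#' Peptides are grouped into `clamp(ceiling(n/5), 1, 4)` pools of 3-5
#' peptides each (sizes differing by at most one), filled round-robin by
#' priority rank so high-priority peptides spread across pools. Between 3 and
#' 20 peptides can be pooled.
#'
#' @param peptide_ids Character or integer vector of peptide identifiers in
#'   priority order.
#' @param dose_per_peptide_mg Dose of each peptide per injection (default
#'   0.3 mg).
#' @param adjuvant_dose_mg Poly-IC adjuvant dose per pool injection (default
#'   0.5 mg).
#' @return Tibble with columns `pool, peptide_id, rank, dose_per_peptide_mg,
#'   adjuvant_dose_mg`.
#' @export
partition_pools <- function(peptide_ids, dose_per_peptide_mg = 0.3,
                            adjuvant_dose_mg = 0.5) {
  n <- length(peptide_ids)
  if (n > 20) abort("at most 20 peptides can be pooled")
  if (n < 3) abort("at least 3 peptides are required to form a pool")
  k <- max(1L, min(4L, as.integer(ceiling(n / 5))))
  pool <- rep_len(seq_len(k), n)
  tibble::tibble(pool = pool, peptide_id = peptide_ids, rank = seq_len(n),
                 dose_per_peptide_mg = dose_per_peptide_mg,
                 adjuvant_dose_mg = adjuvant_dose_mg)
}

prime_offsets <- c(1L, 4L, 8L, 15L, 22L)
boost_offsets <- c(90L, 140L)

#' Prime-boost vaccination schedule
#'
#' Seven subcutaneous doses: five prime doses on days 1, 4, 8, 15 and 22 and
#' two boost doses on days 90 and 140 relative to `day_zero`. Boost doses may
#' be administered up to 15 days after their nominal date.
#'
#' @param day_zero `Date` anchoring the schedule (dose offsets are added to
#'   it, so the first dose on day 1 falls on `day_zero + 1`).
#' @param boost_window_days Allowed delay for boost doses (default 15).
#' @return Tibble `dose, phase, offset_day, date, latest_date`.
#' @export
schedule_vaccinations <- function(day_zero, boost_window_days = 15) {
  day_zero <- as.Date(day_zero)
  if (is.na(day_zero)) abort("day_zero is not a valid date")
  offsets <- c(prime_offsets, boost_offsets)
  phase <- rep(c("prime", "boost"), c(length(prime_offsets),
                                      length(boost_offsets)))
  date <- day_zero + offsets
  tibble::tibble(
    dose = seq_along(offsets), phase = phase, offset_day = offsets,
    date = date,
    latest_date = date + ifelse(phase == "boost", boost_window_days, 0L)
  )
}

#' Check an administered dose against the schedule window
#'
#' @param schedule Tibble from [schedule_vaccinations()].
#' @param dose Dose number (1-7).
#' @param administered `Date` the dose was actually given.
#' @return `TRUE` if the dose is on or before its latest allowed date,
#'   otherwise `FALSE`.
#' @export
dose_within_window <- function(schedule, dose, administered) {
  row <- schedule[schedule$dose == dose, ]
  if (nrow(row) != 1) abort("unknown dose number")
  as.Date(administered) <= row$latest_date
}
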