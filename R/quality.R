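#' Occurrence of a compound's reporter above the detection limit
#'
#' The occurrence is the fraction of spectra in a dataset for which a
#' compound's reporter height exceeds the detection limit (strictly greater
#' than `detection_multiplier * noise`; the flag is stored per record as
#' `below_detection`).  A low occurrence disqualifies a metabolite from
#' downstream statistics.
#'
#' @param records a `quant_records` data.frame.
#' @param compound optional single compound id; when given, returns a single
#'   fraction, otherwise a per-compound data.frame.
#' @return data.frame with `compound_id`, `occurrence`, or a single number.
#' @export
occurrence <- function(records, compound = NULL) {
  if (!is.null(compound)) {
    sub <- records[records$compound_id == compound, ]
    if (nrow(sub) == 0L) stop(sprintf("no records for '%s'", compound),
                              call. = FALSE)
    return(mean(!sub$below_detection))
  }
  agg <- stats::aggregate(list(occurrence = !records$below_detection),
                          by = list(compound_id = records$compound_id),
                          FUN = mean)
  agg[match(unique(records$compound_id), agg$compound_id), , drop = FALSE]
}

# Lower median: for an even-length series the smaller of the two central
# values, which keeps medians (and hence MADs) of integer bin positions
# integral.
.median_lower <- function(x) sort(x)[floor((length(x) + 1) / 2)]

#' Per-spectrum median absolute deviation of signal positions
#'
#' For each spectrum, the absolute distance in bins between the observed
#' target position and the dataset median position.  One MAD step equals one
#' bin (0.0002 ppm on the standard grid).
#'
#' @param positions_bins integer vector of observed positions in bins.
#' @return integer vector of per-spectrum MAD values.
#' @export
mad_positions <- function(positions_bins) {
  if (length(positions_bins) < 1L) stop("empty position series", call. = FALSE)
  abs(positions_bins - .median_lower(positions_bins))
}

#' Positional deviation of a target signal
#'
#' The smallest symmetric radius (in whole bins) around the dataset median
#' that covers at least 95% of the observed target positions.  Metabolite
#' targets in stable spectra typically stay within one bin; drifting signals
#' such as free EDTA can reach around ten.
#'
#' @param positions_bins integer vector of observed positions in bins (one
#'   per spectrum).
#' @param coverage required fraction (default 0.95).
#' @return non-negative integer radius (bins).
#' @export
positional_deviation <- function(positions_bins, coverage = 0.95) {
  n <- length(positions_bins)
  if (n < 1L) stop("empty position series", call. = FALSE)
  if (n < 20L)
    warning("fewer than 20 spectra: positional deviation estimate is coarse")
  dev <- sort(mad_positions(positions_bins))
  as.integer(ceiling(dev[ceiling(coverage * n)]))
}

#' Degree of interference
#'
#' \eqn{F_q} is the fraction of spectra in which the relative interference of
#' a compound exceeds the preset level `q`.  Spectra where the interference is
#' undefined (zero target height) are excluded from the denominator.  The
#' conventional report points are q = 0.05 and q = 0.50.
#'
#' @param delta numeric vector of per-spectrum relative interferences (may
#'   contain `NA` for undefined values).
#' @param q threshold in `[0, 1)`.
#' @return fraction in `[0, 1]` (`NA` if no spectrum has a defined value).
#' @export
degree_of_interference <- function(delta, q) {
  if (q < 0 || q >= 1) stop("`q` must lie in [0, 1)", call. = FALSE)
  ok <- !is.na(delta)
  if (!any(ok)) return(NA_real_)
  sum(delta[ok] > q) / sum(ok)
}

#' Split modelled interference into metabolite and non-metabolite parts
#'
#' Given a solved spectrum (matrix `m`, reporter vector `x`, target vector
#' `y`), the interference received by compound *i* is
#' \eqn{\sum_{j \ne i} m_{ij} x_j}; splitting the sum by the class of the
#' contributing compound *j* gives one part from other metabolites and one
#' from non-metabolites such as EDTA.  Divided by \eqn{y_i} the two parts sum
#' exactly to the total relative interference \eqn{(y_i - x_i)/y_i} (up to the
#' solver residual).
#'
#' @param m interference matrix used in the solve.
#' @param x reporter heights (solution).
#' @param y target heights.
#' @param classes character vector, `"metabolite"`/`"nonmetabolite"` per
#'   compound; defaults to the matrix's `compound_class` attribute.
#' @return data.frame with `compound_id`, `delta_met`, `delta_nonmet`.
#' @export
decompose_interference <- function(m, x, y,
                                   classes = attr(m, "compound_class")) {
  if (is.null(classes)) stop("compound classes required", call. = FALSE)
  parts <- .interference_parts(m, x, y, classes)
  data.frame(compound_id = rownames(m) %||% as.character(seq_along(x)),
             delta_met = parts$delta_met,
             delta_nonmet = parts$delta_nonmet,
             stringsAsFactors = FALSE)
}

#' Compare mean concentrations between two quantification runs
#'
#' Per-compound relative deviation of mean concentrations,
#' \eqn{(\mu_a - \mu_b)/\mu_b}.  Used to measure the error a constant-matrix
#' quantification would commit relative to the per-spectrum adapted one.
#'
#' @param records_a,records_b `quant_records` over the same compound set.
#' @return data.frame with `compound_id`, `mean_a`, `mean_b`,
#'   `rel_deviation` (`NA` where `mean_b` is 0 or concentrations are absent).
#' @export
compare_means <- function(records_a, records_b) {
  mean_by <- function(r) {
    agg <- stats::aggregate(list(mean_conc = r$conc_uM),
                            by = list(compound_id = r$compound_id),
                            FUN = function(v) mean(v))
    agg
  }
  a <- mean_by(records_a); b <- mean_by(records_b)
  common <- intersect(a$compound_id, b$compound_id)
  ma <- a$mean_conc[match(common, a$compound_id)]
  mb <- b$mean_conc[match(common, b$compound_id)]
  data.frame(compound_id = common, mean_a = ma, mean_b = mb,
             rel_deviation = ifelse(is.na(mb) | mb == 0, NA_real_,
                                    (ma - mb) / mb),
             stringsAsFactors = FALSE)
}

#' Quality-indicator report for a quantified dataset
#'
#' Aggregates the per-spectrum records into the per-compound quality
#' indicators: occurrence, positional deviation, and the degree of
#' interference at the requested thresholds, separately for metabolite and
#' non-metabolite interference sources.  Category columns apply the
#' conventional thresholds: occurrence >= 90% (reliable) / >= 5% (reportable);
#' positional deviation <= 1 bin; and a traffic light per interference source
#' (`red`: F0.50 > 0.50, `yellow`: F0.50 <= 0.50 and F0.05 > 0, `green`:
#' F0.05 = 0).
#'
#' @param records a `quant_records` data.frame.
#' @param q two interference thresholds (default `c(0.05, 0.50)`).
#' @param occurrence_thresholds reportable / reliable occurrence levels.
#' @param deviation_threshold_bins positional-deviation flag level (bins).
#' @return a data.frame (class `qc_report`), one row per compound.
#' @export
qc_report <- function(records, q = c(0.05, 0.50),
                      occurrence_thresholds = c(0.05, 0.90),
                      deviation_threshold_bins = 1L) {
  stopifnot(length(q) == 2L)
  q <- sort(q)
  ids <- unique(records$compound_id)
  traffic <- function(f_lo, f_hi) {
    if (is.na(f_lo) || is.na(f_hi)) return(NA_character_)
    if (f_hi > 0.50) "red" else if (f_lo > 0) "yellow" else "green"
  }
  rows <- lapply(ids, function(id) {
    sub <- records[records$compound_id == id, ]
    occ <- mean(!sub$below_detection)
    pd <- suppressWarnings(positional_deviation(sub$position_bin))
    f_met <- vapply(q, function(qq) degree_of_interference(sub$delta_met, qq),
                    numeric(1))
    f_non <- vapply(q, function(qq)
      degree_of_interference(sub$delta_nonmet, qq), numeric(1))
    data.frame(
      compound_id = id,
      compound_class = sub$compound_class[1L],
      occurrence = occ,
      positional_deviation_bins = pd,
      F_met_lo = f_met[1L], F_met_hi = f_met[2L],
      F_nonmet_lo = f_non[1L], F_nonmet_hi = f_non[2L],
      n_delta_undefined = sum(is.na(sub$delta)),
      reportable = occ >= occurrence_thresholds[1L],
      reliable_occurrence = occ >= occurrence_thresholds[2L],
      stable_position = pd <= deviation_threshold_bins,
      interference_met = traffic(f_met[1L], f_met[2L]),
      interference_nonmet = traffic(f_non[1L], f_non[2L]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "F_met_lo"] <- sprintf("F%.2f_met", q[1L])
  names(out)[names(out) == "F_met_hi"] <- sprintf("F%.2f_met", q[2L])
  names(out)[names(out) == "F_nonmet_lo"] <- sprintf("F%.2f_nonmet", q[1L])
  names(out)[names(out) == "F_nonmet_hi"] <- sprintf("F%.2f_nonmet", q[2L])
  attr(out, "q") <- q
  class(out) <- c("qc_report", "data.frame")
  out
}
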