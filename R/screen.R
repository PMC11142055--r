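# Efficacy-ratio selectivity screen: per-(compound, cell line) ratios of
# remaining cancer-cell colonies to remaining bone-marrow colonies,
# activity classification (ratio < 0.5), per-site pooled statistics,
# bone-marrow inhibition/recovery flags, and dose-response IC50 estimation.

#' Load a colony-formation measurement table
#'
#' CSV schema: compound_id, target_site, cell_line, concentration,
#' percent_of_control, timepoint_days (8 or 14), optional replicate.
#' Malformed rows (negative percent, non-numeric fields, bad timepoint) are
#' rejected row-by-row and reported in the `errors` attribute; loading
#' continues.  Unknown cell-line spellings are preserved verbatim;
#' duplicate (compound, cell line, concentration, timepoint, replicate)
#' rows are retained and flagged in the `duplicates` attribute (replicate
#' semantics).
#'
#' @param path CSV file path.
#' @return Data frame of validated measurements; attributes `errors`
#'   (row, reason) and `duplicates` (logical).
#' @export
load_colony_table <- function(path) {
  if (!file.exists(path)) stop("cannot read colony table: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("empty colony table: ", path)
  needed <- c("compound_id", "target_site", "cell_line", "concentration",
              "percent_of_control", "timepoint_days")
  miss <- setdiff(needed, names(raw))
  if (length(miss) > 0) {
    stop("colony table missing columns: ", paste(miss, collapse = ", "))
  }
  conc <- suppressWarnings(as.numeric(raw$concentration))
  pct <- suppressWarnings(as.numeric(raw$percent_of_control))
  tp <- suppressWarnings(as.numeric(raw$timepoint_days))
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(conc) | conc < 0] <- "invalid concentration"
  reason[is.na(pct) | pct < 0] <- "negative or non-numeric percent_of_control"
  reason[!(tp %in% c(8, 14))] <- "timepoint_days must be 8 or 14"
  bad <- !is.na(reason)
  out <- raw[!bad, , drop = FALSE]
  out$concentration <- conc[!bad]
  out$percent_of_control <- pct[!bad]
  out$timepoint_days <- tp[!bad]
  rownames(out) <- NULL
  key <- paste(out$compound_id, out$cell_line, out$concentration,
               out$timepoint_days,
               if ("replicate" %in% names(out)) out$replicate else "")
  attr(out, "errors") <- data.frame(row = which(bad), reason = reason[bad],
                                    stringsAsFactors = FALSE)
  attr(out, "duplicates") <- duplicated(key) | duplicated(key, fromLast = TRUE)
  out
}

#' Efficacy ratio
#'
#' Ratio of percent remaining cancer-cell colonies to percent remaining
#' bone-marrow colonies at matched dose and timepoint.  Scale-invariant in
#' its inputs.  A zero marrow denominator yields NA with a warning
#' (undefined ratio).
#'
#' @param cancer_pct Percent-of-control cancer-cell colonies.
#' @param marrow_pct Percent-of-control bone-marrow colonies.
#' @return Numeric ratio(s), unrounded (round to 2 decimals for printed
#'   table parity).
#' @examples
#' efficacy_ratio(50, 100)  # 0.5
#' @export
efficacy_ratio <- function(cancer_pct, marrow_pct) {
  stopifnot(all(cancer_pct >= 0, na.rm = TRUE),
            all(marrow_pct >= 0, na.rm = TRUE))
  undef <- !is.na(marrow_pct) & marrow_pct == 0
  if (any(undef)) {
    warning("efficacy ratio undefined where bone-marrow percent is 0; NA returned")
  }
  out <- ifelse(undef, NA_real_, cancer_pct / marrow_pct)
  out
}

#' Build an efficacy table from colony measurements
#'
#' Averages replicate percent-of-control values per (compound, cell line,
#' concentration) at the given timepoint and divides each cancer cell
#' line's percent by the matched bone-marrow percent (cell line
#' `marrow_line`).
#'
#' @param colonies Colony measurement data frame (see
#'   [load_colony_table()]).
#' @param timepoint_days Assay day (default 8).
#' @param marrow_line Cell-line label of the marrow series.
#' @return Efficacy table: compound_id, site, cell_line, concentration,
#'   ratio.
#' @export
efficacy_table_from_colonies <- function(colonies, timepoint_days = 8,
                                         marrow_line = "bone_marrow") {
  d <- colonies[colonies$timepoint_days == timepoint_days, , drop = FALSE]
  agg <- stats::aggregate(
    percent_of_control ~ compound_id + target_site + cell_line + concentration,
    data = d, FUN = mean)
  marrow <- agg[agg$cell_line == marrow_line, , drop = FALSE]
  cancer <- agg[agg$cell_line != marrow_line, , drop = FALSE]
  mkey <- paste(marrow$compound_id, marrow$concentration)
  idx <- match(paste(cancer$compound_id, cancer$concentration), mkey)
  out <- data.frame(
    compound_id = cancer$compound_id, site = cancer$target_site,
    cell_line = cancer$cell_line, concentration = cancer$concentration,
    ratio = efficacy_ratio(cancer$percent_of_control,
                           marrow$percent_of_control[idx]),
    stringsAsFactors = FALSE)
  out[order(out$compound_id, out$cell_line, out$concentration), , drop = FALSE]
}

#' Relative activity of a compound
#'
#' Percentage of tested cell lines in which the compound's efficacy ratio
#' falls strictly below the activity threshold, at one concentration.
#' Untested cell lines (NA ratio) are excluded from the denominator.
#' Rounded to the nearest integer (half away from zero).
#'
#' @param compound_id Compound.
#' @param ratios Efficacy table (compound_id, cell_line, concentration,
#'   ratio).
#' @param concentration Concentration, micromolar.
#' @param threshold Activity threshold on the ratio (strict; default 0.5).
#' @return Integer percent in [0, 100].
#' @export
relative_activity <- function(compound_id, ratios, concentration,
                              threshold = 0.5) {
  r <- ratios$ratio[ratios$compound_id == compound_id &
                      ratios$concentration == concentration]
  r <- r[!is.na(r)]
  if (length(r) == 0) stop("no tested cell lines for ", compound_id,
                           " at ", concentration, " uM")
  as.integer(round_half_up(100 * sum(r < threshold) / length(r)))
}

#' Per-site summary of the selectivity screen
#'
#' A compound is active when at least one cell line's efficacy ratio falls
#' strictly below the threshold.  `percent_active` is taken over all
#' compounds tested at the site (pass `tested_compounds` when the efficacy
#' table only lists active compounds, as the printed tables do).  Pooled
#' mean and SEM are computed over the sub-threshold ratios of active
#' compounds - by default pooling all such ratios; `per_compound_mean`
#' pools each active compound's own mean instead.  SEM uses the n-1 sample
#' convention and is 0 for a single pooled value.  The range is
#' [min, max] of the active compounds' relative activities.
#'
#' @param site Site name.
#' @param ratios Efficacy table (compound_id, site, cell_line,
#'   concentration, ratio).
#' @param concentration Concentration, micromolar.
#' @param threshold Strict activity threshold (default 0.5).
#' @param tested_compounds Optional character vector of all compound ids
#'   tested against the site (denominator of `percent_active`).
#' @param pooling "all_ratios" (default) or "per_compound_mean".
#' @return List of class `site_summary`: site, n_tested, n_active,
#'   percent_active, pooled_mean, pooled_sem, relative_activity_range,
#'   active_compounds.
#' @export
site_summary <- function(site, ratios, concentration, threshold = 0.5,
                         tested_compounds = NULL,
                         pooling = c("all_ratios", "per_compound_mean")) {
  pooling <- match.arg(pooling)
  d <- ratios[ratios$site == site & ratios$concentration == concentration &
                !is.na(ratios$ratio), , drop = FALSE]
  listed <- unique(d$compound_id)
  tested <- unique(c(listed, tested_compounds))
  if (length(tested) == 0) stop("no tested compounds for site ", site)
  sub <- d[d$ratio < threshold, , drop = FALSE]
  active <- unique(sub$compound_id)
  pa <- round_half_up(100 * length(active) / length(tested))
  if (length(active) == 0) {
    pooled_mean <- NA_real_; pooled_sem <- NA_real_
    ra_range <- c(NA_real_, NA_real_)
  } else {
    vals <- switch(pooling,
                   all_ratios = sub$ratio,
                   per_compound_mean = vapply(split(sub$ratio, sub$compound_id),
                                              mean, numeric(1)))
    pooled_mean <- mean(vals)
    pooled_sem <- if (length(vals) > 1) {
      stats::sd(vals) / sqrt(length(vals))
    } else 0
    ra <- vapply(active, relative_activity, integer(1), ratios = d,
                 concentration = concentration, threshold = threshold)
    ra_range <- range(ra)
  }
  structure(list(site = site, n_tested = length(tested),
                 n_active = length(active), percent_active = pa,
                 pooled_mean = pooled_mean, pooled_sem = pooled_sem,
                 relative_activity_range = ra_range,
                 active_compounds = active, concentration = concentration,
                 threshold = threshold),
            class = "site_summary")
}

#' @export
print.site_summary <- function(x, ...) {
  cat(sprintf(
    "<site_summary> %s @ %g uM: %d/%d active (%g%%), pooled ratio %s +/- %s, range %s\n",
    x$site, x$concentration, x$n_active, x$n_tested, x$percent_active,
    ifelse(is.na(x$pooled_mean), "NA", sprintf("%.2f", x$pooled_mean)),
    ifelse(is.na(x$pooled_sem), "NA", sprintf("%.2f", x$pooled_sem)),
    if (all(is.na(x$relative_activity_range))) "NA" else
      paste(x$relative_activity_range, collapse = "-")))
  invisible(x)
}

#' Bone-marrow inhibition flags and day-14 recovery call
#'
#' Inhibition flags derive from the day-8 percent-of-control alone:
#' `inhibition_flag_10` when day8 < 90 (more than 10% inhibition),
#' `inhibition_flag_30` when day8 < 70.  The recovery call (defined only
#' when `inhibition_flag_10` is set) is "recovered" when day14 >= 90,
#' "partial" when day8 <= day14 < 90, else "none".  The 90% cutoffs are a
#' package convention (configurable).
#'
#' @param day8,day14 Percent-of-control marrow colony formation.
#' @param recovered_min Day-14 percent at/above which marrow is considered
#'   recovered (default 90).
#' @param flag10_below,flag30_below Day-8 cutoffs for the >10% / >30%
#'   inhibition flags (defaults 90 and 70).
#' @return Data frame: day8, day14, inhibition_flag_10,
#'   inhibition_flag_30, recovery.
#' @export
marrow_flags_and_recovery <- function(day8, day14, recovered_min = 90,
                                      flag10_below = 90, flag30_below = 70) {
  stopifnot(length(day8) == length(day14))
  f10 <- day8 < flag10_below
  f30 <- day8 < flag30_below
  recovery <- ifelse(!f10, "not_applicable",
                     ifelse(day14 >= recovered_min, "recovered",
                            ifelse(day14 >= day8, "partial", "none")))
  data.frame(day8 = day8, day14 = day14, inhibition_flag_10 = f10,
             inhibition_flag_30 = f30, recovery = recovery,
             stringsAsFactors = FALSE)
}

#' Estimate an IC50 from a dose-response series
#'
#' Log-linear interpolation of concentration at 50% of control between the
#' two measured points bracketing the 50% crossing.  Extrapolation is
#' refused: if no adjacent concentration pair brackets 50%, the estimate
#' is flagged not estimable.
#'
#' @param concentration Tested concentrations (same unit as the result).
#' @param percent_of_control Response at each concentration (percent).
#' @return List of class `ic50_fit`: `ic50` (NA when not estimable),
#'   `estimable`, `reason`.
#' @export
ic50_estimate <- function(concentration, percent_of_control) {
  stopifnot(length(concentration) == length(percent_of_control))
  ok <- !is.na(concentration) & !is.na(percent_of_control) & concentration > 0
  conc <- concentration[ok]
  pct <- percent_of_control[ok]
  if (length(conc) < 2) {
    return(structure(list(ic50 = NA_real_, estimable = FALSE,
                          reason = "fewer than 2 usable points"),
                     class = "ic50_fit"))
  }
  o <- order(conc)
  conc <- conc[o]; pct <- pct[o]
  exact <- which(pct == 50)
  if (length(exact) > 0) {
    return(structure(list(ic50 = conc[exact[1]], estimable = TRUE,
                          reason = "exact crossing"), class = "ic50_fit"))
  }
  cross <- which(pct[-length(pct)] > 50 & pct[-1] < 50)
  if (length(cross) == 0) {
    return(structure(list(ic50 = NA_real_, estimable = FALSE,
                          reason = "response does not cross 50% of control"),
                     class = "ic50_fit"))
  }
  i <- cross[1]
  lc <- log10(conc[i]); uc <- log10(conc[i + 1])
  ic50 <- 10^(lc + (50 - pct[i]) * (uc - lc) / (pct[i + 1] - pct[i]))
  structure(list(ic50 = ic50, estimable = TRUE,
                 reason = "log-linear interpolation"), class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (x$estimable) cat(sprintf("<ic50_fit> IC50 = %.4g (%s)\n", x$ic50, x$reason))
  else cat(sprintf("<ic50_fit> not estimable: %s\n", x$reason))
  invisible(x)
}
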