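# identity keys for "the parent carried an identical event":
# NCO = same chromosome + same converted SNP positions;
# CO  = same chromosome + same breakpoint interval
event_keys <- function(events) {
  if (nrow(events) == 0) return(character())
  if (inherits(events, "nco_calls") || "converted_pos" %in% names(events)) {
    vapply(seq_len(nrow(events)), function(i)
      paste0("NCO:", events$chrom[i], ":",
             paste(sort(events$converted_pos[[i]]), collapse = ",")),
      character(1))
  } else {
    paste0("CO:", events$chrom, ":", events$left_pos, "-",
           events$right_pos)
  }
}

#' Classify events as de novo or inherited
#'
#' An event in an offspring is inherited if either parent carries an
#' identical event (same converted SNP set for NCOs, same breakpoint
#' interval for COs) and de novo otherwise. Inherited events shared by
#' siblings are collapsed to one distinct event.
#'
#' @param events `nco_calls` or `crossover_calls` rows for offspring
#'   samples (several samples may be bound together).
#' @param parent_events same-type calls for the parents.
#' @param parents named list mapping each offspring `sample_id` to a
#'   character vector of its parent sample ids; offspring missing from
#'   the list are annotated `"unknown"`.
#' @return list with `events` (input with `inheritance` filled) and
#'   `inherited_distinct` (deduplicated inherited events).
#' @export
classify_inheritance <- function(events, parent_events, parents) {
  if (nrow(events) == 0)
    return(list(events = events, inherited_distinct = events))
  keys <- event_keys(events)
  pkeys <- event_keys(parent_events)
  inh <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    par <- parents[[events$sample_id[i]]]
    if (is.null(par)) { inh[i] <- "unknown"; next }
    carried <- pkeys[parent_events$sample_id %in% par]
    inh[i] <- if (keys[i] %in% carried) "inherited" else "de_novo"
  }
  events$inheritance <- inh
  inherited <- events[inh == "inherited", ]
  inherited_distinct <- inherited[!duplicated(event_keys(inherited)), ]
  list(events = events, inherited_distinct = inherited_distinct)
}

#' Fraction of events that are de novo
#'
#' @param n_de_novo,n_inherited event counts.
#' @return `n_de_novo / (n_de_novo + n_inherited)` (0 when both are 0).
#' @examples
#' de_novo_fraction(821, 1384)  # ~0.372
#' @export
de_novo_fraction <- function(n_de_novo, n_inherited) {
  if (n_de_novo < 0 || n_inherited < 0) stop("counts must be >= 0")
  tot <- n_de_novo + n_inherited
  if (tot == 0) return(0)
  n_de_novo / tot
}

#' Assign parent of origin to de novo events
#'
#' An NCO is assigned to the parent that is heterozygous at all its
#' converted sites while the other parent is homozygous there (only
#' the heterozygous parent's meiosis can convert an allele the
#' offspring observes as new). A CO is assigned analogously from the
#' flanking boundary SNPs: the parent heterozygous on both flanks,
#' when the other is homozygous on both, hosted the switch. Anything
#' else is `"unknown"`.
#'
#' @param events `nco_calls` or `crossover_calls` rows (de novo).
#' @param calls named list of all samples' `sample_genotypes`.
#' @param parents named list: offspring id -> c(mother_id, father_id)
#'   (mother first).
#' @return the events with the `parent` column filled
#'   (`"maternal"`/`"paternal"`/`"unknown"`).
#' @export
assign_parent_of_origin <- function(events, calls, parents) {
  if (nrow(events) == 0) return(events)
  is_nco <- "converted_idx" %in% names(events)
  out <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    par <- parents[[events$sample_id[i]]]
    if (is.null(par) || length(par) < 2) { out[i] <- "unknown"; next }
    idx <- if (is_nco) events$converted_idx[[i]]
           else c(events$left_idx[i], events$right_idx[i])
    mo <- calls[[par[1]]]$call[idx]
    fa <- calls[[par[2]]]$call[idx]
    mo_het <- !any(is.na(mo)) && all(mo == 1L)
    fa_het <- !any(is.na(fa)) && all(fa == 1L)
    mo_hom <- !any(is.na(mo)) && all(mo %in% c(0L, 2L))
    fa_hom <- !any(is.na(fa)) && all(fa %in% c(0L, 2L))
    out[i] <- if (mo_het && fa_hom) "maternal"
              else if (fa_het && mo_hom) "paternal"
              else "unknown"
  }
  events$parent <- out
  events
}

#' Overlap events with ChIP-seq peaks
#'
#' Events are assigned to the nearest peak within `max_dist` bp of
#' either peak set (distance 0 inside a peak), else left unassigned.
#'
#' @param events `nco_calls` or `crossover_calls` rows; NCO centers are
#'   minimal-tract midpoints, CO centers breakpoint-interval midpoints.
#' @param dmc1_peaks,h3k4_peaks data.frames with `chrom`, `start`,
#'   `end` and an `id` column (either may be `NULL`).
#' @param max_dist maximum distance in bp (default 1000).
#' @return list with `events` (input with `hotspot_id` filled) and
#'   `fraction` (assigned / total).
#' @export
overlap_hotspots <- function(events, dmc1_peaks = NULL,
                             h3k4_peaks = NULL, max_dist = 1000) {
  peaks <- rbind(dmc1_peaks, h3k4_peaks)
  if (nrow(events) == 0)
    return(list(events = events, fraction = NA_real_))
  if (is.null(peaks) || nrow(peaks) == 0)
    stop("no peaks supplied")
  center <- if ("min_start" %in% names(events))
    (events$min_start + events$min_end) / 2
  else (events$left_pos + events$right_pos) / 2
  ids <- rep(NA_integer_, nrow(events))
  for (ci in unique(events$chrom)) {
    pe <- peaks[peaks$chrom == ci, ]
    ev <- which(events$chrom == ci)
    if (nrow(pe) == 0 || length(ev) == 0) next
    for (k in ev) {
      d <- pmax(0, pmax(pe$start - center[k], center[k] - pe$end))
      m <- which.min(d)
      if (length(m) == 1 && d[m] <= max_dist) ids[k] <- pe$id[m]
    }
  }
  events$hotspot_id <- ids
  list(events = events, fraction = mean(!is.na(ids)))
}

#' Peak intervals from a hotspot table
#'
#' Convenience: turns simulated hotspots into peak intervals
#' (`center` +/- `halfwidth`) usable with [overlap_hotspots()].
#'
#' @param hotspots hotspot table.
#' @param halfwidth half-width of the peak interval in bp.
#' @return data.frame with `chrom`, `start`, `end`, `id`.
#' @export
hotspot_peaks <- function(hotspots, halfwidth = 500) {
  data.frame(chrom = hotspots$chrom,
             start = hotspots$center - halfwidth,
             end = hotspots$center + halfwidth,
             id = hotspots$id, stringsAsFactors = FALSE)
}
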