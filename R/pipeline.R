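#' Call crossovers and NCOs for one sample
#'
#' Background inference, crossover calling, candidate extraction and
#' the filter cascade, end to end.
#'
#' @param genotypes `sample_genotypes` for the sample.
#' @param snp_map the SNP map.
#' @param founder_calls list(b6 =, cast =) founder genotypes or `NULL`.
#' @param params [hmm_params()].
#' @param fconfig [filter_config()].
#' @return list: `background`, `crossovers`, `ncos`, `report`.
#' @export
call_sample_events <- function(genotypes, snp_map,
                               founder_calls = NULL,
                               params = hmm_params(),
                               fconfig = filter_config()) {
  bg <- infer_background(genotypes, snp_map, params)
  cos <- call_crossovers(bg)
  cand <- call_nco_candidates(genotypes, bg, snp_map)
  flt <- apply_filters(cand, founder_calls, snp_map, fconfig,
                       crossovers = cos)
  list(background = bg, crossovers = cos, ncos = flt$events,
       report = flt$report)
}

#' Call events for every offspring sample of a simulated pedigree
#'
#' Runs [call_sample_events()] on each requested sample and binds the
#' results, annotating inheritance (F5 vs F4 parents) and parent of
#' origin for de novo events.
#'
#' @param calls named list of `sample_genotypes` (must include the
#'   founders `F0.B6`/`F0.CAST` when founder filtering is wanted).
#' @param pedigree the [simulate_pedigree()] output (for the SNP map
#'   and parent links).
#' @param samples sample ids to call (default: all sequenced F2/F4/F5).
#' @param params [hmm_params()].
#' @param fconfig [filter_config()].
#' @return list: `crossovers`, `ncos` (all samples bound, inheritance
#'   and parent filled where determinable), `reports` (per sample),
#'   `inherited_distinct` (deduplicated inherited NCO set).
#' @export
call_pedigree_events <- function(calls, pedigree, samples = NULL,
                                 params = hmm_params(),
                                 fconfig = filter_config()) {
  snp_map <- with_snp_index(pedigree$snp_map)
  founder_calls <- list(b6 = calls[["F0.B6"]], cast = calls[["F0.CAST"]])
  if (is.null(founder_calls$b6)) founder_calls <- NULL
  if (is.null(samples))
    samples <- setdiff(pedigree$sequenced, c("F0.B6", "F0.CAST"))
  cos_l <- list(); nco_l <- list(); reports <- list()
  for (id in samples) {
    res <- call_sample_events(calls[[id]], snp_map, founder_calls,
                              params, fconfig)
    cos_l[[id]] <- res$crossovers
    nco_l[[id]] <- res$ncos
    reports[[id]] <- res$report
  }
  cos <- do.call(rbind, cos_l)
  ncos <- do.call(rbind, nco_l)
  rownames(cos) <- rownames(ncos) <- NULL
  parents <- lapply(pedigree$individuals, function(ind)
    c(ind$mother, ind$father))
  names(parents) <- names(pedigree$individuals)
  f5 <- grepl("^F5", ncos$sample_id)
  f4 <- grepl("^F4", ncos$sample_id)
  inherited_distinct <- NULL
  if (any(f5) && any(f4)) {
    cls <- classify_inheritance(ncos[f5, ], ncos[f4, ], parents)
    ncos$inheritance[f5] <- cls$events$inheritance
    inherited_distinct <- cls$inherited_distinct
    dn <- f5 & ncos$inheritance == "de_novo"
    if (any(dn))
      ncos[dn, ] <- assign_parent_of_origin(ncos[dn, ], calls, parents)
  }
  if (!is.null(cos) && nrow(cos) > 0) {
    cf5 <- grepl("^F5", cos$sample_id)
    cf4 <- grepl("^F4", cos$sample_id)
    if (any(cf5) && any(cf4)) {
      cls <- classify_inheritance(cos[cf5, ], cos[cf4, ], parents)
      cos$inheritance[cf5] <- cls$events$inheritance
      dn <- cf5 & cos$inheritance == "de_novo"
      if (any(dn))
        cos[dn, ] <- assign_parent_of_origin(cos[dn, ], calls, parents)
    }
  }
  list(crossovers = cos, ncos = ncos, reports = reports,
       inherited_distinct = inherited_distinct)
}
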