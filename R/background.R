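#' Parameters of the background-ancestry HMM
#'
#' @param genotyping_error per-call error probability `eps` used in the
#'   emission model (concordant call has probability `1 - eps`, each of
#'   the two discordant calls `eps/2`; missing calls are uninformative).
#' @param switch_rate per-bp scale `r` of the transition probability:
#'   over a gap of `d` bp the chance of leaving the current state is
#'   `1 - exp(-r d)`, split over the reachable states; direct
#'   BB to CC moves are disallowed (they pass through BC).
#' @param posterior_threshold minimum posterior for a SNP's state to be
#'   assigned; below it the SNP is left unassigned.
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(genotyping_error = 0.002,
                       switch_rate = 1e-7,
                       posterior_threshold = 0.9) {
  if (genotyping_error <= 0 || genotyping_error >= 0.5)
    stop("`genotyping_error` must lie in (0, 0.5)")
  if (switch_rate <= 0) stop("`switch_rate` must be positive")
  if (posterior_threshold <= 0.5 || posterior_threshold > 1)
    stop("`posterior_threshold` must lie in (0.5, 1]")
  structure(list(genotyping_error = genotyping_error,
                 switch_rate = switch_rate,
                 posterior_threshold = posterior_threshold),
            class = "hmm_params")
}

BG_STATES <- c("BB", "BC", "CC")

#' Infer background ancestry states along the genome
#'
#' Runs the 3-state HMM (homozygous B6 / heterozygous / homozygous
#' CAST background) on one sample's ordered genotype calls, decodes by
#' per-SNP posterior argmax (forward-backward), and collapses the
#' assigned states into contiguous segments.
#'
#' @param genotypes a `sample_genotypes` object.
#' @param snp_map the SNP map the calls are ordered along.
#' @param params an [hmm_params()] object.
#' @return list of class `background` with elements `state` (integer
#'   per SNP: 0 = BB, 1 = BC, 2 = CC, `NA` = unassigned), `posterior`
#'   (max posterior per SNP), `segments` (data.frame: `sample_id`,
#'   `chrom`, `first_idx`, `last_idx`, `first_pos`, `last_pos`,
#'   `state`, `mean_posterior`), and `sample_id`.
#' @export
infer_background <- function(genotypes, snp_map, params = hmm_params()) {
  stopifnot(inherits(params, "hmm_params"))
  n <- nrow(snp_map)
  if (length(genotypes$call) != n)
    stop("genotype calls and snp_map differ in length")
  state <- rep(NA_integer_, n)
  maxpost <- rep(NA_real_, n)
  for (ci in unique(snp_map$chrom)) {
    idx <- which(snp_map$chrom == ci)
    pos <- snp_map$pos[idx]
    if (is.unsorted(pos, strictly = TRUE))
      stop("SNP positions must be strictly increasing within chromosome")
    calls <- genotypes$call[idx]
    if (all(is.na(calls))) {
      warning("chromosome ", ci, ": all calls missing; states unassigned")
      next
    }
    post <- hmm_fb_cpp(calls, pos, params$genotyping_error,
                       params$switch_rate)
    mp <- apply(post, 1, max)
    st <- max.col(post, ties.method = "first") - 1L
    st[mp < params$posterior_threshold] <- NA_integer_
    state[idx] <- st
    maxpost[idx] <- mp
  }
  segments <- segment_states(state, maxpost, snp_map,
                             genotypes$sample_id)
  structure(list(sample_id = genotypes$sample_id, state = state,
                 posterior = maxpost, segments = segments),
            class = "background")
}

# collapse per-SNP states into maximal same-state runs of assigned SNPs
segment_states <- function(state, posterior, snp_map, sample_id) {
  assigned <- which(!is.na(state))
  if (length(assigned) == 0)
    return(data.frame(sample_id = character(), chrom = integer(),
                      first_idx = integer(), last_idx = integer(),
                      first_pos = numeric(), last_pos = numeric(),
                      state = character(), mean_posterior = numeric(),
                      stringsAsFactors = FALSE))
  ch <- snp_map$chrom[assigned]
  st <- state[assigned]
  new_run <- c(TRUE, st[-1] != st[-length(st)] |
                 ch[-1] != ch[-length(ch)])
  run_id <- cumsum(new_run)
  first <- tapply(assigned, run_id, min)
  last <- tapply(assigned, run_id, max)
  data.frame(
    sample_id = sample_id,
    chrom = snp_map$chrom[first],
    first_idx = as.integer(first),
    last_idx = as.integer(last),
    first_pos = snp_map$pos[first],
    last_pos = snp_map$pos[last],
    state = BG_STATES[st[!duplicated(run_id)] + 1L],
    mean_posterior = as.numeric(
      tapply(posterior[assigned], run_id, mean)),
    stringsAsFactors = FALSE, row.names = NULL)
}
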