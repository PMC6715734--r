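#' Write genotype calls as VCF
#'
#' Emits a minimal VCF 4.2 with GT, DP and AD fields, one column per
#' sample, 1-based positions, B6 allele as REF and CAST allele as ALT.
#'
#' @param calls named list of `sample_genotypes`.
#' @param snp_map the SNP map.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_genotypes_vcf <- function(calls, snp_map, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ncomap",
    paste0("##contig=<ID=chr", unique(snp_map$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", names(calls)), collapse = "\t"))
  cols <- lapply(calls, function(s) {
    gt <- ifelse(is.na(s$call), "./.", gt_code[s$call + 1L])
    paste0(gt, ":", s$dp, ":", s$ad_b6, ",", s$ad_cast)
  })
  body <- do.call(paste, c(list(
    paste0("chr", snp_map$chrom), format(snp_map$pos, scientific = FALSE,
                                         trim = TRUE),
    ".", snp_map$allele_b6, snp_map$allele_cast, ".", "PASS", ".",
    "GT:DP:AD"), cols, sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF written by [write_genotypes_vcf()]
#'
#' Uses the vcfR package to parse GT/DP/AD.
#'
#' @param path VCF path.
#' @return list with `snp_map` (chrom, pos, allele_b6, allele_cast and
#'   classes) and `calls` (named list of `sample_genotypes` without
#'   generation labels).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snp_map <- data.frame(
    chrom = as.integer(sub("^chr", "", fix$CHROM)),
    pos = as.numeric(fix$POS),
    allele_b6 = fix$REF, allele_cast = fix$ALT,
    stringsAsFactors = FALSE)
  snp_map$class_b6 <- base_class(snp_map$allele_b6)
  snp_map$class_cast <- base_class(snp_map$allele_cast)
  class(snp_map) <- c("snp_map", "data.frame")
  gt <- vcfR::extract.gt(v, "GT")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  calls <- lapply(colnames(gt), function(s) {
    g <- gt[, s]
    call <- rep(NA_integer_, length(g))
    call[g %in% c("0/0", "0|0")] <- 0L
    call[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    call[g %in% c("1/1", "1|1")] <- 2L
    adm <- do.call(rbind, strsplit(ad[, s], ",", fixed = TRUE))
    structure(list(sample_id = s, generation = NA_character_,
                   call = call, dp = as.integer(dp[, s]),
                   ad_b6 = as.integer(adm[, 1]),
                   ad_cast = as.integer(adm[, 2])),
              class = "sample_genotypes")
  })
  names(calls) <- colnames(gt)
  list(snp_map = snp_map, calls = calls)
}

#' Write events as BED6+ with annotation columns
#'
#' 0-based half-open intervals: NCO rows span the minimal tract, CO
#' rows the breakpoint interval. Extra columns carry the annotations.
#'
#' @param events `nco_calls` or `crossover_calls`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_events_bed <- function(events, path) {
  is_nco <- "min_start" %in% names(events)
  start <- if (is_nco) events$min_start - 1 else events$left_pos - 1
  end <- if (is_nco) events$min_end else events$right_pos
  df <- data.frame(
    chrom = paste0("chr", events$chrom),
    start = format(start, scientific = FALSE, trim = TRUE),
    end = format(end, scientific = FALSE, trim = TRUE),
    name = paste0(if (is_nco) "NCO" else "CO", ":",
                  events$sample_id),
    score = if (is_nco) events$n_sites else 0L,
    strand = ".",
    inheritance = events$inheritance,
    parent = events$parent,
    complex = events$complex,
    hotspot_id = if ("hotspot_id" %in% names(events))
      events$hotspot_id else NA,
    recipient = if (is_nco) events$recipient_bg else "NA",
    converted = if (is_nco)
      vapply(events$converted_pos, paste, character(1), collapse = ",")
    else "")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write or read a hotspot table as TSV
#'
#' @param hotspots hotspot table.
#' @param path file path.
#' @return the path (write) or the table (read).
#' @export
write_hotspots_tsv <- function(hotspots, path) {
  utils::write.table(hotspots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hotspots_tsv
#' @export
read_hotspots_tsv <- function(path) {
  hs <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(hs) <- c("hotspot_set", "data.frame")
  hs
}

#' Serialise a sim_config to JSON (and back)
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return the path (write); a `sim_config` (read).
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  do.call(sim_config, jsonlite::read_json(path, simplifyVector = TRUE))
}
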