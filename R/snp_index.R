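# Fast positional lookups into a SNP map. The map must be sorted by
# (chrom, pos); simulate_snp_map() guarantees this. The index is cached
# as an attribute so repeated calls are free.

snp_index <- function(snp_map) {
  idx <- attr(snp_map, "snp_index")
  if (!is.null(idx) && idx$n == nrow(snp_map)) return(idx)
  chroms <- sort(unique(snp_map$chrom))
  pos_by <- lapply(chroms, function(ci) snp_map$pos[snp_map$chrom == ci])
  off <- lapply(chroms, function(ci) which(snp_map$chrom == ci)[1] - 1L)
  idx <- list(chroms = chroms, pos = pos_by,
              offset = unlist(off), n = nrow(snp_map))
  idx
}

with_snp_index <- function(snp_map) {
  attr(snp_map, "snp_index") <- snp_index(snp_map)
  snp_map
}

# global row indices of SNPs with pos in [t0, t1] on chromosome ci
snp_range_idx <- function(idx, ci, t0, t1) {
  k <- match(ci, idx$chroms)
  if (is.na(k)) return(integer())
  p <- idx$pos[[k]]
  lo <- findInterval(t0 - 1e-9, p) + 1L
  hi <- findInterval(t1 + 1e-9, p)
  if (hi < lo) return(integer())
  (idx$offset[k] + lo):(idx$offset[k] + hi)
}

# global row index of the SNP nearest to pos on chromosome ci (vectorised)
snp_nearest_idx <- function(idx, ci, pos) {
  out <- rep(NA_integer_, length(pos))
  for (k in seq_along(idx$chroms)) {
    sel <- which(ci == idx$chroms[k])
    if (length(sel) == 0) next
    p <- idx$pos[[k]]
    j <- findInterval(pos[sel], p)
    j0 <- pmax(j, 1L)
    j1 <- pmin(j + 1L, length(p))
    pick <- ifelse(abs(pos[sel] - p[j0]) <= abs(p[j1] - pos[sel]), j0, j1)
    out[sel] <- idx$offset[k] + pick
  }
  out
}
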