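# random genome generators used across tests (always under an explicit seed
# set by the calling test)

# random non-duplicated linear genome over markers 1..n
rand_genome <- function(n, max_chrom = 2L, genome = "G") {
  ord <- sample(n)
  sgn <- sample(c(-1L, 1L), n, replace = TRUE)
  k <- sample.int(min(max_chrom, n), 1L)
  cuts <- if (k > 1L) sort(sample(seq_len(n - 1L), k - 1L)) else integer(0)
  bounds <- c(0L, cuts, n)
  chroms <- lapply(seq_len(k), function(i) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    ord[idx] * sgn[idx]
  })
  marker_genome(chroms, genome = genome)
}

# random signed sequence with duplicate families, as a signed character vector
rand_dup_seq <- function(len, n_fams = 4L, max_mult = 2L) {
  pool <- rep(seq_len(n_fams), max_mult)
  fams <- sample(pool, len, replace = FALSE)
  sgn <- sample(c(-1L, 1L), len, replace = TRUE)
  ifelse(sgn < 0, paste0("-", fams), as.character(fams))
}

# random marker tibble of several genomes with duplicated families
rand_genome_set <- function(n_genomes, markers_per_genome, n_fams,
                            max_chrom = 2L) {
  out <- lapply(seq_len(n_genomes), function(gi) {
    len <- markers_per_genome
    fams <- sample(n_fams, len, replace = TRUE)
    sgn <- sample(c(-1L, 1L), len, replace = TRUE)
    k <- sample.int(max_chrom, 1L)
    cuts <- if (k > 1L && len > 1L) {
      sort(sample(seq_len(len - 1L), min(k - 1L, len - 1L)))
    } else integer(0)
    bounds <- unique(c(0L, cuts, len))
    chroms <- lapply(seq_len(length(bounds) - 1L), function(i) {
      idx <- (bounds[i] + 1L):bounds[i + 1L]
      fams[idx] * sgn[idx]
    })
    marker_genome(chroms, genome = paste0("G", gi))
  })
  dplyr::bind_rows(out)
}
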