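#' Build a marker table from signed vectors
#'
#' The universal currency of the package is the *marker table*: a tibble with
#' one row per marker occurrence and columns `genome`, `chrom`, `pos`
#' (1-based ordinal position along the chromosome), `family` (unsigned family
#' identifier, a character string) and `sign` (`+1` or `-1`, the reading
#' orientation). `marker_genome()` is a convenience constructor turning a list
#' of signed vectors (one per chromosome) into that shape.
#'
#' Signed vectors may be numeric (`c(1, -2, 3)`) or character
#' (`c("a", "-b")`); a leading `-` encodes reverse orientation. Family
#' identifiers must not themselves start with `-`.
#'
#' @param chromosomes list of signed numeric or character vectors, optionally
#'   named (names become chromosome labels; unnamed chromosomes are labelled
#'   `chr1`, `chr2`, ...).
#' @param genome label for the genome.
#' @return a marker tibble.
#' @examples
#' marker_genome(list(c(1, -2, 3), 4), genome = "A")
#' @export
marker_genome <- function(chromosomes, genome = "G") {
  if (!is.list(chromosomes)) chromosomes <- list(chromosomes)
  nm <- names(chromosomes)
  if (is.null(nm)) nm <- rep("", length(chromosomes))
  nm[nm == ""] <- paste0("chr", seq_along(chromosomes))[nm == ""]
  rows <- purrr::map2(chromosomes, nm, function(v, cn) {
    sv <- parse_signed(v)
    if (length(sv$family) == 0L) return(NULL)
    tibble::tibble(
      genome = genome, chrom = cn,
      pos = seq_along(sv$family), family = sv$family, sign = sv$sign
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      genome = character(), chrom = character(), pos = integer(),
      family = character(), sign = integer()
    )
  }
  out
}

# split signed numeric/character entries into family + sign
parse_signed <- function(v) {
  if (length(v) == 0L) return(list(family = character(), sign = integer()))
  if (is.numeric(v)) {
    if (any(v == 0)) stop("marker family identifiers must be nonzero")
    return(list(family = as.character(abs(v)), sign = ifelse(v < 0, -1L, 1L)))
  }
  v <- as.character(v)
  neg <- startsWith(v, "-")
  fam <- ifelse(neg, substring(v, 2L), v)
  if (any(fam == "")) stop("empty marker family identifier")
  list(family = fam, sign = ifelse(neg, -1L, 1L))
}

#' Combine family and sign into a signed identifier
#'
#' @param family character vector of family ids.
#' @param sign integer vector of +1/-1.
#' @return character vector such as `"-F12"`.
#' @export
signed_id <- function(family, sign) {
  paste0(ifelse(sign < 0, "-", ""), family)
}

#' Read and write marker tables
#'
#' The on-disk dialect is a TSV with header
#' `genome_id`, `chromosome_id`, `position`, `signed_family_id`, one row per
#' marker occurrence with `position` 1-based and ascending within each
#' chromosome. Reading and writing round-trips exactly.
#'
#' @param path file path.
#' @return `read_markers()` returns a marker tibble.
#' @examples
#' # a small simulated five-genome dataset ships with the package
#' m <- read_markers(system.file("extdata", "example_markers.tsv",
#'                               package = "ancar"))
#' dplyr::count(m, genome)
#' @export
read_markers <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("genome_id", "chromosome_id", "position", "signed_family_id")
  if (!all(need %in% names(df))) {
    stop("marker TSV must have columns: ", paste(need, collapse = ", "))
  }
  sv <- parse_signed(df$signed_family_id)
  out <- tibble::tibble(
    genome = df$genome_id, chrom = df$chromosome_id,
    pos = as.integer(df$position), family = sv$family, sign = sv$sign
  )
  bad <- out |>
    dplyr::group_by(.data$genome, .data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0) || dplyr::n() == 1L,
                     .groups = "drop")
  if (nrow(out) > 0 && !all(bad$ok)) {
    stop("positions must be strictly ascending within each chromosome")
  }
  out
}

#' @rdname read_markers
#' @param markers a marker tibble.
#' @export
write_markers <- function(markers, path) {
  df <- data.frame(
    genome_id = markers$genome,
    chromosome_id = markers$chrom,
    position = markers$pos,
    signed_family_id = signed_id(markers$family, markers$sign)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_marker_tbl <- function(markers) {
  need <- c("genome", "chrom", "pos", "family", "sign")
  if (!all(need %in% names(markers))) {
    stop("expected a marker tibble with columns ", paste(need, collapse = ", "))
  }
  invisible(markers)
}

# named list: genome -> chrom -> list(fam = chr vector, sgn = int vector)
chrom_split <- function(markers) {
  check_marker_tbl(markers)
  out <- list()
  if (nrow(markers) == 0L) return(out)
  ord <- order(markers$genome, markers$chrom, markers$pos, method = "radix")
  m <- markers[ord, ]
  key <- paste(m$genome, m$chrom, sep = "\r")
  idx <- split(seq_len(nrow(m)), factor(key, levels = unique(key)))
  for (i in idx) {
    g <- m$genome[i[1]]; cn <- m$chrom[i[1]]
    if (is.null(out[[g]])) out[[g]] <- list()
    out[[g]][[cn]] <- list(fam = m$family[i], sgn = m$sign[i])
  }
  out
}
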