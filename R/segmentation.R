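#' Read pairwise local alignments
#'
#' The expected dialect is a LASTZ-general-style TSV with eight columns:
#' `name1, start1, end1, name2, start2, end2, strand2, score`, coordinates
#' 0-based half-open. Lines starting with `#` are ignored. Records whose
#' score falls below `min_score` are dropped, as are trivial self-alignments
#' (same sequence, identical intervals).
#'
#' @param path file path.
#' @param min_score minimum alignment score to keep.
#' @return a tibble of alignments.
#' @export
read_alignments <- function(path, min_score = 0) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(tibble::tibble(name1 = character(), start1 = integer(),
                          end1 = integer(), name2 = character(),
                          start2 = integer(), end2 = integer(),
                          strand2 = character(), score = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 8L)
  if (length(bad) > 0L) {
    stop("malformed alignment row at line ", lineno[bad[1]],
         ": expected 8 tab-separated fields")
  }
  m <- do.call(rbind, parts)
  suppressWarnings({
    s1 <- as.integer(m[, 2]); e1 <- as.integer(m[, 3])
    s2 <- as.integer(m[, 5]); e2 <- as.integer(m[, 6])
    sc <- as.numeric(m[, 8])
  })
  nab <- which(is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2) | is.na(sc))
  if (length(nab) > 0L) {
    stop("malformed alignment row at line ", lineno[nab[1]],
         ": non-numeric coordinate or score")
  }
  bad2 <- which(e1 <= s1 | e2 <= s2)
  if (length(bad2) > 0L) {
    stop("malformed alignment row at line ", lineno[bad2[1]],
         ": interval end must exceed start")
  }
  badst <- which(!m[, 7] %in% c("+", "-"))
  if (length(badst) > 0L) {
    stop("malformed alignment row at line ", lineno[badst[1]],
         ": strand must be + or -")
  }
  al <- tibble::tibble(name1 = m[, 1], start1 = s1, end1 = e1,
                       name2 = m[, 4], start2 = s2, end2 = e2,
                       strand2 = m[, 7], score = sc)
  self <- al$name1 == al$name2 & al$start1 == al$start2 & al$end1 == al$end2
  if (any(self)) {
    message("dropping ", sum(self), " trivial self-alignment(s)")
    al <- al[!self, ]
  }
  al[al$score >= min_score, ]
}

# map integer positions x inside [s_from, e_from) to the partner interval
# [s_to, e_to), linearly, strand-aware, snapped to integers
map_positions <- function(x, s_from, e_from, s_to, e_to, strand) {
  frac <- (x - s_from) / (e_from - s_from)
  if (strand == "+") {
    round(s_to + frac * (e_to - s_to))
  } else {
    round(e_to - frac * (e_to - s_to))
  }
}

#' Close alignment breakpoints to a fixed point
#'
#' Initial breakpoints are the alignment interval endpoints plus the sequence
#' ends. A breakpoint strictly inside one side of an alignment induces the
#' proportionally mapped breakpoint on the other side (strand-aware, snapped
#' to the nearest integer); propagation is iterated until no new breakpoint
#' appears, which is guaranteed to terminate because positions are integers
#' within fixed bounds. No atom may later contain a closed breakpoint in its
#' interior.
#'
#' @param alignments alignment tibble (see [read_alignments()]).
#' @param seq_lengths named integer vector of sequence lengths.
#' @return named list of sorted integer breakpoint vectors, one per sequence.
#' @export
close_breakpoints <- function(alignments, seq_lengths) {
  bps <- lapply(seq_lengths, function(n) c(0L, as.integer(n)))
  names(bps) <- names(seq_lengths)
  add <- function(seqn, x) {
    x <- as.integer(x[x >= 0 & x <= seq_lengths[[seqn]]])
    nw <- setdiff(x, bps[[seqn]])
    if (length(nw) > 0L) {
      bps[[seqn]] <<- sort(c(bps[[seqn]], nw))
      TRUE
    } else FALSE
  }
  if (nrow(alignments) > 0L) {
    for (r in seq_len(nrow(alignments))) {
      add(alignments$name1[r], c(alignments$start1[r], alignments$end1[r]))
      add(alignments$name2[r], c(alignments$start2[r], alignments$end2[r]))
    }
  }
  repeat {
    changed <- FALSE
    if (nrow(alignments) > 0L) for (r in seq_len(nrow(alignments))) {
      a <- alignments[r, ]
      inside1 <- bps[[a$name1]][bps[[a$name1]] > a$start1 &
                                  bps[[a$name1]] < a$end1]
      if (length(inside1) > 0L) {
        mapped <- map_positions(inside1, a$start1, a$end1, a$start2, a$end2,
                                a$strand2)
        changed <- add(a$name2, mapped) || changed
      }
      inside2 <- bps[[a$name2]][bps[[a$name2]] > a$start2 &
                                  bps[[a$name2]] < a$end2]
      if (length(inside2) > 0L) {
        mapped <- map_positions(inside2, a$start2, a$end2, a$start1, a$end1,
                                a$strand2)
        changed <- add(a$name1, mapped) || changed
      }
    }
    if (!changed) break
  }
  bps
}

segments_from_breakpoints <- function(bps) {
  out <- list()
  for (sq in names(bps)) {
    b <- bps[[sq]]
    if (length(b) < 2L) next
    out[[sq]] <- cbind(start = b[-length(b)], end = b[-1])
  }
  out
}

waste_of <- function(alignments, seq_lengths, min_length) {
  bps <- close_breakpoints(alignments, seq_lengths)
  segs <- segments_from_breakpoints(bps)
  atoms <- list()
  covered_len <- 0
  for (sq in names(segs)) {
    sm <- segs[[sq]]
    for (r in seq_len(nrow(sm))) {
      len <- sm[r, 2] - sm[r, 1]
      if (len < min_length) next
      cov <- FALSE
      if (nrow(alignments) > 0L) {
        cov <- any((alignments$name1 == sq & alignments$start1 <= sm[r, 1] &
                      alignments$end1 >= sm[r, 2]) |
                     (alignments$name2 == sq & alignments$start2 <= sm[r, 1] &
                        alignments$end2 >= sm[r, 2]))
      }
      if (!cov) next
      atoms[[length(atoms) + 1L]] <- tibble::tibble(
        seq = sq, start = as.integer(sm[r, 1]), end = as.integer(sm[r, 2]))
      covered_len <- covered_len + len
    }
  }
  list(atoms = if (length(atoms)) dplyr::bind_rows(atoms) else
    tibble::tibble(seq = character(), start = integer(), end = integer()),
    waste = unname(sum(seq_lengths) - covered_len),
    breakpoints = bps)
}

#' Segment sequences into atoms from pairwise local alignments
#'
#' Solves the genome segmentation problem heuristically. Breakpoints are
#' closed under alignment propagation ([close_breakpoints()]); candidate
#' atoms are the maximal segments between consecutive closed breakpoints.
#' Segments shorter than `min_length` or covered by no alignment become
#' *waste*. A greedy improvement pass then repeatedly discards the alignment
#' whose removal (followed by re-closing) reduces total waste the most,
#' stopping when no removal helps — waste is therefore never above the
#' all-alignments-kept baseline.
#'
#' @inheritParams close_breakpoints
#' @param min_length minimum atom length in bp (default 100).
#' @return object of class `segmentation`: `atoms` tibble (`seq`, `start`,
#'   `end`, 0-based half-open; `family`/`orientation` filled by
#'   [assign_families()]), `waste_total`, `min_length`, `seq_lengths`,
#'   `alignments` (the kept set), `dropped` (discarded alignments count).
#' @export
segment <- function(alignments, seq_lengths, min_length = 100L) {
  if (min_length < 1L) stop("min_length must be >= 1")
  seq_lengths <- stats::setNames(as.integer(seq_lengths), names(seq_lengths))
  cur <- alignments
  res <- waste_of(cur, seq_lengths, min_length)
  dropped <- 0L
  while (nrow(cur) > 0L) {
    wastes <- vapply(seq_len(nrow(cur)), function(i) {
      waste_of(cur[-i, ], seq_lengths, min_length)$waste
    }, numeric(1))
    best <- which.min(wastes)
    if (wastes[best] < res$waste) {
      cur <- cur[-best, ]
      res <- waste_of(cur, seq_lengths, min_length)
      dropped <- dropped + 1L
    } else break
  }
  atoms <- res$atoms
  atoms$family <- NA_character_
  atoms$orientation <- NA_character_
  structure(list(atoms = atoms, waste_total = res$waste,
                 min_length = min_length, seq_lengths = seq_lengths,
                 alignments = cur, breakpoints = res$breakpoints,
                 dropped = dropped),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation>", nrow(x$atoms), "atoms | waste:", x$waste_total,
      "bp | min_length:", x$min_length,
      "| alignments kept:", nrow(x$alignments), "dropped:", x$dropped, "\n")
  invisible(x)
}

#' @export
tidy.segmentation <- function(x, ...) x$atoms

#' @export
glance.segmentation <- function(x, ...) {
  tibble::tibble(n_atoms = nrow(x$atoms), waste_total = x$waste_total,
                 min_length = x$min_length,
                 n_families = length(unique(stats::na.omit(x$atoms$family))))
}

interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Group atoms into families via alignments
#'
#' Builds a graph on atoms with an edge whenever an alignment maps at least
#' `overlap_frac` of one atom onto at least `overlap_frac` of another
#' (projection through the alignment is proportional and strand-aware).
#' Families are the connected components; orientations are assigned by
#' breadth-first sign propagation from the first atom of each family (an
#' orientation conflict along an odd inversion cycle keeps the first
#' assignment).
#'
#' @param seg a [segment()] result.
#' @param overlap_frac minimum reciprocal overlap fraction (default 0.8).
#' @return the `segmentation` with `family` and `orientation` filled in.
#' @export
assign_families <- function(seg, overlap_frac = 0.8) {
  stopifnot(inherits(seg, "segmentation"))
  atoms <- seg$atoms
  n <- nrow(atoms)
  if (n == 0L) return(seg)
  al <- seg$alignments
  edges <- list()
  if (nrow(al) > 0L) for (r in seq_len(nrow(al))) {
    a <- al[r, ]
    in1 <- which(atoms$seq == a$name1 & atoms$start >= a$start1 &
                   atoms$end <= a$end1)
    in2 <- which(atoms$seq == a$name2 & atoms$start >= a$start2 &
                   atoms$end <= a$end2)
    for (i in in1) {
      img_s <- map_positions(atoms$start[i], a$start1, a$end1, a$start2,
                             a$end2, a$strand2)
      img_e <- map_positions(atoms$end[i], a$start1, a$end1, a$start2,
                             a$end2, a$strand2)
      lo <- min(img_s, img_e); hi <- max(img_s, img_e)
      for (j in in2) {
        ov <- interval_overlap(lo, hi, atoms$start[j], atoms$end[j])
        li <- atoms$end[i] - atoms$start[i]
        lj <- atoms$end[j] - atoms$start[j]
        if (ov >= overlap_frac * li && ov >= overlap_frac * lj && !(i == j)) {
          edges[[length(edges) + 1L]] <- c(i, j, if (a$strand2 == "+") 1L else -1L)
        }
      }
    }
  }
  fam <- integer(n); ori <- integer(n)
  adj <- vector("list", n)
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], list(e[c(2, 3)]))
    adj[[e[2]]] <- c(adj[[e[2]]], list(e[c(1, 3)]))
  }
  ord <- order(atoms$seq, atoms$start, method = "radix")
  fid <- 0L
  for (root in ord) {
    if (fam[root] != 0L) next
    fid <- fid + 1L
    fam[root] <- fid; ori[root] <- 1L
    queue <- root
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      for (nb in adj[[v]]) {
        u <- nb[1]
        if (fam[u] == 0L) {
          fam[u] <- fid
          ori[u] <- ori[v] * nb[2]
          queue <- c(queue, u)
        }
      }
    }
  }
  atoms$family <- sprintf("F%04d", fam)
  atoms$orientation <- ifelse(ori > 0, "+", "-")
  seg$atoms <- atoms
  seg
}

#' Export atoms as marker sequences and BED
#'
#' Atoms sorted by start on each sequence become a signed marker sequence.
#' Families present in fewer than two genomes are dropped (their atoms are
#' omitted), following the convention of keeping only markers shared by at
#' least two genomes.
#'
#' @param seg a segmentation with families assigned.
#' @param seq_genomes named character vector mapping sequence label to genome
#'   id; unnamed sequences default to their own label.
#' @return a marker tibble (chromosome = sequence label).
#' @export
export_markers <- function(seg, seq_genomes = NULL) {
  stopifnot(inherits(seg, "segmentation"))
  atoms <- seg$atoms
  if (nrow(atoms) == 0L) {
    return(marker_genome(list(), genome = "empty")[0, ])
  }
  if (any(is.na(atoms$family))) stop("assign_families() must be applied first")
  gmap <- function(sq) {
    if (!is.null(seq_genomes) && sq %in% names(seq_genomes)) seq_genomes[[sq]]
    else sq
  }
  atoms$genome <- vapply(atoms$seq, gmap, character(1))
  shared <- atoms |>
    dplyr::distinct(.data$family, .data$genome) |>
    dplyr::count(.data$family) |>
    dplyr::filter(.data$n >= 2L) |>
    dplyr::pull(.data$family)
  atoms <- atoms[atoms$family %in% shared, ]
  if (nrow(atoms) == 0L) {
    return(marker_genome(list(), genome = "empty")[0, ])
  }
  atoms <- atoms[order(atoms$genome, atoms$seq, atoms$start,
                       method = "radix"), ]
  atoms |>
    dplyr::group_by(.data$genome, .data$seq) |>
    dplyr::mutate(pos = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::transmute(genome = .data$genome, chrom = .data$seq,
                     pos = as.integer(.data$pos), family = .data$family,
                     sign = ifelse(.data$orientation == "-", -1L, 1L))
}

#' Write atoms as BED6
#'
#' Name field is `familyId.copyIndex`; score 0; strand from orientation.
#'
#' @param seg a segmentation with families assigned.
#' @param path file path.
#' @export
write_atoms_bed <- function(seg, path) {
  atoms <- seg$atoms
  if (nrow(atoms) > 0L) {
    atoms <- atoms[order(atoms$seq, atoms$start, method = "radix"), ]
    atoms <- atoms |>
      dplyr::group_by(.data$family) |>
      dplyr::mutate(copy = dplyr::row_number()) |>
      dplyr::ungroup()
    df <- data.frame(chrom = atoms$seq, start = atoms$start, end = atoms$end,
                     name = paste0(atoms$family, ".", atoms$copy), score = 0L,
                     strand = atoms$orientation)
  } else {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     name = character(), score = integer(),
                     strand = character())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Sequence identifiers and lengths from a FASTA file
#'
#' The segmentation stage needs only the labels and lengths of the input
#' sequences, not their nucleotide content.
#'
#' @param path FASTA file path.
#' @return named integer vector of sequence lengths.
#' @export
read_seq_lengths <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    len <- Biostrings::fasta.seqlengths(path)
    names(len) <- sub("\\s.*$", "", names(len))
    return(stats::setNames(as.integer(len), names(len)))
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  lens <- vapply(split(lines[!hdr], grp[!hdr]), function(x)
    sum(nchar(gsub("\\s", "", x))), integer(1))
  stats::setNames(as.integer(lens), ids)
}
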