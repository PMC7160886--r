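#' Indel-threshold tables for approximate common intervals
#'
#' The tolerance for inserted and missing markers in an occurrence window
#' depends on the size of the reference content: a `delta_table()` maps
#' content size to the three bounds `delta_add` (inserted markers),
#' `delta_loss` (missing markers) and `delta_sum` (their total). Two named
#' profiles ship with the package; both grow the bounds with content size:
#'
#' * `default`: add = loss = `floor(size/4)`, sum = `floor(size/3)`
#' * `relaxed`: add = loss = `floor(size/3)`, sum = `floor(size/2)`
#'
#' These profiles are conservative stand-ins — tune them to your data, or
#' supply a full custom table (`tibble`/TSV with columns `size`, `delta_add`,
#' `delta_loss`, `delta_sum`; sizes not listed fall back to the largest listed
#' size below them).
#'
#' @param profile `"default"`, `"relaxed"`, a tibble, or a TSV path.
#' @param max_size largest content size materialized for named profiles.
#' @return a tibble of class `delta_table`.
#' @export
delta_table <- function(profile = "default", max_size = 200L) {
  if (is.character(profile) && length(profile) == 1 &&
      profile %in% c("default", "relaxed")) {
    size <- seq_len(max_size)
    tbl <- if (profile == "default") {
      tibble::tibble(size = size, delta_add = size %/% 4L,
                     delta_loss = size %/% 4L, delta_sum = size %/% 3L)
    } else {
      tibble::tibble(size = size, delta_add = size %/% 3L,
                     delta_loss = size %/% 3L, delta_sum = size %/% 2L)
    }
    attr(tbl, "profile") <- profile
  } else {
    tbl <- if (is.character(profile)) {
      tibble::as_tibble(utils::read.delim(profile, sep = "\t"))
    } else {
      tibble::as_tibble(profile)
    }
    need <- c("size", "delta_add", "delta_loss", "delta_sum")
    if (!all(need %in% names(tbl))) {
      stop("custom delta table needs columns: ", paste(need, collapse = ", "))
    }
    tbl <- tbl[order(tbl$size), need]
    attr(tbl, "profile") <- "custom"
  }
  if (any(tbl$delta_add > tbl$delta_sum) || any(tbl$delta_loss > tbl$delta_sum)) {
    stop("delta_add and delta_loss must not exceed delta_sum")
  }
  if (any(diff(tbl$delta_sum) < 0) || any(diff(tbl$delta_add) < 0) ||
      any(diff(tbl$delta_loss) < 0)) {
    stop("delta thresholds must be non-decreasing in content size")
  }
  class(tbl) <- c("delta_table", class(tbl))
  tbl
}

delta_row <- function(delta, size) {
  i <- findInterval(size, delta$size)
  if (i == 0L) {
    return(list(add = 0L, loss = 0L, sum = 0L))
  }
  list(add = delta$delta_add[i], loss = delta$delta_loss[i],
       sum = delta$delta_sum[i])
}

#' Deviation of a window from a reference content
#'
#' @param ref_content character vector of family ids (the reference content).
#' @param window marker tibble or signed vector (the occurrence window).
#' @return named integer vector `c(inserted = , missing = )`: families in the
#'   window but not the reference, and vice versa (set semantics).
#' @export
interval_deviation <- function(ref_content, window) {
  w <- as_signed_seq(window)
  wf <- unique(w$fam)
  c(inserted = length(setdiff(wf, ref_content)),
    missing = length(setdiff(ref_content, wf)))
}

# valid occurrence windows of content gset on one chromosome (fam vector).
# A window must begin and end with a member of gset, satisfy the delta row,
# and not be strictly contained in another valid window.
occ_windows <- function(fam, gset, row) {
  n <- length(fam)
  inG <- fam %in% gset
  P <- which(inG)
  if (length(P) == 0L) return(NULL)
  s <- length(gset)
  valid <- list()
  for (a in P) {
    # incremental content scan from a
    seen <- new.env(parent = emptyenv())
    inserted <- 0L
    hit <- 0L
    for (b in a:n) {
      f <- fam[b]
      if (!exists(f, envir = seen)) {
        assign(f, TRUE, envir = seen)
        if (inG[b]) hit <- hit + 1L else inserted <- inserted + 1L
      }
      if (inserted > row$add) break
      if (inG[b]) {
        missing <- s - hit
        if (missing <= row$loss && inserted + missing <= row$sum) {
          valid[[length(valid) + 1L]] <- c(a, b, inserted, missing)
        }
      }
    }
  }
  if (length(valid) == 0L) return(NULL)
  vm <- do.call(rbind, valid)
  # maximality: drop windows strictly contained in another valid window
  keep <- rep(TRUE, nrow(vm))
  for (i in seq_len(nrow(vm))) {
    contained <- vm[, 1] <= vm[i, 1] & vm[, 2] >= vm[i, 2] &
      (vm[, 1] < vm[i, 1] | vm[, 2] > vm[i, 2])
    if (any(contained)) keep[i] <- FALSE
  }
  vm[keep, , drop = FALSE]
}

#' Discover reference-based approximate common intervals
#'
#' A designated reference genome is taken as scaffold: every maximal interval
#' of its chromosomes (an interval whose content cannot be grown by a
#' one-marker extension on either side) with content size between
#' `min_ref_size` and `max_ref_size` defines a candidate content set. For
#' each candidate, occurrence windows are sought in *all* genomes (including
#' additional occurrences in the reference itself): a window must begin and
#' end with a member of the content, deviate from it by at most the
#' `delta_table` row for the content size (inserted <= delta_add, missing <=
#' delta_loss, inserted + missing <= delta_sum), and be maximal (not strictly
#' contained in another valid window on the same chromosome). Block sets with
#' occurrences in fewer than `quorum` distinct genomes (the reference counts)
#' are dropped, and block sets with identical content and occurrence windows
#' are deduplicated.
#'
#' @param markers marker tibble holding all genomes.
#' @param reference genome id used as scaffold.
#' @param delta a [delta_table()], profile name, or TSV path.
#' @param quorum minimum number of distinct genomes (>= 2).
#' @param min_ref_size minimum reference content size (>= 2).
#' @param max_ref_size cap on reference content size (`Inf` = none); bounds
#'   the quadratic candidate enumeration on large genomes.
#' @param all_intervals if `TRUE`, candidate reference intervals are not
#'   restricted to maximal intervals.
#' @return an object of class `synteny_blocks`: list with `occurrences`
#'   (tibble `block_id`, `genome`, `chrom`, `start`, `end`, `inserted`,
#'   `missing`, `is_reference`) and `content` (named list block_id ->
#'   character vector).
#' @export
discover_blocks <- function(markers, reference, delta = "default",
                            quorum = 2L, min_ref_size = 2L,
                            max_ref_size = Inf, all_intervals = FALSE) {
  check_marker_tbl(markers)
  if (quorum < 2L) stop("quorum must be >= 2")
  if (min_ref_size < 2L) stop("min_ref_size must be >= 2")
  if (!inherits(delta, "delta_table")) delta <- delta_table(delta)
  ch <- chrom_split(markers)
  if (is.null(ch[[reference]])) stop("reference genome '", reference,
                                     "' not present")
  genomes <- names(ch)

  # ---- candidate reference intervals --------------------------------------
  cands <- list()
  for (cn in names(ch[[reference]])) {
    fam <- ch[[reference]][[cn]]$fam
    n <- length(fam)
    for (i in seq_len(n)) {
      cont <- character(0)
      for (j in i:n) {
        cont <- union(cont, fam[j])
        if (length(cont) > max_ref_size) break
        if (length(cont) < min_ref_size) next
        if (!all_intervals) {
          ok_left <- i == 1L || !(fam[i - 1L] %in% cont)
          ok_right <- j == n || !(fam[j + 1L] %in% cont)
          if (!ok_left || !ok_right) next
        }
        cands[[length(cands) + 1L]] <- list(chrom = cn, i = i, j = j,
                                            content = sort(cont))
      }
    }
  }
  if (length(cands) == 0L) {
    return(empty_blocks())
  }

  # ---- occurrences per candidate ------------------------------------------
  occ_rows <- list()
  content_l <- list()
  seen_keys <- new.env(parent = emptyenv())
  bnum <- 0L
  for (cd in cands) {
    gset <- cd$content
    row <- delta_row(delta, length(gset))
    occs <- list()
    for (g in genomes) {
      for (cn in names(ch[[g]])) {
        vm <- occ_windows(ch[[g]][[cn]]$fam, gset, row)
        if (!is.null(vm)) {
          for (r in seq_len(nrow(vm))) {
            occs[[length(occs) + 1L]] <-
              list(genome = g, chrom = cn, start = vm[r, 1], end = vm[r, 2],
                   inserted = vm[r, 3], missing = vm[r, 4])
          }
        }
      }
    }
    ref_occ <- list(genome = reference, chrom = cd$chrom,
                    start = cd$i, end = cd$j, inserted = 0L, missing = 0L)
    # drop any maximal window identical to the reference interval itself
    occs <- Filter(function(o) !(o$genome == reference &&
                                   o$chrom == cd$chrom &&
                                   o$start == cd$i && o$end == cd$j), occs)
    all_occ <- c(list(ref_occ), occs)
    if (length(unique(vapply(all_occ, `[[`, character(1), "genome"))) < quorum) next
    key <- paste(
      paste(gset, collapse = ","),
      paste(sort(vapply(all_occ, function(o)
        paste(o$genome, o$chrom, o$start, o$end, sep = ":"), character(1))),
        collapse = ";"),
      sep = "|")
    if (exists(key, envir = seen_keys)) next
    assign(key, TRUE, envir = seen_keys)
    bnum <- bnum + 1L
    bid <- sprintf("B%05d", bnum)
    content_l[[bid]] <- gset
    for (k in seq_along(all_occ)) {
      o <- all_occ[[k]]
      occ_rows[[length(occ_rows) + 1L]] <- tibble::tibble(
        block_id = bid, genome = o$genome, chrom = o$chrom,
        start = as.integer(o$start), end = as.integer(o$end),
        inserted = as.integer(o$inserted), missing = as.integer(o$missing),
        is_reference = k == 1L)
    }
  }
  if (length(occ_rows) == 0L) return(empty_blocks())
  structure(list(occurrences = dplyr::bind_rows(occ_rows),
                 content = content_l),
            class = "synteny_blocks")
}

empty_blocks <- function() {
  structure(list(
    occurrences = tibble::tibble(
      block_id = character(), genome = character(), chrom = character(),
      start = integer(), end = integer(), inserted = integer(),
      missing = integer(), is_reference = logical()),
    content = list()), class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("<synteny_blocks>", length(x$content), "block sets,",
      nrow(x$occurrences), "occurrences\n")
  invisible(x)
}

#' @export
tidy.synteny_blocks <- function(x, ...) x$occurrences

#' @export
glance.synteny_blocks <- function(x, ...) {
  tibble::tibble(n_blocks = length(x$content),
                 n_occurrences = nrow(x$occurrences),
                 n_genomes = length(unique(x$occurrences$genome)))
}

#' Cap mutually overlapping block sets
#'
#' When more than `cap` block sets mutually overlap (share marker
#' occurrences; see [overlap_components()]), only the `cap` highest-weight
#' ones per overlap component are kept. Weights default to the reference
#' interval length; supply summed local DCJ scores via `weights` (a named
#' numeric vector keyed by block id) to prefer rearrangement-coherent blocks.
#'
#' @param blocks a `synteny_blocks` object.
#' @param weights optional named numeric vector of block weights.
#' @param cap maximum number of block sets per overlap component.
#' @return a filtered `synteny_blocks` object.
#' @export
cap_overlapping_blocks <- function(blocks, weights = NULL, cap = 30L) {
  stopifnot(inherits(blocks, "synteny_blocks"))
  if (length(blocks$content) == 0L) return(blocks)
  comp <- overlap_components(blocks)$membership
  w <- if (is.null(weights)) {
    occ <- blocks$occurrences
    ref <- occ[occ$is_reference, ]
    stats::setNames(ref$end - ref$start + 1, ref$block_id)
  } else weights
  keep <- character(0)
  for (cid in unique(comp$component)) {
    ids <- comp$block_id[comp$component == cid]
    if (length(ids) <= cap) { keep <- c(keep, ids); next }
    ids <- ids[order(-w[ids], ids, method = "radix")]
    keep <- c(keep, ids[seq_len(cap)])
  }
  blocks$occurrences <- blocks$occurrences[blocks$occurrences$block_id %in% keep, ]
  blocks$content <- blocks$content[names(blocks$content) %in% keep]
  blocks
}

#' Write syntenic blocks as TSV
#'
#' Columns: `block_id`, `genome`, `chromosome`, `start_pos`, `end_pos`
#' (1-based marker ordinals, inclusive), `inserted`, `missing`,
#' `is_reference`.
#'
#' @param blocks a `synteny_blocks` object.
#' @param path file path.
#' @export
write_blocks <- function(blocks, path) {
  occ <- blocks$occurrences
  df <- data.frame(block_id = occ$block_id, genome = occ$genome,
                   chromosome = occ$chrom, start_pos = occ$start,
                   end_pos = occ$end, inserted = occ$inserted,
                   missing = occ$missing, is_reference = occ$is_reference)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
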