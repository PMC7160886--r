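#' Overlap components of syntenic block sets
#'
#' Two block sets *overlap* when any of their occurrence windows share a
#' marker occurrence (same genome, chromosome and position). The connected
#' components of the overlap graph are the units within which marker families
#' are refined.
#'
#' @param blocks a `synteny_blocks` object (see [discover_blocks()]).
#' @return a list with `membership` (tibble `block_id`, `component`) and
#'   `occurrences` (tibble `component`, `occ_id` of member occurrences).
#' @export
overlap_components <- function(blocks) {
  occ <- if (inherits(blocks, "synteny_blocks")) blocks$occurrences else blocks
  ids <- unique(occ$block_id)
  if (length(ids) == 0L) {
    return(list(membership = tibble::tibble(block_id = character(),
                                            component = character()),
                occurrences = tibble::tibble(component = character(),
                                             occ_id = character())))
  }
  # expand windows to occurrence ids
  reps <- occ$end - occ$start + 1L
  long <- tibble::tibble(
    block_id = rep(occ$block_id, reps),
    occ_id = paste(rep(occ$genome, reps), rep(occ$chrom, reps),
                   unlist(lapply(seq_len(nrow(occ)),
                                 function(i) occ$start[i]:occ$end[i])),
                   sep = ":"))
  long <- dplyr::distinct(long)
  # union-find over block ids via shared occurrence ids
  bidx <- stats::setNames(seq_along(ids), ids)
  parent <- seq_along(ids)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (grp in split(bidx[long$block_id], long$occ_id)) {
    if (length(grp) > 1L) {
      r1 <- find(grp[[1]])
      for (b in grp[-1]) { rb <- find(b); if (rb != r1) parent[rb] <- r1 }
    }
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  comp_label <- stats::setNames(sprintf("O%03d", as.integer(factor(
    roots, levels = unique(roots)))), ids)
  membership <- tibble::tibble(block_id = ids,
                               component = unname(comp_label[ids]))
  occs <- tibble::tibble(component = unname(comp_label[long$block_id]),
                         occ_id = long$occ_id) |> dplyr::distinct()
  list(membership = membership, occurrences = occs)
}

occ_id_of <- function(markers) {
  paste(markers$genome, markers$chrom, markers$pos, sep = ":")
}

#' Refine families by overlap-component membership (rule i)
#'
#' For each overlap component `O` and each family `F`, let `F_O` be the
#' occurrences of `F` embedded in blocks of `O`. When `F_O` is a *proper*
#' non-empty subset of `F`, those occurrences are split off into a new family
#' `F@O`; when the whole family lies inside one component (or wholly outside
#' all components) it is left untouched — which makes the rule idempotent.
#'
#' @param markers marker tibble (current family assignment).
#' @param components output of [overlap_components()].
#' @return list with `markers` (families rewritten) and `provenance` (tibble
#'   `new_family`, `parent_family`, `component`, `rule`).
#' @export
refine_rule_i <- function(markers, components) {
  check_marker_tbl(markers)
  occs <- components$occurrences
  markers$._occ <- occ_id_of(markers)
  comp_of <- stats::setNames(occs$component, occs$occ_id)
  markers$._comp <- unname(comp_of[markers$._occ])
  prov <- list()
  new_family <- markers$family
  for (f in unique(markers$family)) {
    idx <- which(markers$family == f)
    comps <- markers$._comp[idx]
    present <- unique(stats::na.omit(comps))
    for (co in sort(present)) {
      inside <- idx[!is.na(comps) & comps == co]
      if (length(inside) < length(idx)) {   # proper subset only
        nf <- paste0(f, "@", co)
        new_family[inside] <- nf
        prov[[length(prov) + 1L]] <- tibble::tibble(
          new_family = nf, parent_family = f, component = co, rule = "i")
      }
    }
  }
  markers$family <- new_family
  markers$._occ <- NULL; markers$._comp <- NULL
  list(markers = markers,
       provenance = if (length(prov)) dplyr::bind_rows(prov) else
         tibble::tibble(new_family = character(), parent_family = character(),
                        component = character(), rule = character()))
}

#' Refine families by assignment consistency (rule ii)
#'
#' For each marker occurrence `m1` of the reference genome, the one-to-one
#' assignments of all local DCJ computations it participates in are
#' collected per non-reference genome. If every such genome contributes
#' exactly one distinct partner occurrence — conflicting assignments to two
#' different partners in the same genome disqualify `m1`; being unmatched in
#' some computations does not — the set `{m1, m2, ..., mk}` becomes a new
#' family (provided it is a proper subset of the current family and spans at
#' least two genomes). Partners claimed by two different reference anchors
#' are dropped from both candidate families so the result stays a partition.
#'
#' @param markers marker tibble (after [refine_rule_i()]).
#' @param scores output of [score_block_set()] with `matched` list-column.
#' @param reference reference genome id.
#' @param exclude_heuristic drop computations flagged `exact = FALSE`.
#' @return list with `markers` and `provenance` as in [refine_rule_i()].
#' @export
refine_rule_ii <- function(markers, scores, reference,
                           exclude_heuristic = FALSE) {
  check_marker_tbl(markers)
  if (nrow(scores) == 0L) {
    return(list(markers = markers,
                provenance = tibble::tibble(
                  new_family = character(), parent_family = character(),
                  component = character(), rule = character())))
  }
  sc <- scores
  if (exclude_heuristic) sc <- sc[sc$exact, ]
  # flatten all matched pairs: one row per (computation, ref occ, tgt occ)
  pairs <- list()
  for (i in seq_len(nrow(sc))) {
    m <- sc$matched[[i]]
    if (nrow(m) == 0L) next
    ref_row <- sc[i, ]
    pairs[[length(pairs) + 1L]] <- tibble::tibble(
      block_id = ref_row$block_id,
      comp_id = i,
      ref_chrom = attr_ref_chrom(sc, i),
      ref_pos = m$ref_pos,
      tgt_genome = ref_row$genome,
      tgt_occ = paste(ref_row$genome, ref_row$chrom, m$tgt_pos, sep = ":"))
  }
  if (length(pairs) == 0L) {
    return(list(markers = markers,
                provenance = tibble::tibble(
                  new_family = character(), parent_family = character(),
                  component = character(), rule = character())))
  }
  pr <- dplyr::bind_rows(pairs)
  pr$ref_occ <- paste(reference, pr$ref_chrom, pr$ref_pos, sep = ":")

  # consistency per reference occurrence and target genome
  per_anchor <- pr |>
    dplyr::distinct(.data$ref_occ, .data$tgt_genome, .data$tgt_occ) |>
    dplyr::group_by(.data$ref_occ, .data$tgt_genome) |>
    dplyr::summarise(n_partners = dplyr::n(),
                     partner = dplyr::first(.data$tgt_occ), .groups = "drop")
  consistent_anchor <- per_anchor |>
    dplyr::group_by(.data$ref_occ) |>
    dplyr::summarise(ok = all(.data$n_partners == 1L), .groups = "drop")
  ok_anchors <- consistent_anchor$ref_occ[consistent_anchor$ok]
  members <- per_anchor[per_anchor$ref_occ %in% ok_anchors &
                          per_anchor$n_partners == 1L, ]
  # partners claimed by more than one anchor leave all candidate families
  dup_partners <- members$partner[duplicated(members$partner)]
  members <- members[!members$partner %in% dup_partners, ]

  occ_ids <- occ_id_of(markers)
  fam_of <- stats::setNames(markers$family, occ_ids)
  new_family <- markers$family
  prov <- list()
  serial <- integer(0)
  for (a in sort(unique(members$ref_occ))) {
    partners <- members$partner[members$ref_occ == a]
    grp <- c(a, partners)
    grp <- grp[grp %in% occ_ids]
    if (length(grp) < 2L) next
    fams <- unique(fam_of[grp])
    if (length(fams) != 1L) next       # assignments never cross families
    f <- fams[[1]]
    fam_members <- occ_ids[markers$family == f]
    if (length(grp) == length(fam_members)) next   # already exactly this family
    cur <- serial[f]
    serial[f] <- if (length(cur) == 0L || is.na(cur)) 1L else cur + 1L
    nf <- paste0(f, "#", serial[[f]])
    new_family[match(grp, occ_ids)] <- nf
    prov[[length(prov) + 1L]] <- tibble::tibble(
      new_family = nf, parent_family = f,
      component = NA_character_, rule = "ii")
  }
  markers$family <- new_family
  list(markers = markers,
       provenance = if (length(prov)) dplyr::bind_rows(prov) else
         tibble::tibble(new_family = character(), parent_family = character(),
                        component = character(), rule = character()))
}

attr_ref_chrom <- function(sc, i) sc$ref_chrom[i]

#' Refine marker families from scored syntenic blocks
#'
#' Applies [refine_rule_i()] (overlap-component splitting) followed by
#' [refine_rule_ii()] (assignment-consistency splitting). The result always
#' refines the input partition — families are only ever split, never merged —
#' and applying the procedure twice with the same blocks and scores is a
#' no-op.
#'
#' @param markers marker tibble.
#' @param blocks a `synteny_blocks` object.
#' @param scores output of [score_block_set()] (must carry `ref_chrom`; the
#'   [run_pipeline()] stage adds it, or use [score_block_set()] output
#'   augmented via the blocks' reference rows).
#' @param reference reference genome id.
#' @param exclude_heuristic drop non-exact computations from rule (ii).
#' @return list with `markers` (refined) and `provenance` tibble.
#' @export
refine_families <- function(markers, blocks, scores, reference,
                            exclude_heuristic = FALSE) {
  comp <- overlap_components(blocks)
  r1 <- refine_rule_i(markers, comp)
  scores <- add_ref_chrom(scores, blocks)
  r2 <- refine_rule_ii(r1$markers, scores, reference, exclude_heuristic)
  list(markers = r2$markers,
       provenance = dplyr::bind_rows(r1$provenance, r2$provenance))
}

# attach the reference chromosome of each block to score rows
add_ref_chrom <- function(scores, blocks) {
  if ("ref_chrom" %in% names(scores)) return(scores)
  occ <- if (inherits(blocks, "synteny_blocks")) blocks$occurrences else blocks
  ref <- occ[occ$is_reference, c("block_id", "chrom")]
  names(ref)[2] <- "ref_chrom"
  dplyr::left_join(scores, ref, by = "block_id")
}

#' Write a family-refinement provenance table
#'
#' @param provenance tibble from [refine_families()].
#' @param path file path.
#' @export
write_provenance <- function(provenance, path) {
  utils::write.table(as.data.frame(provenance), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
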