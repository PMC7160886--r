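#' Ancestral genome content from refined genomes
#'
#' A (refined) family contributes one ancestral marker when its occurrences
#' span at least two genomes and, if a two-clade split of the phylogeny is
#' supplied, at least one genome on each side of the split (families
#' conserved across the split were present in the common ancestor). Without
#' a split, any two genomes suffice.
#'
#' @param markers marker tibble of the (refined) extant genomes.
#' @param clade_split optional list of two character vectors of genome ids.
#' @return character vector of ancestral family ids.
#' @export
ancestral_content <- function(markers, clade_split = NULL) {
  check_marker_tbl(markers)
  fg <- dplyr::distinct(markers, .data$family, .data$genome)
  if (is.null(clade_split)) {
    tab <- table(fg$family)
    return(sort(names(tab)[tab >= 2L]))
  }
  stopifnot(length(clade_split) == 2L)
  a <- clade_split[[1]]; b <- clade_split[[2]]
  fams <- split(fg$genome, fg$family)
  keep <- vapply(fams, function(g) any(g %in% a) && any(g %in% b), logical(1))
  sort(names(fams)[keep])
}

#' Candidate ancestral intervals and adjacencies
#'
#' Two candidate sources: (a) *adjacencies* — unordered pairs of ancestral
#' families consecutive in an extant chromosome after restricting it to
#' ancestral content, observed in at least two genomes; (b) *block contents*
#' — the content of each syntenic block set restricted to ancestral
#' families (kept when at least two families remain). Weights are either the
#' number of distinct supporting genomes (`weight_mode = "occurrence"`) or,
#' for block candidates, the summed local DCJ scores of the block's scored
#' occurrences (`weight_mode = "dcj"`; adjacency candidates are always
#' weighted by genome support, and blocks with non-positive summed score are
#' dropped). Candidates with identical content are merged, summing weights.
#'
#' @param markers marker tibble of the (refined) extant genomes.
#' @param content ancestral family ids (see [ancestral_content()]).
#' @param blocks optional `synteny_blocks` object.
#' @param scores optional [score_block_set()] output (needed for
#'   `weight_mode = "dcj"`).
#' @param weight_mode `"dcj"` or `"occurrence"`.
#' @return tibble with list-column `content`, numeric `weight`, character
#'   `type` (`adjacency`/`block`/`merged`).
#' @export
collect_candidates <- function(markers, content, blocks = NULL,
                               scores = NULL,
                               weight_mode = c("dcj", "occurrence")) {
  weight_mode <- match.arg(weight_mode)
  check_marker_tbl(markers)
  cset <- new.env(parent = emptyenv())
  for (x in content) assign(x, TRUE, envir = cset)
  inC <- function(v) vapply(v, function(x) exists(x, envir = cset), logical(1))

  # (a) adjacencies on content-restricted chromosomes
  ch <- chrom_split(markers)
  adj <- list()
  for (g in names(ch)) {
    pairs <- character(0)
    for (cn in names(ch[[g]])) {
      fam <- ch[[g]][[cn]]$fam
      fam <- fam[inC(fam)]
      if (length(fam) < 2L) next
      a <- fam[-length(fam)]; b <- fam[-1]
      keep <- a != b
      pairs <- c(pairs, paste(pmin(a, b), pmax(a, b), sep = "\r")[keep])
    }
    adj[[g]] <- unique(pairs)
  }
  adj_tab <- table(unlist(adj, use.names = FALSE))
  adj_keep <- names(adj_tab)[adj_tab >= 2L]
  cands <- list()
  for (k in adj_keep) {
    cands[[length(cands) + 1L]] <- list(
      content = strsplit(k, "\r", fixed = TRUE)[[1]],
      weight = as.numeric(adj_tab[[k]]), type = "adjacency")
  }

  # (b) block contents restricted to ancestral families
  if (!is.null(blocks) && length(blocks$content) > 0L) {
    sc_by_block <- NULL
    if (weight_mode == "dcj") {
      if (is.null(scores)) stop("weight_mode 'dcj' needs scores")
      sc_by_block <- tapply(scores$score, scores$block_id, sum)
    }
    occ <- blocks$occurrences
    for (bid in names(blocks$content)) {
      cc <- blocks$content[[bid]][inC(blocks$content[[bid]])]
      if (length(cc) < 2L) next
      w <- if (weight_mode == "dcj") {
        s <- sc_by_block[bid]
        if (is.na(s) || s <= 0) next
        as.numeric(s)
      } else {
        length(unique(occ$genome[occ$block_id == bid]))
      }
      cands[[length(cands) + 1L]] <- list(content = sort(cc), weight = w,
                                          type = "block")
    }
  }
  if (length(cands) == 0L) {
    return(tibble::tibble(content = list(), weight = numeric(),
                          type = character()))
  }
  out <- tibble::tibble(
    content = lapply(cands, `[[`, "content"),
    weight = vapply(cands, `[[`, numeric(1), "weight"),
    type = vapply(cands, `[[`, character(1), "type"))
  key <- vapply(out$content, function(x)
    paste(sort(x, method = "radix"), collapse = "\r"), character(1))
  out |>
    dplyr::mutate(._key = key) |>
    dplyr::group_by(.data$._key) |>
    dplyr::summarise(content = .data$content[1],
                     weight = sum(.data$weight),
                     type = if (dplyr::n() > 1L) "merged" else .data$type[1],
                     .groups = "drop") |>
    dplyr::select(-"._key")
}

#' Extract contiguous ancestral regions from a PQ-tree
#'
#' Each child subtree of the root is one CAR (if the root is a Q-node or a
#' leaf, the whole tree is a single CAR). CAR marker order is the canonical
#' frontier; markers under a P-node are flagged unordered. The *fixation*
#' metric is the mean number of children over all Q-nodes (`NA` when the
#' tree has none) — larger values mean more of the ancestral order is pinned
#' down.
#'
#' @param tree a `pq_tree`.
#' @return object of class `car_set`: list with `cars` (tibble `car_id`,
#'   `pos`, `family`, `ordered`), `tree`, and `metrics` (list `car_count`,
#'   `marker_count`, `q_node_mean_children`).
#' @export
extract_cars <- function(tree) {
  stopifnot(inherits(tree, "pq_tree"))
  root <- tree$root
  subtrees <- if (root$type == "P") root$children else list(root)
  rows <- list()
  for (i in seq_along(subtrees)) {
    nd <- subtrees[[i]]
    fams <- pq_frontier(structure(list(root = nd), class = "pq_tree"))
    ordered <- car_ordered_flags(nd)
    rows[[i]] <- tibble::tibble(car_id = NA_integer_, pos = seq_along(fams),
                                family = fams, ordered = ordered,
                                ._first = fams[1])
  }
  # deterministic CAR numbering by first frontier marker
  ord <- order(vapply(rows, function(r) r$._first[1], character(1)),
               method = "radix")
  rows <- rows[ord]
  for (i in seq_along(rows)) rows[[i]]$car_id <- i
  cars <- dplyr::bind_rows(rows) |> dplyr::select(-"._first")
  qn <- pq_collect_nodes(root, "Q")
  metrics <- list(
    car_count = length(rows),
    marker_count = nrow(cars),
    q_node_mean_children = if (length(qn)) mean(vapply(qn, function(n)
      length(n$children), numeric(1))) else NA_real_)
  structure(list(cars = cars, tree = tree, metrics = metrics),
            class = "car_set")
}

# per-marker flag: TRUE when the marker's parent is a Q-node (or it is the
# lone marker of its CAR)
car_ordered_flags <- function(node) {
  if (node$type == "leaf") return(TRUE)
  walk <- function(nd, parent_q) {
    if (nd$type == "leaf") return(parent_q)
    kids <- nd$children
    if (nd$type == "P") {
      keys <- vapply(kids, function(k) sort(pq_leaves_of(k),
                                            method = "radix")[1], character(1))
      kids <- kids[order(keys, method = "radix")]
    }
    unlist(lapply(kids, walk, parent_q = nd$type == "Q"), use.names = FALSE)
  }
  walk(node, FALSE)
}

#' @export
print.car_set <- function(x, ...) {
  cat("<car_set>", x$metrics$car_count, "CARs over",
      x$metrics$marker_count, "markers | Q-node mean children:",
      if (is.na(x$metrics$q_node_mean_children)) "none" else
        format(x$metrics$q_node_mean_children, digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.car_set <- function(x, ...) x$cars

#' @export
glance.car_set <- function(x, ...) {
  tibble::as_tibble(x$metrics)
}

#' Render CARs in the parenthesized text convention
#'
#' One line per CAR: `car_id` then tab-separated family ids, with unordered
#' P-groups wrapped in parentheses.
#'
#' @param car_set a [extract_cars()] result.
#' @return character vector of lines.
#' @export
format_cars <- function(car_set) {
  root <- car_set$tree$root
  subtrees <- if (root$type == "P") root$children else list(root)
  render <- function(nd) {
    if (nd$type == "leaf") return(nd$leaf)
    kids <- nd$children
    if (nd$type == "P") {
      keys <- vapply(kids, function(k) sort(pq_leaves_of(k),
                                            method = "radix")[1], character(1))
      kids <- kids[order(keys, method = "radix")]
    }
    inner <- paste(vapply(kids, render, character(1)), collapse = "\t")
    if (nd$type == "P") paste0("(", inner, ")") else inner
  }
  txt <- vapply(subtrees, render, character(1))
  first <- vapply(subtrees, function(nd)
    pq_frontier(structure(list(root = nd), class = "pq_tree"))[1], character(1))
  txt <- txt[order(first, method = "radix")]
  paste0("CAR", seq_along(txt), "\t", txt)
}

#' Write CARs and their metrics
#'
#' @param car_set a [extract_cars()] result.
#' @param path path for the CAR text file; metrics are written next to it as
#'   `<path>.metrics.json`.
#' @export
write_cars <- function(car_set, path) {
  writeLines(format_cars(car_set), path)
  jsonlite::write_json(car_set$metrics, paste0(path, ".metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Reconstruct CARs from refined genomes and scored blocks
#'
#' Convenience wrapper chaining [ancestral_content()],
#' [collect_candidates()], [build_pq_tree()] and [extract_cars()].
#'
#' @inheritParams collect_candidates
#' @param clade_split optional two-clade split for the content rule.
#' @return a `car_set`; the acceptance log is attached as attribute `log`,
#'   the ancestral content as attribute `content`.
#' @export
reconstruct_cars <- function(markers, blocks = NULL, scores = NULL,
                             weight_mode = c("dcj", "occurrence"),
                             clade_split = NULL) {
  weight_mode <- match.arg(weight_mode)
  content <- ancestral_content(markers, clade_split)
  if (length(content) == 0L) stop("empty ancestral content")
  cands <- collect_candidates(markers, content, blocks, scores, weight_mode)
  bt <- build_pq_tree(cands, content)
  res <- extract_cars(bt$tree)
  attr(res, "log") <- bt$log
  attr(res, "content") <- content
  res
}
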