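#' PQ-trees for consecutive-ones ordering
#'
#' A PQ-tree represents a family of orderings of a fixed leaf set: children
#' of a *P-node* may be permuted arbitrarily, children of a *Q-node* keep
#' their order up to full reversal. `pq_tree()` creates the universal tree (a
#' single P-node over all leaves, every ordering allowed); [pq_insert()]
#' restricts it so that a given leaf subset is consecutive in every remaining
#' ordering.
#'
#' @param leaves character vector of distinct leaf identifiers.
#' @return an object of class `pq_tree`.
#' @export
pq_tree <- function(leaves) {
  leaves <- as.character(leaves)
  if (anyDuplicated(leaves)) stop("leaves must be distinct")
  root <- if (length(leaves) == 1L) {
    pq_leaf(leaves)
  } else {
    pq_node("P", lapply(leaves, pq_leaf))
  }
  structure(list(root = root, leaves = leaves), class = "pq_tree")
}

pq_leaf <- function(id) list(type = "leaf", leaf = id)
pq_node <- function(type, children) list(type = type, children = children)

pq_leaves_of <- function(node) {
  if (node$type == "leaf") return(node$leaf)
  unlist(lapply(node$children, pq_leaves_of), use.names = FALSE)
}

pq_normalize <- function(node) {
  if (node$type == "leaf") return(node)
  node$children <- lapply(node$children, pq_normalize)
  if (length(node$children) == 1L) return(node$children[[1]])
  if (node$type == "Q" && length(node$children) == 2L) node$type <- "P"
  node
}

wrap_p <- function(children) {
  if (length(children) == 1L) children[[1]] else pq_node("P", children)
}

# ---- reduction ------------------------------------------------------------
# nonroot_reduce returns list(status = empty|full|partial|fail, node = ...).
# A partial node is a Q-node whose children are ordered empty-end -> full-end.

nonroot_reduce <- function(node, inS) {
  if (node$type == "leaf") {
    return(list(status = if (inS(node$leaf)) "full" else "empty", node = node))
  }
  rs <- lapply(node$children, nonroot_reduce, inS = inS)
  st <- vapply(rs, `[[`, character(1), "status")
  if (any(st == "fail")) return(list(status = "fail", node = node))
  kids <- lapply(rs, `[[`, "node")
  if (all(st == "empty")) { node$children <- kids; return(list(status = "empty", node = node)) }
  if (all(st == "full"))  { node$children <- kids; return(list(status = "full",  node = node)) }

  if (node$type == "P") {
    E <- kids[st == "empty"]; F_ <- kids[st == "full"]; PT <- kids[st == "partial"]
    if (length(PT) >= 2L) return(list(status = "fail", node = node))
    if (length(PT) == 0L) {
      part <- pq_node("Q", list(wrap_p(E), wrap_p(F_)))
      return(list(status = "partial", node = part))
    }
    z <- PT[[1]]
    ch <- c(if (length(E)) list(wrap_p(E)), z$children,
            if (length(F_)) list(wrap_p(F_)))
    return(list(status = "partial", node = pq_node("Q", ch)))
  }

  # Q-node: after possible reversal the statuses must read E* [partial] F*
  for (orient in 1:2) {
    sq <- if (orient == 1) st else rev(st)
    kq <- if (orient == 1) kids else rev(kids)
    np <- sum(sq == "partial")
    if (np > 1L) next
    ne <- which(sq == "empty"); nf <- which(sq == "full")
    pp <- which(sq == "partial")
    k <- length(sq)
    ok <- TRUE
    if (length(ne) && any(ne != seq_along(ne))) ok <- FALSE
    if (length(nf) && any(nf != (k - length(nf) + 1L):k)) ok <- FALSE
    if (length(pp) && pp != length(ne) + 1L) ok <- FALSE
    if (!ok) next
    ch <- list()
    for (i in seq_len(k)) {
      if (sq[i] == "partial") ch <- c(ch, kq[[i]]$children)
      else ch <- c(ch, list(kq[[i]]))
    }
    return(list(status = "partial", node = pq_node("Q", ch)))
  }
  list(status = "fail", node = node)
}

root_reduce <- function(node, inS) {
  if (node$type == "leaf") return(node)
  rs <- lapply(node$children, nonroot_reduce, inS = inS)
  st <- vapply(rs, `[[`, character(1), "status")
  if (any(st == "fail")) return(NULL)
  kids <- lapply(rs, `[[`, "node")

  if (node$type == "P") {
    E <- kids[st == "empty"]; F_ <- kids[st == "full"]; PT <- kids[st == "partial"]
    if (length(PT) > 2L) return(NULL)
    if (length(PT) == 0L) {
      if (length(E) == 0L || length(F_) == 0L) { node$children <- kids; return(node) }
      node$children <- c(E, list(wrap_p(F_)))
      return(node)
    }
    if (length(PT) == 1L) {
      newq <- pq_node("Q", c(PT[[1]]$children, if (length(F_)) list(wrap_p(F_))))
      if (length(E) == 0L) return(newq)
      node$children <- c(E, list(newq))
      return(node)
    }
    newq <- pq_node("Q", c(PT[[1]]$children,
                           if (length(F_)) list(wrap_p(F_)),
                           rev(PT[[2]]$children)))
    if (length(E) == 0L) return(newq)
    node$children <- c(E, list(newq))
    return(node)
  }

  # Q-node root: the non-empty children must form one contiguous run whose
  # interior is all full; partial children may sit only at the run ends,
  # oriented with their full side inward.
  k <- length(st)
  nonempty <- which(st != "empty")
  if (length(nonempty) == 0L) { node$children <- kids; return(node) }
  if (any(diff(nonempty) != 1L)) return(NULL)
  run <- nonempty
  interior <- run[-c(1, length(run))]
  if (any(st[interior] == "partial")) return(NULL)
  if (sum(st == "partial") > 2L) return(NULL)
  ch <- list()
  for (i in seq_len(k)) {
    if (st[i] != "partial") { ch <- c(ch, list(kids[[i]])); next }
    if (i == run[1] && length(run) > 1L) {
      ch <- c(ch, kids[[i]]$children)           # empty side outward (left)
    } else if (i == run[length(run)] && length(run) > 1L) {
      ch <- c(ch, rev(kids[[i]]$children))      # empty side outward (right)
    } else {
      # single non-empty child that is partial: keep its own orientation
      ch <- c(ch, kids[[i]]$children)
    }
  }
  node$children <- ch
  node
}

#' Restrict a PQ-tree so a leaf subset is consecutive
#'
#' Standard PQ-tree reduction. When the constraint is compatible with the
#' orderings the tree represents, the tree is updated and `accepted` is
#' `TRUE`; otherwise the tree is returned unchanged with `accepted = FALSE`.
#'
#' @param tree a `pq_tree`.
#' @param interval character vector of leaf ids (subset of the tree's
#'   leaves).
#' @return list with elements `tree` and `accepted`.
#' @export
pq_insert <- function(tree, interval) {
  stopifnot(inherits(tree, "pq_tree"))
  S <- unique(as.character(interval))
  if (!all(S %in% tree$leaves)) {
    stop("interval contains leaves not in the tree")
  }
  if (length(S) <= 1L || length(S) == length(tree$leaves)) {
    return(list(tree = tree, accepted = TRUE))
  }
  sset <- new.env(parent = emptyenv())
  for (x in S) assign(x, TRUE, envir = sset)
  inS <- function(id) exists(id, envir = sset)
  ns <- length(S)

  descend <- function(node) {
    if (node$type != "leaf") {
      cnts <- vapply(node$children, function(ch)
        sum(vapply(pq_leaves_of(ch), inS, logical(1))), integer(1))
      hit <- which(cnts == ns)
      if (length(hit) == 1L) {
        sub <- descend(node$children[[hit]])
        if (is.null(sub)) return(NULL)
        node$children[[hit]] <- sub
        return(node)
      }
    }
    root_reduce(node, inS)
  }
  newroot <- descend(tree$root)
  if (is.null(newroot)) return(list(tree = tree, accepted = FALSE))
  tree$root <- pq_normalize(newroot)
  list(tree = tree, accepted = TRUE)
}

#' Canonical frontier of a PQ-tree
#'
#' One ordering from the represented family: Q-node children are emitted in
#' stored order; P-node children are emitted sorted by their smallest leaf
#' (radix order) for reproducibility.
#'
#' @param tree a `pq_tree` or node.
#' @return character vector of leaves.
#' @export
pq_frontier <- function(tree) {
  node <- if (inherits(tree, "pq_tree")) tree$root else tree
  emit <- function(nd) {
    if (nd$type == "leaf") return(nd$leaf)
    kids <- nd$children
    if (nd$type == "P") {
      keys <- vapply(kids, function(k) sort(pq_leaves_of(k),
                                            method = "radix")[1], character(1))
      kids <- kids[order(keys, method = "radix")]
    }
    unlist(lapply(kids, emit), use.names = FALSE)
  }
  emit(node)
}

#' Greedy weighted construction of a PQ-tree
#'
#' Candidates are processed in decreasing weight (ties: smaller content
#' first, then lexicographic by content) and inserted with [pq_insert()];
#' incompatible candidates are skipped. The acceptance log records the
#' processing order and each outcome.
#'
#' @param candidates tibble with list-column `content` (character vectors of
#'   leaf ids) and numeric column `weight`.
#' @param leaves character vector of all leaf ids.
#' @return list with `tree` (a `pq_tree`) and `log` (tibble `order`,
#'   `content`, `size`, `weight`, `accepted`).
#' @export
build_pq_tree <- function(candidates, leaves) {
  tree <- pq_tree(leaves)
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(list(tree = tree,
                log = tibble::tibble(order = integer(), content = character(),
                                     size = integer(), weight = numeric(),
                                     accepted = logical())))
  }
  key <- vapply(candidates$content, function(x)
    paste(sort(x, method = "radix"), collapse = ","), character(1))
  size <- lengths(candidates$content)
  ord <- order(-candidates$weight, size, key, method = "radix")
  logs <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    res <- pq_insert(tree, candidates$content[[i]])
    tree <- res$tree
    logs[[k]] <- tibble::tibble(order = k, content = key[i],
                                size = size[i],
                                weight = candidates$weight[i],
                                accepted = res$accepted)
  }
  list(tree = tree, log = dplyr::bind_rows(logs))
}

#' @export
print.pq_tree <- function(x, ...) {
  render <- function(nd) {
    if (nd$type == "leaf") return(nd$leaf)
    inner <- paste(vapply(nd$children, render, character(1)), collapse = " ")
    if (nd$type == "P") paste0("(", inner, ")") else paste0("[", inner, "]")
  }
  cat("<pq_tree>", length(x$leaves), "leaves:", render(x$root), "\n")
  invisible(x)
}

pq_collect_nodes <- function(node, type) {
  out <- list()
  walk <- function(nd) {
    if (nd$type == "leaf") return(invisible(NULL))
    if (nd$type == type) out[[length(out) + 1L]] <<- nd
    lapply(nd$children, walk)
    invisible(NULL)
  }
  walk(node)
  out
}

#' @export
glance.pq_tree <- function(x, ...) {
  qn <- pq_collect_nodes(x$root, "Q")
  pn <- pq_collect_nodes(x$root, "P")
  tibble::tibble(
    n_leaves = length(x$leaves),
    n_q_nodes = length(qn),
    n_p_nodes = length(pn),
    q_node_mean_children = if (length(qn)) mean(vapply(qn, function(n)
      length(n$children), numeric(1))) else NA_real_)
}
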