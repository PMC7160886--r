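#' Genome content, multiplicity and balance
#'
#' `content()` returns the set of (unsigned) family identifiers occurring in a
#' marker table; `multiplicity()` counts the occurrences of one family;
#' `is_balanced()` tests whether two marker tables have identical content with
#' identical per-family multiplicities (orientations are irrelevant). All
#' three operate on any slice of a marker table — a single chromosome, a
#' genome, or a whole collection — since multiplicity and balance propagate
#' naturally from sequences to genomes.
#'
#' @param markers a marker tibble (see [marker_genome()]).
#' @return `content()`: a character vector (sorted, unique);
#'   `multiplicity()`: a non-negative integer; `is_balanced()`: a logical.
#' @examples
#' content(marker_genome(list(c(1, -2, 2))))       # "1" "2"
#' multiplicity(marker_genome(list(c(1, -2, 2))), "2")  # 2
#' @export
content <- function(markers) {
  check_marker_tbl(markers)
  sort(unique(markers$family))
}

#' @rdname content
#' @param family an unsigned family identifier.
#' @export
multiplicity <- function(markers, family) {
  check_marker_tbl(markers)
  sum(markers$family == as.character(family))
}

#' @rdname content
#' @param x,y marker tibbles to compare.
#' @export
is_balanced <- function(x, y) {
  check_marker_tbl(x); check_marker_tbl(y)
  tx <- table(x$family); ty <- table(y$family)
  if (length(tx) != length(ty)) return(FALSE)
  if (!setequal(names(tx), names(ty))) return(FALSE)
  all(tx[names(ty)] == ty)
}

is_duplicated_genome <- function(markers) {
  anyDuplicated(markers$family) > 0L
}

# extremity labels: "<family>\th" / "<family>\tt" (tab cannot occur in ids
# written through the TSV dialect)
ext_label <- function(family, end) paste0(family, "\t", end)

# adjacency list for one genome given as chrom-split entry; each adjacency is
# a character vector of 1 (telomeric) or 2 extremities, canonically sorted
adjacencies_of <- function(chroms) {
  adjs <- list()
  for (ch in chroms) {
    fam <- ch$fam; sgn <- ch$sgn
    n <- length(fam)
    if (n == 0L) next
    left  <- ext_label(fam, ifelse(sgn > 0, "t", "h"))
    right <- ext_label(fam, ifelse(sgn > 0, "h", "t"))
    adjs[[length(adjs) + 1L]] <- left[1]
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        adjs[[length(adjs) + 1L]] <- sort(c(right[i], left[i + 1L]))
      }
    }
    adjs[[length(adjs) + 1L]] <- right[n]
  }
  adjs
}

#' Adjacency set of a non-duplicated genome
#'
#' Each marker `g` read in chromosome direction contributes its tail and head
#' extremities (reversed markers swap the two). An internal adjacency is the
#' unordered pair of incident extremities of consecutive markers; the
#' outermost extremities of a linear chromosome form singleton *telomeric*
#' adjacencies.
#'
#' @param markers a marker tibble holding one non-duplicated genome.
#' @return a tibble with columns `ext1`, `ext2` (`ext2` is `NA` for telomeric
#'   adjacencies); extremities are rendered as `"<family>:h"` / `"<family>:t"`.
#' @export
adjacency_set <- function(markers) {
  check_marker_tbl(markers)
  if (is_duplicated_genome(markers)) {
    stop("adjacency_set() requires a non-duplicated genome ",
         "(some family has multiplicity > 1)")
  }
  adjs <- adjacencies_of(unlist(chrom_split(markers), recursive = FALSE))
  pretty <- function(e) sub("\t", ":", e, fixed = TRUE)
  tibble::tibble(
    ext1 = vapply(adjs, function(a) pretty(a[1]), character(1)),
    ext2 = vapply(adjs, function(a) if (length(a) == 2L) pretty(a[2]) else NA_character_,
                  character(1))
  )
}

# core component decomposition shared by adjacency_graph() and the local DCJ
# scorer; gchroms/hchroms are lists of list(fam, sgn)
ag_components <- function(gchroms, hchroms) {
  U <- adjacencies_of(gchroms)
  V <- adjacencies_of(hchroms)
  # map extremity -> adjacency index on each side
  umap <- new.env(parent = emptyenv())
  for (i in seq_along(U)) for (e in U[[i]]) assign(e, i, envir = umap)
  vmap <- new.env(parent = emptyenv())
  for (i in seq_along(V)) for (e in V[[i]]) assign(e, i, envir = vmap)
  exts <- unlist(U, use.names = FALSE)
  eu <- vapply(exts, function(e) get(e, envir = umap), integer(1),
               USE.NAMES = FALSE)
  ev <- vapply(exts, function(e) {
    if (!exists(e, envir = vmap)) stop("genomes are not balanced: extremity ",
                                       sub("\t", ":", e), " missing from one side")
    get(e, envir = vmap)
  }, integer(1), USE.NAMES = FALSE)
  if (length(exts) != length(unlist(V, use.names = FALSE))) {
    stop("genomes are not balanced")
  }
  # union-find over vertices (U offset 0, V offset length(U))
  nU <- length(U); nV <- length(V)
  parent <- seq_len(nU + nV)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (k in seq_along(eu)) {
    ra <- find(eu[k]); rb <- find(nU + ev[k])
    if (ra != rb) parent[ra] <- rb
  }
  comp_of_edge <- vapply(eu, find, integer(1))
  deg <- integer(nU + nV)
  for (k in seq_along(eu)) {
    deg[eu[k]] <- deg[eu[k]] + 1L
    deg[nU + ev[k]] <- deg[nU + ev[k]] + 1L
  }
  comp_ids <- unique(comp_of_edge)
  kind <- character(length(comp_ids)); nedge <- integer(length(comp_ids))
  vroot <- vapply(seq_len(nU + nV), find, integer(1))
  for (j in seq_along(comp_ids)) {
    cid <- comp_ids[j]
    ne <- sum(comp_of_edge == cid)
    verts <- which(vroot == cid & deg > 0L)
    nedge[j] <- ne
    if (ne == length(verts)) {
      kind[j] <- "cycle"
    } else {
      kind[j] <- if (ne %% 2L == 1L) "odd_path" else "even_path"
    }
  }
  tibble::tibble(kind = kind, edges = nedge)
}

#' Adjacency graph of two balanced non-duplicated genomes
#'
#' The adjacency graph is the bipartite multigraph whose two vertex sets are
#' the adjacency sets of the genomes, with one edge per shared extremity.
#' Every vertex has degree at most two, so the graph decomposes into cycles
#' and paths; path endpoints are telomeric adjacencies. The decomposition
#' carries the classic DCJ distance (see [dcj_distance()]).
#'
#' @param g,h marker tibbles, each one non-duplicated genome; the two must be
#'   balanced.
#' @return an object of class `adjacency_graph`: list with `components`
#'   (tibble of `kind` in cycle/odd_path/even_path and `edges`), `n_markers`,
#'   `c` (cycles) and `o` (odd paths).
#' @export
adjacency_graph <- function(g, h) {
  check_marker_tbl(g); check_marker_tbl(h)
  if (is_duplicated_genome(g) || is_duplicated_genome(h)) {
    stop("adjacency_graph() requires non-duplicated genomes")
  }
  if (!is_balanced(g, h)) stop("genomes are not balanced")
  comp <- ag_components(unlist(chrom_split(g), recursive = FALSE),
                        unlist(chrom_split(h), recursive = FALSE))
  structure(
    list(components = comp,
         n_markers = nrow(g),
         c = sum(comp$kind == "cycle"),
         o = sum(comp$kind == "odd_path")),
    class = "adjacency_graph"
  )
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("<adjacency_graph> n =", x$n_markers,
      "| cycles:", x$c, "| odd paths:", x$o,
      "| even paths:", sum(x$components$kind == "even_path"), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.adjacency_graph <- function(x, ...) x$components

#' @export
glance.adjacency_graph <- function(x, ...) {
  tibble::tibble(n_markers = x$n_markers, cycles = x$c, odd_paths = x$o,
                 even_paths = sum(x$components$kind == "even_path"),
                 dcj_distance = x$n_markers - x$c - x$o / 2)
}

#' DCJ distance between two balanced non-duplicated genomes
#'
#' The minimum number of double-cut-and-join operations transforming one
#' genome into the other, computed as `n - c - o/2` from the number of cycles
#' `c` and odd paths `o` of the adjacency graph over `n` markers.
#'
#' @inheritParams adjacency_graph
#' @return a non-negative number.
#' @examples
#' g <- marker_genome(list(c(1, 2, 3)))
#' h <- marker_genome(list(c(1, -2, 3)))
#' dcj_distance(g, h)  # 1
#' @export
dcj_distance <- function(g, h) {
  ag <- adjacency_graph(g, h)
  ag$n_markers - ag$c - ag$o / 2
}

#' Exhaustive DCJ distance by breadth-first search
#'
#' Independent validation route for [dcj_distance()]: performs a breadth-first
#' search over genome states (represented by their adjacency sets, so circular
#' intermediates are permitted, as in the unrestricted DCJ model) applying all
#' possible DCJ operations until the target genome is reached. Exponential —
#' intended for small instances (a handful of markers) only.
#'
#' @inheritParams adjacency_graph
#' @param max_depth search depth guard.
#' @return the minimum number of DCJ operations.
#' @export
dcj_distance_search <- function(g, h, max_depth = 32L) {
  check_marker_tbl(g); check_marker_tbl(h)
  if (is_duplicated_genome(g) || is_duplicated_genome(h)) {
    stop("dcj_distance_search() requires non-duplicated genomes")
  }
  if (!is_balanced(g, h)) stop("genomes are not balanced")
  fams <- content(g)
  fid <- stats::setNames(seq_along(fams), fams)
  enc <- function(markers) {
    chroms <- unlist(chrom_split(markers), recursive = FALSE)
    lapply(chroms, function(ch) as.integer(fid[ch$fam]) * ch$sgn)
  }
  dcj_bfs_cpp(enc(g), enc(h), length(fams), as.integer(max_depth))
}
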