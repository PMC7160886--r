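# Independent brute-force oracles. Each reimplements the operation it checks
# by a different route (plain enumeration, igraph components, permutation
# scans) so that agreement with the package implementation is meaningful.

# ---- adjacency-graph components via igraph (for the local DCJ oracle) -----
# s_fams/t_fams: integer ids of a non-duplicated balanced pair (single
# chromosomes); signs +-1. Returns data.frame(kind, edges).
oracle_components <- function(s_fams, s_sgn, t_fams, t_sgn) {
  adjs_of <- function(fams, sgn, tag) {
    n <- length(fams)
    left <- paste0(fams, ifelse(sgn > 0, "t", "h"))
    right <- paste0(fams, ifelse(sgn > 0, "h", "t"))
    adj <- c(list(left[1]),
             if (n > 1) lapply(seq_len(n - 1), function(i)
               c(right[i], left[i + 1])),
             list(right[n]))
    names(adj) <- paste0(tag, seq_along(adj))
    adj
  }
  A <- adjs_of(s_fams, s_sgn, "u")
  B <- adjs_of(t_fams, t_sgn, "v")
  owner <- function(adj) {
    m <- list()
    for (nm in names(adj)) for (e in adj[[nm]]) m[[e]] <- nm
    m
  }
  ob <- owner(B)
  edges <- character(0)
  for (nm in names(A)) for (e in A[[nm]]) {
    edges <- c(edges, nm, ob[[e]])
  }
  g <- igraph::make_graph(edges, directed = FALSE)
  comp <- igraph::components(g)
  out <- data.frame(kind = character(0), edges = integer(0))
  for (ci in seq_len(comp$no)) {
    verts <- which(comp$membership == ci)
    sg <- igraph::induced_subgraph(g, verts)
    ne <- igraph::ecount(sg)
    nv <- igraph::vcount(sg)
    kind <- if (ne == nv) "cycle" else if (ne %% 2 == 1) "odd_path" else "even_path"
    out <- rbind(out, data.frame(kind = kind, edges = ne))
  }
  out
}

# ---- exhaustive local DCJ similarity --------------------------------------
# signed character/numeric vectors in; enumerates every subsequence choice
# realizing min-multiplicity balanced content and every bijection.
oracle_local_dcj <- function(s, t, p = 0.25, L = 8) {
  ps <- function(v) {
    v <- as.character(v)
    neg <- startsWith(v, "-")
    list(fam = ifelse(neg, substring(v, 2), v), sgn = ifelse(neg, -1L, 1L))
  }
  S <- ps(s); Tt <- ps(t)
  fams <- intersect(S$fam, Tt$fam)
  kf <- vapply(fams, function(g) min(sum(S$fam == g), sum(Tt$fam == g)),
               integer(1))
  m <- sum(kf)
  d <- length(S$fam) + length(Tt$fam) - 2L * m
  f <- function(l) (2 - l) / (L - 2) + 1
  if (m == 0L) return(-d * p)
  combs <- function(x, k) {
    if (length(x) == k) return(list(x))
    utils::combn(x, k, simplify = FALSE)
  }
  perms <- function(k) {
    if (k <= 1) return(list(seq_len(k)))
    do.call(c, lapply(seq_len(k), function(i)
      lapply(perms(k - 1), function(r) c(i, (seq_len(k)[-i])[r]))))
  }
  fam_opts <- lapply(seq_along(fams), function(fi) {
    g <- fams[fi]; k <- kf[[fi]]
    sp <- which(S$fam == g); tp <- which(Tt$fam == g)
    opts <- list()
    for (sc in combs(sp, k)) for (tc in combs(tp, k)) for (pm in perms(k)) {
      opts[[length(opts) + 1]] <- cbind(sc, tc[pm])
    }
    opts
  })
  best <- -Inf
  rec <- function(i, acc) {
    if (i > length(fam_opts)) {
      mat <- do.call(rbind, acc)
      spos <- mat[, 1]; tpos <- mat[, 2]
      os <- order(spos)
      ids <- integer(length(spos)); ids[os] <- seq_along(spos)
      ot <- order(tpos)
      comp <- oracle_components(seq_along(spos), S$sgn[spos[os]],
                                ids[ot], Tt$sgn[tpos[ot]])
      sc <- 0
      for (r in seq_len(nrow(comp))) {
        l <- switch(comp$kind[r], cycle = comp$edges[r],
                    odd_path = comp$edges[r] + 1, even_path = comp$edges[r] + 2)
        w <- if (comp$kind[r] == "cycle") 1 else 0.5
        sc <- sc + w * f(l)
      }
      best <<- max(best, sc - d * p)
      return(invisible(NULL))
    }
    for (opt in fam_opts[[i]]) rec(i + 1, c(acc, list(opt)))
  }
  rec(1, list())
  best
}

# ---- brute-force reference-based approximate common intervals -------------
# mirrors the documented definitions of discover_blocks() with plain loops
# over every interval and every window; returns a canonical set of keys
# "content|occ;occ;..." for comparison.
oracle_blocks <- function(markers, reference, delta, quorum = 2,
                          min_ref_size = 2) {
  sp <- split(markers[order(markers$genome, markers$chrom, markers$pos,
                            method = "radix"), ],
              paste(markers$genome, markers$chrom, sep = "\r"))
  chroms <- lapply(sp, function(x) x$family)
  genome_of <- vapply(sp, function(x) x$genome[1], character(1))
  ref_keys <- names(chroms)[genome_of == reference]
  drow <- function(size) {
    i <- findInterval(size, delta$size)
    if (i == 0) list(add = 0, loss = 0, sum = 0)
    else list(add = delta$delta_add[i], loss = delta$delta_loss[i],
              sum = delta$delta_sum[i])
  }
  blocks <- character(0)
  for (rk in ref_keys) {
    fam <- chroms[[rk]]
    n <- length(fam)
    for (i in seq_len(n)) for (j in i:n) {
      win <- fam[i:j]
      cont <- sort(unique(win))
      if (length(cont) < min_ref_size) next
      if (i > 1 && fam[i - 1] %in% cont) next
      if (j < n && fam[j + 1] %in% cont) next
      row <- drow(length(cont))
      occs <- character(0)
      for (ck in names(chroms)) {
        cf <- chroms[[ck]]
        nn <- length(cf)
        valid <- matrix(integer(0), ncol = 2)
        for (a in seq_len(nn)) for (b in a:nn) {
          if (!(cf[a] %in% cont) || !(cf[b] %in% cont)) next
          wf <- unique(cf[a:b])
          ins <- length(setdiff(wf, cont))
          mis <- length(setdiff(cont, wf))
          if (ins <= row$add && mis <= row$loss && ins + mis <= row$sum) {
            valid <- rbind(valid, c(a, b))
          }
        }
        if (nrow(valid) == 0) next
        keep <- rep(TRUE, nrow(valid))
        for (r in seq_len(nrow(valid))) {
          keep[r] <- !any(valid[, 1] <= valid[r, 1] & valid[, 2] >= valid[r, 2] &
                            (valid[, 1] < valid[r, 1] | valid[, 2] > valid[r, 2]))
        }
        for (r in which(keep)) {
          occs <- c(occs, paste(genome_of[[ck]],
                                sub("^.*\r", "", ck),
                                valid[r, 1], valid[r, 2], sep = ":"))
        }
      }
      ref_occ <- paste(reference, sub("^.*\r", "", rk), i, j, sep = ":")
      occs <- unique(c(ref_occ, occs))
      gset <- unique(vapply(strsplit(occs, ":"), `[[`, character(1), 1))
      if (length(gset) < quorum) next
      blocks <- c(blocks, paste(paste(cont, collapse = ","),
                                paste(sort(occs), collapse = ";"), sep = "|"))
    }
  }
  sort(unique(blocks))
}

blocks_to_keys <- function(blocks) {
  occ <- blocks$occurrences
  out <- character(0)
  for (bid in names(blocks$content)) {
    rows <- occ[occ$block_id == bid, ]
    occs <- paste(rows$genome, rows$chrom, rows$start, rows$end, sep = ":")
    out <- c(out, paste(paste(blocks$content[[bid]], collapse = ","),
                        paste(sort(unique(occs)), collapse = ";"), sep = "|"))
  }
  sort(unique(out))
}

# ---- consecutive-ones feasibility by permutation enumeration --------------
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  out
}

# position matrices POS[r, v] = position of value v in permutation r, cached
.c1p_cache <- new.env(parent = emptyenv())
perm_positions <- function(n) {
  key <- as.character(n)
  if (!is.null(.c1p_cache[[key]])) return(.c1p_cache[[key]])
  pm <- perm_matrix(n)
  R <- nrow(pm)
  POS <- matrix(0L, R, n)
  POS[cbind(rep(seq_len(R), n), as.vector(pm))] <- rep(seq_len(n), each = R)
  .c1p_cache[[key]] <- POS
  POS
}

# sets: list of character vectors; leaves: character vector
oracle_c1p_feasible <- function(sets, leaves) {
  n <- length(leaves)
  POS <- perm_positions(n)
  ok <- rep(TRUE, nrow(POS))
  for (s in sets) {
    idx <- match(s, leaves)
    sub <- POS[, idx, drop = FALSE]
    mx <- sub[, 1]; mn <- sub[, 1]
    for (j in seq_len(ncol(sub))[-1]) {
      mx <- pmax(mx, sub[, j]); mn <- pmin(mn, sub[, j])
    }
    ok <- ok & (mx - mn + 1L == length(idx))
  }
  any(ok)
}

# all frontiers of a pq_tree (small trees only)
all_frontiers <- function(tree) {
  node <- tree$root
  rec <- function(nd) {
    if (nd$type == "leaf") return(list(nd$leaf))
    kid_fr <- lapply(nd$children, rec)
    combine_seq <- function(frs) {
      out <- list(character(0))
      for (f in frs) {
        out <- do.call(c, lapply(out, function(pre)
          lapply(f, function(x) c(pre, x))))
      }
      out
    }
    if (nd$type == "Q") {
      fwd <- combine_seq(kid_fr)
      bwd <- combine_seq(rev(kid_fr))
      return(unique(c(fwd, bwd)))
    }
    pm <- perm_matrix(length(kid_fr))
    out <- list()
    for (r in seq_len(nrow(pm))) {
      out <- c(out, combine_seq(kid_fr[pm[r, ]]))
    }
    unique(out)
  }
  rec(node)
}

# ---- segmentation: exhaustive subset search -------------------------------
# own breakpoint-closure and waste computation (no calls into the package)
oracle_waste_fixed <- function(al, seq_lengths, min_length) {
  bp <- lapply(seq_lengths, function(n) c(0, n))
  if (nrow(al) > 0) {
    repeat {
      changed <- FALSE
      for (r in seq_len(nrow(al))) {
        a <- al[r, ]
        want1 <- c(a$start1, a$end1)
        want2 <- c(a$start2, a$end2)
        in1 <- bp[[a$name1]][bp[[a$name1]] > a$start1 & bp[[a$name1]] < a$end1]
        frac <- (in1 - a$start1) / (a$end1 - a$start1)
        want2 <- c(want2, if (a$strand2 == "+")
          round(a$start2 + frac * (a$end2 - a$start2))
          else round(a$end2 - frac * (a$end2 - a$start2)))
        in2 <- bp[[a$name2]][bp[[a$name2]] > a$start2 & bp[[a$name2]] < a$end2]
        frac2 <- (in2 - a$start2) / (a$end2 - a$start2)
        want1 <- c(want1, if (a$strand2 == "+")
          round(a$start1 + frac2 * (a$end1 - a$start1))
          else round(a$end1 - frac2 * (a$end1 - a$start1)))
        n1 <- setdiff(want1, bp[[a$name1]]); n2 <- setdiff(want2, bp[[a$name2]])
        if (length(n1)) { bp[[a$name1]] <- sort(c(bp[[a$name1]], n1)); changed <- TRUE }
        if (length(n2)) { bp[[a$name2]] <- sort(c(bp[[a$name2]], n2)); changed <- TRUE }
      }
      if (!changed) break
    }
  }
  covered <- 0
  for (sq in names(seq_lengths)) {
    b <- bp[[sq]]
    for (i in seq_len(length(b) - 1)) {
      s <- b[i]; e <- b[i + 1]
      if (e - s < min_length) next
      cov <- nrow(al) > 0 &&
        any((al$name1 == sq & al$start1 <= s & al$end1 >= e) |
              (al$name2 == sq & al$start2 <= s & al$end2 >= e))
      if (cov) covered <- covered + (e - s)
    }
  }
  sum(seq_lengths) - covered
}

oracle_min_waste <- function(alignments, seq_lengths, min_length) {
  k <- nrow(alignments)
  best <- Inf
  for (mask in 0:(2^k - 1)) {
    keep <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    w <- oracle_waste_fixed(alignments[keep, ], seq_lengths, min_length)
    best <- min(best, w)
  }
  best
}
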