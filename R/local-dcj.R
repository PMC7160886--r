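#' Component length score for local DCJ similarity
#'
#' Cycles and paths of the adjacency graph are rewarded proportionally to
#' their length: `f(l) = (2 - l)/(L - 2) + 1` for even `l >= 2`. Short
#' structures indicate similarity (`f(2) = 1`), structures of length `L`
#' score zero, and longer ones are penalized. `L` is an even length threshold
#' demarcating short from long cycles and paths.
#'
#' @param l even integer vector of component lengths (>= 2).
#' @param L even length threshold (> 2); default 8.
#' @return numeric scores.
#' @examples
#' f_score(c(2, 8, 14))  # 1, 0, -1
#' @export
f_score <- function(l, L = 8) {
  if (L <= 2 || L %% 2 != 0) stop("L must be an even integer > 2")
  if (length(l) == 0) return(numeric(0))
  if (any(l < 2) || any(l %% 2 != 0)) {
    stop("f_score() is defined on even lengths >= 2")
  }
  (2 - l) / (L - 2) + 1
}

as_signed_seq <- function(x) {
  if (is.list(x) && !is.data.frame(x) && all(c("fam", "sgn") %in% names(x))) {
    return(x)
  }
  if (is.data.frame(x)) {
    check_marker_tbl(x)
    ch <- unlist(chrom_split(x), recursive = FALSE)
    if (length(ch) > 1L) stop("expected a single linear marker sequence")
    if (length(ch) == 0L) return(list(fam = character(), sgn = integer()))
    return(ch[[1]])
  }
  parse_signed_vec <- parse_signed(x)
  list(fam = parse_signed_vec$family, sgn = parse_signed_vec$sign)
}

#' Maximal balanced content of two marker sequences
#'
#' The multiset realized by maximal balanced subsequences: each family `g`
#' present in both sequences contributes `min(m_S(g), m_T(g))` copies.
#'
#' @param s,t marker tibbles (single sequence) or signed vectors.
#' @return named integer vector (family -> copies), families sorted.
#' @export
balanced_content <- function(s, t) {
  ss <- as_signed_seq(s); tt <- as_signed_seq(t)
  fams <- intersect(unique(ss$fam), unique(tt$fam))
  if (length(fams) == 0L) return(stats::setNames(integer(0), character(0)))
  k <- vapply(fams, function(g) min(sum(ss$fam == g), sum(tt$fam == g)),
              integer(1))
  k <- k[order(names(k), method = "radix")]
  k
}

# all permutations of 1..k as a list of integer vectors (k small)
perms_of <- function(k) {
  if (k == 0L) return(list(integer(0)))
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- perms_of(k - 1L)
    for (r in rest) out[[length(out) + 1L]] <- c(i, (seq_len(k)[-i])[r])
  }
  out
}

# score a complete one-to-one assignment; spos/tpos are parallel vectors of
# matched positions. Returns list(score, components)
score_assignment <- function(spos, tpos, sgnS, sgnT, lenS, lenT, p, L) {
  m <- length(spos)
  d <- lenS + lenT - 2L * m
  if (m == 0L) {
    return(list(score = -d * p,
                components = tibble::tibble(kind = character(), edges = integer())))
  }
  os <- order(spos)
  ids <- integer(m)
  ids[os] <- seq_len(m)         # id by rank of S position
  fam1 <- as.character(seq_len(m))
  sg1 <- sgnS[spos[os]]
  ot <- order(tpos)
  fam2 <- as.character(ids[ot])
  sg2 <- sgnT[tpos[ot]]
  comp <- ag_components(list(list(fam = fam1, sgn = sg1)),
                        list(list(fam = fam2, sgn = sg2)))
  sc <- 0
  if (nrow(comp) > 0) {
    lens <- ifelse(comp$kind == "cycle", comp$edges,
                   ifelse(comp$kind == "odd_path", comp$edges + 1L,
                          comp$edges + 2L))
    w <- ifelse(comp$kind == "cycle", 1, 0.5)
    sc <- sum(w * f_score(lens, L))
  }
  list(score = sc - d * p, components = comp)
}

#' Local DCJ similarity of two marker sequences
#'
#' The local rearrangement score of a pair of syntenic substrings `S`, `T`.
#' Over all pairs of balanced subsequences realizing the maximal balanced
#' content (see [balanced_content()]) and all one-to-one assignments of their
#' occurrences, the similarity maximizes
#' \deqn{s = \sum_{C} f(|C|) + \tfrac12\big(\sum_{O} f(|O|+1) + \sum_{E} f(|E|+2)\big) - d\,p}
#' where the sums run over cycles, odd paths and even paths of the adjacency
#' graph of the matched, uniquely relabelled subsequences (component length =
#' number of edges; path lengths corrected so structures with equal sorting
#' distance have equal length), and `d` is the number of deleted (unmatched)
#' markers, each penalized by `p`.
#'
#' The search enumerates per-family occurrence bijections depth-first in a
#' fixed deterministic order, keeping the first optimum encountered; it stops
#' early when the incumbent reaches the provable upper bound (number of
#' matched pairs minus the constant deletion penalty). If `node_budget`
#' complete assignments are evaluated without finishing, the best incumbent is
#' returned with `exact = FALSE`.
#'
#' @inheritParams balanced_content
#' @param p deletion penalty per unmatched marker (>= 0); default 0.25.
#' @param L even length threshold of [f_score()]; default 8.
#' @param node_budget cap on evaluated complete assignments.
#' @return an object of class `local_dcj`: list with `score`, `matched`
#'   (tibble `family`, `ref_pos`, `ref_sign`, `tgt_pos`, `tgt_sign`), `d`,
#'   `components`, `exact`, `p`, `L`.
#' @examples
#' local_dcj_similarity(c(1, 2, 3), c(1, -2, 3))$score  # 5/3
#' @export
local_dcj_similarity <- function(s, t, p = 0.25, L = 8, node_budget = 1e5) {
  ss <- as_signed_seq(s); tt <- as_signed_seq(t)
  if (p < 0) stop("p must be >= 0")
  bc <- balanced_content(ss, tt)
  lenS <- length(ss$fam); lenT <- length(tt$fam)
  m_total <- sum(bc)
  d <- lenS + lenT - 2L * m_total

  empty_res <- function(score) {
    structure(list(
      score = score,
      matched = tibble::tibble(family = character(), ref_pos = integer(),
                               ref_sign = integer(), tgt_pos = integer(),
                               tgt_sign = integer()),
      d = d,
      components = tibble::tibble(kind = character(), edges = integer()),
      exact = TRUE, p = p, L = L), class = "local_dcj")
  }
  if (m_total == 0L) return(empty_res(-(lenS + lenT) * p))

  # per-family option lists: each option is list(spos=, tpos=) of length k
  fams <- names(bc)
  combn_safe <- function(x, k) {
    if (length(x) == k) return(list(x))
    utils::combn(x, k, simplify = FALSE)
  }
  options_per_fam <- lapply(fams, function(g) {
    sp <- which(ss$fam == g); tp <- which(tt$fam == g)
    k <- bc[[g]]
    scomb <- combn_safe(sp, k)
    tcomb <- combn_safe(tp, k)
    pms <- perms_of(k)
    opts <- list()
    for (sc in scomb) for (tc in tcomb) for (pm in pms) {
      opts[[length(opts) + 1L]] <- list(spos = sc, tpos = tc[pm])
    }
    opts
  })
  n_opts <- vapply(options_per_fam, length, integer(1))
  # put large branching factors last so early exits cut more
  ord <- order(n_opts, fams, method = "radix")
  options_per_fam <- options_per_fam[ord]
  fams_o <- fams[ord]

  upper <- m_total - d * p
  best <- list(score = -Inf, spos = NULL, tpos = NULL, comp = NULL)
  evals <- 0L
  exhausted <- TRUE

  sel_s <- vector("list", length(fams_o))
  sel_t <- vector("list", length(fams_o))
  dfs <- function(i) {
    if (evals >= node_budget) { exhausted <<- FALSE; return(TRUE) }
    if (i > length(fams_o)) {
      spos <- unlist(sel_s, use.names = FALSE)
      tpos <- unlist(sel_t, use.names = FALSE)
      r <- score_assignment(spos, tpos, ss$sgn, tt$sgn, lenS, lenT, p, L)
      evals <<- evals + 1L
      if (r$score > best$score + 1e-12) {
        best <<- list(score = r$score, spos = spos, tpos = tpos,
                      comp = r$components)
        if (best$score >= upper - 1e-9) return(TRUE)  # provably optimal
      }
      return(FALSE)
    }
    for (opt in options_per_fam[[i]]) {
      sel_s[[i]] <<- opt$spos
      sel_t[[i]] <<- opt$tpos
      if (dfs(i + 1L)) return(TRUE)
    }
    FALSE
  }
  dfs(1L)

  spos <- best$spos; tpos <- best$tpos
  os <- order(spos)
  matched <- tibble::tibble(
    family = ss$fam[spos[os]],
    ref_pos = spos[os], ref_sign = ss$sgn[spos[os]],
    tgt_pos = tpos[os], tgt_sign = tt$sgn[tpos[os]]
  )
  structure(list(score = best$score, matched = matched, d = d,
                 components = best$comp, exact = exhausted, p = p, L = L),
            class = "local_dcj")
}

#' @export
print.local_dcj <- function(x, ...) {
  cat("<local_dcj> score:", format(x$score, digits = 6),
      "| matched:", nrow(x$matched), "| deleted:", x$d,
      if (!x$exact) "| (heuristic: node budget hit)" else "", "\n")
  invisible(x)
}

#' @export
tidy.local_dcj <- function(x, ...) x$matched

#' @export
glance.local_dcj <- function(x, ...) {
  tibble::tibble(score = x$score, n_matched = nrow(x$matched), d = x$d,
                 exact = x$exact, p = x$p, L = x$L)
}

#' Score the occurrences of syntenic block sets against their reference
#'
#' For every non-reference occurrence of each block set, computes the local
#' DCJ similarity between the reference substring and the occurrence
#' substring. Results carry stable occurrence identifiers
#' (`genome:chrom:start-end`) for the family-refinement stage; matched
#' positions are reported as absolute chromosome positions.
#'
#' @param blocks a `synteny_blocks` object (see [discover_blocks()]) or its
#'   tidy occurrence tibble.
#' @param markers the marker tibble the blocks were discovered in.
#' @inheritParams local_dcj_similarity
#' @return tibble with columns `block_id`, `genome`, `chrom`, `start`, `end`,
#'   `occurrence_id`, `score`, `d`, `exact`, and list-column `matched` (each a
#'   tibble of matched pairs with absolute `ref_pos`/`tgt_pos`).
#' @export
score_block_set <- function(blocks, markers, p = 0.25, L = 8,
                            node_budget = 1e5) {
  occ <- if (inherits(blocks, "synteny_blocks")) blocks$occurrences else blocks
  check_marker_tbl(markers)
  ch <- chrom_split(markers)
  sub_seq <- function(genome, chrom, a, b) {
    v <- ch[[genome]][[chrom]]
    list(fam = v$fam[a:b], sgn = v$sgn[a:b])
  }
  out <- list()
  for (bid in unique(occ$block_id)) {
    rows <- occ[occ$block_id == bid, ]
    ref <- rows[rows$is_reference, ][1, ]
    if (is.na(ref$genome)) stop("block ", bid, " has no reference occurrence")
    S <- sub_seq(ref$genome, ref$chrom, ref$start, ref$end)
    tg <- rows[!rows$is_reference, ]
    if (nrow(tg) == 0L) next
    for (j in seq_len(nrow(tg))) {
      Tt <- sub_seq(tg$genome[j], tg$chrom[j], tg$start[j], tg$end[j])
      r <- local_dcj_similarity(signed_id(S$fam, S$sgn),
                                signed_id(Tt$fam, Tt$sgn),
                                p = p, L = L, node_budget = node_budget)
      mt <- r$matched
      mt$ref_pos <- mt$ref_pos + ref$start - 1L
      mt$tgt_pos <- mt$tgt_pos + tg$start[j] - 1L
      out[[length(out) + 1L]] <- tibble::tibble(
        block_id = bid, genome = tg$genome[j], chrom = tg$chrom[j],
        start = tg$start[j], end = tg$end[j],
        occurrence_id = paste0(tg$genome[j], ":", tg$chrom[j], ":",
                               tg$start[j], "-", tg$end[j]),
        score = r$score, d = r$d, exact = r$exact, matched = list(mt)
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(block_id = character(), genome = character(),
                          chrom = character(), start = integer(),
                          end = integer(), occurrence_id = character(),
                          score = numeric(), d = integer(), exact = logical(),
                          matched = list()))
  }
  dplyr::bind_rows(out)
}

#' Write local DCJ scores as TSV
#'
#' One row per scored occurrence; matched pairs are serialized as
#' `refPos:sign<->tgtPos:sign;...`.
#'
#' @param scores output of [score_block_set()].
#' @param path file path.
#' @export
write_scores <- function(scores, path) {
  ser <- vapply(scores$matched, function(m) {
    paste0(m$ref_pos, ":", m$ref_sign, "<->", m$tgt_pos, ":", m$tgt_sign,
           collapse = ";")
  }, character(1))
  df <- data.frame(block_id = scores$block_id, target_genome = scores$genome,
                   occurrence_id = scores$occurrence_id, score = scores$score,
                   d = scores$d, matched_pairs = ser)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
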