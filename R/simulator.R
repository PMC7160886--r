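#' Phylogeny nodes for the genome simulator
#'
#' A simulation phylogeny is a rooted tree of `sim_branch()` nodes. Each
#' branch carries the evolutionary events applied on the way from its parent
#' to it: zero or more whole-genome events (`"wgd"` doubles, `"wgt"` triples
#' the chromosome complement, each followed by random fractionation at
#' `loss_rate`), then `dcj_ops` random DCJ rearrangements. Leaves (nodes
#' without children) become extant genomes.
#'
#' @param name node label (leaf names become genome ids).
#' @param dcj_ops number of random DCJ operations on this branch.
#' @param wg_events character vector drawn from `"wgd"`, `"wgt"`.
#' @param loss_rate probability in `[0, 1)` that a *redundant* (post-event)
#'   marker copy is lost during fractionation; pre-event copies are retained,
#'   so every marker keeps at least one descendant copy.
#' @param children list of child `sim_branch()` nodes.
#' @return a list describing the branch.
#' @export
sim_branch <- function(name, dcj_ops = 0L, wg_events = character(),
                       loss_rate = 0.6, children = list()) {
  if (loss_rate < 0 || loss_rate >= 1) stop("loss_rate must be in [0, 1)")
  if (!all(wg_events %in% c("wgd", "wgt"))) {
    stop("wg_events must be 'wgd' or 'wgt'")
  }
  list(name = name, dcj_ops = as.integer(dcj_ops), wg_events = wg_events,
       loss_rate = loss_rate, children = children)
}

#' Eudicot-shaped example phylogeny
#'
#' A five-leaf phylogeny shaped like the classic eudicot study system: one
#' rosid-like outgroup leaf and four asterid-like leaves, with a whole-genome
#' triplication on the asterid stem and a whole-genome duplication on one
#' terminal branch. Internal branches carry `internal_ops` DCJ operations
#' (short stem branches), terminal branches `terminal_ops`.
#'
#' @param internal_ops DCJ operations per internal branch (default 5).
#' @param terminal_ops DCJ operations per terminal branch (default 10).
#' @param loss_rate fractionation loss rate (default 0.6).
#' @return a `sim_branch()` tree.
#' @export
eudicot_phylogeny <- function(internal_ops = 5L, terminal_ops = 10L,
                              loss_rate = 0.6) {
  sim_branch("root", children = list(
    sim_branch("rosid", dcj_ops = terminal_ops, loss_rate = loss_rate),
    sim_branch("asterid_anc", dcj_ops = internal_ops, wg_events = "wgt",
               loss_rate = loss_rate, children = list(
      sim_branch("asterid1", dcj_ops = terminal_ops, loss_rate = loss_rate),
      sim_branch("asterid_x", dcj_ops = internal_ops, loss_rate = loss_rate,
                 children = list(
        sim_branch("asterid2", dcj_ops = terminal_ops, loss_rate = loss_rate),
        sim_branch("asterid_y", dcj_ops = internal_ops, loss_rate = loss_rate,
                   children = list(
          sim_branch("asterid3", dcj_ops = terminal_ops,
                     loss_rate = loss_rate),
          sim_branch("asterid4", dcj_ops = terminal_ops, wg_events = "wgd",
                     loss_rate = loss_rate)))))))))
}

# internal simulation state: list of chromosomes, each list(occ = unique
# occurrence ids, fam = ancestral family ids, sgn = +-1)
state_to_markers <- function(state, genome) {
  rows <- list()
  for (i in seq_along(state)) {
    ch <- state[[i]]
    if (length(ch$fam) == 0L) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      genome = genome, chrom = names(state)[i] %||% paste0("chr", i),
      pos = seq_along(ch$fam), family = ch$fam, sign = ch$sgn, occ = ch$occ)
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(genome = character(), chrom = character(),
                          pos = integer(), family = character(),
                          sign = integer(), occ = character()))
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an ancestral genome
#'
#' `n_markers` unique signed markers (`m0001`, `m0002`, ...) are shuffled,
#' given random orientations, and partitioned into `n_chromosomes` linear
#' chromosomes at random cut points. Deterministic for a fixed RNG state.
#'
#' @param n_markers number of distinct markers (>= 0).
#' @param n_chromosomes number of linear chromosomes (<= `n_markers`).
#' @return marker tibble with genome id `"ancestor"` plus column `occ`
#'   (occurrence id, equal to the family for the ancestor).
#' @export
simulate_ancestor <- function(n_markers, n_chromosomes = 1L) {
  if (n_chromosomes > max(n_markers, 0L)) {
    if (n_markers == 0L && n_chromosomes == 0L) {
      return(state_to_markers(list(), "ancestor"))
    }
    stop("n_chromosomes must not exceed n_markers")
  }
  if (n_markers == 0L) return(state_to_markers(list(), "ancestor"))
  ids <- sprintf("m%04d", seq_len(n_markers))
  ord <- sample(n_markers)
  sgn <- sample(c(-1L, 1L), n_markers, replace = TRUE)
  cuts <- if (n_chromosomes > 1L) {
    sort(sample(seq_len(n_markers - 1L), n_chromosomes - 1L))
  } else integer(0)
  bounds <- c(0L, cuts, n_markers)
  state <- list()
  for (i in seq_len(n_chromosomes)) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    state[[paste0("chr", i)]] <- list(occ = ids[ord[idx]],
                                      fam = ids[ord[idx]],
                                      sgn = sgn[idx])
  }
  state_to_markers(state, "ancestor")
}

markers_to_state <- function(markers) {
  m <- markers[order(markers$chrom, markers$pos, method = "radix"), ]
  out <- list()
  for (cn in unique(m$chrom)) {
    i <- which(m$chrom == cn)
    occ <- if ("occ" %in% names(m)) m$occ[i] else m$family[i]
    out[[cn]] <- list(occ = occ, fam = m$family[i], sgn = m$sign[i])
  }
  out
}

# ---- DCJ operations on the occurrence-level adjacency set -----------------

state_adjacencies <- function(state) {
  adjs <- list()
  for (cn in names(state)) {
    ch <- state[[cn]]
    n <- length(ch$occ)
    if (n == 0L) next
    left <- paste0(ch$occ, ifelse(ch$sgn > 0, "\rt", "\rh"))
    right <- paste0(ch$occ, ifelse(ch$sgn > 0, "\rh", "\rt"))
    adjs[[length(adjs) + 1L]] <- c(NA_character_, left[1])
    if (n > 1L) for (i in seq_len(n - 1L)) {
      adjs[[length(adjs) + 1L]] <- c(right[i], left[i + 1L])
    }
    adjs[[length(adjs) + 1L]] <- c(right[n], NA_character_)
  }
  adjs
}

# rebuild linear chromosomes from an adjacency list; NULL if any circular
# component exists
adjacencies_to_state <- function(adjs, fam_of, sgn_base) {
  # next extremity map: other end of each adjacency
  nxt <- new.env(parent = emptyenv())
  telo <- character(0)
  for (a in adjs) {
    x <- a[1]; y <- a[2]
    if (is.na(x) && is.na(y)) next
    if (is.na(x)) { telo <- c(telo, y); next }
    if (is.na(y)) { telo <- c(telo, x); next }
    assign(x, y, envir = nxt); assign(y, x, envir = nxt)
  }
  other_end <- function(e) {
    occ <- sub("\r[ht]$", "", e)
    end <- sub("^.*\r", "", e)
    paste0(occ, "\r", if (end == "h") "t" else "h")
  }
  visited <- new.env(parent = emptyenv())
  state <- list()
  ci <- 0L
  for (t0 in sort(telo)) {
    if (exists(t0, envir = visited)) next
    occs <- character(0); sgns <- integer(0)
    e <- t0
    repeat {
      assign(e, TRUE, envir = visited)
      occ <- sub("\r[ht]$", "", e)
      end <- sub("^.*\r", "", e)
      occs <- c(occs, occ)
      sgns <- c(sgns, if (end == "t") 1L else -1L)
      e2 <- other_end(e)
      assign(e2, TRUE, envir = visited)
      if (!exists(e2, envir = nxt)) break   # telomere reached
      e <- get(e2, envir = nxt)
    }
    ci <- ci + 1L
    state[[paste0("chr", ci)]] <- list(occ = occs, fam = occs, sgn = sgns)
  }
  n_placed <- sum(vapply(state, function(ch) length(ch$occ), integer(1)))
  n_total <- length(unique(sub("\r[ht]$", "",
                               stats::na.omit(unlist(adjs)))))
  if (n_placed != n_total) return(NULL)   # circular chromosome excised
  for (cn in names(state)) {
    state[[cn]]$fam <- unname(fam_of[state[[cn]]$occ])
  }
  state
}

#' Apply random DCJ operations to a genome
#'
#' Each operation picks two distinct adjacencies uniformly (telomeric ones
#' included) and rejoins their extremities in one of the two alternative
#' ways, or cuts a single internal adjacency into two telomeres (fission).
#' Outcomes that excise a circular chromosome, and no-ops, are rejected and
#' redrawn, so the genome stays linear and every accepted operation changes
#' the adjacency set. Operates at occurrence level, so duplicated genomes
#' (post-polyploidy) are handled.
#'
#' @param markers marker tibble of one genome (with optional `occ` column).
#' @param k number of operations.
#' @return marker tibble after `k` operations (chromosomes relabelled
#'   `chr1..`, `occ` column retained).
#' @export
apply_dcj_ops <- function(markers, k) {
  state <- markers_to_state(markers)
  genome <- if (nrow(markers)) markers$genome[1] else "G"
  all_occ <- unlist(lapply(state, `[[`, "occ"), use.names = FALSE)
  if (anyDuplicated(all_occ)) {
    stop("apply_dcj_ops() needs unique occurrence ids ",
         "(duplicated genome without an 'occ' column?)")
  }
  fam_of <- character(0)
  for (ch in state) fam_of[ch$occ] <- ch$fam
  for (step in seq_len(k)) {
    adjs <- state_adjacencies(state)
    na <- length(adjs)
    if (na < 2L) break
    internal <- which(vapply(adjs, function(a) !any(is.na(a)), logical(1)))
    n_pair_ops <- na * (na - 1L) / 2L * 2L
    n_ops <- n_pair_ops + length(internal)
    done <- FALSE
    for (attempt in seq_len(200L)) {
      pick <- sample.int(n_ops, 1L)
      new_adjs <- adjs
      if (pick <= n_pair_ops) {
        variant <- (pick - 1L) %% 2L
        pair_idx <- (pick - 1L) %/% 2L  # 0-based index into pairs
        # decode pair (i, j), i < j
        i <- 1L; cum <- na - 1L
        while (pair_idx >= cum) { pair_idx <- pair_idx - cum; i <- i + 1L; cum <- na - i }
        j <- i + pair_idx + 1L
        p <- adjs[[i]][1]; q <- adjs[[i]][2]
        r <- adjs[[j]][1]; s <- adjs[[j]][2]
        if (variant == 0L) { a1 <- c(p, r); a2 <- c(q, s) }
        else { a1 <- c(p, s); a2 <- c(q, r) }
        rep_l <- list()
        if (!all(is.na(a1))) rep_l <- c(rep_l, list(a1))
        if (!all(is.na(a2))) rep_l <- c(rep_l, list(a2))
        new_adjs <- c(adjs[-c(i, j)], rep_l)
      } else {
        i <- internal[pick - n_pair_ops]
        new_adjs <- c(adjs[-i], list(c(NA_character_, adjs[[i]][1]),
                                     c(NA_character_, adjs[[i]][2])))
      }
      ns <- adjacencies_to_state(new_adjs, fam_of, NULL)
      if (is.null(ns)) next                       # circular — redraw
      if (identical(canon_state(ns), canon_state(state))) next  # no-op
      state <- ns
      done <- TRUE
      break
    }
    if (!done) break
  }
  out <- state_to_markers(state, genome)
  out
}

# canonical key of a state, invariant to chromosome order/orientation
canon_state <- function(state) {
  keys <- vapply(state, function(ch) {
    fwd <- paste(ch$occ, ch$sgn, collapse = "|")
    rv <- paste(rev(ch$occ), rev(-ch$sgn), collapse = "|")
    min(fwd, rv)
  }, character(1))
  paste(sort(keys), collapse = "/")
}

#' Apply a whole-genome duplication or triplication with fractionation
#'
#' The chromosome complement is copied once (`"wgd"`) or twice (`"wgt"`);
#' every marker occurrence on the *new* copies is then deleted independently
#' with probability `loss_rate`. Pre-event copies are never deleted, so each
#' marker keeps at least one copy and `loss_rate = 1` would restore the
#' pre-event multiplicities exactly (hence the constraint `loss_rate < 1`
#' in [sim_branch()] is about retaining signal, not correctness).
#'
#' @param markers marker tibble of one genome (with optional `occ` column).
#' @param kind `"wgd"` or `"wgt"`.
#' @param loss_rate per-copy loss probability in `[0, 1]`.
#' @return marker tibble after the event.
#' @export
apply_polyploidy <- function(markers, kind = c("wgd", "wgt"), loss_rate) {
  kind <- match.arg(kind)
  state <- markers_to_state(markers)
  genome <- if (nrow(markers)) markers$genome[1] else "G"
  ncopy <- if (kind == "wgd") 1L else 2L
  # copy ids carry a per-event index so nested polyploidies never collide
  prev <- unlist(lapply(state, `[[`, "occ"), use.names = FALSE)
  ev <- suppressWarnings(max(0L, as.integer(sub(
    "^.*\\.w(\\d+)c\\d+$", "\\1", grep("\\.w\\d+c\\d+$", prev, value = TRUE)
  )))) + 1L
  new_state <- state
  for (cp in seq_len(ncopy)) {
    for (cn in names(state)) {
      ch <- state[[cn]]
      keep <- stats::runif(length(ch$occ)) >= loss_rate
      if (!any(keep)) next
      new_state[[paste0(cn, ".", cp + 1L)]] <- list(
        occ = paste0(ch$occ[keep], ".w", ev, "c", cp + 1L),
        fam = ch$fam[keep], sgn = ch$sgn[keep])
    }
  }
  state_to_markers(new_state, genome)
}

#' Simulate a full dataset along a phylogeny
#'
#' Walks the phylogeny from a random ancestor, applying each branch's
#' whole-genome events (with fractionation) and then its DCJ operations,
#' and collects the leaf genomes plus ground truth. All randomness is
#' controlled by `seed`.
#'
#' @param n_markers ancestor marker count.
#' @param n_chromosomes ancestor chromosome count.
#' @param phylogeny a [sim_branch()] tree (events on the root node are
#'   ignored; the root state is the ancestor itself).
#' @param seed integer seed (mandatory — every run is reproducible).
#' @return list with `genomes` (marker tibble of all leaves, chromosome
#'   labels prefixed by genome), `ancestor` (marker tibble), `truth` (list
#'   with `orthologs` tibble mapping each leaf occurrence to its ancestral
#'   marker and copy lineage, and `true_adjacencies` tibble of unsigned
#'   neighbouring ancestor pairs), `ops_log` (per-branch event record).
#' @export
simulate_dataset <- function(n_markers, n_chromosomes, phylogeny, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  anc <- simulate_ancestor(n_markers, n_chromosomes)
  leaves <- list()
  ops_log <- list()
  walk <- function(node, markers) {
    for (ev in node$wg_events) {
      markers <- apply_polyploidy(markers, ev, node$loss_rate)
      ops_log[[length(ops_log) + 1L]] <<- list(node = node$name, event = ev,
                                               loss_rate = node$loss_rate)
    }
    if (node$dcj_ops > 0L) {
      markers <- apply_dcj_ops(markers, node$dcj_ops)
      ops_log[[length(ops_log) + 1L]] <<- list(node = node$name,
                                               event = "dcj",
                                               count = node$dcj_ops)
    }
    if (length(node$children) == 0L) {
      m <- markers
      m$genome <- node$name
      m$chrom <- paste0(node$name, ".", m$chrom)
      leaves[[node$name]] <<- m
    } else {
      for (child in node$children) walk(child, markers)
    }
  }
  root <- phylogeny
  walk_children_only <- function() {
    if (length(root$children) == 0L) {
      walk(root, anc)
    } else {
      for (child in root$children) walk(child, anc)
    }
  }
  walk_children_only()
  genomes <- dplyr::bind_rows(leaves)
  orthologs <- tibble::tibble(
    genome = genomes$genome, chrom = genomes$chrom, pos = genomes$pos,
    occ_id = paste(genomes$genome, genomes$chrom, genomes$pos, sep = ":"),
    copy_lineage = genomes$occ,
    ancestral_marker = genomes$family)
  ch <- chrom_split(anc)
  tadj <- list()
  for (cn in names(ch[["ancestor"]])) {
    fam <- ch[["ancestor"]][[cn]]$fam
    if (length(fam) > 1L) {
      a <- fam[-length(fam)]; b <- fam[-1]
      tadj[[cn]] <- tibble::tibble(a = pmin(a, b), b = pmax(a, b))
    }
  }
  truth <- list(
    orthologs = orthologs,
    true_adjacencies = if (length(tadj)) dplyr::bind_rows(tadj) else
      tibble::tibble(a = character(), b = character()))
  list(genomes = genomes[, c("genome", "chrom", "pos", "family", "sign")],
       ancestor = anc[, c("genome", "chrom", "pos", "family", "sign")],
       truth = truth, ops_log = ops_log)
}

#' Write a simulated dataset to disk
#'
#' Marker TSVs (`<genome>.markers.tsv` per leaf plus `ancestor.markers.tsv`),
#' an ortholog truth TSV and an operations log JSON.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
emit_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in unique(dataset$genomes$genome)) {
    write_markers(dataset$genomes[dataset$genomes$genome == g, ],
                  file.path(dir, paste0(g, ".markers.tsv")))
  }
  write_markers(dataset$ancestor, file.path(dir, "ancestor.markers.tsv"))
  utils::write.table(as.data.frame(dataset$truth$orthologs),
                     file.path(dir, "orthologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(dataset$truth$true_adjacencies),
                     file.path(dir, "true_adjacencies.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$ops_log, file.path(dir, "ops_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
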