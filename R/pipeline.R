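default_config <- function() {
  list(
    io = list(markers = NULL, alignments = NULL, seq_lengths = NULL,
              seq_genomes = NULL),
    segmentation = list(min_length = 100L, min_score = 0, overlap_frac = 0.8),
    synteny = list(reference = NULL, quorum = 2L, delta_profile = "default",
                   delta_table_path = NULL, min_ref_size = 2L,
                   max_ref_size = 10L, overlap_cap = 30L),
    scoring = list(p = 0.25, L = 8L, node_budget = 1e5),
    refinement = list(enabled = TRUE, exclude_heuristic = FALSE),
    car = list(weight_mode = "dcj", clade_split = NULL),
    ablate_refinement = FALSE,
    seed = 1L,
    log_level = "info"
  )
}

merge_config <- function(defaults, user, path = character()) {
  for (k in names(user)) {
    if (!k %in% names(defaults)) {
      stop("unknown config key: ", paste(c(path, k), collapse = "."))
    }
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) stop("config key ", k, " must be a mapping")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a nested list; unknown keys are
#' rejected, known keys override the documented defaults (min atom length
#' 100 bp, deletion penalty `p = 0.25`, length threshold `L = 8`, quorum 2,
#' default delta profile, DCJ-score candidate weighting).
#'
#' @param config path or list (may be `NULL` for pure defaults).
#' @return fully materialized configuration list.
#' @export
load_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config)
  else config
  merge_config(default_config(), user)
}

pipe_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  message("[ancar] ", ...)
}

#' Run the full ancestral-reconstruction pipeline
#'
#' Orchestrates segmentation (optional) -> syntenic block discovery ->
#' local DCJ scoring -> family refinement -> CAR reconstruction, writing
#' every stage artifact plus a `metrics.json` into `outdir`. The pipeline
#' may start from marker TSVs (gene-based mode, segmentation skipped) by
#' setting `io.markers`, or from alignments by setting `io.alignments` and
#' `io.seq_lengths`. With `ablate_refinement = TRUE` the CAR stage is run
#' twice — with and without refined families — and both ancestral content
#' sizes and fixation metrics are reported.
#'
#' All stages are deterministic; rerunning with the same inputs reproduces
#' every artifact byte for byte.
#'
#' @param config configuration (path or list; see [load_config()]).
#' @param outdir run directory (created).
#' @param markers optional marker tibble, overriding `io.markers`.
#' @return the metrics list, invisibly; artifacts on disk in `outdir`.
#' @export
run_pipeline <- function(config = NULL, outdir, markers = NULL) {
  cfg <- load_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(
    c(list(tool = "ancar",
           version = as.character(utils::packageVersion("ancar"))), cfg),
    file.path(outdir, "config.resolved.yaml"))

  # ---- stage 1: markers ---------------------------------------------------
  if (is.null(markers)) {
    if (!is.null(cfg$io$markers)) {
      paths <- cfg$io$markers
      markers <- dplyr::bind_rows(lapply(paths, read_markers))
      pipe_log(cfg, "markers: read ", nrow(markers), " occurrences from ",
               length(paths), " file(s)")
    } else if (!is.null(cfg$io$alignments)) {
      if (is.null(cfg$io$seq_lengths)) {
        stop("segmentation stage: io.seq_lengths (FASTA or named lengths) ",
             "is required with io.alignments")
      }
      sl <- cfg$io$seq_lengths
      if (is.character(sl) && length(sl) == 1L && file.exists(sl)) {
        sl <- read_seq_lengths(sl)
      } else {
        sl <- unlist(sl)
      }
      al <- read_alignments(cfg$io$alignments,
                            min_score = cfg$segmentation$min_score)
      seg <- segment(al, sl, min_length = cfg$segmentation$min_length)
      seg <- assign_families(seg, overlap_frac = cfg$segmentation$overlap_frac)
      write_atoms_bed(seg, file.path(outdir, "atoms.bed"))
      sg <- cfg$io$seq_genomes
      markers <- export_markers(seg, if (is.null(sg)) NULL else unlist(sg))
      pipe_log(cfg, "segmentation: ", nrow(seg$atoms), " atoms, waste ",
               seg$waste_total, " bp")
    } else {
      stop("stage 'markers': provide io.markers or io.alignments in config")
    }
  }
  check_marker_tbl(markers)
  write_markers(markers, file.path(outdir, "markers.tsv"))

  # ---- stage 2: synteny ---------------------------------------------------
  reference <- cfg$synteny$reference
  if (is.null(reference)) {
    stop("stage 'synteny': config key synteny.reference is required")
  }
  delta <- if (!is.null(cfg$synteny$delta_table_path)) {
    delta_table(cfg$synteny$delta_table_path)
  } else {
    delta_table(cfg$synteny$delta_profile)
  }
  blocks <- discover_blocks(markers, reference = reference, delta = delta,
                            quorum = cfg$synteny$quorum,
                            min_ref_size = cfg$synteny$min_ref_size,
                            max_ref_size = cfg$synteny$max_ref_size)
  pipe_log(cfg, "synteny: ", length(blocks$content), " block sets")

  # ---- stage 3: local DCJ scores ------------------------------------------
  scores <- score_block_set(blocks, markers, p = cfg$scoring$p,
                            L = cfg$scoring$L,
                            node_budget = cfg$scoring$node_budget)
  pipe_log(cfg, "scoring: ", nrow(scores), " occurrence scores")
  if (!is.null(cfg$synteny$overlap_cap) &&
      is.finite(cfg$synteny$overlap_cap)) {
    w <- tapply(scores$score, scores$block_id, sum)
    blocks <- cap_overlapping_blocks(blocks, weights = w,
                                     cap = cfg$synteny$overlap_cap)
    scores <- scores[scores$block_id %in% names(blocks$content), ]
  }
  write_blocks(blocks, file.path(outdir, "blocks.tsv"))
  write_scores(scores, file.path(outdir, "scores.tsv"))

  # ---- stage 4: refinement ------------------------------------------------
  refined <- markers
  provenance <- NULL
  if (isTRUE(cfg$refinement$enabled)) {
    rf <- refine_families(markers, blocks, scores, reference,
                          exclude_heuristic = cfg$refinement$exclude_heuristic)
    refined <- rf$markers
    provenance <- rf$provenance
    write_markers(refined, file.path(outdir, "markers.refined.tsv"))
    write_provenance(provenance, file.path(outdir, "provenance.tsv"))
    pipe_log(cfg, "refinement: ", nrow(provenance), " new families")
  }

  # ---- stage 5: CARs ------------------------------------------------------
  split <- cfg$car$clade_split
  cars <- reconstruct_cars(refined, blocks, scores,
                           weight_mode = cfg$car$weight_mode,
                           clade_split = split)
  write_cars(cars, file.path(outdir, "cars.txt"))
  pipe_log(cfg, "cars: ", cars$metrics$car_count, " CARs over ",
           cars$metrics$marker_count, " markers")

  metrics <- list(
    n_marker_occurrences = nrow(markers),
    n_families = length(unique(markers$family)),
    n_blocks = length(blocks$content),
    n_scored_occurrences = nrow(scores),
    n_refined_families = length(unique(refined$family)),
    ancestral_content = cars$metrics$marker_count,
    car_count = cars$metrics$car_count,
    q_node_mean_children = cars$metrics$q_node_mean_children
  )

  if (isTRUE(cfg$ablate_refinement) && isTRUE(cfg$refinement$enabled)) {
    cars0 <- reconstruct_cars(markers, blocks, scores,
                              weight_mode = cfg$car$weight_mode,
                              clade_split = split)
    write_cars(cars0, file.path(outdir, "cars.unrefined.txt"))
    metrics$ancestral_content_unrefined <- cars0$metrics$marker_count
    metrics$car_count_unrefined <- cars0$metrics$car_count
    metrics$q_node_mean_children_unrefined <- cars0$metrics$q_node_mean_children
    metrics$content_change_pct <-
      100 * (metrics$ancestral_content - metrics$ancestral_content_unrefined) /
      metrics$ancestral_content_unrefined
  }

  jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res <- list(metrics = metrics, cars = cars, blocks = blocks,
              scores = scores, markers = markers, refined = refined,
              provenance = provenance, config = cfg)
  invisible(res)
}

#' Fraction of true ancestral adjacencies recovered within CARs
#'
#' Evaluation helper for simulated datasets: a true ancestral adjacency
#' `(a, b)` is *recovered* when some reconstructed CAR contains markers
#' mapping to both `a` and `b` (refined family ids map to their ancestral
#' family by stripping refinement suffixes). Only adjacencies whose two
#' endpoints are both represented in the reconstruction are counted
#' (restriction to reconstructed content).
#'
#' @param car_set a `car_set` from [extract_cars()]/[reconstruct_cars()].
#' @param true_adjacencies tibble with columns `a`, `b` (unsigned ancestral
#'   neighbours), e.g. `simulate_dataset()$truth$true_adjacencies`.
#' @return list with `recovered`, `evaluable`, `rate`.
#' @export
adjacency_recovery <- function(car_set, true_adjacencies) {
  cars <- car_set$cars
  base <- sub("[@#].*$", "", cars$family)
  car_of <- split(cars$car_id, base)
  present <- names(car_of)
  ta <- true_adjacencies[true_adjacencies$a %in% present &
                           true_adjacencies$b %in% present, ]
  if (nrow(ta) == 0L) return(list(recovered = 0L, evaluable = 0L,
                                  rate = NA_real_))
  hit <- vapply(seq_len(nrow(ta)), function(i) {
    length(intersect(car_of[[ta$a[i]]], car_of[[ta$b[i]]])) > 0L
  }, logical(1))
  list(recovered = sum(hit), evaluable = nrow(ta),
       rate = mean(hit))
}
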