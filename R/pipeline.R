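#' Pipeline configuration
#'
#' Collects and validates every stage parameter of the end-to-end
#' fingerprinting pipeline. Seeds are explicit so the random DMST root
#' choice and the cross-test draws are reproducible.
#'
#' @param input_dir Directory of neutral-container runs
#'   (`p<participant>_r<run>.tsv` + sidecars), or `NULL` when `simulate`
#'   is given.
#' @param output_dir Artifact directory (created if missing).
#' @param simulate `NULL`, or a list with `n_participants`, `task_gains`
#'   and optionally `separability`/`density` for an in-memory synthetic
#'   cohort.
#' @param filter A [filter_spec()], or `NULL` to skip filtering.
#' @param artifact_hook Cleaning function for [artifact_removal()].
#' @param m,tau Symbolization embedding parameters.
#' @param dmst_mode,dmst_root Weight orientation and root policy for
#'   [minimum_arborescence()].
#' @param theta,normalize Spectrum coarse-graining parameters.
#' @param reference_run Run whose three events build the reference set.
#' @param n_draws Cross-test draw count (0 skips the cross test).
#' @param seed Master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = tempfile("brainfp_"),
                            simulate = NULL, filter = filter_spec(),
                            artifact_hook = identity, m = 3L, tau = 1L,
                            dmst_mode = "literal", dmst_root = "random",
                            theta = 0.5, normalize = TRUE,
                            reference_run = 1L, n_draws = 0L, seed = 1L) {
  if (is.null(input_dir) && is.null(simulate)) {
    stop("pipeline_config: provide input_dir or simulate")
  }
  if (theta <= 0) stop("pipeline_config: theta must be positive")
  if (m < 2L || tau < 1L) stop("pipeline_config: invalid embedding (m, tau)")
  if (!dmst_mode %in% c("literal", "negate")) {
    stop("pipeline_config: dmst_mode must be literal or negate")
  }
  if (!is.null(filter) && !inherits(filter, "filter_spec")) {
    stop("pipeline_config: filter must be a filter_spec or NULL")
  }
  if (n_draws < 0L) stop("pipeline_config: n_draws must be >= 0")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 simulate = simulate, filter = filter,
                 artifact_hook = artifact_hook, m = m, tau = tau,
                 dmst_mode = dmst_mode, dmst_root = dmst_root,
                 theta = theta, normalize = normalize,
                 reference_run = as.integer(reference_run),
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Preprocess one recording and estimate its coupling matrices
#'
#' The fixed stage order for a single run: band-pass filter the whole run,
#' apply the artifact hook, cut event segments (occurrences of the same
#' code concatenated), first-difference each segment, and estimate one
#' transfer-entropy matrix per event present in the run.
#'
#' @param rec A [recording()].
#' @param config A [pipeline_config()] (filtering/embedding fields used).
#' @return Named list of [ste_matrix()] objects, one per event code.
#' @export
process_recording <- function(rec, config = pipeline_config(simulate = list())) {
  if (!is.null(config$filter)) rec <- bandpass(rec, config$filter)
  rec <- artifact_removal(rec, config$artifact_hook)
  segs <- extract_segments(rec, concatenate_same_event = TRUE)
  out <- lapply(segs, function(s) {
    ste_matrix(first_difference(s), m = config$m, tau = config$tau)
  })
  names(out) <- paste0("e", vapply(segs, function(s) s$event, integer(1)))
  out
}

#' Run the full fingerprinting pipeline
#'
#' Orchestrates read/simulate, preprocessing, transfer-entropy estimation,
#' brain-network construction, spectrum coarse-graining, reference-set
#' fitting and held-out identification, writing every artifact as plain
#' text under `config$output_dir`:
#' `ste/` coupling matrices, `trees/` arborescence edge lists, `grids/`
#' reference fingerprints, `identification.tsv` held-out scores, and
#' `crosstest.tsv` per-draw accuracies when a cross test is configured
#' (three held-out runs required). A `run_log.txt` records the stage
#' parameters and seeds.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted `sdss_ref` reference, the
#'   held-out identification table, the cross-test result (or `NULL`) and
#'   the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("ste", "trees", "grids")) {
    dir.create(file.path(config$output_dir, d), showWarnings = FALSE)
  }
  log_lines <- c(sprintf("brainfp pipeline, seed %d", config$seed),
                 sprintf("theta %g, m %d, tau %d, dmst_mode %s",
                         config$theta, config$m, config$tau, config$dmst_mode))

  # --- load or simulate recordings -------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    cohort <- make_cohort(sim$n_participants,
                          separability = sim$separability %||% 1,
                          density = sim$density %||% 0.05,
                          seed = config$seed)
    recs <- simulate_cohort(cohort, task_gains = sim$task_gains %||% c(1, 1.5, 2, 2.5),
                            seed = config$seed)
    log_lines <- c(log_lines, sprintf("simulated cohort: %d participants, %d runs each",
                                      length(recs), length(recs[[1L]])))
  } else {
    stems <- sort(unique(sub("\\.tsv$", "",
                             list.files(config$input_dir, "^p\\d+_r\\d+\\.tsv$",
                                        full.names = TRUE))))
    stems <- stems[!grepl("\\.events$", stems)]
    if (!length(stems)) stop("run_pipeline: no runs found in ", config$input_dir)
    info <- regmatches(basename(stems),
                       regexec("^p(\\d+)_r(\\d+)$", basename(stems)))
    recs <- list()
    for (k in seq_along(stems)) {
      p <- as.integer(info[[k]][2L]); r <- as.integer(info[[k]][3L])
      rec <- read_recording(stems[k])
      rec$participant_id <- p; rec$run_id <- r
      recs[[as.character(p)]][[r]] <- rec
    }
    log_lines <- c(log_lines, sprintf("loaded %d runs from %s",
                                      length(stems), config$input_dir))
  }

  # --- STE, trees, spectra ---------------------------------------------
  spectra <- vector("list", length(recs))   # spectra[[p]][[run]][[event]]
  for (p in seq_along(recs)) {
    spectra[[p]] <- vector("list", length(recs[[p]]))
    for (r in seq_along(recs[[p]])) {
      rec <- recs[[p]][[r]]
      mats <- process_recording(rec, config)
      for (ev in names(mats)) {
        m <- mats[[ev]]
        stem <- sprintf("p%02d_r%02d_%s", rec$participant_id, r, ev)
        write_ste_matrix(m, file.path(config$output_dir, "ste",
                                      paste0(stem, ".tsv")))
        tree <- minimum_arborescence(from_ste(m, config$dmst_mode),
                                     root = config$dmst_root,
                                     seed = config$seed)
        write_arborescence(tree, file.path(config$output_dir, "trees",
                                           paste0(stem, ".tsv")))
      }
      spectra[[p]][[r]] <- lapply(mats, eigen_spectrum)
    }
  }

  # --- reference fit and held-out identification -----------------------
  ref_run <- config$reference_run
  ref_spectra <- lapply(spectra, function(by_run) by_run[[ref_run]])
  names(ref_spectra) <- as.character(seq_along(spectra))
  ref <- sdss_reference(ref_spectra, theta = config$theta,
                        normalize = config$normalize)
  for (id in ref$participants) {
    write_spectrum_grid(ref$grids[[id]],
                        file.path(config$output_dir, "grids",
                                  sprintf("p%02d.tsv", as.integer(id))))
  }

  rows <- list()
  for (p in seq_along(spectra)) {
    for (r in setdiff(seq_along(spectra[[p]]), ref_run)) {
      for (ev in names(spectra[[p]][[r]])) {
        sc <- predict(ref, spectra[[p]][[r]][[ev]])
        rows[[length(rows) + 1L]] <-
          data.frame(participant = p, run = r, event = ev,
                     winner = as.integer(sc$winner),
                     correct = as.integer(sc$winner) == p,
                     score = max(sc$scores), tie = sc$tie)
      }
    }
  }
  ident <- do.call(rbind, rows)
  utils::write.table(ident, file.path(config$output_dir, "identification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_lines <- c(log_lines, sprintf("held-out identification accuracy: %.4f",
                                    mean(ident$correct)))

  # --- cross test (needs three held-out runs covering everyone) --------
  ct <- NULL
  heldout_runs <- setdiff(seq_along(spectra[[1L]]), ref_run)
  if (config$n_draws > 0L && length(heldout_runs) >= 3L) {
    groups <- lapply(heldout_runs[1:3], function(r) {
      g <- lapply(seq_along(spectra), function(p) {
        evs <- spectra[[p]][[r]]
        evs[[length(evs)]]   # last event of the run as the group's test item
      })
      names(g) <- ref$participants
      g
    })
    ct <- cross_test(ref, groups, n_draws = config$n_draws,
                     seed = config$seed)
    utils::write.table(data.frame(draw = seq_along(ct$accuracies),
                                  accuracy = ct$accuracies),
                       file.path(config$output_dir, "crosstest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c(log_lines, sprintf("cross-test mean accuracy: %.4f (%d draws)",
                                      ct$mean_accuracy, ct$n_draws))
  }

  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  invisible(list(reference = ref, identification = ident, cross_test = ct,
                 output_dir = config$output_dir))
}
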